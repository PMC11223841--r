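# phoenixscore

Apply the Phoenix pediatric sepsis score and criteria to tabular
patient-level data.

The Phoenix criteria define pediatric sepsis as life-threatening organ
dysfunction, measured by a score over four organ systems — respiratory
(0–3), cardiovascular (0–6), coagulation (0–2), neurologic (0–2) — with
age-adjusted thresholds for mean arterial pressure and creatinine.  Writing
`R`, `C`, `G`, `N` for the four sub-scores, the Phoenix sepsis score is

    S = R + C + G + N            (0–13)
    sepsis        ⇔  S ≥ 2
    septic shock  ⇔  S ≥ 2  and  C ≥ 1

An 8-system research extension, Phoenix-8, adds endocrine, immunologic,
renal, and hepatic sub-scores (one point each) for a total of 0–17; the
sepsis and septic-shock indicators never depend on the extra four systems.
Missing inputs map to zero points — the rubric's own convention for
settings where a lab was not ordered or is unavailable — and every
threshold is compared on unrounded floating-point values.

The package is for researchers scoring EHR extracts: one row per
patient/encounter snapshot, any subset of ~25 physiologic, laboratory, and
support variables, consistent results across datasets and sites.  The
emitted sepsis flag is the score criterion only; the clinical definition's
suspected-infection component needs longitudinal order data outside this
row-snapshot model.

## Worked example

A 3-year-old with fever and hypotension is started on a norepinephrine
drip; blood pressure is 67/32 mmHg and a CBC shows platelets 95 ×10³/µL.
Nothing else is recorded.

```r
library(phoenixscore)
phoenix(vasoactive_count = 1,
        map = resolve_map(sbp = 67, dbp = 32),  # 32 + (67-32)/3 = 43.67 mmHg
        platelets = 95, age = 36)
#>   phoenix_respiratory_score phoenix_cardiovascular_score
#> 1                         0                            2
#>   phoenix_coagulation_score phoenix_neurologic_score phoenix_sepsis_total_score
#> 1                         1                        0                          3
#>   phoenix_sepsis phoenix_septic_shock
#> 1              1                    1
```

Respiratory and neurologic score 0 (no data → no points); cardiovascular
scores 2 (one vasoactive agent, plus MAP 43.67 inside the 1-point band
[32, 45) for ages 24–60 months); coagulation scores 1 (platelets below
100).  The total of 3 meets the sepsis threshold (≥ 2), and with a
cardiovascular point present the septic-shock flag is also set.  Flags are
0/1 integers so score tables round-trip through CSV exactly.

Whole tables go through the reader/scorer pair (here on the bundled
synthetic cohort generator):

```r
f <- tempfile(fileext = ".csv")
write_scores(generate_cohort(n = 20, seed = 101), f)
out <- score_table(read_cohort(f), mode = "phoenix8")
head(out, 2)
#>    pid phoenix_respiratory_score phoenix_cardiovascular_score
#> 1 p001                         3                            6
#> 2 p002                         0                            0
#>   phoenix_coagulation_score phoenix_neurologic_score phoenix_sepsis_total_score
#> 1                         2                        2                         13
#> 2                         0                        0                          0
#>   phoenix_sepsis phoenix_septic_shock phoenix_endocrine_score
#> 1              1                    1                       1
#> 2              0                    0                       0
#>   phoenix_immunologic_score phoenix_renal_score phoenix_hepatic_score
#> 1                         1                   1                     1
#> 2                         0                   0                     0
#>   phoenix_8_score
#> 1              17
#> 2               0
```

(Row 1 is the generator's critically-ill sentinel — every block at its
maximum, Phoenix-8 total 17; row 2 is its all-normal sentinel.)

The same pipeline is exposed as a command-line tool:

```sh
exec/phoenix-score fixture --output cohort.csv --n 20 --seed 101
exec/phoenix-score score --input cohort.csv --output scores.csv --mode phoenix8
```

Column names are bound to canonical fields with a YAML/JSON mapping
(`--mapping`, `read_column_map()`); unmapped fields are treated as missing.
Validation is fail-fast with the offending row and column named;
`--lenient` scores the valid rows and writes a sidecar error report.

See `vignettes/phoenix-scoring.Rmd` for the full rubric, the
missing-data and boundary conventions, and the design of the synthetic
generator and boundary grid.

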
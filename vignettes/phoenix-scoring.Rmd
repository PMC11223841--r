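---
title: "Scoring pediatric sepsis with the Phoenix criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pediatric sepsis with the Phoenix criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phoenixscore)
```

## The model

The Phoenix criteria define pediatric sepsis through life-threatening organ
dysfunction rather than inflammatory response.  Four organ systems are
scored — respiratory (0–3), cardiovascular (0–6), coagulation (0–2), and
neurologic (0–2) — and summed into the Phoenix sepsis score (0–13).  A
total of 2 or more points constitutes sepsis (in clinical use, together
with suspected infection; see *Scope* below), and sepsis with at least one
cardiovascular point constitutes septic shock.  A research extension,
Phoenix-8, adds four single-point systems — endocrine, immunologic, renal,
hepatic — for an 8-system total of 0–17.  The flags never depend on the
extra four systems.

Each block is a small threshold rubric:

* **Respiratory** — oxygenation ratios gated by support level.  Three
  points require invasive mechanical ventilation (IMV) with PaO₂:FiO₂
  (PF) < 100 or SpO₂:FiO₂ (SF) < 148; two points IMV with PF < 200 or
  SF < 220; one point any respiratory support with PF < 400 or SF < 292.
  The highest applicable tier wins, and when both ratios are present either
  may trigger a tier.  The SF ratio is physiologically meaningful only when
  SpO₂ ≤ 97 (at higher saturations the oximeter ceiling decouples SpO₂ from
  oxygenation), so `compute_sf_ratio()` returns missing above 97.
* **Cardiovascular** — the sum of three components: vasoactive medications
  (1 point for one agent, 2 for two or more, among systemic dobutamine,
  dopamine, epinephrine, milrinone, norepinephrine, vasopressin), lactate
  (1 point for 5 ≤ lactate < 11 mmol/L, 2 for ≥ 11), and mean arterial
  pressure against age-adjusted cut-points (`phoenix_age_brackets`).
* **Coagulation** — one point each for platelets < 100 ×10³/µL, INR > 1.3,
  D-dimer > 2 mg/L FEU, fibrinogen < 100 mg/dL, capped at 2.
* **Neurologic** — bilaterally fixed pupils score 2 regardless of GCS;
  otherwise total GCS ≤ 10 scores 1.
* **Endocrine** — blood glucose < 50 or > 150 mg/dL (the closed interval
  [50, 150] is normal).
* **Immunologic** — ANC < 500 and/or ALC < 1000 cells/mm³ (one point).
* **Renal** — creatinine at or above the age-adjusted cut-point.
* **Hepatic** — total bilirubin ≥ 4 mg/dL and/or ALT > 102 IU/L (one
  point).

Age is in months, not adjusted for prematurity, and is the only required
input.  The criteria apply to patients under 18 years (< 216 months); older
ages error by default, with `clamp_age = TRUE` available to score them
against the oldest bracket under a warning, since silent extrapolation
would misrepresent the rubric.

## Missing data map to zero points

Any other input may be absent, and absence is a first-class state: a
missing value never satisfies any inequality, and a missing support,
medication, or pupil flag is treated as absent.  An empty snapshot scores
zero in every block.  This is the rubric's own convention — for many labs a
missing value means the test was not ordered, and the criteria are meant to
work in settings where some measurements are unavailable — not an
imputation strategy, and the package performs no other imputation.
A corollary used by the test suite: nulling any single input can never
increase any score.

## Boundary and numeric conventions

All comparisons are on floating-point values with no rounding; the
strict/inclusive form of every inequality follows the software-facing
statement of the rubric (e.g. one lactate point on exactly 5.0, zero MAP
points on exactly the bracket's upper cut).  All cut-points live in two
exported constants, `phoenix_age_brackets` and `phoenix_thresholds`, so the
implementation can be audited against the rubric line by line.  Sub-scores,
totals, and the 0/1 sepsis and septic-shock indicators are returned as
integer columns, which keeps file round-trips exact.

The boundary grid used by the tests probes each threshold at the value and
±0.01 — far above double-precision noise and below clinical resolution.

## Deriving scorer inputs from raw extracts

Real extracts rarely carry PF ratios or agent counts directly, so the
reader derives them:

* `compute_pf_ratio()`, `compute_sf_ratio()` — ratios from PaO₂/SpO₂ and
  FiO₂.  FiO₂ is canonically a fraction in [0.21, 1]; a column recorded in
  percent (values in (1, 100]) is rescaled with one warning per column,
  since both dialects are common.  Values below room air after rescaling
  are rejected.
* `resolve_map()` — a measured mean arterial pressure is used
  preferentially; otherwise MAP is estimated as `dbp + (sbp − dbp)/3`.
  Invasive and oscillometric measurements are not distinguished (the input
  schema carries no source metadata); users who track that hierarchy should
  resolve it upstream and map the result to `map_mmhg`.
* `count_vasoactives()` — the number of agent flags set.

A precomputed `sf_ratio` column is trusted as given — the SpO₂ ≤ 97 gate
cannot be re-checked without the raw SpO₂ — and this assumption is the
user's responsibility when bypassing `spo2_pct`.

`read_cohort()` binds input columns to these canonical fields through a
flat YAML/JSON mapping (`read_column_map()`); with no mapping it picks up
any columns matching the generator's names.  Validation is fail-fast by
default, naming the first offending row and column; `lenient = TRUE`
instead drops invalid rows and reports them in an `errors` attribute (the
CLI writes it to a sidecar file), because silently part-scoring a row with
a corrupt cell is more dangerous than skipping it.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* of a raw pediatric EHR
extract: 27 columns (row id, age, raw respiratory fields with a
none/other/imv support level, six agent flags, systolic/diastolic pressure,
lactate, four coagulation labs, GCS, pupils, glucose, ANC, ALC, creatinine,
bilirubin, ALT), ages stratified round-robin over the six brackets, values
spanning every scoring tier, and realistic per-field missingness (vitals
mostly present, send-out labs often not).  Three sentinel rows anchor
coverage deterministically: row 1 is critically ill in every block, row 2
normal in every block, row 3 sits in the middle MAP tier, so all three MAP
tiers and every block's nonzero score are always represented.  Output is
byte-identical for identical `(n, seed, missingness)`.

The generator draws fields independently given severity anchors; it does
not emulate physiologic correlation between labs, longitudinal
trajectories, or care-setting-dependent missingness patterns.  Tests
passing on it therefore establish the correctness of the scoring logic on
realistic marginal distributions, not clinical performance of the criteria
on real cohorts.

`boundary_grid()` is the deterministic test harness: every threshold at
±0.01 around its value for each age bracket (probed at its lower edge, an
interior age, and just below its upper edge) crossed with the relevant flag
combinations, plus a full cross-block product of representative inputs for
every attainable sub-score level — about 46,000 rows in total.  The
equivalence suite scores the whole grid against an independently coded
naive per-row scorer and requires exact agreement; the test run stays well
under a minute on one CPU at this size.

## Scope and limitations

* The sepsis flag is the **score criterion only**.  The full clinical
  definition also requires suspected infection, operationalized over a
  24-hour encounter window with antimicrobial and microbiology order data;
  that needs longitudinal event data outside this package's one-row-per-
  snapshot input model, and no flag here should be read as a sepsis
  *diagnosis*.
* No time-windowing or worst-value aggregation: each row is scored as
  given.  Selecting the worst values over an encounter window is upstream
  preprocessing.
* No mortality prediction or calibration on top of the score.
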
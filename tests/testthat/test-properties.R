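# Property-style suites over generated inputs: score ranges, missingness and
# clinical monotonicity, additivity, and vectorization consistency.  The
# full-grid oracle equivalence and definition-threshold sweeps live in
# test-acceptance.R.

sub_cols <- c("phoenix_respiratory_score", "phoenix_cardiovascular_score",
              "phoenix_coagulation_score", "phoenix_neurologic_score",
              "phoenix_endocrine_score", "phoenix_immunologic_score",
              "phoenix_renal_score", "phoenix_hepatic_score")

# a reusable random snapshot table spanning all tiers
random_snapshots <- function(n, seed) {
  co <- generate_cohort(n = n, seed = seed)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_scores(co, f)
  read_cohort(f)
}

test_that("every sub-score stays inside its printed range on random sweeps", {
  snaps <- random_snapshots(200, seed = 401)
  s <- score_table(snaps, "phoenix8")
  lims <- c(phoenix_respiratory_score = 3, phoenix_cardiovascular_score = 6,
            phoenix_coagulation_score = 2, phoenix_neurologic_score = 2,
            phoenix_endocrine_score = 1, phoenix_immunologic_score = 1,
            phoenix_renal_score = 1, phoenix_hepatic_score = 1)
  for (col in names(lims)) {
    expect_true(all(s[[col]] >= 0 & s[[col]] <= lims[[col]]), info = col)
  }
  expect_true(all(s$phoenix_sepsis_total_score <= 13))
  expect_true(all(s$phoenix_8_score <= 17))
})

test_that("nulling any single field never increases any score", {
  snaps <- random_snapshots(150, seed = 402)
  base <- score_table(snaps, "phoenix8")
  fields <- setdiff(names(snaps), c("pid", "age_months"))
  flag_fields <- c("on_imv", "on_respiratory_support", "fixed_pupils")
  for (f in fields) {
    nulled <- snaps
    # missing flags are scored as FALSE, so FALSE is the nulled state
    nulled[[f]] <- if (f %in% flag_fields) FALSE else NA
    s <- score_table(nulled, "phoenix8")
    num <- setdiff(names(s), "pid")
    expect_true(all(as.matrix(s[num]) <= as.matrix(base[num])),
                info = paste("scores after nulling", f))
  }
})

test_that("worsening any numeric field in its risk direction never lowers its sub-score", {
  snaps <- random_snapshots(150, seed = 403)
  base <- score_table(snaps, "phoenix8")
  worse <- list(
    pf_ratio = list(function(x) pmax(x - 60, 0), "phoenix_respiratory_score"),
    sf_ratio = list(function(x) pmax(x - 40, 0), "phoenix_respiratory_score"),
    vasoactive_count = list(function(x) pmin(x + 1L, 6L),
                            "phoenix_cardiovascular_score"),
    lactate_mmol_l = list(function(x) x + 3, "phoenix_cardiovascular_score"),
    map_mmhg = list(function(x) pmax(x - 6, 0), "phoenix_cardiovascular_score"),
    platelets_k_ul = list(function(x) x / 2, "phoenix_coagulation_score"),
    inr = list(function(x) x + 0.5, "phoenix_coagulation_score"),
    d_dimer_mg_l = list(function(x) x + 1.5, "phoenix_coagulation_score"),
    fibrinogen_mg_dl = list(function(x) x / 2, "phoenix_coagulation_score"),
    gcs = list(function(x) pmax(x - 3L, 3L), "phoenix_neurologic_score"),
    anc_cells_mm3 = list(function(x) x / 4, "phoenix_immunologic_score"),
    alc_cells_mm3 = list(function(x) x / 4, "phoenix_immunologic_score"),
    creatinine_mg_dl = list(function(x) x + 0.4, "phoenix_renal_score"),
    bilirubin_mg_dl = list(function(x) x + 2, "phoenix_hepatic_score"),
    alt_iu_l = list(function(x) x + 60, "phoenix_hepatic_score"))
  for (f in names(worse)) {
    worsened <- snaps
    worsened[[f]] <- worse[[f]][[1]](snaps[[f]])
    s <- score_table(worsened, "phoenix8")
    col <- worse[[f]][[2]]
    expect_true(all(s[[col]] >= base[[col]]), info = f)
  }
  # flags: turning them on never lowers the block score
  for (f in c("on_imv", "on_respiratory_support", "fixed_pupils")) {
    worsened <- snaps
    worsened[[f]] <- TRUE
    s <- score_table(worsened, "phoenix8")
    col <- if (f == "fixed_pupils") "phoenix_neurologic_score" else
      "phoenix_respiratory_score"
    expect_true(all(s[[col]] >= base[[col]]), info = f)
  }
})

test_that("totals are the sums of their sub-scores and flags are consistent", {
  snaps <- random_snapshots(250, seed = 404)
  s <- score_table(snaps, "phoenix8")
  expect_identical(s$phoenix_sepsis_total_score,
                   s$phoenix_respiratory_score + s$phoenix_cardiovascular_score +
                     s$phoenix_coagulation_score + s$phoenix_neurologic_score)
  expect_identical(s$phoenix_8_score,
                   s$phoenix_sepsis_total_score + s$phoenix_endocrine_score +
                     s$phoenix_immunologic_score + s$phoenix_renal_score +
                     s$phoenix_hepatic_score)
  expect_identical(s$phoenix_sepsis,
                   as.integer(s$phoenix_sepsis_total_score >= 2))
  expect_identical(s$phoenix_septic_shock,
                   as.integer(s$phoenix_sepsis == 1L &
                                s$phoenix_cardiovascular_score >= 1L))
  expect_true(all(s$phoenix_septic_shock <= s$phoenix_sepsis))
})

test_that("scoring a table equals scoring each row independently, including n = 0 and 1", {
  for (n in c(0L, 1L, 25L)) {
    snaps <- random_snapshots(n, seed = 405 + n)
    whole <- score_table(snaps, "phoenix8")
    expect_identical(nrow(whole), n)
    by_row <- lapply(seq_len(n), function(i)
      score_table(snaps[i, , drop = FALSE], "phoenix8"))
    if (n > 0) {
      stacked <- do.call(rbind, by_row)
      rownames(stacked) <- NULL
      expect_identical(stacked, whole)
    }
  }
})
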
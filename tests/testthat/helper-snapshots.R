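# Build snapshot tables for tests: all scorer inputs missing unless given.

snap <- function(..., age_months = 36, n = NULL) {
  given <- list(...)
  base <- list(
    age_months = age_months, pf_ratio = NA_real_, sf_ratio = NA_real_,
    on_imv = NA, on_respiratory_support = NA,
    vasoactive_count = NA_integer_, lactate_mmol_l = NA_real_,
    map_mmhg = NA_real_, platelets_k_ul = NA_real_, inr = NA_real_,
    d_dimer_mg_l = NA_real_, fibrinogen_mg_dl = NA_real_,
    gcs = NA_integer_, fixed_pupils = NA, glucose_mg_dl = NA_real_,
    anc_cells_mm3 = NA_real_, alc_cells_mm3 = NA_real_,
    creatinine_mg_dl = NA_real_, bilirubin_mg_dl = NA_real_,
    alt_iu_l = NA_real_)
  base[names(given)] <- given
  if (is.null(n)) n <- max(vapply(base, length, integer(1)))
  as.data.frame(lapply(base, rep_len, length.out = n))
}

# snapshot table that maxes out every organ block at a given age
max_snapshot <- function(age_months = 36) {
  snap(age_months = age_months, pf_ratio = 50, on_imv = TRUE,
       on_respiratory_support = TRUE, vasoactive_count = 2L,
       lactate_mmol_l = 12, map_mmhg = 5, platelets_k_ul = 40, inr = 2,
       d_dimer_mg_l = 5, fibrinogen_mg_dl = 50, gcs = 3L,
       fixed_pupils = TRUE, glucose_mg_dl = 40, anc_cells_mm3 = 100,
       alc_cells_mm3 = 500, creatinine_mg_dl = 3, bilirubin_mg_dl = 6,
       alt_iu_l = 300)
}
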
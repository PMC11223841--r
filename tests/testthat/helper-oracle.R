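# Independent naive scorer used as the reference in equivalence tests.
# Deliberately scalar, branchy, and hard-coded straight from the rubric
# table: it shares no code or constant tables with the package's vectorized
# implementation.

o_lt <- function(x, cut) !is.na(x) && x < cut
o_gt <- function(x, cut) !is.na(x) && x > cut
o_ge <- function(x, cut) !is.na(x) && x >= cut

oracle_respiratory <- function(pf, sf, imv, support) {
  imv <- isTRUE(imv)
  support <- isTRUE(support) || imv
  if (imv && (o_lt(pf, 100) || o_lt(sf, 148))) return(3L)
  if (imv && (o_lt(pf, 200) || o_lt(sf, 220))) return(2L)
  if (support && (o_lt(pf, 400) || o_lt(sf, 292))) return(1L)
  0L
}

oracle_map_cuts <- function(age) {
  if (age < 1)   return(c(17, 31))
  if (age < 12)  return(c(25, 39))
  if (age < 24)  return(c(31, 44))
  if (age < 60)  return(c(32, 45))
  if (age < 144) return(c(36, 49))
  c(38, 52)
}

oracle_cardiovascular <- function(n_vaso, lactate, map, age) {
  pts <- 0L
  if (!is.na(n_vaso)) {
    if (n_vaso >= 2) pts <- pts + 2L else if (n_vaso == 1) pts <- pts + 1L
  }
  if (o_ge(lactate, 11)) pts <- pts + 2L else if (o_ge(lactate, 5)) pts <- pts + 1L
  cuts <- oracle_map_cuts(age)
  if (o_lt(map, cuts[1])) pts <- pts + 2L else if (o_lt(map, cuts[2])) pts <- pts + 1L
  pts
}

oracle_coagulation <- function(platelets, inr, d_dimer, fibrinogen) {
  pts <- sum(o_lt(platelets, 100), o_gt(inr, 1.3), o_gt(d_dimer, 2),
             o_lt(fibrinogen, 100))
  min(as.integer(pts), 2L)
}

oracle_neurologic <- function(gcs, fixed_pupils) {
  if (isTRUE(fixed_pupils)) return(2L)
  if (!is.na(gcs) && gcs <= 10) return(1L)
  0L
}

oracle_endocrine <- function(glucose) {
  as.integer(o_lt(glucose, 50) || o_gt(glucose, 150))
}

oracle_immunologic <- function(anc, alc) {
  as.integer(o_lt(anc, 500) || o_lt(alc, 1000))
}

oracle_renal <- function(creatinine, age) {
  cut <- if (age < 1) 0.8 else if (age < 12) 0.3 else if (age < 24) 0.4 else
    if (age < 60) 0.6 else if (age < 144) 0.7 else 1.0
  as.integer(o_ge(creatinine, cut))
}

oracle_hepatic <- function(bilirubin, alt) {
  as.integer(o_ge(bilirubin, 4) || o_gt(alt, 102))
}

# Row-by-row scoring of a snapshot table; returns the phoenix8 column set.
oracle_score_table <- function(snapshots) {
  out <- lapply(seq_len(nrow(snapshots)), function(i) {
    r <- snapshots[i, ]
    resp <- oracle_respiratory(r$pf_ratio, r$sf_ratio, r$on_imv,
                               r$on_respiratory_support)
    cv <- oracle_cardiovascular(r$vasoactive_count, r$lactate_mmol_l,
                                r$map_mmhg, r$age_months)
    coag <- oracle_coagulation(r$platelets_k_ul, r$inr, r$d_dimer_mg_l,
                               r$fibrinogen_mg_dl)
    neuro <- oracle_neurologic(r$gcs, r$fixed_pupils)
    endo <- oracle_endocrine(r$glucose_mg_dl)
    imm <- oracle_immunologic(r$anc_cells_mm3, r$alc_cells_mm3)
    renal <- oracle_renal(r$creatinine_mg_dl, r$age_months)
    hep <- oracle_hepatic(r$bilirubin_mg_dl, r$alt_iu_l)
    total <- resp + cv + coag + neuro
    c(phoenix_respiratory_score = resp, phoenix_cardiovascular_score = cv,
      phoenix_coagulation_score = coag, phoenix_neurologic_score = neuro,
      phoenix_sepsis_total_score = total,
      phoenix_sepsis = as.integer(total >= 2),
      phoenix_septic_shock = as.integer(total >= 2 && cv >= 1),
      phoenix_endocrine_score = endo, phoenix_immunologic_score = imm,
      phoenix_renal_score = renal, phoenix_hepatic_score = hep,
      phoenix_8_score = total + endo + imm + renal + hep)
  })
  as.data.frame(do.call(rbind, out))
}
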
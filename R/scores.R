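# Vectorized organ-dysfunction scorers.  Each function maps equal-length (or
# length-1, recycled) input vectors to an integer sub-score vector.  Missing
# inputs contribute zero points: an NA never satisfies any inequality, and
# missing support/medication flags are treated as absent.  This mirrors the
# rubric's development convention that untested values indicate no concern.

#' Respiratory dysfunction score
#'
#' 0-3 points from oxygenation ratios gated by the level of respiratory
#' support.  Three points require invasive mechanical ventilation (IMV) with
#' PaO2:FiO2 < 100 or SpO2:FiO2 < 148; two points IMV with PF < 200 or
#' SF < 220; one point any respiratory support with PF < 400 or SF < 292.
#' The highest applicable tier wins.  When both ratios are present either may
#' trigger a tier.
#'
#' The SF ratio is only physiologically valid when SpO2 <= 97; a precomputed
#' `sf_ratio` is trusted to have been gated upstream (see
#' [compute_sf_ratio()]).
#'
#' @param pf_ratio numeric, PaO2:FiO2 ratio (unitless); NA if unknown.
#' @param sf_ratio numeric, SpO2:FiO2 ratio (unitless, valid only for
#'   SpO2 <= 97); NA if unknown.
#' @param on_imv logical or 0/1, on invasive mechanical ventilation; missing
#'   is treated as `FALSE`.
#' @param on_respiratory_support logical or 0/1, on any respiratory support
#'   (IMV counts: a row with `on_imv = TRUE` is treated as supported
#'   regardless of this flag); missing is treated as `FALSE`.
#' @return integer vector, 0-3 points.
#' @examples
#' phoenix_respiratory(pf_ratio = 90, on_imv = TRUE)                   # 3
#' phoenix_respiratory(pf_ratio = 90, on_respiratory_support = TRUE)   # 1
#' phoenix_respiratory()                                               # 0
#' @export
phoenix_respiratory <- function(pf_ratio = NA_real_, sf_ratio = NA_real_,
                                on_imv = NA, on_respiratory_support = NA) {
  a <- recycle_args(pf_ratio = pf_ratio, sf_ratio = sf_ratio,
                    on_imv = on_imv,
                    on_respiratory_support = on_respiratory_support)
  pf <- assert_nonnegative(a$pf_ratio, "pf_ratio")
  sf <- assert_nonnegative(a$sf_ratio, "sf_ratio")
  imv <- as_flag(a$on_imv, "on_imv")
  support <- as_flag(a$on_respiratory_support, "on_respiratory_support") | imv

  th <- phoenix_thresholds$respiratory
  score <- integer(length(pf))
  score[support & (lt(pf, th[["pf_1pt_below"]]) | lt(sf, th[["sf_1pt_below"]]))] <- 1L
  score[imv     & (lt(pf, th[["pf_2pt_below"]]) | lt(sf, th[["sf_2pt_below"]]))] <- 2L
  score[imv     & (lt(pf, th[["pf_3pt_below"]]) | lt(sf, th[["sf_3pt_below"]]))] <- 3L
  score
}

#' Cardiovascular dysfunction score
#'
#' 0-6 points: the sum of a systemic vasoactive medication component (0, 1,
#' or 2 points for none, one, or two-plus agents among dobutamine, dopamine,
#' epinephrine, milrinone, norepinephrine, vasopressin), a lactate component
#' (1 point for 5 <= lactate < 11 mmol/L, 2 for lactate >= 11), and an
#' age-adjusted mean arterial pressure component (see
#' [phoenix_age_brackets]).  Lactate and MAP are compared as floating-point
#' values; no rounding is applied.
#'
#' @param vasoactive_count integer 0-6, number of distinct systemic
#'   vasoactive agents; missing is treated as 0.  See [count_vasoactives()].
#' @param lactate numeric, mmol/L (arterial or venous); NA if unknown.
#' @param map numeric, mean arterial pressure, mmHg; NA if unknown.  See
#'   [resolve_map()].
#' @param age numeric, age in months (required, not adjusted for
#'   prematurity); must be in `[0, 216)` unless `clamp_age = TRUE`.
#' @param clamp_age logical; if `TRUE`, ages of 216 months (18 years) or more
#'   are scored with the oldest bracket, with a warning, instead of erroring.
#' @return integer vector, 0-6 points.
#' @examples
#' # one pressor, MAP 43.67 mmHg at 36 months -> 1 + 1 = 2 points
#' phoenix_cardiovascular(vasoactive_count = 1, map = 32 + (67 - 32) / 3,
#'                        age = 36)
#' @export
phoenix_cardiovascular <- function(vasoactive_count = NA_integer_,
                                   lactate = NA_real_, map = NA_real_,
                                   age, clamp_age = FALSE) {
  if (missing(age)) stop("'age' (months) is required", call. = FALSE)
  a <- recycle_args(vasoactive_count = vasoactive_count, lactate = lactate,
                    map = map, age = age)
  n_meds <- assert_integerish(a$vasoactive_count, "vasoactive_count", 0, 6)
  lactate <- assert_nonnegative(a$lactate, "lactate")
  map <- assert_nonnegative(a$map, "map")
  idx <- age_bracket_index(as.numeric(a$age), clamp_age = clamp_age)

  med_pts <- integer(length(n_meds))
  med_pts[!is.na(n_meds) & n_meds == 1] <- 1L
  med_pts[!is.na(n_meds) & n_meds >= 2] <- 2L

  th <- phoenix_thresholds$cardiovascular
  lact_pts <- integer(length(lactate))
  lact_pts[ge(lactate, th[["lactate_1pt_lower"]])] <- 1L
  lact_pts[ge(lactate, th[["lactate_2pt_lower"]])] <- 2L

  map_pts <- integer(length(map))
  map_pts[lt(map, phoenix_age_brackets$map_0pt_lower[idx])] <- 1L
  map_pts[lt(map, phoenix_age_brackets$map_1pt_lower[idx])] <- 2L

  med_pts + lact_pts + map_pts
}

#' Coagulation dysfunction score
#'
#' 0-2 points: one point for each abnormal lab (platelets < 100 10^3/uL,
#' INR > 1.3, D-dimer > 2 mg/L FEU, fibrinogen < 100 mg/dL), capped at 2.
#'
#' @param platelets numeric, 10^3/uL.
#' @param inr numeric, international normalized ratio (unitless).
#' @param d_dimer numeric, mg/L FEU.
#' @param fibrinogen numeric, mg/dL.
#' @return integer vector, 0-2 points.
#' @examples
#' phoenix_coagulation(platelets = 95)                     # 1
#' phoenix_coagulation(platelets = 50, inr = 2, d_dimer = 5,
#'                     fibrinogen = 80)                    # 2 (capped)
#' @export
phoenix_coagulation <- function(platelets = NA_real_, inr = NA_real_,
                                d_dimer = NA_real_, fibrinogen = NA_real_) {
  a <- recycle_args(platelets = platelets, inr = inr, d_dimer = d_dimer,
                    fibrinogen = fibrinogen)
  platelets <- assert_nonnegative(a$platelets, "platelets")
  inr <- assert_nonnegative(a$inr, "inr")
  d_dimer <- assert_nonnegative(a$d_dimer, "d_dimer")
  fibrinogen <- assert_nonnegative(a$fibrinogen, "fibrinogen")
  th <- phoenix_thresholds$coagulation
  pts <- lt(platelets, th[["platelets_below"]]) +
    gt(inr, th[["inr_above"]]) +
    gt(d_dimer, th[["d_dimer_above"]]) +
    lt(fibrinogen, th[["fibrinogen_below"]])
  as.integer(pmin(pts, 2L))
}

#' Neurologic dysfunction score
#'
#' 0-2 points: bilaterally fixed pupils score 2 regardless of the Glasgow
#' Coma Scale (GCS); otherwise GCS <= 10 scores 1.
#'
#' @param gcs integer 3-15, total Glasgow Coma Scale (higher is better).
#' @param fixed_pupils logical or 0/1, bilaterally fixed pupils; missing is
#'   treated as `FALSE`.
#' @return integer vector, 0-2 points.
#' @examples
#' phoenix_neurologic(gcs = 8)                      # 1
#' phoenix_neurologic(gcs = 15, fixed_pupils = TRUE) # 2
#' @export
phoenix_neurologic <- function(gcs = NA_integer_, fixed_pupils = NA) {
  a <- recycle_args(gcs = gcs, fixed_pupils = fixed_pupils)
  gcs <- assert_integerish(a$gcs, "gcs", 3, 15)
  fixed <- as_flag(a$fixed_pupils, "fixed_pupils")
  score <- integer(length(gcs))
  score[!is.na(gcs) & gcs <= phoenix_thresholds$neurologic[["gcs_at_or_below"]]] <- 1L
  score[fixed] <- 2L
  score
}

#' Endocrine dysfunction score
#'
#' 0-1 point: blood glucose < 50 or > 150 mg/dL scores 1; the closed interval
#' `[50, 150]` scores 0.
#'
#' @param glucose numeric, blood glucose, mg/dL.
#' @return integer vector, 0-1 points.
#' @export
phoenix_endocrine <- function(glucose = NA_real_) {
  glucose <- assert_nonnegative(glucose, "glucose")
  th <- phoenix_thresholds$endocrine
  as.integer(lt(glucose, th[["glucose_below"]]) | gt(glucose, th[["glucose_above"]]))
}

#' Immunologic dysfunction score
#'
#' 0-1 point from the absolute neutrophil and/or lymphocyte count:
#' ANC < 500 or ALC < 1000 cells/mm^3 scores the single point.
#'
#' @param anc numeric, absolute neutrophil count, cells/mm^3.
#' @param alc numeric, absolute lymphocyte count, cells/mm^3.
#' @return integer vector, 0-1 points.
#' @export
phoenix_immunologic <- function(anc = NA_real_, alc = NA_real_) {
  a <- recycle_args(anc = anc, alc = alc)
  anc <- assert_nonnegative(a$anc, "anc")
  alc <- assert_nonnegative(a$alc, "alc")
  th <- phoenix_thresholds$immunologic
  as.integer(lt(anc, th[["anc_below"]]) | lt(alc, th[["alc_below"]]))
}

#' Renal dysfunction score
#'
#' 0-1 point: creatinine at or above the age-adjusted cut-point (see
#' [phoenix_age_brackets]) scores 1.
#'
#' @param creatinine numeric, serum creatinine, mg/dL.
#' @inheritParams phoenix_cardiovascular
#' @return integer vector, 0-1 points.
#' @export
phoenix_renal <- function(creatinine = NA_real_, age, clamp_age = FALSE) {
  if (missing(age)) stop("'age' (months) is required", call. = FALSE)
  a <- recycle_args(creatinine = creatinine, age = age)
  creatinine <- assert_nonnegative(a$creatinine, "creatinine")
  idx <- age_bracket_index(as.numeric(a$age), clamp_age = clamp_age)
  as.integer(ge(creatinine, phoenix_age_brackets$creatinine_1pt_lower[idx]))
}

#' Hepatic dysfunction score
#'
#' 0-1 point from total bilirubin and/or ALT: bilirubin >= 4 mg/dL or
#' ALT > 102 IU/L scores the single point.
#'
#' @param bilirubin numeric, total bilirubin, mg/dL.
#' @param alt numeric, alanine aminotransferase, IU/L.
#' @return integer vector, 0-1 points.
#' @export
phoenix_hepatic <- function(bilirubin = NA_real_, alt = NA_real_) {
  a <- recycle_args(bilirubin = bilirubin, alt = alt)
  bilirubin <- assert_nonnegative(a$bilirubin, "bilirubin")
  alt <- assert_nonnegative(a$alt, "alt")
  th <- phoenix_thresholds$hepatic
  as.integer(ge(bilirubin, th[["bilirubin_at_or_above"]]) | gt(alt, th[["alt_above"]]))
}

#' Phoenix sepsis score and criteria
#'
#' Applies the 4-system Phoenix rubric element-wise: the total is the sum of
#' the respiratory, cardiovascular, coagulation, and neurologic sub-scores.
#' The score-based sepsis indicator is 1 when the total is at least 2;
#' septic shock additionally requires at least one cardiovascular point.
#'
#' The full clinical sepsis definition also requires suspected infection
#' (operationalized over a 24-hour encounter window with medication and
#' microbiology order data).  That component is outside this package's
#' row-snapshot input model; the `phoenix_sepsis` column is the score
#' criterion only.
#'
#' @inheritParams phoenix_respiratory
#' @inheritParams phoenix_cardiovascular
#' @inheritParams phoenix_coagulation
#' @inheritParams phoenix_neurologic
#' @return A `data.frame` with one row per input element and 7 integer
#'   columns: `phoenix_respiratory_score`, `phoenix_cardiovascular_score`,
#'   `phoenix_coagulation_score`, `phoenix_neurologic_score`,
#'   `phoenix_sepsis_total_score`, `phoenix_sepsis` (0/1), and
#'   `phoenix_septic_shock` (0/1).
#' @examples
#' # 3-year-old on a norepinephrine drip, BP 67/32, platelets 95 K/uL:
#' phoenix(vasoactive_count = 1, map = resolve_map(sbp = 67, dbp = 32),
#'         platelets = 95, age = 36)
#' @export
phoenix <- function(pf_ratio = NA_real_, sf_ratio = NA_real_, on_imv = NA,
                    on_respiratory_support = NA,
                    vasoactive_count = NA_integer_, lactate = NA_real_,
                    map = NA_real_, platelets = NA_real_, inr = NA_real_,
                    d_dimer = NA_real_, fibrinogen = NA_real_,
                    gcs = NA_integer_, fixed_pupils = NA, age,
                    clamp_age = FALSE) {
  if (missing(age)) stop("'age' (months) is required", call. = FALSE)
  a <- recycle_args(
    pf_ratio = pf_ratio, sf_ratio = sf_ratio, on_imv = on_imv,
    on_respiratory_support = on_respiratory_support,
    vasoactive_count = vasoactive_count, lactate = lactate, map = map,
    platelets = platelets, inr = inr, d_dimer = d_dimer,
    fibrinogen = fibrinogen, gcs = gcs, fixed_pupils = fixed_pupils,
    age = age)

  resp <- phoenix_respiratory(a$pf_ratio, a$sf_ratio, a$on_imv,
                              a$on_respiratory_support)
  cv <- phoenix_cardiovascular(a$vasoactive_count, a$lactate, a$map, a$age,
                               clamp_age = clamp_age)
  coag <- phoenix_coagulation(a$platelets, a$inr, a$d_dimer, a$fibrinogen)
  neuro <- phoenix_neurologic(a$gcs, a$fixed_pupils)

  total <- resp + cv + coag + neuro
  sepsis <- as.integer(total >= 2L)
  data.frame(
    phoenix_respiratory_score    = resp,
    phoenix_cardiovascular_score = cv,
    phoenix_coagulation_score    = coag,
    phoenix_neurologic_score     = neuro,
    phoenix_sepsis_total_score   = total,
    phoenix_sepsis               = sepsis,
    phoenix_septic_shock         = as.integer(sepsis == 1L & cv >= 1L)
  )
}

#' Phoenix-8 extended score
#'
#' The research extension of the Phoenix score: everything [phoenix()]
#' returns, plus the endocrine, immunologic, renal, and hepatic sub-scores
#' and the 8-system total (`phoenix_8_score`, 0-17).  The sepsis and septic
#' shock indicators depend only on the 4-system total and the cardiovascular
#' sub-score, never on the four extra systems.
#'
#' @inheritParams phoenix
#' @inheritParams phoenix_endocrine
#' @inheritParams phoenix_immunologic
#' @inheritParams phoenix_renal
#' @inheritParams phoenix_hepatic
#' @return A `data.frame` with one row per input element and 12 integer
#'   columns: the 7 columns of [phoenix()] followed by
#'   `phoenix_endocrine_score`, `phoenix_immunologic_score`,
#'   `phoenix_renal_score`, `phoenix_hepatic_score`, and `phoenix_8_score`.
#' @export
phoenix8 <- function(pf_ratio = NA_real_, sf_ratio = NA_real_, on_imv = NA,
                     on_respiratory_support = NA,
                     vasoactive_count = NA_integer_, lactate = NA_real_,
                     map = NA_real_, platelets = NA_real_, inr = NA_real_,
                     d_dimer = NA_real_, fibrinogen = NA_real_,
                     gcs = NA_integer_, fixed_pupils = NA,
                     glucose = NA_real_, anc = NA_real_, alc = NA_real_,
                     creatinine = NA_real_, bilirubin = NA_real_,
                     alt = NA_real_, age, clamp_age = FALSE) {
  if (missing(age)) stop("'age' (months) is required", call. = FALSE)
  a <- recycle_args(
    pf_ratio = pf_ratio, sf_ratio = sf_ratio, on_imv = on_imv,
    on_respiratory_support = on_respiratory_support,
    vasoactive_count = vasoactive_count, lactate = lactate, map = map,
    platelets = platelets, inr = inr, d_dimer = d_dimer,
    fibrinogen = fibrinogen, gcs = gcs, fixed_pupils = fixed_pupils,
    glucose = glucose, anc = anc, alc = alc, creatinine = creatinine,
    bilirubin = bilirubin, alt = alt, age = age)

  out <- phoenix(a$pf_ratio, a$sf_ratio, a$on_imv, a$on_respiratory_support,
                 a$vasoactive_count, a$lactate, a$map, a$platelets, a$inr,
                 a$d_dimer, a$fibrinogen, a$gcs, a$fixed_pupils, a$age,
                 clamp_age = clamp_age)
  out$phoenix_endocrine_score   <- phoenix_endocrine(a$glucose)
  out$phoenix_immunologic_score <- phoenix_immunologic(a$anc, a$alc)
  out$phoenix_renal_score       <- phoenix_renal(a$creatinine, a$age,
                                                 clamp_age = clamp_age)
  out$phoenix_hepatic_score     <- phoenix_hepatic(a$bilirubin, a$alt)
  out$phoenix_8_score <- out$phoenix_sepsis_total_score +
    out$phoenix_endocrine_score + out$phoenix_immunologic_score +
    out$phoenix_renal_score + out$phoenix_hepatic_score
  out
}
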
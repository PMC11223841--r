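# Helpers that turn raw vitals/labs into the canonical scorer inputs.

# FiO2 is canonically a fraction in [0.21, 1].  Columns recorded as percent
# (values in (1, 100]) are rescaled once with a single warning.
normalize_fio2 <- function(fio2, field = "fio2", quiet = FALSE) {
  fio2 <- assert_nonnegative(fio2, field)
  pct <- !is.na(fio2) & fio2 > 1
  if (any(pct)) {
    if (any(fio2[pct] > 100)) {
      stop(sprintf("'%s' values > 100 are not a valid fraction or percent (rows: %s)",
                   field, index_preview(which(!is.na(fio2) & fio2 > 100))),
           call. = FALSE)
    }
    if (!quiet) {
      warning(sprintf("'%s': %d value(s) > 1 interpreted as percent and divided by 100",
                      field, sum(pct)), call. = FALSE)
    }
    fio2[pct] <- fio2[pct] / 100
  }
  low <- !is.na(fio2) & fio2 < 0.21
  if (any(low)) {
    stop(sprintf("'%s' must be >= 0.21 (room air) after percent rescaling (rows: %s)",
                 field, index_preview(which(low))), call. = FALSE)
  }
  fio2
}

#' PaO2:FiO2 (PF) oxygenation ratio
#'
#' @param pao2 numeric, arterial oxygen pressure, mmHg.
#' @param fio2 numeric, fraction of inspired oxygen in `[0.21, 1]`; values in
#'   `(1, 100]` are interpreted as percent and rescaled with a warning.
#' @return numeric vector, `pao2 / fio2`; NA where either input is missing.
#' @examples
#' compute_pf_ratio(pao2 = 80, fio2 = 0.8)  # 100
#' @export
compute_pf_ratio <- function(pao2, fio2) {
  a <- recycle_args(pao2 = pao2, fio2 = fio2)
  pao2 <- assert_nonnegative(a$pao2, "pao2")
  fio2 <- normalize_fio2(a$fio2)
  pao2 / fio2
}

#' SpO2:FiO2 (SF) oxygenation ratio
#'
#' The SF ratio is only valid when SpO2 <= 97: at higher saturations the
#' oximeter ceiling decouples SpO2 from oxygenation, so the ratio is returned
#' as missing there (and the row can earn no respiratory points from it).
#'
#' @param spo2 numeric, pulse-oximetry oxygen saturation, percent (0-100).
#' @inheritParams compute_pf_ratio
#' @return numeric vector, `spo2 / fio2` where SpO2 <= 97; NA where
#'   SpO2 > 97 or either input is missing.
#' @examples
#' compute_sf_ratio(spo2 = 92, fio2 = 0.4)  # 230
#' compute_sf_ratio(spo2 = 98, fio2 = 0.3)  # NA: ratio not valid
#' @export
compute_sf_ratio <- function(spo2, fio2) {
  a <- recycle_args(spo2 = spo2, fio2 = fio2)
  spo2 <- assert_nonnegative(a$spo2, "spo2")
  bad <- which(!is.na(spo2) & spo2 > 100)
  if (length(bad)) {
    stop(sprintf("'spo2' must be a percent in [0, 100] (rows: %s)",
                 index_preview(bad)), call. = FALSE)
  }
  fio2 <- normalize_fio2(a$fio2)
  out <- spo2 / fio2
  out[!is.na(spo2) & spo2 > 97] <- NA_real_
  out
}

#' Resolve mean arterial pressure
#'
#' Uses a measured MAP preferentially; otherwise estimates it from systolic
#' and diastolic pressure as `dbp + (sbp - dbp) / 3`.  Invasive and
#' oscillometric measurements are not distinguished: any measured value
#' outranks the calculation.
#'
#' @param map_measured numeric, measured mean arterial pressure, mmHg.
#' @param sbp numeric, systolic blood pressure, mmHg.
#' @param dbp numeric, diastolic blood pressure, mmHg.
#' @return numeric vector of MAP, mmHg; NA where no measured MAP and no
#'   complete SBP/DBP pair is available.
#' @examples
#' resolve_map(sbp = 67, dbp = 32)                   # 43.67
#' resolve_map(map_measured = 50, sbp = 67, dbp = 32) # 50
#' @export
resolve_map <- function(map_measured = NA_real_, sbp = NA_real_,
                        dbp = NA_real_) {
  a <- recycle_args(map_measured = map_measured, sbp = sbp, dbp = dbp)
  map_measured <- assert_nonnegative(a$map_measured, "map_measured")
  sbp <- assert_nonnegative(a$sbp, "sbp")
  dbp <- assert_nonnegative(a$dbp, "dbp")
  bad <- which(!is.na(sbp) & !is.na(dbp) & dbp > sbp)
  if (length(bad)) {
    stop(sprintf("'dbp' exceeds 'sbp' (rows: %s)", index_preview(bad)),
         call. = FALSE)
  }
  calc <- dbp + (sbp - dbp) / 3
  ifelse(is.na(map_measured), calc, map_measured)
}

#' Count systemic vasoactive medications
#'
#' Counts the distinct agents in use among the six the cardiovascular block
#' recognizes: dobutamine, dopamine, epinephrine, milrinone, norepinephrine,
#' and vasopressin (any systemic dose).  Missing flags count as not in use.
#'
#' @param dobutamine,dopamine,epinephrine,milrinone,norepinephrine,vasopressin
#'   logical or 0/1 vectors; missing is treated as `FALSE`.
#' @return integer vector in 0-6.
#' @examples
#' count_vasoactives(norepinephrine = TRUE)  # 1
#' @export
count_vasoactives <- function(dobutamine = NA, dopamine = NA,
                              epinephrine = NA, milrinone = NA,
                              norepinephrine = NA, vasopressin = NA) {
  a <- recycle_args(dobutamine = dobutamine, dopamine = dopamine,
                    epinephrine = epinephrine, milrinone = milrinone,
                    norepinephrine = norepinephrine,
                    vasopressin = vasopressin)
  flags <- mapply(as_flag, a, names(a), SIMPLIFY = FALSE)
  as.integer(Reduce(`+`, flags))
}
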
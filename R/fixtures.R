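# Synthetic data: a seeded cohort generator emulating the structure of a
# raw pediatric EHR extract (shape, variable set, plausible values,
# missingness), a hand-built worked-example patient, and a deterministic
# boundary grid for exhaustive threshold testing.  All randomness in the
# package lives in this file; scoring is deterministic.

.cohort_columns <- c(
  "pid", "age_months", "spo2_pct", "fio2", "pao2_mmhg", "resp_support",
  "dobutamine", "dopamine", "epinephrine", "milrinone", "norepinephrine",
  "vasopressin", "sbp_mmhg", "dbp_mmhg", "lactate_mmol_l", "platelets_k_ul",
  "inr", "d_dimer_mg_l", "fibrinogen_mg_dl", "gcs", "fixed_pupils",
  "glucose_mg_dl", "anc_cells_mm3", "alc_cells_mm3", "creatinine_mg_dl",
  "bilirubin_mg_dl", "alt_iu_l")

# default per-field missingness rates: common vitals mostly present,
# send-out labs often not ordered
.default_missingness <- c(
  spo2_pct = 0.05, fio2 = 0.20, pao2_mmhg = 0.60, resp_support = 0.05,
  dobutamine = 0.10, dopamine = 0.10, epinephrine = 0.10, milrinone = 0.10,
  norepinephrine = 0.10, vasopressin = 0.10, sbp_mmhg = 0.05,
  dbp_mmhg = 0.05, lactate_mmol_l = 0.40, platelets_k_ul = 0.15, inr = 0.30,
  d_dimer_mg_l = 0.50, fibrinogen_mg_dl = 0.50, gcs = 0.20,
  fixed_pupils = 0.30, glucose_mg_dl = 0.20, anc_cells_mm3 = 0.30,
  alc_cells_mm3 = 0.30, creatinine_mg_dl = 0.15, bilirubin_mg_dl = 0.30,
  alt_iu_l = 0.30)

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic patient cohort
#'
#' Emits a raw-extract-style table of `n` patient snapshots over the 27
#' columns the scoring pipeline consumes: a row id, age, raw respiratory
#' fields (SpO2, FiO2, PaO2, a none/other/imv support level), the six
#' vasoactive-agent flags, systolic/diastolic pressure, lactate, the four
#' coagulation labs, GCS, pupils, glucose, ANC, ALC, creatinine, bilirubin,
#' and ALT.  Ages are stratified round-robin over the six age brackets, and
#' three sentinel rows anchor the severity range: row 1 is critically ill in
#' every organ block, row 2 is normal in every block, row 3 sits in the
#' middle (1-point) MAP tier, so each cardiovascular MAP tier is always
#' represented.  Remaining rows are random draws spanning all scoring tiers.
#' Per-field missingness is applied to rows 4 onward; when `n >= 5` every
#' optional field is additionally guaranteed at least one missing row.
#'
#' Identical `(n, seed, missingness)` yield an identical table; the caller's
#' RNG state is left untouched.
#'
#' @param n number of rows (default 20).
#' @param seed integer RNG seed.
#' @param missingness `NULL` for the built-in per-field rates, a single
#'   number in `[0, 1]` applied to every optional field, or a named vector
#'   overriding individual fields.
#' @return A data.frame with `n` rows and 27 columns.
#' @examples
#' cohort <- generate_cohort(n = 20, seed = 101)
#' dim(cohort)  # 20 27
#' @export
generate_cohort <- function(n = 20, seed = 101, missingness = NULL) {
  if (length(n) != 1 || is.na(n) || n < 0 || n != round(n)) {
    stop("'n' must be a single non-negative integer", call. = FALSE)
  }
  rates <- .default_missingness
  if (!is.null(missingness)) {
    if (is.null(names(missingness))) {
      if (length(missingness) != 1 || missingness < 0 || missingness > 1) {
        stop("unnamed 'missingness' must be a single rate in [0, 1]",
             call. = FALSE)
      }
      rates[] <- missingness
    } else {
      unknown <- setdiff(names(missingness), names(rates))
      if (length(unknown)) {
        stop(sprintf("unknown field(s) in 'missingness': %s",
                     paste(unknown, collapse = ", ")), call. = FALSE)
      }
      if (any(missingness < 0 | missingness > 1)) {
        stop("'missingness' rates must be in [0, 1]", call. = FALSE)
      }
      rates[names(missingness)] <- missingness
    }
  }
  if (n == 0) {
    out <- generate_cohort(n = 1, seed = seed)[0, ]
    rownames(out) <- NULL
    return(out)
  }

  with_local_seed(seed, {
    br <- phoenix_age_brackets
    bracket <- ((seq_len(n) - 1L) %% 6L) + 1L
    age <- round(stats::runif(n, br$age_lo[bracket],
                              pmin(br$age_hi[bracket], 215.9)), 1)

    fio2 <- sample(c(0.21, 0.3, 0.4, 0.5, 0.6, 0.8, 1.0), n, replace = TRUE)
    d <- data.frame(
      pid = sprintf("p%03d", seq_len(n)),
      age_months = age,
      spo2_pct = round(stats::runif(n, 85, 100), 0),
      fio2 = fio2,
      pao2_mmhg = round(stats::runif(n, 40, 110), 0),
      resp_support = sample(c("none", "other", "imv"), n, replace = TRUE,
                            prob = c(0.5, 0.25, 0.25)),
      dobutamine = stats::rbinom(n, 1, 0.10),
      dopamine = stats::rbinom(n, 1, 0.10),
      epinephrine = stats::rbinom(n, 1, 0.15),
      milrinone = stats::rbinom(n, 1, 0.10),
      norepinephrine = stats::rbinom(n, 1, 0.20),
      vasopressin = stats::rbinom(n, 1, 0.10),
      dbp_mmhg = NA_real_, sbp_mmhg = NA_real_,
      lactate_mmol_l = round(stats::runif(n, 0.5, 14), 1),
      platelets_k_ul = round(stats::runif(n, 20, 450), 0),
      inr = round(stats::runif(n, 0.9, 2.5), 2),
      d_dimer_mg_l = round(stats::runif(n, 0.1, 6), 2),
      fibrinogen_mg_dl = round(stats::runif(n, 60, 400), 0),
      gcs = sample(3:15, n, replace = TRUE),
      fixed_pupils = stats::rbinom(n, 1, 0.10),
      glucose_mg_dl = round(stats::runif(n, 30, 250), 0),
      anc_cells_mm3 = round(stats::runif(n, 100, 9000), 0),
      alc_cells_mm3 = round(stats::runif(n, 200, 4000), 0),
      creatinine_mg_dl = round(stats::runif(n, 0.1, 1.6), 2),
      bilirubin_mg_dl = round(stats::runif(n, 0.2, 6), 1),
      alt_iu_l = round(stats::runif(n, 10, 250), 0))
    d$dbp_mmhg <- round(stats::runif(n, 25, 70), 0)
    d$sbp_mmhg <- d$dbp_mmhg + round(stats::runif(n, 10, 60), 0)

    # sentinel rows: 1 critical everywhere, 2 normal everywhere, 3 mid MAP tier
    map_lo <- br$map_1pt_lower[bracket]
    map_hi <- br$map_0pt_lower[bracket]
    crit <- list(spo2_pct = 88, fio2 = 1.0, pao2_mmhg = 60,
                 resp_support = "imv", norepinephrine = 1L, epinephrine = 1L,
                 lactate_mmol_l = 12.5, platelets_k_ul = 40, inr = 2.1,
                 d_dimer_mg_l = 4.5, fibrinogen_mg_dl = 80, gcs = 3L,
                 fixed_pupils = 1L, glucose_mg_dl = 40, anc_cells_mm3 = 300,
                 alc_cells_mm3 = 700, bilirubin_mg_dl = 5.2, alt_iu_l = 210)
    for (f in names(crit)) d[[f]][1] <- crit[[f]]
    d$dbp_mmhg[1] <- max(map_lo[1] - 5, 5)
    d$sbp_mmhg[1] <- d$dbp_mmhg[1] + 6  # calculated MAP stays below the floor
    d$creatinine_mg_dl[1] <- br$creatinine_1pt_lower[bracket[1]] + 0.2
    if (n >= 2) {
      norm <- list(spo2_pct = 99, fio2 = 0.21, pao2_mmhg = 95,
                   resp_support = "none", dobutamine = 0L, dopamine = 0L,
                   epinephrine = 0L, milrinone = 0L, norepinephrine = 0L,
                   vasopressin = 0L, lactate_mmol_l = 1.1,
                   platelets_k_ul = 250, inr = 1.0, d_dimer_mg_l = 0.3,
                   fibrinogen_mg_dl = 300, gcs = 15L, fixed_pupils = 0L,
                   glucose_mg_dl = 90, anc_cells_mm3 = 4000,
                   alc_cells_mm3 = 2500, bilirubin_mg_dl = 0.4,
                   alt_iu_l = 25)
      for (f in names(norm)) d[[f]][2] <- norm[[f]]
      d$creatinine_mg_dl[2] <- max(br$creatinine_1pt_lower[bracket[2]] - 0.2, 0.05)
      d$dbp_mmhg[2] <- map_hi[2] + 10
      d$sbp_mmhg[2] <- d$dbp_mmhg[2] + 40  # calculated MAP well above cut
    }
    if (n >= 3) {
      mid <- round((map_lo[3] + map_hi[3]) / 2, 1)
      d$dbp_mmhg[3] <- mid - 3
      d$sbp_mmhg[3] <- mid * 3 - 2 * d$dbp_mmhg[3]  # dbp + (sbp-dbp)/3 = mid
    }

    # missingness on non-sentinel rows; one guaranteed NA per optional field
    optional <- names(rates)
    if (n >= 4) {
      for (f in optional) {
        hit <- which(stats::runif(n) < rates[[f]])
        hit <- hit[hit >= 4]
        d[[f]][hit] <- NA
      }
    }
    if (n >= 5) {
      slots <- 4L + (seq_along(optional) - 1L) %% (n - 3L)
      for (k in seq_along(optional)) d[[optional[k]]][slots[k]] <- NA
    }
    d <- d[, .cohort_columns]
    rownames(d) <- NULL
    d
  })
}

#' The worked-example patient
#'
#' A 3-year-old (36 months) started on a norepinephrine drip for hypotension
#' with blood pressure 67/32 mmHg and a platelet count of 95 10^3/uL; every
#' other input unrecorded.  Scoring this row yields respiratory 0,
#' cardiovascular 2 (one agent + 1 MAP point), coagulation 1, neurologic 0,
#' total 3, sepsis and septic shock both flagged.
#'
#' @return A one-row data.frame in the raw 27-column cohort layout.
#' @examples
#' score_table(read_cohort(write_scores(worked_example_row(),
#'                                      tempfile(fileext = ".csv"))))
#' @export
worked_example_row <- function() {
  d <- as.data.frame(stats::setNames(rep(list(NA), length(.cohort_columns)),
                                     .cohort_columns))
  d$pid <- "example-001"
  d$age_months <- 36
  d$norepinephrine <- 1
  d$sbp_mmhg <- 67
  d$dbp_mmhg <- 32
  d$platelets_k_ul <- 95
  d
}

# template snapshot block with all scorer inputs missing
.blank_snapshots <- function(n, age) {
  data.frame(
    age_months = rep(age, length.out = n),
    pf_ratio = NA_real_, sf_ratio = NA_real_,
    on_imv = FALSE, on_respiratory_support = FALSE,
    vasoactive_count = NA_integer_, lactate_mmol_l = NA_real_,
    map_mmhg = NA_real_, platelets_k_ul = NA_real_, inr = NA_real_,
    d_dimer_mg_l = NA_real_, fibrinogen_mg_dl = NA_real_,
    gcs = NA_integer_, fixed_pupils = FALSE, glucose_mg_dl = NA_real_,
    anc_cells_mm3 = NA_real_, alc_cells_mm3 = NA_real_,
    creatinine_mg_dl = NA_real_, bilirubin_mg_dl = NA_real_,
    alt_iu_l = NA_real_)
}

around <- function(x, eps) c(NA, as.vector(rbind(x - eps, x, x + eps)))

#' Deterministic boundary grid
#'
#' An exhaustive sweep of every scoring threshold at the threshold value and
#' `eps` on either side, for each age bracket (probed at its lower edge, an
#' interior age, and just below its upper edge), crossed with the relevant
#' support/pupil flag combinations — plus a full cross-block product of
#' representative inputs for every attainable sub-score level.  Inputs not
#' under test in a block sweep are missing.  Used by the oracle-equivalence
#' and definition-threshold test suites.
#'
#' The generator recomputes its own expected row count from the tier-set
#' sizes and asserts it, so the grid cannot silently lose a stratum.
#'
#' @param eps offset around each threshold (default 0.01: far above
#'   double-precision noise, below clinical resolution).
#' @return A data.frame of patient snapshots in canonical scorer-input
#'   columns, with attribute `"part"` labelling block-sweep vs cross-block
#'   rows.
#' @export
boundary_grid <- function(eps = 0.01) {
  br <- phoenix_age_brackets
  probe_ages <- sort(c(br$age_lo, c(0.5, 6, 18, 36, 100, 180),
                       br$age_hi - eps))
  th <- phoenix_thresholds

  fill <- function(age, values) {
    g <- do.call(expand.grid,
                 c(values, list(KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE)))
    out <- .blank_snapshots(nrow(g), age)
    for (f in names(g)) out[[f]] <- g[[f]]
    out
  }

  parts <- list()
  counts <- integer(0)
  for (age in probe_ages) {
    b <- findInterval(age, .age_breaks)
    resp <- fill(age, list(
      pf_ratio = around(unname(th$respiratory[c("pf_3pt_below", "pf_2pt_below",
                                                "pf_1pt_below")]), eps),
      sf_ratio = around(unname(th$respiratory[c("sf_3pt_below", "sf_2pt_below",
                                                "sf_1pt_below")]), eps),
      support_level = 0:2))
    resp$on_imv <- resp$support_level == 2
    resp$on_respiratory_support <- resp$support_level >= 1
    resp$support_level <- NULL
    cv <- fill(age, list(
      vasoactive_count = c(NA_integer_, 0L, 1L, 2L, 6L),
      lactate_mmol_l = around(unname(th$cardiovascular), eps),
      map_mmhg = around(c(br$map_1pt_lower[b], br$map_0pt_lower[b]), eps)))
    coag <- fill(age, list(
      platelets_k_ul = around(unname(th$coagulation[["platelets_below"]]), eps),
      inr = around(unname(th$coagulation[["inr_above"]]), eps),
      d_dimer_mg_l = around(unname(th$coagulation[["d_dimer_above"]]), eps),
      fibrinogen_mg_dl = around(unname(th$coagulation[["fibrinogen_below"]]), eps)))
    neuro <- fill(age, list(gcs = c(NA_integer_, 3L, 10L, 11L, 15L),
                            fixed_pupils = c(FALSE, TRUE)))
    endo <- fill(age, list(glucose_mg_dl = around(unname(th$endocrine), eps)))
    imm <- fill(age, list(anc_cells_mm3 = around(unname(th$immunologic[["anc_below"]]), eps),
                          alc_cells_mm3 = around(unname(th$immunologic[["alc_below"]]), eps)))
    renal <- fill(age, list(
      creatinine_mg_dl = around(br$creatinine_1pt_lower[b], eps)))
    hep <- fill(age, list(bilirubin_mg_dl = around(unname(th$hepatic[["bilirubin_at_or_above"]]), eps),
                          alt_iu_l = around(unname(th$hepatic[["alt_above"]]), eps)))
    blocks <- list(resp, cv, coag, neuro, endo, imm, renal, hep)
    parts[[length(parts) + 1L]] <- do.call(rbind, blocks)
    counts <- c(counts, sum(vapply(blocks, nrow, integer(1))))
  }
  n_sweep <- nrow(do.call(rbind, parts[1]))  # per-age sweep size
  sweep <- do.call(rbind, parts)
  sweep$part <- "block_sweep"

  # cross-block product: representative input per attainable sub-score level
  cross_ages <- c(0.5, 180)
  cross <- lapply(cross_ages, function(age) {
    b <- findInterval(age, .age_breaks)
    lvl <- expand.grid(
      resp = 0:3, vaso = c(0L, 1L, 2L), lact = 0:2, mapl = 0:2,
      coag = 0:2, neuro = 0:2, endo = 0:1, imm = 0:1, renal = 0:1,
      hep = 0:1, KEEP.OUT.ATTRS = FALSE)
    out <- .blank_snapshots(nrow(lvl), age)
    out$pf_ratio <- c(NA, 350, 150, 50)[lvl$resp + 1L]
    out$on_imv <- lvl$resp >= 2
    out$on_respiratory_support <- lvl$resp >= 1
    out$vasoactive_count <- lvl$vaso
    out$lactate_mmol_l <- c(NA, 6, 12)[lvl$lact + 1L]
    out$map_mmhg <- c(NA, (br$map_1pt_lower[b] + br$map_0pt_lower[b]) / 2,
                      br$map_1pt_lower[b] - 1)[lvl$mapl + 1L]
    out$platelets_k_ul <- c(NA, 50, 50)[lvl$coag + 1L]
    out$inr <- c(NA, NA, 2)[lvl$coag + 1L]
    out$gcs <- c(NA, 5L, NA)[lvl$neuro + 1L]
    out$fixed_pupils <- lvl$neuro == 2
    out$glucose_mg_dl <- c(NA, 40)[lvl$endo + 1L]
    out$anc_cells_mm3 <- c(NA, 200)[lvl$imm + 1L]
    out$creatinine_mg_dl <- c(NA, br$creatinine_1pt_lower[b] + 1)[lvl$renal + 1L]
    out$bilirubin_mg_dl <- c(NA, 6)[lvl$hep + 1L]
    out
  })
  cross <- do.call(rbind, cross)
  cross$part <- "cross_block"

  grid <- rbind(sweep, cross)
  rownames(grid) <- NULL

  # self-consistency: recompute the expected count from tier-set sizes
  n_resp <- 10 * 10 * 3
  n_cv <- 5 * 7 * 7
  n_coag <- 4^4
  n_expected <- length(probe_ages) *
    (n_resp + n_cv + n_coag + 5 * 2 + 7 + 4 * 4 + 4 + 4 * 4) +
    length(cross_ages) * (4 * 3 * 3 * 3 * 3 * 3 * 2 * 2 * 2 * 2)
  stopifnot(identical(counts, rep(n_sweep, length(probe_ages))),
            nrow(grid) == n_expected)
  grid
}
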
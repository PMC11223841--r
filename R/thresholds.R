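# All numeric cut-points used by the scorers live in this file, in one
# declarative table per block, so the rubric can be audited line by line.

#' Age brackets with age-adjusted MAP and creatinine cut-points
#'
#' The Phoenix rubric adjusts two thresholds for age, measured in months and
#' not adjusted for prematurity.  The six brackets are half-open
#' `[lo, hi)` and contiguous over `[0, 216)` months (0 to <18 years).
#'
#' For mean arterial pressure (MAP, mmHg) each bracket carries two lower
#' bounds: below `map_1pt_lower` scores 2 cardiovascular points, the interval
#' `[map_1pt_lower, map_0pt_lower)` scores 1, and at or above `map_0pt_lower`
#' scores 0.  For creatinine (mg/dL), values at or above
#' `creatinine_1pt_lower` score the single renal point.
#'
#' @format A data frame with 6 rows and 5 columns:
#' \describe{
#'   \item{age_lo, age_hi}{bracket bounds in months, half-open `[lo, hi)`}
#'   \item{map_1pt_lower}{MAP below this scores 2 points, mmHg}
#'   \item{map_0pt_lower}{MAP at/above this scores 0 points, mmHg}
#'   \item{creatinine_1pt_lower}{creatinine at/above this scores 1 point, mg/dL}
#' }
#' @export
phoenix_age_brackets <- data.frame(
  age_lo               = c(0,   1,  12,  24,  60, 144),
  age_hi               = c(1,  12,  24,  60, 144, 216),
  map_1pt_lower        = c(17, 25,  31,  32,  36,  38),
  map_0pt_lower        = c(31, 39,  44,  45,  49,  52),
  creatinine_1pt_lower = c(0.8, 0.3, 0.4, 0.6, 0.7, 1.0)
)

#' Scalar scoring thresholds
#'
#' Non-age-adjusted cut-points of the Phoenix rubric, grouped by organ block.
#' All comparisons are performed on floating-point values without rounding.
#' Strictness of each comparison follows the software-facing form of the
#' rubric, e.g. 1 cardiovascular lactate point for `5 <= lactate < 11`.
#'
#' @format A named list of named numeric vectors, one element per organ block.
#' @export
phoenix_thresholds <- list(
  respiratory = c(
    pf_1pt_below = 400, pf_2pt_below = 200, pf_3pt_below = 100,
    sf_1pt_below = 292, sf_2pt_below = 220, sf_3pt_below = 148
  ),
  cardiovascular = c(lactate_1pt_lower = 5, lactate_2pt_lower = 11),
  coagulation = c(
    platelets_below = 100,  # 10^3/uL
    inr_above       = 1.3,
    d_dimer_above   = 2,    # mg/L FEU
    fibrinogen_below = 100  # mg/dL
  ),
  neurologic  = c(gcs_at_or_below = 10),
  endocrine   = c(glucose_below = 50, glucose_above = 150),  # mg/dL
  immunologic = c(anc_below = 500, alc_below = 1000),        # cells/mm^3
  hepatic     = c(bilirubin_at_or_above = 4, alt_above = 102)
)

# months breaks for findInterval(): [0,1,12,24,60,144,216)
.age_breaks <- c(phoenix_age_brackets$age_lo, 216)

# Bracket index (1..6) for each age; age >= 216 or < 0 errors unless
# clamp_age = TRUE, which clamps to the nearest bracket with a warning.
age_bracket_index <- function(age, clamp_age = FALSE, field = "age") {
  if (any(is.na(age))) {
    stop(sprintf("'%s' is required and may not be missing (rows: %s)",
                 field, index_preview(which(is.na(age)))), call. = FALSE)
  }
  if (any(age < 0)) {
    stop(sprintf("'%s' must be non-negative (rows: %s)",
                 field, index_preview(which(age < 0))), call. = FALSE)
  }
  over <- age >= 216
  if (any(over)) {
    if (!clamp_age) {
      stop(sprintf(paste0(
        "'%s' must be < 216 months; the rubric was developed for patients ",
        "under 18 years (rows: %s). Set clamp_age = TRUE to score such rows ",
        "with the oldest bracket."), field, index_preview(which(over))),
        call. = FALSE)
    }
    warning(sprintf("%d row(s) with age >= 216 months clamped to the 144-216 month bracket",
                    sum(over)), call. = FALSE)
    age[over] <- 215
  }
  findInterval(age, .age_breaks, rightmost.closed = FALSE)
}
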
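# Reading delimited patient tables, mapping user columns to canonical
# fields, normalizing raw vitals/labs into scorer inputs, and writing score
# tables back out.

# Canonical raw fields and how each is parsed.  A mapping binds canonical
# field -> input column name; unmapped fields are absent (missing) for all
# rows.  Either a raw form (e.g. spo2_pct + fio2) or a precomputed form
# (sf_ratio) of an input may be mapped.
.canonical_fields <- list(
  pid              = "id",
  age_months       = "numeric",
  spo2_pct         = "numeric",
  fio2             = "numeric",
  pao2_mmhg        = "numeric",
  pf_ratio         = "numeric",
  sf_ratio         = "numeric",
  resp_support     = "support",   # none / other / imv
  on_imv           = "flag",
  on_respiratory_support = "flag",
  dobutamine       = "flag",
  dopamine         = "flag",
  epinephrine      = "flag",
  milrinone        = "flag",
  norepinephrine   = "flag",
  vasopressin      = "flag",
  vasoactive_count = "numeric",
  sbp_mmhg         = "numeric",
  dbp_mmhg         = "numeric",
  map_measured_mmhg = "numeric",
  map_mmhg         = "numeric",
  lactate_mmol_l   = "numeric",
  platelets_k_ul   = "numeric",
  inr              = "numeric",
  d_dimer_mg_l     = "numeric",
  fibrinogen_mg_dl = "numeric",
  gcs              = "numeric",
  fixed_pupils     = "flag",
  glucose_mg_dl    = "numeric",
  anc_cells_mm3    = "numeric",
  alc_cells_mm3    = "numeric",
  creatinine_mg_dl = "numeric",
  bilirubin_mg_dl  = "numeric",
  alt_iu_l         = "numeric"
)

# Canonical snapshot columns produced by normalization (scorer inputs).
.snapshot_fields <- c(
  "age_months", "pf_ratio", "sf_ratio", "on_imv", "on_respiratory_support",
  "vasoactive_count", "lactate_mmol_l", "map_mmhg", "platelets_k_ul", "inr",
  "d_dimer_mg_l", "fibrinogen_mg_dl", "gcs", "fixed_pupils",
  "glucose_mg_dl", "anc_cells_mm3", "alc_cells_mm3", "creatinine_mg_dl",
  "bilirubin_mg_dl", "alt_iu_l")

#' Default column mapping
#'
#' The identity mapping over the column names the bundled synthetic-cohort
#' generator emits ([generate_cohort()]), so the quickstart needs no mapping
#' file.  When used implicitly by [read_cohort()] (`mapping = NULL`), only
#' the columns actually present in the input are mapped; an explicit mapping
#' is enforced strictly instead.
#'
#' @return Named character vector, canonical field -> column name.
#' @export
default_column_map <- function() {
  fields <- c("pid", "age_months", "spo2_pct", "fio2", "pao2_mmhg",
              "resp_support", "dobutamine", "dopamine", "epinephrine",
              "milrinone", "norepinephrine", "vasopressin", "sbp_mmhg",
              "dbp_mmhg", "lactate_mmol_l", "platelets_k_ul", "inr",
              "d_dimer_mg_l", "fibrinogen_mg_dl", "gcs", "fixed_pupils",
              "glucose_mg_dl", "anc_cells_mm3", "alc_cells_mm3",
              "creatinine_mg_dl", "bilirubin_mg_dl", "alt_iu_l")
  stats::setNames(fields, fields)
}

#' Read a column mapping from a YAML or JSON file
#'
#' The file is a flat object whose keys are canonical field names (see
#' [default_column_map()] and the package vignette) and whose values are the
#' corresponding column names in the input table.  The format is chosen by
#' extension: `.yaml`/`.yml` or `.json`.
#'
#' @param path path to the mapping file.
#' @return Named character vector, canonical field -> column name.
#' @export
read_column_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop(sprintf("unsupported mapping format '.%s' (use .yaml, .yml, or .json)",
                 ext), call. = FALSE))
  if (is.null(names(raw)) || any(names(raw) == "")) {
    stop("mapping file must be a named field -> column object", call. = FALSE)
  }
  out <- vapply(raw, function(v) as.character(v)[1], character(1))
  validate_mapping(out)
  out
}

validate_mapping <- function(mapping) {
  unknown <- setdiff(names(mapping), names(.canonical_fields))
  if (length(unknown)) {
    stop(sprintf("unknown canonical field(s) in mapping: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  dup <- mapping[duplicated(mapping)]
  if (length(dup)) {
    stop(sprintf("column(s) mapped to more than one canonical field: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  invisible(mapping)
}

# -- cell parsers (input is character; "" already read as NA) ---------------

parse_numeric_col <- function(x, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  list(values = v,
       errors = cell_errors(bad, col, sprintf("cannot parse '%s' as a number",
                                              x[bad])))
}

parse_flag_col <- function(x, col) {
  lx <- tolower(trimws(as.character(x)))
  v <- rep(NA, length(x))
  v[lx %in% c("1", "true", "t", "yes", "y")] <- TRUE
  v[lx %in% c("0", "false", "f", "no", "n")] <- FALSE
  bad <- which(!is.na(x) & is.na(v))
  list(values = v,
       errors = cell_errors(bad, col, sprintf("cannot parse '%s' as a 0/1 flag",
                                              x[bad])))
}

parse_support_col <- function(x, col) {
  lx <- tolower(trimws(as.character(x)))
  v <- rep(NA_character_, length(x))
  v[lx %in% c("none", "0")] <- "none"
  v[lx %in% c("other", "1")] <- "other"
  v[lx %in% c("imv", "2")] <- "imv"
  bad <- which(!is.na(x) & is.na(v))
  list(values = v,
       errors = cell_errors(bad, col,
                            sprintf("'%s' is not one of none/other/imv", x[bad])))
}

cell_errors <- function(rows, col, msgs) {
  if (!length(rows)) return(empty_errors())
  data.frame(row = rows, field = col, message = msgs,
             stringsAsFactors = FALSE)
}

empty_errors <- function() {
  data.frame(row = integer(0), field = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

# -- domain checks on parsed raw values, collected per row ------------------

check_range <- function(x, col, lo = 0, hi = Inf, msg) {
  bad <- which(!is.na(x) & (x < lo | x > hi))
  cell_errors(bad, col, rep_len(msg, length(bad)))
}

raw_domain_errors <- function(raw, mapping, clamp_age) {
  errs <- list(empty_errors())
  colname <- function(f) unname(mapping[[f]])
  for (f in names(raw)) {
    kind <- .canonical_fields[[f]]
    if (identical(kind, "numeric") &&
        !f %in% c("gcs", "vasoactive_count", "age_months")) {
      errs[[length(errs) + 1L]] <-
        check_range(raw[[f]], colname(f), lo = 0,
                    msg = "negative value not allowed")
    }
  }
  if (!is.null(raw$age_months)) {
    age <- raw$age_months
    bad_na <- which(is.na(age))
    errs[[length(errs) + 1L]] <-
      cell_errors(bad_na, colname("age_months"),
                  rep_len("age is required", length(bad_na)))
    errs[[length(errs) + 1L]] <-
      check_range(age, colname("age_months"), lo = 0,
                  hi = if (clamp_age) Inf else 216 - 1e-9,
                  msg = "age must be in [0, 216) months")
  }
  if (!is.null(raw$spo2_pct)) {
    errs[[length(errs) + 1L]] <-
      check_range(raw$spo2_pct, colname("spo2_pct"), 0, 100,
                  "SpO2 must be a percent in [0, 100]")
  }
  if (!is.null(raw$fio2)) {
    fio2 <- raw$fio2
    bad <- which(!is.na(fio2) &
                   (fio2 > 100 | (fio2 < 0.21) | (fio2 > 1 & fio2 < 21)))
    errs[[length(errs) + 1L]] <-
      cell_errors(bad, colname("fio2"),
                  rep_len("FiO2 must be a fraction in [0.21, 1] or percent in [21, 100]",
                          length(bad)))
  }
  if (!is.null(raw$gcs)) {
    g <- raw$gcs
    bad <- which(!is.na(g) & (g < 3 | g > 15 | g != round(g)))
    errs[[length(errs) + 1L]] <-
      cell_errors(bad, colname("gcs"),
                  rep_len("GCS must be an integer in [3, 15]", length(bad)))
  }
  if (!is.null(raw$vasoactive_count)) {
    v <- raw$vasoactive_count
    bad <- which(!is.na(v) & (v < 0 | v > 6 | v != round(v)))
    errs[[length(errs) + 1L]] <-
      cell_errors(bad, colname("vasoactive_count"),
                  rep_len("vasoactive count must be an integer in [0, 6]",
                          length(bad)))
  }
  if (!is.null(raw$sbp_mmhg) && !is.null(raw$dbp_mmhg)) {
    s <- raw$sbp_mmhg; d <- raw$dbp_mmhg
    bad <- which(!is.na(s) & !is.na(d) & d > s)
    errs[[length(errs) + 1L]] <-
      cell_errors(bad, colname("dbp_mmhg"),
                  rep_len("diastolic pressure exceeds systolic", length(bad)))
  }
  do.call(rbind, errs)
}

# -- normalization: raw fields -> snapshot columns --------------------------

normalize_raw <- function(raw, n, verbose = FALSE) {
  get <- function(f, default = rep(NA_real_, n)) {
    if (is.null(raw[[f]])) default else raw[[f]]
  }
  note <- function(...) if (verbose) message(sprintf(...))

  fio2 <- raw$fio2
  if (!is.null(fio2)) {
    pct <- sum(!is.na(fio2) & fio2 > 1)
    fio2 <- normalize_fio2(fio2, quiet = TRUE)
    if (pct > 0) note("fio2: %d value(s) rescaled from percent to fraction", pct)
  }

  pf <- raw$pf_ratio
  if (is.null(pf)) {
    pf <- if (!is.null(raw$pao2_mmhg) && !is.null(fio2)) {
      note("pf_ratio derived from pao2/fio2")
      raw$pao2_mmhg / fio2
    } else rep(NA_real_, n)
  }
  sf <- raw$sf_ratio
  if (is.null(sf)) {
    sf <- if (!is.null(raw$spo2_pct) && !is.null(fio2)) {
      note("sf_ratio derived from spo2/fio2 (missing where SpO2 > 97)")
      compute_sf_ratio(raw$spo2_pct, fio2)
    } else rep(NA_real_, n)
  }

  if (!is.null(raw$resp_support)) {
    imv <- !is.na(raw$resp_support) & raw$resp_support == "imv"
    support <- !is.na(raw$resp_support) & raw$resp_support != "none"
  } else {
    imv <- as_flag(get("on_imv", rep(NA, n)), "on_imv")
    support <- as_flag(get("on_respiratory_support", rep(NA, n)),
                       "on_respiratory_support") | imv
  }

  n_vaso <- raw$vasoactive_count
  if (is.null(n_vaso)) {
    agents <- c("dobutamine", "dopamine", "epinephrine", "milrinone",
                "norepinephrine", "vasopressin")
    present <- intersect(agents, names(raw))
    n_vaso <- if (length(present)) {
      args <- stats::setNames(lapply(present, function(f) raw[[f]]), present)
      do.call(count_vasoactives, args)
    } else rep(NA_integer_, n)
  }

  map <- raw$map_mmhg
  if (is.null(map)) {
    map <- resolve_map(get("map_measured_mmhg"), get("sbp_mmhg"),
                       get("dbp_mmhg"))
  }

  out <- data.frame(
    age_months = get("age_months"),
    pf_ratio = pf, sf_ratio = sf,
    on_imv = imv, on_respiratory_support = support,
    vasoactive_count = n_vaso,
    lactate_mmol_l = get("lactate_mmol_l"),
    map_mmhg = map,
    platelets_k_ul = get("platelets_k_ul"),
    inr = get("inr"),
    d_dimer_mg_l = get("d_dimer_mg_l"),
    fibrinogen_mg_dl = get("fibrinogen_mg_dl"),
    gcs = get("gcs"),
    fixed_pupils = as_flag(get("fixed_pupils", rep(NA, n)), "fixed_pupils"),
    glucose_mg_dl = get("glucose_mg_dl"),
    anc_cells_mm3 = get("anc_cells_mm3"),
    alc_cells_mm3 = get("alc_cells_mm3"),
    creatinine_mg_dl = get("creatinine_mg_dl"),
    bilirubin_mg_dl = get("bilirubin_mg_dl"),
    alt_iu_l = get("alt_iu_l"))
  if (!is.null(raw$pid)) out <- cbind(pid = raw$pid, out)
  out
}

#' Read and normalize a patient cohort table
#'
#' Reads a delimited file (CSV by default), binds its columns to canonical
#' fields via a mapping, parses and validates cells, and derives the scorer
#' inputs: oxygenation ratios from raw PaO2/SpO2/FiO2, MAP from measured MAP
#' or systolic/diastolic pressure, the vasoactive-agent count from the six
#' agent flags, and the respiratory-support indicators.  Empty cells are
#' missing; missing stays missing (it is mapped to zero points only at
#' scoring time).
#'
#' @param path path to a delimited text file with a header row (UTF-8).
#' @param mapping named character vector (canonical field -> column name),
#'   e.g. from [read_column_map()].  `NULL` (default) auto-maps any columns
#'   whose names match [default_column_map()].  With an explicit mapping,
#'   every mapped column must exist in the input.
#' @param sep field separator: `","` (default) or `"\t"`.
#' @param lenient if `FALSE` (default), the first validation problem aborts
#'   with row and column identified.  If `TRUE`, offending rows are dropped
#'   and returned in the `"errors"` attribute (a data.frame with `row`,
#'   `field`, `message`).
#' @param clamp_age passed through to age validation; see
#'   [phoenix_cardiovascular()].
#' @param verbose if `TRUE`, per-column normalization notes are emitted as
#'   messages.
#' @return A data.frame of patient snapshots, one row per (valid) input row,
#'   with the canonical scorer-input columns (plus `pid` when mapped), and
#'   attributes `errors` (lenient mode) and `source_rows` (original row
#'   numbers).
#' @export
read_cohort <- function(path, mapping = NULL, sep = ",", lenient = FALSE,
                        clamp_age = FALSE, verbose = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  tbl <- utils::read.csv(path, sep = sep, colClasses = "character",
                         check.names = FALSE, na.strings = c("", "NA"),
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")

  auto <- is.null(mapping)
  if (auto) mapping <- default_column_map()
  validate_mapping(mapping)
  missing_cols <- setdiff(unname(mapping), names(tbl))
  if (length(missing_cols)) {
    if (auto) {
      mapping <- mapping[!mapping %in% missing_cols]
    } else {
      stop(sprintf("mapped column(s) not in input: %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
  }
  if (!"age_months" %in% names(mapping)) {
    stop("an 'age_months' column mapping is required", call. = FALSE)
  }

  n <- nrow(tbl)
  raw <- list()
  errors <- list(empty_errors())
  for (f in names(mapping)) {
    x <- tbl[[mapping[[f]]]]
    parsed <- switch(.canonical_fields[[f]],
      id      = list(values = x, errors = empty_errors()),
      numeric = parse_numeric_col(x, mapping[[f]]),
      flag    = parse_flag_col(x, mapping[[f]]),
      support = parse_support_col(x, mapping[[f]]))
    raw[[f]] <- parsed$values
    errors[[length(errors) + 1L]] <- parsed$errors
  }
  errors[[length(errors) + 1L]] <- raw_domain_errors(raw, mapping, clamp_age)
  errors <- do.call(rbind, errors)
  errors <- errors[order(errors$row), , drop = FALSE]
  rownames(errors) <- NULL

  if (nrow(errors) && !lenient) {
    msgs <- sprintf("row %d, column '%s': %s", utils::head(errors$row, 10),
                    utils::head(errors$field, 10),
                    utils::head(errors$message, 10))
    more <- if (nrow(errors) > 10) sprintf("\n... and %d more", nrow(errors) - 10) else ""
    stop(sprintf("%d validation error(s) in %s:\n%s%s", nrow(errors), path,
                 paste(msgs, collapse = "\n"), more), call. = FALSE)
  }

  keep <- setdiff(seq_len(n), unique(errors$row))
  raw <- lapply(raw, function(x) x[keep])
  if (lenient && length(keep) < n && verbose) {
    message(sprintf("dropped %d invalid row(s); %d scored", n - length(keep),
                    length(keep)))
  }
  out <- normalize_raw(raw, length(keep), verbose = verbose)
  attr(out, "errors") <- errors
  attr(out, "source_rows") <- keep
  out
}

#' Score a cohort of patient snapshots
#'
#' Applies the Phoenix or Phoenix-8 rubric element-wise to a snapshot table
#' (as returned by [read_cohort()] or built by hand with the canonical
#' column names).  Row order and count are preserved; a `pid` column, when
#' present, is carried through as the first output column.
#'
#' @param snapshots data.frame of canonical snapshot columns; unlisted
#'   columns are treated as all-missing.
#' @param mode `"phoenix"` (7 score columns) or `"phoenix8"` (12).
#' @param clamp_age see [phoenix_cardiovascular()].
#' @return A data.frame of integer scores; see [phoenix()] and [phoenix8()].
#' @export
score_table <- function(snapshots, mode = c("phoenix", "phoenix8"),
                        clamp_age = FALSE) {
  mode <- match.arg(mode)
  n <- nrow(snapshots)
  get <- function(f, default = NA) {
    if (is.null(snapshots[[f]])) rep(default, n) else snapshots[[f]]
  }
  if (is.null(snapshots[["age_months"]])) {
    stop("'snapshots' must contain an 'age_months' column", call. = FALSE)
  }
  common <- list(
    pf_ratio = get("pf_ratio", NA_real_), sf_ratio = get("sf_ratio", NA_real_),
    on_imv = get("on_imv"), on_respiratory_support = get("on_respiratory_support"),
    vasoactive_count = get("vasoactive_count", NA_integer_),
    lactate = get("lactate_mmol_l", NA_real_), map = get("map_mmhg", NA_real_),
    platelets = get("platelets_k_ul", NA_real_), inr = get("inr", NA_real_),
    d_dimer = get("d_dimer_mg_l", NA_real_),
    fibrinogen = get("fibrinogen_mg_dl", NA_real_),
    gcs = get("gcs", NA_integer_), fixed_pupils = get("fixed_pupils"),
    age = snapshots[["age_months"]], clamp_age = clamp_age)
  out <- if (mode == "phoenix") {
    do.call(phoenix, common)
  } else {
    do.call(phoenix8, c(common, list(
      glucose = get("glucose_mg_dl", NA_real_),
      anc = get("anc_cells_mm3", NA_real_), alc = get("alc_cells_mm3", NA_real_),
      creatinine = get("creatinine_mg_dl", NA_real_),
      bilirubin = get("bilirubin_mg_dl", NA_real_),
      alt = get("alt_iu_l", NA_real_))))
  }
  if (!is.null(snapshots[["pid"]])) {
    out <- cbind(pid = snapshots[["pid"]], out)
  }
  rownames(out) <- NULL
  out
}

#' Write a score table to CSV
#'
#' Deterministic column order (as in the input table), integers written
#' without decimal points, flags as 0/1, `NA` cells empty.
#'
#' @param table data.frame, e.g. from [score_table()] or [generate_cohort()].
#' @param path output path; the directory must exist and be writable.
#' @return `path`, invisibly.
#' @export
write_scores <- function(table, path) {
  ok <- tryCatch({
    utils::write.csv(table, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
         call. = FALSE)
  }
  invisible(path)
}
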
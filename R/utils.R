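# Internal helpers: argument recycling, validation, missing-safe comparisons.

index_preview <- function(idx, limit = 5L) {
  shown <- paste(utils::head(idx, limit), collapse = ", ")
  if (length(idx) > limit) shown <- paste0(shown, ", ... (", length(idx), " total)")
  shown
}

# Recycle arguments to a common length; lengths must be 1 or equal.
# Returns a list of equal-length vectors (length 0 if any input has length 0).
recycle_args <- function(...) {
  args <- list(...)
  lens <- vapply(args, length, integer(1))
  n <- if (any(lens == 0L)) 0L else max(lens, 1L)
  bad <- lens != n & lens != 1L & lens != 0L
  if (any(bad)) {
    stop(sprintf("arguments must have length 1 or %d; '%s' has length %d",
                 n, names(args)[bad][1], lens[bad][1]), call. = FALSE)
  }
  lapply(args, rep_len, length.out = n)
}

assert_nonnegative <- function(x, field) {
  if (!is.numeric(x) && !all(is.na(x))) {
    stop(sprintf("'%s' must be numeric", field), call. = FALSE)
  }
  bad <- which(!is.na(x) & x < 0)
  if (length(bad)) {
    stop(sprintf("'%s' must be non-negative (rows: %s)", field,
                 index_preview(bad)), call. = FALSE)
  }
  as.numeric(x)
}

assert_integerish <- function(x, field, lo, hi) {
  x <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & (x < lo | x > hi | x != round(x)))
  if (length(bad)) {
    stop(sprintf("'%s' must be an integer in [%s, %s] (rows: %s)",
                 field, lo, hi, index_preview(bad)), call. = FALSE)
  }
  x
}

# Coerce a logical/0-1 flag vector; missing maps to FALSE.
as_flag <- function(x, field) {
  if (is.logical(x)) {
    out <- x
  } else if (is.numeric(x)) {
    bad <- which(!is.na(x) & !x %in% c(0, 1))
    if (length(bad)) {
      stop(sprintf("'%s' must be logical or 0/1 (rows: %s)", field,
                   index_preview(bad)), call. = FALSE)
    }
    out <- x == 1
  } else {
    stop(sprintf("'%s' must be logical or 0/1", field), call. = FALSE)
  }
  out[is.na(out)] <- FALSE
  out
}

# Missing-safe comparisons: NA never satisfies the inequality.
lt <- function(x, cut) !is.na(x) & x < cut
gt <- function(x, cut) !is.na(x) & x > cut
ge <- function(x, cut) !is.na(x) & x >= cut
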
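#' Day-by-minute heart-rate matrix
#'
#' The central container of the package: a numeric matrix with one row per
#' day and one column per minute of day, missing values stored as `NA`.
#' Column `j` covers clock minute `col_offset + j - 1` (minutes of day are
#' 0-based, 0–1439); a full day has 1440 columns and `col_offset = 0`, a
#' binned extract (see [extract_bin()]) has fewer columns and a positive
#' offset.
#'
#' @param values numeric matrix, days in rows, minutes in columns. Non-`NA`
#'   entries must be finite and positive (beats/min).
#' @param days character vector of day identifiers (one per row, distinct).
#'   Defaults to existing rownames.
#' @param col_offset minute of day of the first column (0-based).
#' @return an object of class `day_matrix`.
#' @seealso [build_day_matrix()], [extract_bin()], [generate_days()]
#' @export
day_matrix <- function(values, days = rownames(values), col_offset = 0L) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_format("`values` must be a numeric matrix")
  }
  if (nrow(values) < 1L || ncol(values) < 1L || ncol(values) > 1440L) {
    stop_format("day matrix needs >= 1 row and 1..1440 columns")
  }
  if (!is_count(col_offset, min = 0L) || col_offset + ncol(values) > 1440L) {
    stop_format("col_offset %s + %d columns exceeds the 1440-minute day",
                format(col_offset), ncol(values))
  }
  if (is.null(days)) days <- sprintf("day%03d", seq_len(nrow(values)))
  days <- as.character(days)
  if (length(days) != nrow(values) || anyDuplicated(days)) {
    stop_format("`days` must name each row uniquely")
  }
  obs <- values[!is.na(values)]
  if (any(!is.finite(obs)) || any(obs <= 0)) {
    stop_format("observed heart-rate values must be finite and > 0")
  }
  dimnames(values) <- list(days,
                           sprintf("m%04d", col_offset + seq_len(ncol(values)) - 1L))
  structure(values, col_offset = as.integer(col_offset), class = "day_matrix")
}

#' @export
print.day_matrix <- function(x, ...) {
  cat(sprintf("<day_matrix> %d day(s) x %d minute(s), offset %d, %d missing cell(s)\n",
              nrow(x), ncol(x), col_offset(x), sum(is.na(x))))
  invisible(x)
}

#' Minute-of-day of the first column of a day matrix
#' @param x a `day_matrix`.
#' @return integer minute of day (0-based).
#' @export
col_offset <- function(x) {
  off <- attr(x, "col_offset")
  if (is.null(off)) 0L else off
}

#' @export
`[.day_matrix` <- function(x, ...) {
  # subsetting drops to a plain matrix/vector; day_matrix geometry is managed
  # by the dedicated operations (extract_bin, apply_gap, ...)
  NextMethod()
}

dm_values <- function(x) {
  unclass_dm <- unclass(x)
  attr(unclass_dm, "col_offset") <- NULL
  unclass_dm
}

# Rebuild a day_matrix with the same geometry but new cell values. Used for
# imputer outputs, whose contract is "finite", not "positive": a linear
# imputer may legitimately extrapolate at or below zero on non-physiological
# fixtures, so only finiteness is enforced here.
dm_like <- function(template, values) {
  stopifnot(is.matrix(values), nrow(values) == nrow(template),
            ncol(values) == ncol(template))
  if (any(!is.finite(values[!is.na(values)]))) {
    stop_format("imputed values must be finite")
  }
  dimnames(values) <- dimnames(template)
  structure(values, col_offset = col_offset(template), class = "day_matrix")
}

assert_day_matrix <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "day_matrix")) {
    stop_format("`%s` must be a day_matrix (see ?day_matrix)", arg)
  }
  invisible(x)
}
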
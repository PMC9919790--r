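#' Specify a contiguous missing window
#'
#' @param start_min first masked minute of day (0-based, 0–1439).
#' @param length_min number of masked minutes (the study uses 15 and 60).
#' @param target_day day to mask: a row index or a day identifier.
#' @return a `gap_spec` list.
#' @export
gap_spec <- function(start_min, length_min, target_day) {
  if (!is_count(start_min, min = 0L) || start_min > 1439L) {
    stop_format("start_min must be a minute of day in 0..1439")
  }
  if (!is_count(length_min) || start_min + length_min > 1440L) {
    stop_format("gap [%d, %d) does not fit in the 1440-minute day",
                start_min, start_min + length_min)
  }
  structure(list(start_min = as.integer(start_min),
                 length_min = as.integer(length_min),
                 target_day = target_day),
            class = "gap_spec")
}

resolve_day <- function(matrix, target_day) {
  if (is.character(target_day)) {
    idx <- match(target_day, rownames(matrix))
    if (is.na(idx)) stop_format("unknown day '%s'", target_day)
    idx
  } else {
    if (!is_count(target_day) || target_day > nrow(matrix)) {
      stop_format("target_day must be a row index in 1..%d", nrow(matrix))
    }
    as.integer(target_day)
  }
}

#' Mask a gap and retain the removed values
#'
#' Replaces the target day's values inside the gap window with `NA` and
#' stores the removed values outside the matrix, so no imputer can see them
#' by construction.
#'
#' @param matrix a [day_matrix()].
#' @param gap a [gap_spec()].
#' @return a `masked_experiment`: list with `masked` (the [day_matrix()]
#'   with the gap cells `NA`), `truth` (data frame `day`, `minute`, `value`
#'   of the removed cells), and `gap`.
#' @export
apply_gap <- function(matrix, gap) {
  assert_day_matrix(matrix)
  stopifnot(inherits(gap, "gap_spec"))
  off <- col_offset(matrix)
  j0 <- gap$start_min - off + 1L
  j1 <- j0 + gap$length_min - 1L
  if (j0 < 1L || j1 > ncol(matrix)) {
    stop_format("gap [%d, %d) lies outside the matrix columns [%d, %d)",
                gap$start_min, gap$start_min + gap$length_min,
                off, off + ncol(matrix))
  }
  d <- resolve_day(matrix, gap$target_day)
  vals <- dm_values(matrix)
  removed <- vals[d, j0:j1]
  keep <- !is.na(removed)
  if (!any(keep)) {
    stop_format("day '%s' is already fully missing inside the gap window; nothing to evaluate",
                rownames(matrix)[d])
  }
  vals[d, j0:j1] <- NA_real_
  truth <- data.frame(day = rownames(matrix)[d],
                      minute = (gap$start_min + which(keep) - 1L),
                      value = removed[keep],
                      stringsAsFactors = FALSE)
  structure(list(masked = dm_like(matrix, vals), truth = truth, gap = gap),
            class = "masked_experiment")
}

#' Leave-one-day-out gap masking over many days
#'
#' Yields one [apply_gap()] experiment per listed day: only that day's
#' window is masked while all other days keep their values and act as
#' donors. (Masking every day's window simultaneously would leave a bin of
#' exactly the gap size with no observed values at all, so per-day masking
#' is the evaluation design used throughout.)
#'
#' @param matrix a [day_matrix()].
#' @param start_min,length_min the gap window (see [gap_spec()]).
#' @param days row indices or day identifiers to evaluate.
#' @return list of `masked_experiment` objects, one per day.
#' @export
iterate_gap_days <- function(matrix, start_min, length_min,
                             days = seq_len(nrow(matrix))) {
  assert_day_matrix(matrix)
  if (length(days) == 0L) stop_format("`days` must list at least one day")
  lapply(days, function(d) apply_gap(matrix, gap_spec(start_min, length_min, d)))
}
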
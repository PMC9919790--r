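#' Centre a bin of a given size on a gap window
#'
#' The bin pads the gap symmetrically: `pad_total = bin_size - gap_len`,
#' `pad_before = floor(pad_total / 2)`, the remaining (odd) minute goes
#' after the gap. Bins never wrap across midnight — all of the study's
#' frames fit inside a day (a 6-h bin around 3–4 am spans 00:30–06:30) —
#' so a window that would cross a day boundary raises an error instead of
#' being clamped silently.
#'
#' @param gap_start first missing minute of day (0-based).
#' @param gap_len gap length in minutes.
#' @param bin_size bin size in minutes, at least `gap_len`; the token
#'   `"total"` denotes the whole 1440-minute day.
#' @return a `bin_window`: list with `start_min`, `end_min` (half-open
#'   `[start, end)`) and `size_min`.
#' @export
bin_bounds <- function(gap_start, gap_len, bin_size) {
  if (identical(bin_size, "total")) bin_size <- 1440L
  if (!is_count(gap_start, min = 0L) || !is_count(gap_len)) {
    stop_format("gap_start/gap_len must be non-negative integers")
  }
  if (!is_count(bin_size) || bin_size < gap_len) {
    stop_format("bin_size (%s min) must be at least the gap length (%d min)",
                format(bin_size), gap_len)
  }
  pad_total <- bin_size - gap_len
  pad_before <- pad_total %/% 2L
  start <- gap_start - pad_before
  end <- gap_start + gap_len + (pad_total - pad_before)
  if (bin_size == 1440L) {
    start <- 0L
    end <- 1440L
  }
  if (start < 0L || end > 1440L) {
    stop_format(paste0("bin [%d, %d) crosses the day boundary; ",
                       "shrink the bin so it fits inside 0..1439"),
                start, end)
  }
  structure(list(start_min = as.integer(start), end_min = as.integer(end),
                 size_min = as.integer(end - start)),
            class = "bin_window")
}

#' Extract the bin columns of a day matrix
#'
#' Returns the `D x size_min` submatrix covering the window across all
#' days, preserving missing cells. A window of the full day (size 1440,
#' the `"total"` bin) returns the matrix itself.
#'
#' @param matrix a [day_matrix()].
#' @param window a `bin_window` from [bin_bounds()], or the token
#'   `"total"`.
#' @return a [day_matrix()] with `col_offset = window$start_min`.
#' @export
extract_bin <- function(matrix, window) {
  assert_day_matrix(matrix)
  if (identical(window, "total")) {
    window <- list(start_min = col_offset(matrix),
                   end_min = col_offset(matrix) + ncol(matrix))
  }
  off <- col_offset(matrix)
  j0 <- window$start_min - off + 1L
  j1 <- window$end_min - off
  if (j0 < 1L || j1 > ncol(matrix) || j0 > j1) {
    stop_format("window [%d, %d) lies outside the matrix columns [%d, %d)",
                window$start_min, window$end_min, off, off + ncol(matrix))
  }
  if (j0 == 1L && j1 == ncol(matrix)) return(matrix)
  vals <- dm_values(matrix)[, j0:j1, drop = FALSE]
  day_matrix_raw(vals, rownames(matrix), as.integer(window$start_min))
}

# like day_matrix() but without re-validating cell values (extraction
# cannot invalidate them)
day_matrix_raw <- function(vals, days, col_offset) {
  dimnames(vals) <- list(days,
                         sprintf("m%04d", col_offset + seq_len(ncol(vals)) - 1L))
  structure(vals, col_offset = col_offset, class = "day_matrix")
}
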
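#' Read raw device samples from CSV
#'
#' Parses a device-style export with one row per sample. Timestamps must be
#' ISO-8601 (`YYYY-MM-DD HH:MM:SS` or with a `T` separator); rows whose value
#' does not parse as a number are dropped (and counted in a message), and
#' duplicate timestamps — devices retransmit — are collapsed by averaging.
#'
#' @param path CSV file path.
#' @param timestamp_col,value_col column names holding the timestamp and the
#'   heart rate; remap these for other dialects.
#' @param subject_id identifier stored on the returned series.
#' @param nominal_interval_s nominal sampling interval in seconds (the
#'   device's advertised cadence, e.g. 5 for a 5-s tracker).
#' @return a `raw_samples` object: data frame with columns `time`
#'   (POSIXct, UTC as naive local clock) and `value` (beats/min), sorted by
#'   time, with attributes `subject_id` and `nominal_interval_s`.
#' @export
read_samples_csv <- function(path, timestamp_col = "timestamp",
                             value_col = "heart_rate",
                             subject_id = "subject",
                             nominal_interval_s = 5L) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(timestamp_col, value_col), names(raw))
  if (length(missing_cols)) {
    stop_format("missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  ts_chr <- as.character(raw[[timestamp_col]])
  tm <- as.POSIXct(strptime(ts_chr, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  retry <- is.na(tm)
  if (any(retry)) {
    tm[retry] <- as.POSIXct(strptime(ts_chr[retry], "%Y-%m-%dT%H:%M:%OS",
                                     tz = "UTC"))
  }
  val <- suppressWarnings(as.numeric(raw[[value_col]]))
  keep <- !is.na(tm) & !is.na(val) & is.finite(val) & val > 0
  n_dropped <- nrow(raw) - sum(keep)
  if (n_dropped > 0) {
    message(sprintf("read_samples_csv: dropped %d unparseable row(s)", n_dropped))
  }
  if (!any(keep)) stop_format("no parseable samples in %s", path)
  tm <- tm[keep]; val <- val[keep]
  ord <- order(tm)
  tm <- tm[ord]; val <- val[ord]
  # collapse duplicate timestamps by mean
  if (anyDuplicated(tm)) {
    grp <- match(tm, unique(tm))
    val <- as.numeric(tapply(val, grp, mean))
    tm <- unique(tm)
  }
  raw_samples(tm, val, subject_id = subject_id,
              nominal_interval_s = nominal_interval_s)
}

#' Construct a raw sample series
#'
#' @param time POSIXct timestamps, strictly increasing.
#' @param value heart rates (beats/min), finite and positive.
#' @inheritParams read_samples_csv
#' @return a `raw_samples` object.
#' @export
raw_samples <- function(time, value, subject_id = "subject",
                        nominal_interval_s = 5L) {
  stopifnot(inherits(time, "POSIXct"), length(time) == length(value))
  if (length(time) && any(diff(as.numeric(time)) <= 0)) {
    stop_format("timestamps must be strictly increasing")
  }
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop_format("sample values must be finite and > 0")
  }
  if (!is_count(nominal_interval_s)) {
    stop_format("nominal_interval_s must be a positive integer")
  }
  structure(data.frame(time = time, value = as.numeric(value)),
            subject_id = as.character(subject_id),
            nominal_interval_s = as.integer(nominal_interval_s),
            class = c("raw_samples", "data.frame"))
}

#' Average sub-minute samples into a 1440-slot minute series
#'
#' Slot `m` (0-based minute of day) receives the arithmetic mean of all
#' samples with a timestamp in the half-open interval `[m:00, m+1:00)` on
#' `date`; slots with no samples are `NA`.
#'
#' @param series a `raw_samples` object.
#' @param date the calendar date (`Date` or coercible).
#' @return a `minute_series`: list with `date` and a 1440-long `values`
#'   vector (beats/min or `NA`).
#' @export
to_minute_series <- function(series, date) {
  stopifnot(inherits(series, "raw_samples"))
  date <- as.Date(date)
  day_start <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  sec <- as.numeric(series$time) - as.numeric(day_start)
  on_day <- sec >= 0 & sec < 86400
  values <- rep(NA_real_, 1440L)
  if (any(on_day)) {
    minute <- floor(sec[on_day] / 60)  # half-open [m:00, m+1:00)
    means <- tapply(series$value[on_day], minute, mean)
    values[as.integer(names(means)) + 1L] <- as.numeric(means)
  }
  structure(list(date = date, values = values), class = "minute_series")
}

#' Stack minute series into a day matrix
#'
#' @param days list of `minute_series` with distinct dates.
#' @return a [day_matrix()] with `D x 1440` cells, rows in input order.
#' @export
build_day_matrix <- function(days) {
  if (!is.list(days) || length(days) == 0L) {
    stop_format("`days` must be a non-empty list of minute_series")
  }
  if (!all(vapply(days, inherits, logical(1), "minute_series"))) {
    stop_format("all elements of `days` must be minute_series")
  }
  dates <- vapply(days, function(d) format(d$date), character(1))
  if (anyDuplicated(dates)) stop_format("duplicate dates in `days`")
  values <- do.call(rbind, lapply(days, `[[`, "values"))
  day_matrix(values, days = dates, col_offset = 0L)
}

#' Sample days with no inherent missing data
#'
#' Mirrors the study design of drawing a fixed number of complete days from
#' a multi-month pool: uniformly samples, without replacement, `n` rows whose
#' completeness is at least `min_completeness` (default: strictly complete),
#' then returns them in their original chronological order.
#'
#' @param matrix a [day_matrix()].
#' @param n number of days to select.
#' @param seed integer seed for the sampling.
#' @param min_completeness minimum fraction of non-missing minutes for a row
#'   to count as "complete" (default 1, i.e. zero missing minutes).
#' @return a [day_matrix()] with `n` rows.
#' @export
select_complete_days <- function(matrix, n, seed, min_completeness = 1) {
  assert_day_matrix(matrix)
  if (!is_count(n)) stop_format("`n` must be a positive integer")
  frac <- rowMeans(!is.na(dm_values(matrix)))
  complete <- which(frac >= min_completeness)
  if (length(complete) < n) {
    stop_format("requested %d complete days but only %d available",
                n, length(complete))
  }
  chosen <- with_seed(seed, sample(complete, n))
  chosen <- sort(chosen)  # preserve chronological order
  dm <- dm_values(matrix)[chosen, , drop = FALSE]
  day_matrix(dm, days = rownames(matrix)[chosen], col_offset = col_offset(matrix))
}

#' Write / read a day matrix as CSV
#'
#' The format is lossless: header `day,m0000,...`, one row per day, missing
#' cells written as empty fields.
#'
#' @param matrix a [day_matrix()].
#' @param path CSV file path.
#' @return `write_matrix_csv` returns `path` invisibly; `read_matrix_csv`
#'   returns the [day_matrix()].
#' @export
write_matrix_csv <- function(matrix, path) {
  assert_day_matrix(matrix)
  vals <- dm_values(matrix)
  body <- cbind(day = rownames(matrix),
                `colnames<-`(format_cells(vals), colnames(matrix)))
  write.table(body, path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

format_cells <- function(vals) {
  out <- matrix("", nrow(vals), ncol(vals))
  obs <- !is.na(vals)
  # full precision so the round trip is the identity on doubles
  out[obs] <- formatC(vals[obs], format = "g", digits = 17)
  out
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  if (ncol(raw) < 2L || names(raw)[1] != "day" ||
      !all(grepl("^m[0-9]{4}$", names(raw)[-1]))) {
    stop_format("malformed day-matrix header in %s", path)
  }
  minutes <- as.integer(sub("^m", "", names(raw)[-1]))
  if (any(diff(minutes) != 1L)) {
    stop_format("day-matrix columns must be contiguous minutes")
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & cells != "")
  if (length(bad)) {
    stop_format("non-numeric cell(s) in %s (e.g. \"%s\")", path, cells[bad[1]])
  }
  day_matrix(vals, days = raw$day, col_offset = minutes[1])
}
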
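#' Root mean square error of an imputation against retained truth
#'
#' \deqn{RMSE = \sqrt{\sum_{i=1}^{N} (R_i - I_i)^2 / N}}
#' over the `N` ground-truth cells removed by [apply_gap()], where `R_i`
#' is the actual and `I_i` the imputed value.
#'
#' @param truth the `truth` data frame of a `masked_experiment` (columns
#'   `day`, `minute`, `value`).
#' @param imputed a completed [day_matrix()] (e.g. `result$imputed`).
#' @return RMSE in beats/min.
#' @export
imputation_rmse <- function(truth, imputed) {
  assert_day_matrix(imputed)
  stopifnot(is.data.frame(truth), all(c("day", "minute", "value") %in% names(truth)))
  if (nrow(truth) == 0L) stop_format("truth is empty; nothing to score")
  rows <- match(truth$day, rownames(imputed))
  cols <- truth$minute - col_offset(imputed) + 1L
  if (anyNA(rows) || any(cols < 1L | cols > ncol(imputed))) {
    stop_format("truth cells lie outside the imputed matrix")
  }
  ivals <- dm_values(imputed)[cbind(rows, cols)]
  if (anyNA(ivals)) {
    stop_format("imputed matrix still has missing truth cells (imputer contract violation)")
  }
  sqrt(mean((truth$value - ivals)^2))
}

#' Configuration of the full binning-evaluation experiment
#'
#' Defaults reproduce the study design: 1-h and 15-min gaps in the
#' inactive (3–4 am) and active (3–4 pm) frames, the bin ladder
#' 15/30/45/60 min and 2–6 h plus the whole-day `"total"` bin, all five
#' imputation methods, and 30 evaluated days. Bins smaller than a frame's
#' gap are skipped as inadmissible (the 1-h gap's smallest bin is 1 h).
#'
#' @param frames list of `c(start_min, length_min)` gap frames.
#' @param bins bin sizes in minutes, plus the token `"total"`.
#' @param methods imputation methods to compare.
#' @param days number of days to evaluate (the first `days` rows).
#' @param seed integer seed passed to every imputer.
#' @param mask_mode `"leave-one-out"` (default) masks only the evaluated
#'   day's window; `"simultaneous"` masks the window on all evaluated days
#'   at once (only sensible for bins strictly wider than the gap).
#' @param imputer_args named list of per-method [imputer_config()]
#'   overrides, e.g. `list(KNN = list(k = 3))`.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(frames = list(inactive_1h = c(180L, 60L),
                                            active_1h = c(900L, 60L),
                                            inactive_15min = c(180L, 15L),
                                            active_15min = c(900L, 15L)),
                              bins = c(15L, 30L, 45L, 60L, 120L, 180L, 240L,
                                       300L, 360L, "total"),
                              methods = c("EM", "II", "KNN", "RF", "SI"),
                              days = 30L,
                              seed = 1L,
                              mask_mode = c("leave-one-out", "simultaneous"),
                              imputer_args = list()) {
  mask_mode <- match.arg(mask_mode)
  if (is.null(names(frames))) {
    names(frames) <- vapply(frames, function(f) sprintf("f%04d+%d", f[1], f[2]),
                            character(1))
  }
  stopifnot(all(vapply(frames, length, integer(1)) == 2L))
  methods <- match.arg(methods, c("EM", "II", "KNN", "RF", "SI"),
                       several.ok = TRUE)
  structure(list(frames = frames, bins = bins, methods = methods,
                 days = as.integer(days), seed = as.integer(seed),
                 mask_mode = mask_mode, imputer_args = imputer_args),
            class = "experiment_config")
}

bin_minutes <- function(bin) {
  ifelse(bin == "total", 1440L, suppressWarnings(as.integer(bin)))
}

admissible_bins <- function(bins, gap_len) {
  keep <- bins == "total" | bin_minutes(bins) >= gap_len
  bins[keep]
}

method_config <- function(method, econf) {
  args <- econf$imputer_args[[method]]
  do.call(imputer_config,
          c(list(method = method, seed = econf$seed), args))
}

#' Run the full frame x day x bin x method evaluation
#'
#' For every gap frame, every evaluated day, every admissible bin size and
#' every method: mask the day's window (leave-one-day-out), extract the
#' centred bin from the masked matrix, impute it, and score the imputation
#' against the retained truth. The result table has exactly
#' `days * n_admissible_bins * n_methods` rows per frame; a fixed seed
#' gives an identical table.
#'
#' @param matrix a [day_matrix()] with at least `config$days` rows (the
#'   first `config$days` rows are evaluated).
#' @param config an [experiment_config()].
#' @return a data frame of evaluation records with columns `frame`, `day`,
#'   `method`, `bin` (minutes as character, or `"total"`) and `rmse`.
#' @export
run_experiment <- function(matrix, config = experiment_config()) {
  assert_day_matrix(matrix)
  stopifnot(inherits(config, "experiment_config"))
  if (nrow(matrix) < config$days) {
    stop_format("matrix has %d rows but config asks for %d days",
                nrow(matrix), config$days)
  }
  eval_days <- rownames(matrix)[seq_len(config$days)]
  configs <- lapply(stats::setNames(config$methods, config$methods),
                    method_config, econf = config)
  r_frame <- character(0); r_day <- character(0)
  r_method <- character(0); r_bin <- character(0); r_rmse <- numeric(0)
  for (fname in names(config$frames)) {
    frame <- config$frames[[fname]]
    gap_start <- frame[1]; gap_len <- frame[2]
    bins <- admissible_bins(config$bins, gap_len)
    experiments <- if (config$mask_mode == "leave-one-out") {
      iterate_gap_days(matrix, gap_start, gap_len, eval_days)
    } else {
      masked_all <- Reduce(function(m, d) apply_gap(m, gap_spec(gap_start, gap_len, d))$masked,
                           eval_days, matrix)
      lapply(eval_days, function(d) {
        tr <- apply_gap(matrix, gap_spec(gap_start, gap_len, d))$truth
        list(masked = masked_all, truth = tr)
      })
    }
    for (ex in experiments) {
      day <- ex$truth$day[1]
      for (bin in bins) {
        window <- if (bin == "total") "total" else {
          bin_bounds(gap_start, gap_len, bin_minutes(bin))
        }
        sub <- extract_bin(ex$masked, window)
        for (method in config$methods) {
          rm_val <- tryCatch(
            imputation_rmse(ex$truth, impute(sub, configs[[method]])$imputed),
            error = function(e) {
              stop_format("experiment failed at (%s, %s, %s, %s): %s",
                          fname, day, bin, method, conditionMessage(e))
            })
          r_frame <- c(r_frame, fname); r_day <- c(r_day, day)
          r_method <- c(r_method, method); r_bin <- c(r_bin, as.character(bin))
          r_rmse <- c(r_rmse, rm_val)
        }
      }
    }
  }
  data.frame(frame = r_frame, day = r_day, method = r_method, bin = r_bin,
             rmse = r_rmse, stringsAsFactors = FALSE)
}

#' Success rate of binning for one method
#'
#' The fraction of evaluated days whose RMSE at the reference bin is
#' strictly lower than at the whole-day `"total"` bin. Days where the RMSE
#' did not reduce — including exact ties — count as failures.
#'
#' @param records an evaluation-record data frame (one frame) from
#'   [run_experiment()].
#' @param method the method to assess.
#' @param reference_bin reference bin: minutes, `"total"`, the default
#'   `"smallest"` (smallest admissible bin present), or `"best"` (each
#'   day's best non-total bin for this method).
#' @return fraction in `[0, 1]`.
#' @export
success_rate <- function(records, method, reference_bin = "smallest") {
  stopifnot(is.data.frame(records))
  if (length(unique(records$frame)) > 1L) {
    stop_format("records span several frames; filter to one frame first")
  }
  rec <- records[records$method == method, , drop = FALSE]
  if (nrow(rec) == 0L) stop_format("no records for method '%s'", method)
  numeric_bins <- setdiff(unique(rec$bin), "total")
  if (identical(reference_bin, "best")) {
    if (!length(numeric_bins)) stop_format("records contain only the total bin")
    binned <- rec[rec$bin != "total", ]
    best <- tapply(binned$rmse, binned$day, min)
    tot <- rec[rec$bin == "total", ]
    if (!all(names(best) %in% tot$day)) {
      stop_format("missing (day, total) records")
    }
    return(mean(best < tot$rmse[match(names(best), tot$day)]))
  }
  if (is.null(reference_bin) || identical(reference_bin, "smallest")) {
    if (!length(numeric_bins)) stop_format("records contain only the total bin")
    reference_bin <- numeric_bins[which.min(bin_minutes(numeric_bins))]
  }
  reference_bin <- as.character(reference_bin)
  days <- unique(rec$day)
  ref <- rec[rec$bin == reference_bin, ]
  tot <- rec[rec$bin == "total", ]
  missing_ref <- setdiff(days, ref$day)
  missing_tot <- setdiff(days, tot$day)
  if (length(missing_ref) || length(missing_tot)) {
    stop_format("missing (day, bin) records: %s",
                paste(c(sprintf("(%s, %s)", missing_ref, reference_bin),
                        sprintf("(%s, total)", missing_tot)), collapse = ", "))
  }
  mean(ref$rmse[match(days, ref$day)] < tot$rmse[match(days, tot$day)])
}

#' Optimal bin size for one day
#'
#' The bin minimising the sum of all methods' RMSE values for that day;
#' ties break toward the smallest bin (`"total"` ranks largest).
#'
#' @param day_records evaluation records of a single day (all methods, all
#'   bins, one frame).
#' @param aggregate `"sum"` (default) minimises the methods' summed RMSE,
#'   which always exists; `"simultaneous"` requires a bin at which *every*
#'   method attains its own minimum and returns `"none"` when no such bin
#'   exists.
#' @return the winning bin as character (`"15"`, ..., `"total"`, or
#'   `"none"` under the simultaneous definition).
#' @export
optimal_bin_size <- function(day_records, aggregate = c("sum", "simultaneous")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(day_records))
  if (length(unique(day_records$day)) != 1L ||
      length(unique(day_records$frame)) != 1L) {
    stop_format("day_records must cover exactly one (frame, day)")
  }
  grid <- table(day_records$method, day_records$bin)
  if (any(grid != 1L)) {
    stop_format("incomplete method x bin grid for day '%s'", day_records$day[1])
  }
  if (aggregate == "simultaneous") {
    per <- split(day_records, day_records$method)
    mins <- lapply(per, function(m) m$bin[m$rmse == min(m$rmse)])
    joint <- Reduce(intersect, mins)
    if (!length(joint)) return("none")
    return(joint[order(bin_minutes(joint))][1])
  }
  agg <- tapply(day_records$rmse, day_records$bin, sum)
  bins <- names(agg)[order(bin_minutes(names(agg)))]
  agg <- agg[bins]
  bins[which.min(agg)]  # which.min takes the first minimum = smallest bin
}

#' Histogram of optimal bin sizes over days
#'
#' @param records evaluation records of a single frame.
#' @return named integer vector: days per winning bin; counts sum to the
#'   number of days.
#' @export
optimal_bin_histogram <- function(records) {
  stopifnot(is.data.frame(records))
  if (length(unique(records$frame)) > 1L) {
    stop_format("records span several frames; filter to one frame first")
  }
  wins <- vapply(split(records, records$day), optimal_bin_size, character(1))
  lev <- unique(records$bin)
  lev <- lev[order(bin_minutes(lev))]
  table(factor(wins, levels = lev))
}

#' Write the three experiment summary CSVs
#'
#' Produces `records.csv` (`frame,day,method,bin,rmse`), `summary.csv`
#' (`frame,method,success_rate,n_days`) and `optimal_bins.csv`
#' (`frame,bin,count`) under `dir`.
#'
#' @param records a record table from [run_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_csv <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- records
  fmt$rmse <- formatC(fmt$rmse, format = "g", digits = 17)
  write.table(fmt, file.path(dir, "records.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  summ <- do.call(rbind, lapply(split(records, records$frame), function(fr) {
    data.frame(frame = fr$frame[1],
               method = unique(fr$method),
               success_rate = vapply(unique(fr$method),
                                     function(m) success_rate(fr, m), numeric(1)),
               n_days = length(unique(fr$day)),
               stringsAsFactors = FALSE)
  }))
  write.table(summ, file.path(dir, "summary.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  opt <- do.call(rbind, lapply(split(records, records$frame), function(fr) {
    h <- optimal_bin_histogram(fr)
    data.frame(frame = fr$frame[1], bin = names(h), count = as.integer(h),
               stringsAsFactors = FALSE)
  }))
  write.table(opt, file.path(dir, "optimal_bins.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
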
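mk_records <- function(...) {
  # build a record table from rows of (frame, day, method, bin, rmse)
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(frame = r[[1]], day = r[[2]], method = r[[3]], bin = r[[4]],
               rmse = as.numeric(r[[5]]), stringsAsFactors = FALSE)
  }))
}

test_that("the RMSE formula matches hand-computed values", {
  truth <- data.frame(day = "d1", minute = c(100L, 101L), value = c(3, 4))
  vals <- matrix(80, 2, 1440)
  vals[1, 101:102] <- NA
  m <- day_matrix(vals, days = c("d1", "d2"))
  imp <- dm_vals(m)
  imp[1, 101:102] <- 1e-12       # "zero" (day-matrix values must be positive)
  imputed <- day_matrix(imp, days = rownames(m))
  expect_equal(imputation_rmse(truth, imputed), sqrt((9 + 16) / 2),
               tolerance = 1e-12)
  # perfect imputation scores zero; a single cell scores its own error
  imp2 <- dm_vals(m)
  imp2[1, 101:102] <- c(3, 4)
  expect_equal(imputation_rmse(truth, day_matrix(imp2, days = rownames(m))), 0)
  one <- data.frame(day = "d2", minute = 5L, value = 70)
  imp3 <- dm_vals(m)
  imp3[2, 6] <- 72
  expect_equal(imputation_rmse(one, day_matrix(imp3, days = rownames(m))), 2)
})

test_that("RMSE refuses unimputed truth cells", {
  truth <- data.frame(day = "d1", minute = 100L, value = 70)
  vals <- matrix(80, 1, 1440)
  vals[1, 101] <- NA
  m <- day_matrix(vals, days = "d1")
  expect_error(imputation_rmse(truth, m), "contract violation")
  expect_error(imputation_rmse(truth[0, ], m), "empty")
})

test_that("success rate counts strict reductions only", {
  rec <- mk_records(
    list("f", "d1", "EM", "15", 5), list("f", "d1", "EM", "total", 9),
    list("f", "d2", "EM", "15", 7), list("f", "d2", "EM", "total", 6),
    list("f", "d3", "EM", "15", 4), list("f", "d3", "EM", "total", 8))
  expect_equal(success_rate(rec, "EM"), 2 / 3)
  # ties are failures
  tie <- mk_records(list("f", "d1", "SI", "15", 5), list("f", "d1", "SI", "total", 5))
  expect_equal(success_rate(tie, "SI"), 0)
  # self-comparison is identically zero
  expect_equal(success_rate(rec, "EM", reference_bin = "total"), 0)
  # missing pairs are reported
  broken <- rec[-2, ]
  expect_error(success_rate(broken, "EM"), "missing \\(day, bin\\)")
  expect_error(success_rate(rec, "RF"), "no records")
})

test_that("the paper-style 25-of-30 case gives 83%", {
  rows <- lapply(1:30, function(d) {
    better <- d <= 25
    list(list("f", paste0("d", d), "EM", "60", if (better) 4 else 7),
         list("f", paste0("d", d), "EM", "total", 6))
  })
  rec <- do.call(mk_records, unlist(rows, recursive = FALSE))
  expect_equal(success_rate(rec, "EM"), 25 / 30, tolerance = 1e-12)
})

test_that("optimal bin size minimises the cross-method aggregate", {
  methods <- c("EM", "II", "KNN", "RF", "SI")
  rec <- do.call(mk_records, c(
    lapply(methods, function(m) list("f", "d1", m, "15", 8)),
    lapply(methods, function(m) list("f", "d1", m, "30", 7.6)),
    lapply(methods, function(m) list("f", "d1", m, "total", 9))))
  expect_equal(optimal_bin_size(rec), "30")
  # ties break toward the smallest bin
  rec2 <- do.call(mk_records, c(
    lapply(methods, function(m) list("f", "d1", m, "15", 8)),
    lapply(methods, function(m) list("f", "d1", m, "60", 8)),
    lapply(methods, function(m) list("f", "d1", m, "total", 9))))
  expect_equal(optimal_bin_size(rec2), "15")
  expect_error(optimal_bin_size(rec[-1, ]), "incomplete")
})

test_that("the optimal-bin histogram counts every day once", {
  methods <- c("EM", "II", "KNN", "RF", "SI")
  rows <- list()
  for (d in 1:6) {
    best <- if (d <= 4) "15" else "60"
    for (b in c("15", "60", "total")) {
      for (m in methods) {
        rows[[length(rows) + 1L]] <-
          list("f", paste0("d", d), m, b, if (b == best) 5 else 6)
      }
    }
  }
  h <- do.call(mk_records, rows) |> optimal_bin_histogram()
  expect_equal(sum(h), 6L)
  expect_equal(as.integer(h[c("15", "60")]), c(4L, 2L))
  expect_equal(as.integer(h["total"]), 0L)
})

test_that("run_experiment emits the exact factorial record count", {
  hr <- generate_days(small_synth(n_days = 6))$hr
  cfg <- experiment_config(frames = list(am = c(180L, 15L)),
                           bins = c("15", "30", "total"),
                           methods = c("SI", "KNN"),
                           days = 4L, seed = 3L)
  rec <- run_experiment(hr, cfg)
  expect_equal(nrow(rec), 4L * 3L * 2L)
  expect_equal(sort(unique(rec$bin)), sort(c("15", "30", "total")))
  # determinism: identical tables on a rerun
  expect_identical(run_experiment(hr, cfg), rec)
  # inadmissible bins are skipped for longer gaps
  cfg2 <- experiment_config(frames = list(am = c(180L, 60L)),
                            bins = c("15", "30", "60", "total"),
                            methods = "SI", days = 2L, seed = 3L)
  rec2 <- run_experiment(hr, cfg2)
  expect_equal(sort(unique(rec2$bin)), sort(c("60", "total")))
  expect_equal(nrow(rec2), 2L * 2L * 1L)
  # a single-cell config gives a single record
  cfg3 <- experiment_config(frames = list(am = c(180L, 15L)), bins = "total",
                            methods = "SI", days = 1L, seed = 1L)
  expect_equal(nrow(run_experiment(hr, cfg3)), 1L)
  expect_error(run_experiment(hr, experiment_config(days = 40L)), "40 days")
})

test_that("experiment CSVs round-trip deterministically", {
  hr <- generate_days(small_synth(n_days = 5))$hr
  cfg <- experiment_config(frames = list(pm = c(900L, 15L)),
                           bins = c("15", "total"),
                           methods = c("SI", "EM"), days = 5L, seed = 2L)
  rec <- run_experiment(hr, cfg)
  d1 <- tempfile(); d2 <- tempfile()
  write_experiment_csv(rec, d1)
  write_experiment_csv(run_experiment(hr, cfg), d2)
  for (f in c("records.csv", "summary.csv", "optimal_bins.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  got <- utils::read.csv(file.path(d1, "records.csv"),
                         colClasses = c(bin = "character"))
  expect_equal(nrow(got), nrow(rec))
  expect_equal(got$rmse, rec$rmse, tolerance = 1e-15)
})
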
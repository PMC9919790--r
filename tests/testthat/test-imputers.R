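test_that("simple imputation fills with column means and grand-mean fallback", {
  m <- day_matrix(cbind(c(60, NA, 66, 72), c(NA, NA, NA, NA), c(50, 50, 50, NA)))
  r <- impute_simple(m)
  v <- dm_vals(r$imputed)
  expect_equal(v[2, 1], 66)                       # mean of 60, 66, 72
  expect_equal(v[4, 3], 50)
  # fully-missing column falls back to the grand mean of observed cells
  expect_equal(unname(v[, 2]), rep(mean(c(60, 66, 72, 50, 50, 50)), 4))
  expect_false(anyNA(v))

  # single-donor column
  m2 <- day_matrix(matrix(c(NA, 50), 2, 1))
  expect_equal(unname(dm_vals(impute_simple(m2)$imputed)[1, 1]), 50)

  # fully observed input is the identity
  full <- random_dm(4, 6, seed = 1)
  expect_identical(dm_vals(impute_simple(full)$imputed), dm_vals(full))
  expect_error(impute_simple(day_matrix(matrix(NA_real_, 2, 2))),
               "entirely missing")
})

test_that("EM recovers the empirical Gaussian conditional mean", {
  # bivariate check at rho = 0.8 against the closed-form conditional
  set.seed(21)
  n <- 400
  x2 <- rnorm(n)
  x1 <- 0.8 * x2 + sqrt(1 - 0.64) * rnorm(n)
  vals <- cbind(100 + 5 * x1, 100 + 5 * x2)
  target_x2 <- 100 + 5 * 1.3
  vals <- rbind(vals, c(NA, target_x2))
  r <- impute_em(day_matrix(vals))
  mu <- colMeans(vals[1:n, ])
  S <- stats::cov(vals[1:n, ])
  oracle <- mu[1] + S[1, 2] / S[2, 2] * (target_x2 - mu[2])
  expect_lt(abs(dm_vals(r$imputed)[n + 1, 1] - oracle), 0.05)
  expect_true(r$converged)
})

test_that("EM handles degenerate shapes", {
  # fully observed: identity with zero iterations
  full <- random_dm(5, 4, seed = 2)
  r <- impute_em(full)
  expect_identical(dm_vals(r$imputed), dm_vals(full))
  expect_equal(r$n_iterations, 0L)
  # single column: conditional with no observed coordinates = column mean
  m <- day_matrix(matrix(c(60, 70, NA, 80), 4, 1))
  expect_equal(unname(dm_vals(impute_em(m)$imputed)[3, 1]), 70)
  expect_error(impute_em(day_matrix(matrix(c(70, NA), 1, 2))), "2 rows")
})

test_that("EM change sequence settles into monotone decay", {
  # every row incomplete forces the completed-matrix EM iteration; the
  # change sequence may wobble while the moments mix, but must end in a
  # monotone decay far below its starting level
  for (s in 1:3) {
    vals <- dm_vals(gaussian_dm(20, 6, rho = 0.8, seed = s))
    set.seed(s + 1)
    for (i in 1:20) vals[i, sample(6, 1)] <- NA
    r <- impute_em(day_matrix(vals),
                   imputer_config("EM", tol = 1e-8, max_iter = 120))
    ch <- r$max_changes
    expect_gte(length(ch), 20L)
    expect_true(all(diff(tail(ch, 20)) <= 1e-9))
    expect_lt(tail(ch, 1), ch[1] / 100)
  }
})

test_that("EM beats SI when columns are correlated and rows partially observed", {
  wins <- 0L
  for (rep in 1:100) {
    dm <- gaussian_dm(40, 5, rho = 0.75, seed = 1000 + rep)
    truthv <- dm_vals(dm)
    vals <- truthv
    set.seed(2000 + rep)
    rows <- rep(sample(40, 16), each = 2)
    cols <- as.integer(replicate(16, sample(5, 2)))
    holes <- cbind(rows, cols)
    vals[holes] <- NA
    m <- day_matrix(vals)
    em <- dm_vals(impute_em(m)$imputed)[holes]
    si <- dm_vals(impute_simple(m)$imputed)[holes]
    tv <- truthv[holes]
    if (sqrt(mean((em - tv)^2)) < sqrt(mean((si - tv)^2))) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("kNN reproduces the worked nearest-neighbour example", {
  vals <- rbind(c(1, 1, 10),
                c(1, 2, 20),
                c(5, 5, 30),
                c(1, 1, NA)) + 60   # shifted positive; distances unchanged
  r <- impute_knn(day_matrix(vals), imputer_config("KNN", k = 2))
  expect_equal(unname(dm_vals(r$imputed)[4, 3]), mean(c(70, 80)))
  # k covering all donors averages every donor value
  r3 <- impute_knn(day_matrix(vals), imputer_config("KNN", k = 3))
  expect_equal(unname(dm_vals(r3$imputed)[4, 3]), mean(c(70, 80, 90)))
})

test_that("kNN equals the brute-force oracle on random fixtures", {
  for (seed in 1:10) {
    dm <- random_dm(8, 6, seed = 300 + seed, miss_frac = 0.2)
    got <- dm_vals(impute_knn(dm, imputer_config("KNN", k = 5))$imputed)
    want <- knn_oracle(dm, k = 5)
    expect_identical(unname(got), unname(want))
  }
})

test_that("a fully missing row falls back to donor column means under large k", {
  hr <- generate_days(small_synth(n_days = 6))$hr
  ex <- apply_gap(hr, gap_spec(180, 15, 3))
  sub <- extract_bin(ex$masked, bin_bounds(180, 15, 15))
  r <- impute_knn(sub, imputer_config("KNN", k = 5))  # k >= D - 1
  si <- impute_simple(sub)
  expect_equal(dm_vals(r$imputed), dm_vals(si$imputed), tolerance = 1e-12)
})

test_that("iterative regression recovers exact linear structure", {
  # y = 2x on the donors; tiny ridge approaches ordinary least squares
  vals <- rbind(c(1, 2), c(2, 4), c(4, 8), c(3, NA)) + 50
  r <- impute_iterative(day_matrix(vals),
                        imputer_config("II", ridge = 1e-10))
  expect_lt(abs(dm_vals(r$imputed)[4, 2] - 56), 0.01)
  # fully observed input: identity, zero passes
  full <- random_dm(5, 4, seed = 4)
  r0 <- impute_iterative(full)
  expect_identical(dm_vals(r0$imputed), dm_vals(full))
  expect_equal(r0$n_iterations, 0L)
})

test_that("iterative regression on independent noise regresses to the mean", {
  set.seed(9)
  vals <- matrix(80 + rnorm(60 * 5, 0, 4), 60, 5)
  mu <- colMeans(vals)
  vals[cbind(1:5, 1:5)] <- NA
  r <- impute_iterative(day_matrix(vals))
  got <- dm_vals(r$imputed)[cbind(1:5, 1:5)]
  # with no real signal, predictions stay within a few sd/sqrt(n) of means
  expect_true(all(abs(got - mu) < 3 * 4 / sqrt(59) * 3))
})

test_that("single-column iterative imputation falls back to the simple imputer", {
  m <- day_matrix(matrix(c(60, 70, NA, 80), 4, 1))
  expect_equal(unname(dm_vals(impute_iterative(m)$imputed)[3, 1]), 70)
})

test_that("random-forest imputation is deterministic and handles constants", {
  dm <- random_dm(12, 6, seed = 8, miss_frac = 0.15)
  cfg <- imputer_config("RF", seed = 77)
  a <- impute_rf(dm, cfg)
  b <- impute_rf(dm, cfg)
  expect_identical(dm_vals(a$imputed), dm_vals(b$imputed))
  expect_false(anyNA(a$imputed))

  # fully observed input is the identity
  full <- random_dm(6, 4, seed = 10)
  expect_identical(dm_vals(impute_rf(full, cfg)$imputed), dm_vals(full))

  # a constant column with gaps is imputed with the constant
  vals <- dm_vals(random_dm(10, 4, seed = 12))
  vals[, 2] <- 75
  vals[c(2, 5), 2] <- NA
  r <- impute_rf(day_matrix(vals), cfg)
  expect_equal(unname(dm_vals(r$imputed)[c(2, 5), 2]), c(75, 75))
})

test_that("the dispatcher routes methods and preserves observed cells", {
  dm <- random_dm(10, 10, seed = 20, miss_frac = 0.2)
  vals <- dm_vals(dm)
  obs <- !is.na(vals)
  for (m in c("EM", "II", "KNN", "RF", "SI")) {
    r <- impute(dm, imputer_config(m, seed = 5))
    out <- dm_vals(r$imputed)
    expect_identical(out[obs], vals[obs])       # observed cells bitwise intact
    expect_false(anyNA(out))                    # completeness
    expect_true(all(is.finite(out)))
  }
  expect_equal(dm_vals(impute(dm, imputer_config("SI"))$imputed),
               dm_vals(impute_simple(dm)$imputed))
  expect_error(imputer_config("XYZ"))
})
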
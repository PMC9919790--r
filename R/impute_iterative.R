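#' Iterative regression ("chained equations") imputation
#'
#' Initialises missing cells with column means, then cycles over the
#' incomplete columns in ascending order of missing count, each time
#' regressing the column on all other columns with a ridge-regularised
#' linear model fitted on the rows where the column was originally
#' observed, and overwriting the column's missing cells with the fitted
#' predictions. Passes repeat until the largest change of an imputed cell
#' falls below `tol * scale` or `max_iter` passes. The procedure is
#' deterministic given its input.
#'
#' Ridge (`lambda = ridge * mean feature variance`) keeps the normal
#' equations well posed when the bin makes p comparable to or larger than
#' the number of days; as `ridge -> 0` the fit approaches ordinary least
#' squares on well-posed data. When the column count exceeds the number of
#' training rows the coefficients are computed through the equivalent dual
#' (kernel) form with an `n x n` solve.
#'
#' @inheritParams impute
#' @return an `imputation_result`.
#' @export
impute_iterative <- function(matrix, config = imputer_config("II")) {
  assert_day_matrix(matrix)
  vals <- dm_values(matrix)
  miss <- is.na(vals)
  if (!any(miss)) {
    return(new_imputation_result(matrix, vals, config, 0L, TRUE))
  }
  if (nrow(vals) < 2L) stop_format("iterative imputation needs at least 2 rows")
  if (ncol(vals) < 2L) {
    # no covariates to regress on: fall back to the simple imputer
    res <- impute_simple(matrix, config)
    res$method <- config
    return(res)
  }
  n <- nrow(vals)
  scale <- mean(abs(vals[!miss]))
  filled <- si_fill_values(vals)
  avg_var <- mean(apply(filled, 2L, stats::var))
  lambda <- config$ridge * avg_var

  n_miss <- colSums(miss)
  cols <- order(n_miss, seq_len(ncol(vals)))
  cols <- cols[n_miss[cols] > 0L]

  # shared-Gram fast path: when every incomplete column trains on exactly the
  # fully observed rows (the leave-one-day-out geometry), the centred donor
  # matrix and its Gram matrix are fixed, and each column's dual ridge system
  # is the shared Gram minus a rank-one term
  complete_rows <- which(rowSums(miss) == 0L)
  shared_train <- length(complete_rows) >= 2L &&
    all(colSums(!miss[-complete_rows, cols, drop = FALSE]) == 0L)

  max_changes <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  if (shared_train) {
    xm <- colMeans(vals[complete_rows, , drop = FALSE])
    Z <- sweep(vals[complete_rows, , drop = FALSE], 2L, xm)
    G <- tcrossprod(Z)
    nc <- length(complete_rows)
    for (pass in seq_len(config$max_iter)) {
      change <- 0
      for (j in cols) {
        yc <- Z[, j]
        Gj <- G - tcrossprod(yc) + diag(lambda, nc)
        a <- tryCatch(solve(Gj, yc), error = function(e) {
          stop_format("singular regression system; set ridge > 0 to regularise")
        })
        beta_full <- crossprod(Z, a)       # includes the j-th entry, excluded below
        te <- which(miss[, j])
        xt <- sweep(filled[te, , drop = FALSE], 2L, xm)
        pred <- xm[j] + xt %*% beta_full - xt[, j] * beta_full[j]
        change <- max(change, abs(pred - filled[te, j]))
        filled[te, j] <- pred
      }
      n_iter <- pass
      max_changes <- c(max_changes, change)
      if (change <= config$tol * scale) {
        converged <- TRUE
        break
      }
    }
  } else {
    for (pass in seq_len(config$max_iter)) {
      change <- 0
      for (j in cols) {
        tr <- !miss[, j]
        te <- miss[, j]
        if (sum(tr) == 0L) next            # column mean already in place
        y <- vals[tr, j]
        Xtr <- filled[tr, -j, drop = FALSE]
        xm <- colMeans(Xtr)
        ym <- mean(y)
        Xc <- sweep(Xtr, 2L, xm)
        beta <- ridge_beta(Xc, y - ym, lambda)
        pred <- ym + sweep(filled[te, -j, drop = FALSE], 2L, xm) %*% beta
        change <- max(change, abs(pred - filled[te, j]))
        filled[te, j] <- pred
      }
      n_iter <- pass
      max_changes <- c(max_changes, change)
      if (change <= config$tol * scale) {
        converged <- TRUE
        break
      }
    }
  }
  new_imputation_result(matrix, filled, config, n_iter, converged, max_changes)
}

# ridge coefficients on centred data; primal q x q solve when features are
# few, dual n x n solve when p >> n (identical solutions)
ridge_beta <- function(Xc, yc, lambda) {
  n <- nrow(Xc)
  q <- ncol(Xc)
  ch <- function(M) {
    tryCatch(chol(M), error = function(e) {
      stop_format("singular regression system; set ridge > 0 to regularise")
    })
  }
  if (q <= n) {
    U <- ch(crossprod(Xc) + diag(lambda, q))
    backsolve(U, backsolve(U, crossprod(Xc, yc), transpose = TRUE))
  } else {
    if (lambda <= 0) {
      stop_format("singular regression system; set ridge > 0 to regularise")
    }
    U <- ch(tcrossprod(Xc) + diag(lambda, n))
    crossprod(Xc, backsolve(U, backsolve(U, yc, transpose = TRUE)))
  }
}
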
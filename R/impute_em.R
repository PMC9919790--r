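#' Expectation-maximization imputation under a multivariate normal model
#'
#' Treats days as draws from a multivariate normal over the minute columns
#' and replaces each incomplete row's missing coordinates by their
#' conditional mean given the row's observed coordinates,
#' \eqn{\mu_m + \Sigma_{mo} \Sigma_{oo}^{-1} (x_o - \mu_o)}, under an
#' estimated mean vector and ridge-regularised covariance matrix
#' (`Sigma + ridge * mean(diag(Sigma)) * I`).
#'
#' When at least two fully observed rows exist, the moments are estimated
#' from those rows (classical regression imputation): they are then exact
#' sufficient statistics, do not depend on the values being imputed, and
#' the algorithm converges in one effective step. Estimating the moments
#' from the completed matrix instead — imputed rows included — has a
#' degenerate fixed point in the wide-matrix regime: once a row keeps
#' `n - 1` or more observed coordinates, its observed residual lies exactly
#' in the centred row space and the conditional mean reproduces the row's
#' own current fill, so the iteration never leaves its initialisation.
#' That completed-matrix iteration is therefore used only as the fallback
#' when fewer than two complete rows are available (scattered
#' missingness), where it is the standard EM scheme: initialise with
#' column means, alternate conditional-mean fill-in (E) with moment
#' re-estimation on the completed matrix (M), and stop when the largest
#' absolute change of an imputed cell falls below `tol * scale` (scale =
#' mean absolute observed value) or at `max_iter`.
#'
#' The regularised covariance is `S + lambda I` with `S` of rank below the
#' number of estimation rows, so the conditional mean is evaluated exactly
#' through the Woodbury identity with a small dense solve whenever the
#' number of observed coordinates exceeds the number of rows. This keeps
#' the p >> n regime — a 30-day matrix with all 1440 minute columns —
#' exact and fast without truncating features.
#'
#' @inheritParams impute
#' @return an `imputation_result`; `max_changes` records the largest
#'   imputed-cell change at each iteration.
#' @export
impute_em <- function(matrix, config = imputer_config("EM")) {
  assert_day_matrix(matrix)
  vals <- dm_values(matrix)
  miss <- is.na(vals)
  if (!any(miss)) {
    return(new_imputation_result(matrix, vals, config, 0L, TRUE))
  }
  if (nrow(vals) < 2L) stop_format("EM needs at least 2 rows")
  scale <- mean(abs(vals[!miss]))
  filled <- si_fill_values(vals)

  complete_rows <- which(rowSums(miss) == 0L)
  est_rows <- if (length(complete_rows) >= 2L) complete_rows else seq_len(nrow(vals))

  # group incomplete rows by missing pattern so each pattern is solved once
  inc_rows <- which(rowSums(miss) > 0L)
  pat_key <- apply(miss[inc_rows, , drop = FALSE], 1L,
                   function(z) paste(which(z), collapse = ","))
  groups <- split(inc_rows, pat_key)

  max_changes <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(config$max_iter)) {
    est <- filled[est_rows, , drop = FALSE]
    ne <- nrow(est)
    mu <- colMeans(est)
    B <- sweep(est, 2L, mu) / sqrt(ne - 1)   # S = t(B) %*% B
    avg_var <- mean(colSums(B^2))
    lambda <- config$ridge * avg_var
    change <- 0
    for (g in groups) {
      m <- miss[g[1L], ]
      o <- !m
      if (!any(o)) {
        new_vals <- matrix(mu[m], nrow = length(g), ncol = sum(m), byrow = TRUE)
      } else {
        r <- sweep(vals[g, o, drop = FALSE], 2L, mu[o])  # observed residuals
        Bo <- B[, o, drop = FALSE]
        Bm <- B[, m, drop = FALSE]
        w <- cond_solve(Bo, t(r), lambda)                # Sigma_oo^{-1} r
        new_vals <- sweep(t(crossprod(Bm, Bo %*% w)), 2L, mu[m], `+`)
      }
      change <- max(change, abs(new_vals - filled[g, m, drop = FALSE]))
      filled[g, m] <- new_vals
    }
    n_iter <- it
    max_changes <- c(max_changes, change)
    if (change <= config$tol * scale) {
      converged <- TRUE
      break
    }
  }
  new_imputation_result(matrix, filled, config, n_iter, converged, max_changes)
}

# Solve (t(Bo) %*% Bo + lambda I) X = R exactly, choosing the cheaper of the
# direct q x q solve and the Woodbury n x n solve (q = #observed columns).
# R is q x k.
cond_solve <- function(Bo, R, lambda) {
  n <- nrow(Bo)
  q <- ncol(Bo)
  ch <- function(M) {
    tryCatch(chol(M), error = function(e) {
      stop_format(paste0("covariance is not positive definite; ",
                         "set ridge > 0 to regularise"))
    })
  }
  if (q <= n) {
    U <- ch(crossprod(Bo) + diag(lambda, q))
    backsolve(U, backsolve(U, R, transpose = TRUE))
  } else {
    if (lambda <= 0) {
      stop_format(paste0("covariance is rank deficient (more observed columns ",
                         "than estimation rows); set ridge > 0 to regularise"))
    }
    K <- tcrossprod(Bo) + diag(lambda, n)
    U <- ch(K)
    BR <- Bo %*% R
    (R - crossprod(Bo, backsolve(U, backsolve(U, BR, transpose = TRUE)))) / lambda
  }
}
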
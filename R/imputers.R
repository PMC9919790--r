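#' Imputation method configuration
#'
#' Bundles the method selector and the hyperparameters of the five
#' imputation algorithms. Defaults mirror the documented defaults of the
#' software families each method comes from (k = 5 neighbours; missForest's
#' 100 trees, \eqn{\lceil p/3 \rceil} split candidates and minimum leaf
#' size 5; small ridge regularisation for the two linear solvers).
#'
#' @param method one of `"EM"`, `"II"`, `"KNN"`, `"RF"`, `"SI"`.
#' @param k neighbour count (kNN).
#' @param max_iter iteration cap; defaults per method: 100 (EM), 10 (II),
#'   10 (RF).
#' @param tol relative convergence threshold on the largest change of an
#'   imputed cell, in units of the mean absolute observed value; defaults
#'   1e-4 (EM) and 1e-3 (II).
#' @param ridge nonnegative regulariser for the EM covariance and the II
#'   regressions, relative to the average feature variance.
#' @param n_trees tree count (RF).
#' @param seed integer seed for the RF bootstrap/feature sampling.
#' @return an `imputer_config` list.
#' @export
imputer_config <- function(method = c("EM", "II", "KNN", "RF", "SI"),
                           k = 5L, max_iter = NULL, tol = NULL,
                           ridge = 1e-6, n_trees = 100L, seed = 1L) {
  method <- match.arg(method)
  if (is.null(max_iter)) max_iter <- switch(method, EM = 100L, 10L)
  if (is.null(tol)) tol <- switch(method, EM = 1e-4, 1e-3)
  if (!is_count(k)) stop_format("k must be a positive integer")
  if (!is_count(max_iter)) stop_format("max_iter must be a positive integer")
  if (!is_number(tol, min = 1e-300)) stop_format("tol must be > 0")
  if (!is_number(ridge, min = 0)) stop_format("ridge must be >= 0")
  if (!is_count(n_trees)) stop_format("n_trees must be a positive integer")
  structure(list(method = method, k = as.integer(k),
                 max_iter = as.integer(max_iter), tol = tol, ridge = ridge,
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "imputer_config")
}

new_imputation_result <- function(template, values, config, n_iterations,
                                  converged, max_changes = numeric(0)) {
  structure(list(imputed = dm_like(template, values),
                 method = config,
                 n_iterations = as.integer(n_iterations),
                 converged = isTRUE(converged),
                 max_changes = max_changes),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> %s: %d iteration(s), %sconverged\n",
              x$method$method, x$n_iterations, if (x$converged) "" else "not "))
  invisible(x)
}

#' Impute missing cells of a day matrix
#'
#' Dispatches to the method named in the configuration. Every imputer
#' leaves originally observed cells bitwise unchanged and returns a matrix
#' with no missing cells.
#'
#' @param matrix a [day_matrix()] with `NA` marking missing cells.
#' @param config an [imputer_config()].
#' @return an `imputation_result` with elements `imputed` (the completed
#'   [day_matrix()]), `method`, `n_iterations` and `converged`.
#' @export
impute <- function(matrix, config = imputer_config()) {
  stopifnot(inherits(config, "imputer_config"))
  switch(config$method,
         SI = impute_simple(matrix, config),
         EM = impute_em(matrix, config),
         II = impute_iterative(matrix, config),
         KNN = impute_knn(matrix, config),
         RF = impute_rf(matrix, config),
         stop_format("unknown imputation method '%s'", config$method))
}

# column means of the observed cells, empty columns falling back to the
# grand mean; the shared initialisation of EM, II and RF
si_fill_values <- function(vals) {
  if (all(is.na(vals))) {
    stop_format("matrix is entirely missing; nothing to learn from")
  }
  mu <- colMeans(vals, na.rm = TRUE)
  mu[is.nan(mu)] <- mean(vals, na.rm = TRUE)
  filled <- vals
  idx <- which(is.na(vals), arr.ind = TRUE)
  filled[idx] <- mu[idx[, 2]]
  filled
}

#' Simple (per-minute mean) imputation
#'
#' Replaces each missing cell with the arithmetic mean of the observed
#' values in its minute column; a column with no observed value at all
#' falls back to the grand mean of the matrix.
#'
#' @inheritParams impute
#' @return an `imputation_result`.
#' @export
impute_simple <- function(matrix, config = imputer_config("SI")) {
  assert_day_matrix(matrix)
  vals <- dm_values(matrix)
  new_imputation_result(matrix, si_fill_values(vals), config,
                        n_iterations = 0L, converged = TRUE)
}

#' k-nearest-neighbour imputation with missing-aware distances
#'
#' Row-to-row distances are Euclidean over the coordinates observed in both
#' rows, rescaled by `sqrt(n_features / n_shared)` so distances stay
#' comparable across row pairs with different overlap. For each missing
#' cell the donors are the rows observing that column, ranked by distance
#' (rows sharing no observed coordinate rank after all others; ties break
#' toward the lower row index), and the imputed value is the unweighted
#' mean of the `min(k, available)` nearest donors' values. A cell with no
#' donor at all falls back to the simple-imputer value.
#'
#' @inheritParams impute
#' @return an `imputation_result`.
#' @export
impute_knn <- function(matrix, config = imputer_config("KNN")) {
  assert_day_matrix(matrix)
  vals <- dm_values(matrix)
  miss <- is.na(vals)
  if (!any(miss)) {
    return(new_imputation_result(matrix, vals, config, 0L, TRUE))
  }
  if (nrow(vals) < 2L) {
    stop_format("kNN needs at least 2 rows")
  }
  n <- nrow(vals); p <- ncol(vals)
  obs <- 1 - miss                       # 0/1 mask
  x0 <- vals; x0[miss] <- 0
  n_shared <- obs %*% t(obs)
  sq <- x0^2
  # sum over shared coords of (xi - xl)^2, via masked cross-products
  d2 <- sq %*% t(obs) + obs %*% t(sq) - 2 * x0 %*% t(x0)
  d2 <- pmax(d2, 0)
  dist <- sqrt(p / n_shared * d2)       # n_shared = 0 -> Inf (no overlap)
  dist[n_shared == 0] <- Inf
  diag(dist) <- NA                      # a row never donates to itself

  fallback <- si_fill_values(vals)
  filled <- vals
  for (i in seq_len(n)) {
    cols <- which(miss[i, ])
    if (!length(cols)) next
    ord <- order(dist[i, ], seq_len(n), na.last = NA)  # drops self
    for (j in cols) {
      donors <- ord[!miss[ord, j]]
      if (!length(donors)) {
        filled[i, j] <- fallback[i, j]
      } else {
        filled[i, j] <- mean(vals[donors[seq_len(min(config$k, length(donors)))], j])
      }
    }
  }
  new_imputation_result(matrix, filled, config, 1L, TRUE)
}
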
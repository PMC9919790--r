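# Fixtures are generated in code; all values are kept positive so they pass
# the day_matrix heart-rate validity checks.

# a small day matrix with values around `center` and optional missing cells
random_dm <- function(n, p, seed, miss_frac = 0, center = 80, sd = 8) {
  set.seed(seed)
  vals <- matrix(center + rnorm(n * p, 0, sd), n, p)
  if (miss_frac > 0) {
    holes <- sample(n * p, round(miss_frac * n * p))
    vals[holes] <- NA_real_
  }
  # keep at least one observed value per column so column means exist
  for (j in seq_len(p)) {
    if (all(is.na(vals[, j]))) vals[1, j] <- center
  }
  day_matrix(vals)
}

# equicorrelated Gaussian day matrix (pairwise correlation rho), positive
gaussian_dm <- function(n, p, rho, seed, center = 100, sd = 5) {
  set.seed(seed)
  shared <- rnorm(n)
  vals <- center + sd * (sqrt(rho) * matrix(shared, n, p) +
                         sqrt(1 - rho) * matrix(rnorm(n * p), n, p))
  day_matrix(vals)
}

# brute-force kNN imputation oracle: double loops, no linear algebra
knn_oracle <- function(dm, k) {
  vals <- unclass(dm)
  attr(vals, "col_offset") <- NULL
  class(vals) <- NULL
  vals <- matrix(as.numeric(vals), nrow(dm), ncol(dm))
  miss <- is.na(vals)
  n <- nrow(vals); p <- ncol(vals)
  dist <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    for (l in seq_len(n)) {
      if (i == l) next
      shared <- which(!miss[i, ] & !miss[l, ])
      if (length(shared) > 0) {
        dist[i, l] <- sqrt(p / length(shared) *
                             sum((vals[i, shared] - vals[l, shared])^2))
      }
    }
  }
  mu <- colMeans(vals, na.rm = TRUE)
  mu[is.nan(mu)] <- mean(vals, na.rm = TRUE)
  out <- vals
  for (i in seq_len(n)) {
    others <- seq_len(n)[-i]
    donors_by_rank <- others[order(dist[i, others], others)]
    for (j in which(miss[i, ])) {
      donors <- donors_by_rank[!miss[donors_by_rank, j]]
      if (length(donors) == 0) {
        out[i, j] <- mu[j]
      } else {
        out[i, j] <- mean(vals[donors[seq_len(min(k, length(donors)))], j])
      }
    }
  }
  out
}

dm_vals <- function(dm) {
  v <- unclass(dm)
  attr(v, "col_offset") <- NULL
  matrix(as.numeric(v), nrow(dm), ncol(dm), dimnames = dimnames(dm))
}

# tiny default synthetic configuration used across tests where the full
# 30-day default would be wasteful
small_synth <- function(n_days = 10, seed = 42, ...) {
  synth_config(n_days = n_days, seed = seed, ...)
}
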
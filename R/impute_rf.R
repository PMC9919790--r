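#' Iterative random-forest imputation (missForest scheme)
#'
#' Initialises missing cells with column means, then cycles over the
#' incomplete columns in ascending order of missing count, each time
#' training a random-forest regressor of the column on all other columns
#' using the rows where the column was originally observed, and predicting
#' the column's missing cells. After each full pass the change statistic
#' `sum((new - old)^2) / sum(new^2)` over the imputed cells is evaluated;
#' the algorithm stops and returns the previous pass's values as soon as
#' the statistic increases, or at `max_iter`.
#'
#' The forest is built from first principles in compiled code: `n_trees`
#' bagged regression trees, each grown on a bootstrap sample of the
#' training rows with \eqn{\lceil p/3 \rceil} candidate features per
#' split, variance-reduction split selection, and a minimum leaf size of 5
#' bootstrap samples. All randomness flows from `config$seed` through a
#' dedicated generator, so equal inputs give bitwise-equal outputs.
#'
#' @inheritParams impute
#' @return an `imputation_result`.
#' @export
impute_rf <- function(matrix, config = imputer_config("RF")) {
  assert_day_matrix(matrix)
  vals <- dm_values(matrix)
  if (!anyNA(vals)) {
    return(new_imputation_result(matrix, vals, config, 0L, TRUE))
  }
  if (nrow(vals) < 2L || ncol(vals) < 2L) {
    stop_format("random-forest imputation needs at least 2 rows and 2 columns")
  }
  res <- rf_missforest_impl(vals, config$n_trees, 5L, config$max_iter,
                            config$seed)
  new_imputation_result(matrix, res$imputed, config, res$n_iterations,
                        res$converged)
}
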
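# Hyperparameter grid search and sensitivity sweeps.

#' Default penalty grid
#'
#' Powers of two from 2^-8 to 2^5, the range searched when selecting
#' lambda and beta on the full SL corpus.
#'
#' @return Numeric vector of 14 grid values.
#' @export
default_grid <- function() 2^seq(-8, 5)

#' Grid search for the penalty weights lambda and beta
#'
#' Evaluates [cross_validate()] at every (lambda, beta) combination on the
#' *same* fold split (fixed by `seed`) and returns the combination with
#' the highest mean AUC. Ties are broken toward the smaller lambda, then
#' the smaller beta (prefer the lighter penalty). Because tuning and
#' reporting share one split, the selected mean AUC is optimistically
#' biased; treat it as a selection score, not an unbiased estimate.
#'
#' @param X An `"sl_matrix"`.
#' @param graph A `"similarity_graph"` (required when any beta > 0).
#' @param lambda_grid,beta_grid Positive candidate values; `beta_grid` may
#'   additionally contain 0 for the SMF ablation.
#' @param control Base [grsmf_control()]; lambda/beta are overridden per
#'   grid point.
#' @param n_folds,seed Passed to [cross_validate()].
#' @param n_negative Optional negative-set cap per fold, passed through.
#' @return Object of class `"grid_search"`: list with `best_lambda`,
#'   `best_beta`, `best_mean_auc` and `results` (data frame `lambda`,
#'   `beta`, `mean_auc`, `ci_halfwidth`, plus one `auc_fold<k>` column per
#'   fold; exactly `length(lambda_grid) * length(beta_grid)` rows).
#' @export
grid_search <- function(X, graph = NULL, lambda_grid = default_grid(),
                        beta_grid = default_grid(),
                        control = grsmf_control(), n_folds = 5L, seed = 1L,
                        n_negative = NULL) {
  if (length(lambda_grid) == 0L || length(beta_grid) == 0L) {
    stop("lambda_grid and beta_grid must be non-empty")
  }
  if (any(lambda_grid < 0) || any(beta_grid < 0)) {
    stop("grid values must be non-negative")
  }
  if (any(lambda_grid == 0)) stop("lambda_grid values must be positive")
  combos <- expand.grid(lambda = lambda_grid, beta = beta_grid,
                        KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    ctl <- control
    ctl$lambda <- combos$lambda[r]
    ctl$beta <- combos$beta[r]
    rep <- cross_validate(X, graph, ctl, n_folds, seed, n_negative)
    c(lambda = ctl$lambda, beta = ctl$beta, mean_auc = rep$mean_auc,
      ci_halfwidth = rep$ci_halfwidth,
      stats::setNames(rep$per_fold_auc,
                      paste0("auc_fold", seq_len(n_folds) - 1L)))
  })
  results <- as.data.frame(do.call(rbind, rows))
  # argmax by mean AUC; ties -> smallest lambda, then smallest beta
  ord <- order(-results$mean_auc, results$lambda, results$beta)
  best <- results[ord[1L], ]
  structure(list(best_lambda = best$lambda, best_beta = best$beta,
                 best_mean_auc = best$mean_auc, results = results),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat("grid_search over", nrow(x$results), "combinations\n")
  cat("  best: lambda =", format(x$best_lambda), "beta =",
      format(x$best_beta), "mean AUC =",
      formatC(x$best_mean_auc, digits = 4, format = "f"), "\n")
  invisible(x)
}

#' One-dimensional sensitivity sweep of lambda or beta
#'
#' Fixes one penalty weight and sweeps the other over `grid`, reporting
#' the cross-validated mean AUC and its interval at each value
#' (the material for lambda/beta sensitivity curves).
#'
#' @param X An `"sl_matrix"`.
#' @param graph A `"similarity_graph"`.
#' @param sweep `"lambda"` or `"beta"`: the parameter being varied.
#' @param grid Values for the swept parameter (non-empty).
#' @param fixed_value Value of the other parameter (defaults: beta fixed
#'   at 2^-5 when sweeping lambda, lambda fixed at 2^-7 when sweeping
#'   beta).
#' @param control,n_folds,seed,n_negative As in [grid_search()].
#' @return Data frame with columns `<sweep parameter>`, `mean_auc`,
#'   `ci_halfwidth`, one row per grid value.
#' @export
sensitivity_sweep <- function(X, graph = NULL,
                              sweep = c("lambda", "beta"), grid,
                              fixed_value = NULL,
                              control = grsmf_control(), n_folds = 5L,
                              seed = 1L, n_negative = NULL) {
  sweep <- match.arg(sweep)
  if (missing(grid) || length(grid) == 0L) stop("sweep grid is empty")
  if (is.null(fixed_value)) {
    fixed_value <- if (sweep == "lambda") 2^-5 else 2^-7
  }
  rows <- lapply(grid, function(v) {
    ctl <- control
    if (sweep == "lambda") {
      ctl$lambda <- v
      ctl$beta <- fixed_value
    } else {
      ctl$beta <- v
      ctl$lambda <- fixed_value
    }
    rep <- cross_validate(X, graph, ctl, n_folds, seed, n_negative)
    c(v, rep$mean_auc, rep$ci_halfwidth)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(sweep, "mean_auc", "ci_halfwidth")
  out
}
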
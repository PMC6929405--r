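# GRSMF core: objective, gradient split, relaxed-MM multiplicative updates,
# convergence loop, and prediction X_hat = U' X U.

#' Control parameters for GRSMF fitting
#'
#' @param lambda Non-negative l2 penalty weight on U. Default `2^-7`,
#'   the value selected by grid search on the full SL corpus.
#' @param beta Non-negative graph-regularization weight. Default `2^-5`;
#'   `beta = 0` gives the plain self-representative model (SMF).
#' @param tol Stopping tolerance on the relative change of the objective,
#'   `|J(t+1) - J(t)| / |J(t)| < tol`. Default `1e-4`. When `J(t)` is 0
#'   the test falls back to absolute change.
#' @param max_iter Maximum number of multiplicative updates (default 1000).
#' @param eps_div Floor applied to denominators of the update rule so that
#'   zero gradients on sparse data never divide by zero. Default `1e-12`.
#' @param init `"uniform"` (deterministic, all entries 1/n) or
#'   `"dirichlet"` (each column drawn from a symmetric Dirichlet).
#' @param seed Integer seed used by `"dirichlet"` initialization.
#' @param dirichlet_alpha Concentration of the symmetric Dirichlet.
#' @param renormalize_columns If `TRUE`, rescale each column of U to sum
#'   exactly 1 after every update (then clip to \[0,1\] and rescale once
#'   more). Default `FALSE`: the update rule is applied literally and
#'   column-sum drift is only monitored.
#' @param ascent_slack Absolute floor on the tolerated per-iteration
#'   objective increase. The relaxed-MM update is not provably monotone:
#'   transient ascents of a fraction of a percent that still converge are
#'   normal (observed with `beta = 0` on sparse masked data). Default
#'   `1e-9`.
#' @param divergence_tol Relative ascent threshold: an iteration counts as
#'   a divergence violation when the objective grows by more than
#'   `ascent_slack + divergence_tol * |J|`. Default `0.02`.
#' @param max_ascent Number of consecutive violating iterations before the
#'   fit aborts with a divergence error. Default 5.
#' @return A list of class `"grsmf_control"`.
#' @export
grsmf_control <- function(lambda = 2^-7, beta = 2^-5, tol = 1e-4,
                          max_iter = 1000L, eps_div = 1e-12,
                          init = c("uniform", "dirichlet"), seed = 1L,
                          dirichlet_alpha = 1,
                          renormalize_columns = FALSE,
                          ascent_slack = 1e-9, divergence_tol = 0.02,
                          max_ascent = 5L) {
  init <- match.arg(init)
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0,
            is.numeric(beta), length(beta) == 1L, beta >= 0,
            is.numeric(tol), tol > 0,
            is.numeric(max_iter), max_iter >= 1,
            is.numeric(eps_div), eps_div > 0,
            is.logical(renormalize_columns))
  structure(list(lambda = lambda, beta = beta, tol = tol,
                 max_iter = as.integer(max_iter), eps_div = eps_div,
                 init = init, seed = as.integer(seed),
                 dirichlet_alpha = dirichlet_alpha,
                 renormalize_columns = renormalize_columns,
                 ascent_slack = ascent_slack,
                 divergence_tol = divergence_tol,
                 max_ascent = as.integer(max_ascent)),
            class = "grsmf_control")
}

#' Initialize the representation matrix U
#'
#' Columns live on the probability simplex and are strictly positive so
#' that multiplicative updates never freeze an entry at zero.
#'
#' @param n Number of genes (at least 2).
#' @param control A [grsmf_control()]; `init`, `seed` and
#'   `dirichlet_alpha` are used.
#' @return An n x n matrix with entries in (0, 1\] and unit column sums.
#' @export
initialize_U <- function(n, control = grsmf_control()) {
  if (n < 2) stop("n must be at least 2")
  if (control$init == "uniform") {
    matrix(1 / n, n, n)
  } else {
    U <- with_seed(control$seed, {
      g <- matrix(stats::rgamma(n * n, shape = control$dirichlet_alpha), n, n)
      # guard against exact zeros from underflow
      g[g < .Machine$double.xmin] <- .Machine$double.xmin
      g
    })
    sweep(U, 2L, colSums(U), "/")
  }
}

#' GRSMF objective value
#'
#' `J(U) = ||X - U'XU||_F^2 + lambda * ||U||_F^2 + beta * Tr(U'LU)`.
#' With `beta = 0` (or no graph) this is the plain SMF objective.
#'
#' @param X Interaction matrix (`"sl_matrix"` or plain 0/1 matrix).
#' @param U Representation matrix.
#' @param graph Optional `"similarity_graph"`; required when `beta > 0`.
#' @param lambda,beta Penalty weights.
#' @return A single non-negative finite number.
#' @export
grsmf_objective <- function(X, U, graph = NULL, lambda = 2^-7, beta = 2^-5) {
  X <- as_X(X)
  R <- X - crossprod(U, X %*% U)
  fit_term <- sum(R * R)
  if (!is.finite(fit_term)) stop("non-finite self-representation residual")
  pen_l2 <- lambda * sum(U * U)
  if (!is.finite(pen_l2)) stop("non-finite l2 penalty term")
  pen_graph <- 0
  if (beta > 0) {
    if (is.null(graph)) stop("beta > 0 requires a similarity graph")
    pen_graph <- beta * graph_penalty(U, graph)
    if (!is.finite(pen_graph)) stop("non-finite graph penalty term")
  }
  fit_term + pen_l2 + pen_graph
}

#' Graph-Laplacian penalty Tr(U'LU)
#'
#' Equals the pairwise form `1/2 * sum_l sum_ij (U[i,l] - U[j,l])^2 * S[i,j]`,
#' hence is non-negative for any real U.
#'
#' @param U Representation matrix.
#' @param graph A `"similarity_graph"`.
#' @return `Tr(U' L U)` as a single number.
#' @export
graph_penalty <- function(U, graph) {
  stopifnot(inherits(graph, "similarity_graph"))
  if (nrow(U) != nrow(graph$L)) {
    stop("U has ", nrow(U), " rows but the graph has ",
         nrow(graph$L), " genes")
  }
  # Tr(U'LU) = Tr(U'DU) - Tr(U'SU); D diagonal so U'DU contributes
  # sum_i degree_i * ||U[i,]||^2
  sum(graph$degree * rowSums(U * U)) - sum(U * (graph$S %*% U))
}

#' Split gradient of the GRSMF objective
#'
#' The gradient with respect to U is
#' `4(XU)(U'XU) + 2*lambda*U + 2*beta*(DU) - 4(XU)X - 2*beta*(SU)`,
#' split into its elementwise non-negative positive and negative parts
#' (both are products of non-negative matrices when U >= 0).
#'
#' @inheritParams grsmf_objective
#' @return List with elements `pos` and `neg`, both n x n and
#'   elementwise non-negative; `pos - neg` is the full gradient.
#' @export
gradient_split <- function(X, U, graph = NULL, lambda = 2^-7, beta = 2^-5) {
  X <- as_X(X)
  XU <- X %*% U
  pos <- 4 * XU %*% crossprod(U, XU) + 2 * lambda * U
  neg <- 4 * XU %*% X
  if (beta > 0) {
    if (is.null(graph)) stop("beta > 0 requires a similarity graph")
    pos <- pos + 2 * beta * (graph$degree * U)  # (DU)[l,i] = degree[l]*U[l,i]
    neg <- neg + 2 * beta * (graph$S %*% U)
  }
  if (any(!is.finite(pos)) || any(!is.finite(neg))) {
    stop("non-finite gradient encountered")
  }
  list(pos = pos, neg = neg)
}

#' Per-column scalars of the relaxed-MM update
#'
#' `a[i] = sum_l U[l,i] / pos[l,i]` and
#' `b[i] = sum_l U[l,i] * neg[l,i] / pos[l,i]`, with the denominator
#' floored at `eps_div`. These arise from the simplex constraint's
#' Lagrange multiplier in the majorization step.
#'
#' @param U Representation matrix.
#' @param grad Gradient split, as returned by [gradient_split()].
#' @param eps_div Denominator floor.
#' @return List with numeric vectors `a` and `b` (length n, non-negative).
#' @export
compute_column_scalars <- function(U, grad, eps_div = 1e-12) {
  pos <- pmax(grad$pos, eps_div)
  a <- colSums(U / pos)
  b <- colSums(U * grad$neg / pos)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("non-finite column scalars; denominator guard eps_div = ", eps_div)
  }
  list(a = a, b = b)
}

#' One multiplicative update of U
#'
#' `U[l,i] <- U[l,i] * (a[i]*neg[l,i] + 1) / (a[i]*pos[l,i] + b[i])`.
#' Entries stay non-negative from a non-negative start; the denominator is
#' floored at `eps_div`. With `renormalize_columns` each column is rescaled
#' to unit sum, clipped to \[0,1\], and rescaled once more.
#'
#' @param U Current representation matrix.
#' @param grad Gradient split from [gradient_split()].
#' @param scalars Column scalars from [compute_column_scalars()].
#' @param control A [grsmf_control()].
#' @return Updated matrix U'.
#' @export
update_U <- function(U, grad, scalars, control = grsmf_control()) {
  n <- nrow(U)
  a_row <- rep(scalars$a, each = n)  # a_i constant down column i
  b_row <- rep(scalars$b, each = n)
  num <- a_row * grad$neg + 1
  den <- pmax(a_row * grad$pos + b_row, control$eps_div)
  U_new <- U * num / den
  if (any(!is.finite(U_new))) stop("non-finite entries after update")
  if (control$renormalize_columns) {
    U_new <- sweep(U_new, 2L, pmax(colSums(U_new), control$eps_div), "/")
    U_new[U_new > 1] <- 1
    U_new <- sweep(U_new, 2L, pmax(colSums(U_new), control$eps_div), "/")
  }
  U_new
}

#' Fit the GRSMF model
#'
#' Iterates gradient split, per-column scalars and the multiplicative
#' update, recording the objective each iteration, until the relative
#' objective change drops below `control$tol` or `control$max_iter` is
#' reached. The fit aborts with an error if the objective increases beyond
#' `ascent_slack` for more than `max_ascent` consecutive iterations.
#'
#' @param X Interaction matrix (`"sl_matrix"` or plain symmetric 0/1
#'   matrix).
#' @param graph Optional `"similarity_graph"` sharing X's gene index;
#'   required when `control$beta > 0`.
#' @param control A [grsmf_control()].
#' @return Object of class `"grsmf_fit"`: list with `U`, `trace`
#'   (objective values, element 1 = initial value), `n_iter`, `converged`,
#'   `final_relative_change`, `column_sum_drift` (max |colsum - 1|),
#'   `genes`, `X` and `control`.
#' @examples
#' sim <- generate_synthetic(synthetic_scenario(n_genes = 40, n_groups = 4,
#'   sl_group_pairs = list(c(1, 2), c(3, 4)), seed = 7))
#' fit <- grsmf_fit(sim$interactions, sim$similarity,
#'                  grsmf_control(max_iter = 50))
#' fit$converged
#' @export
grsmf_fit <- function(X, graph = NULL, control = grsmf_control()) {
  slm <- if (inherits(X, "sl_matrix")) X else NULL
  Xm <- as_X(X)
  n <- nrow(Xm)
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "similarity_graph"))
    if (nrow(graph$S) != n) {
      stop("interaction matrix (", n, " genes) and similarity graph (",
           nrow(graph$S), " genes) do not match")
    }
    if (!is.null(slm) && !identical(unclass(slm$genes),
                                    unclass(graph$genes))) {
      stop("interaction matrix and similarity graph index different genes")
    }
  }
  U <- initialize_U(n, control)
  J <- grsmf_objective(Xm, U, graph, control$lambda, control$beta)
  trace <- numeric(control$max_iter + 1L)
  trace[1L] <- J
  converged <- FALSE
  rel_change <- NA_real_
  ascents <- 0L
  t <- 0L
  while (t < control$max_iter) {
    t <- t + 1L
    grad <- gradient_split(Xm, U, graph, control$lambda, control$beta)
    scalars <- compute_column_scalars(U, grad, control$eps_div)
    U <- update_U(U, grad, scalars, control)
    J_new <- grsmf_objective(Xm, U, graph, control$lambda, control$beta)
    trace[t + 1L] <- J_new
    if (J_new > J + control$ascent_slack + control$divergence_tol * abs(J)) {
      ascents <- ascents + 1L
      if (ascents > control$max_ascent) {
        stop("optimizer divergence: objective increased for ", ascents,
             " consecutive iterations (iteration ", t, ", J = ",
             format(J_new), ")")
      }
    } else {
      ascents <- 0L
    }
    rel_change <- if (J != 0) abs(J_new - J) / abs(J) else abs(J_new - J)
    J <- J_new
    if (rel_change < control$tol) {
      converged <- TRUE
      break
    }
  }
  genes <- if (!is.null(slm)) slm$genes else
    gene_index(rownames(Xm) %||% as.character(seq_len(n)), sort = FALSE)
  dimnames(U) <- list(unclass(genes), unclass(genes))
  structure(list(U = U, trace = trace[seq_len(t + 1L)], n_iter = t,
                 converged = converged, final_relative_change = rel_change,
                 column_sum_drift = max(abs(colSums(U) - 1)),
                 genes = genes, X = Xm, control = control),
            class = "grsmf_fit")
}

#' @export
print.grsmf_fit <- function(x, ...) {
  cat("grsmf_fit:", length(x$genes), "genes | lambda =",
      format(x$control$lambda), "beta =", format(x$control$beta), "\n")
  cat("  ", x$n_iter, " iterations, converged = ", x$converged,
      ", objective ", format(x$trace[1], digits = 6), " -> ",
      format(x$trace[length(x$trace)], digits = 6), "\n", sep = "")
  cat("  max column-sum drift:", format(x$column_sum_drift, digits = 3), "\n")
  invisible(x)
}

#' Predicted interaction score matrix X_hat = U' X U
#'
#' Symmetric and non-negative because X is symmetric non-negative and
#' U is non-negative.
#'
#' @param X Interaction matrix used in training.
#' @param U Representation matrix (e.g. `fit$U`).
#' @return Numeric n x n score matrix with X's dimnames.
#' @export
grsmf_predict <- function(X, U) {
  X <- as_X(X)
  if (nrow(U) != nrow(X)) {
    stop("U (", nrow(U), " rows) does not match X (", nrow(X), " genes)")
  }
  X_hat <- crossprod(U, X %*% U)
  dimnames(X_hat) <- dimnames(X)
  X_hat
}

#' @param object A `"grsmf_fit"`.
#' @param ... Unused.
#' @rdname grsmf_predict
#' @export
predict.grsmf_fit <- function(object, ...) {
  grsmf_predict(object$X, object$U)
}

# --- internal helpers --------------------------------------------------------

as_X <- function(X) {
  if (inherits(X, "sl_matrix")) X$X else {
    stopifnot(is.matrix(X), nrow(X) == ncol(X))
    X
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
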
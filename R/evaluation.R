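# Cross-validation over known SL pairs and rank-based AUC.

#' Split the known SL pairs into cross-validation folds
#'
#' The positive (known) unordered pairs are partitioned into `n_folds`
#' non-overlapping subsets of as-equal-as-possible size (sizes differ by at
#' most one). The assignment is deterministic for a given seed.
#'
#' @param X An `"sl_matrix"`.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return Object of class `"cv_folds"`: list with `pairs` (data frame
#'   `gene_a`, `gene_b`, `fold` with fold ids 0..n_folds-1), `n_folds`,
#'   `seed`.
#' @export
make_folds <- function(X, n_folds = 5L, seed = 1L) {
  stopifnot(inherits(X, "sl_matrix"))
  idx <- which(upper.tri(X$X) & X$X == 1L, arr.ind = TRUE)
  npos <- nrow(idx)
  if (npos < n_folds) {
    stop("only ", npos, " positive pairs but ", n_folds, " folds requested")
  }
  fold <- with_seed(seed, {
    sample(rep_len(seq_len(n_folds) - 1L, npos))
  })
  genes <- unclass(X$genes)
  pairs <- data.frame(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
                      fold = fold, stringsAsFactors = FALSE)
  structure(list(pairs = pairs, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "cv_folds")
}

#' Mask one fold's positive pairs out of the training matrix
#'
#' Both orientations (i, j) and (j, i) of every held-out pair are set to 0,
#' so the training matrix stays symmetric with a zero diagonal.
#'
#' @param X An `"sl_matrix"`.
#' @param folds A `"cv_folds"` from [make_folds()].
#' @param fold_id Fold to hold out (0-based, as stored in `folds`).
#' @return List with `train` (an `"sl_matrix"`) and `test_pairs`
#'   (data frame `gene_a`, `gene_b` of held-out unordered pairs).
#' @export
mask_test_fold <- function(X, folds, fold_id) {
  stopifnot(inherits(X, "sl_matrix"), inherits(folds, "cv_folds"))
  if (!fold_id %in% (seq_len(folds$n_folds) - 1L)) {
    stop("fold_id must be in 0..", folds$n_folds - 1L)
  }
  test <- folds$pairs[folds$pairs$fold == fold_id, c("gene_a", "gene_b")]
  Xtr <- X$X
  i <- match(test$gene_a, unclass(X$genes))
  j <- match(test$gene_b, unclass(X$genes))
  Xtr[cbind(i, j)] <- 0L
  Xtr[cbind(j, i)] <- 0L
  list(train = new_sl_matrix(Xtr, X$genes), test_pairs = test)
}

#' Rank-based AUC over scored gene pairs
#'
#' The probability that a randomly chosen positive pair scores above a
#' randomly chosen negative pair, ties counted one-half; equivalent to the
#' Mann-Whitney statistic.
#'
#' @param scores Score matrix (e.g. from [grsmf_predict()]) or a
#'   `"grsmf_fit"`.
#' @param positive_pairs,negative_pairs Two-column data frames or matrices
#'   of gene identifiers; the sets must be disjoint and non-empty.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, positive_pairs, negative_pairs) {
  if (inherits(scores, "grsmf_fit")) scores <- predict(scores)
  sp <- pair_scores(scores, positive_pairs)
  sn <- pair_scores(scores, negative_pairs)
  if (length(sp) == 0L) stop("no positive pairs supplied")
  if (length(sn) == 0L) stop("no negative pairs supplied")
  r <- rank(c(sp, sn))  # average ranks implement the half-tie convention
  P <- length(sp)
  (sum(r[seq_len(P)]) - P * (P + 1) / 2) / (P * length(sn))
}

pair_scores <- function(scores, pairs) {
  pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
  if (nrow(pairs) == 0L) return(numeric(0))
  i <- match(pairs[, 1L], rownames(scores))
  j <- match(pairs[, 2L], colnames(scores))
  if (any(is.na(i)) || any(is.na(j))) {
    stop("pair list mentions genes absent from the score matrix")
  }
  scores[cbind(i, j)]
}

#' All unordered unknown (non-interacting) pairs of an SL matrix
#'
#' The candidate/negative set: pairs (i < j) with `X[i, j] == 0`.
#'
#' @param X An `"sl_matrix"`.
#' @param n_sample Optionally subsample this many negatives (seeded) for
#'   speed at large scale; `NULL` (default) keeps all.
#' @param seed Seed for subsampling.
#' @return Data frame `gene_a`, `gene_b`.
#' @export
unknown_pairs <- function(X, n_sample = NULL, seed = 1L) {
  stopifnot(inherits(X, "sl_matrix"))
  idx <- which(upper.tri(X$X) & X$X == 0L, arr.ind = TRUE)
  if (!is.null(n_sample) && n_sample < nrow(idx)) {
    keep <- with_seed(seed, sample.int(nrow(idx), n_sample))
    idx <- idx[keep, , drop = FALSE]
  }
  genes <- unclass(X$genes)
  data.frame(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' 5-fold cross-validated AUC of the GRSMF model
#'
#' For each fold: the fold's positive pairs are masked out of X, the model
#' is fitted on the remainder, and the AUC is computed with the held-out
#' pairs as positives and the unknown pairs of the *full* matrix as
#' negatives (training positives belong to neither class). The summary
#' interval is the normal approximation `mean +/- 1.96 * sd / sqrt(k)`
#' across folds.
#'
#' @param X An `"sl_matrix"`.
#' @param graph Optional `"similarity_graph"` (required when
#'   `control$beta > 0`).
#' @param control A [grsmf_control()].
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for the fold split (and negative subsampling).
#' @param n_negative Optional cap on the number of negatives per fold
#'   (seeded subsample) for speed; default keeps all unknown pairs.
#' @return Object of class `"cv_report"`: list with `per_fold_auc`,
#'   `mean_auc`, `sd_auc`, `ci_halfwidth`, `n_folds`, `seed`.
#' @export
cross_validate <- function(X, graph = NULL, control = grsmf_control(),
                           n_folds = 5L, seed = 1L, n_negative = NULL) {
  folds <- make_folds(X, n_folds, seed)
  negatives <- unknown_pairs(X, n_sample = n_negative, seed = seed)
  aucs <- vapply(seq_len(n_folds) - 1L, function(k) {
    m <- mask_test_fold(X, folds, k)
    fit <- grsmf_fit(m$train, graph, control)
    auc_score(predict(fit), m$test_pairs, negatives)
  }, numeric(1))
  sd_auc <- stats::sd(aucs)
  structure(list(per_fold_auc = aucs, mean_auc = mean(aucs),
                 sd_auc = sd_auc,
                 ci_halfwidth = 1.96 * sd_auc / sqrt(n_folds),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report (", x$n_folds, "-fold, seed ", x$seed, ")\n", sep = "")
  cat("  per-fold AUC:",
      paste(formatC(x$per_fold_auc, digits = 4, format = "f"),
            collapse = " "), "\n")
  cat("  mean AUC: ", formatC(x$mean_auc, digits = 4, format = "f"),
      " +/- ", formatC(x$ci_halfwidth, digits = 4, format = "f"),
      " (95% CI)\n", sep = "")
  invisible(x)
}

#' Write a cross-validation report as TSV
#'
#' One row per fold plus a `mean` summary row.
#'
#' @param report A `"cv_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  d <- data.frame(fold = c(seq_along(report$per_fold_auc) - 1L, NA),
                  auc = c(report$per_fold_auc, report$mean_auc),
                  label = c(rep("fold", length(report$per_fold_auc)), "mean"))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
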
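# Candidate discovery: descending ranking of unknown pairs by predicted
# interaction score.

#' Rank unknown gene pairs by predicted interaction score
#'
#' Known SL pairs (X = 1) and self-pairs are excluded; each remaining
#' unordered pair appears once, sorted by score descending with ties
#' broken lexicographically by (gene_a, gene_b), so the ranking is fully
#' deterministic.
#'
#' @param X An `"sl_matrix"` (the training data).
#' @param X_hat Score matrix from [grsmf_predict()], or a `"grsmf_fit"`.
#' @param top_k Number of rows to keep (default 10); capped at the number
#'   of unknown pairs.
#' @return Data frame `rank`, `gene_a`, `gene_b`, `score`.
#' @export
rank_candidates <- function(X, X_hat, top_k = 10L) {
  stopifnot(inherits(X, "sl_matrix"), top_k >= 1)
  if (inherits(X_hat, "grsmf_fit")) X_hat <- predict(X_hat)
  if (!all(dim(X_hat) == dim(X$X))) {
    stop("score matrix dimensions do not match the interaction matrix")
  }
  idx <- which(upper.tri(X$X) & X$X == 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no unknown pairs to rank")
  genes <- unclass(X$genes)
  a <- genes[idx[, 1L]]
  b <- genes[idx[, 2L]]
  # gene_a is the lexicographically smaller name (index is sorted, but be
  # explicit so ties break identically for any index order)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  score <- X_hat[idx]
  ord <- order(-score, a, b, method = "radix")
  keep <- utils::head(ord, top_k)
  data.frame(rank = seq_along(keep), gene_a = a[keep], gene_b = b[keep],
             score = score[keep], stringsAsFactors = FALSE)
}

#' Write a candidate ranking as TSV
#'
#' Columns `rank`, `gene_a`, `gene_b`, `score`; scores are printed with
#' 4 decimal places.
#'
#' @param ranking Data frame from [rank_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  out <- ranking
  out$score <- formatC(out$score, digits = 4, format = "f")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a training trace as TSV
#'
#' Two columns: `iteration` (0 = initial value) and `objective`.
#'
#' @param fit A `"grsmf_fit"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  d <- data.frame(iteration = seq_along(fit$trace) - 1L,
                  objective = fit$trace)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
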
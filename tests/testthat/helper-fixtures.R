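# Shared fixtures and independent oracles.

# random symmetric 0/1 matrix with zero diagonal, as sl_matrix
random_X <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  X <- matrix(0L, n, n)
  X[upper.tri(X)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  X <- X + t(X)
  genes <- sprintf("g%02d", seq_len(n))
  dimnames(X) <- list(genes, genes)
  grsmf:::new_sl_matrix(X, gene_index(genes))
}

# random similarity graph on the same gene names as random_X(n)
random_graph <- function(n, seed = 1) {
  set.seed(seed)
  S <- matrix(stats::runif(n * n), n, n)
  build_similarity_graph(S, sprintf("g%02d", seq_len(n)))
}

# random strictly positive column-stochastic U
random_simplex_U <- function(n, seed = 1) {
  set.seed(seed)
  U <- matrix(stats::rgamma(n * n, 1) + 1e-6, n, n)
  sweep(U, 2, colSums(U), "/")
}

# oracle: centered finite-difference gradient of the objective
fd_gradient <- function(X, U, graph, lambda, beta, h = 1e-6) {
  n <- nrow(U)
  G <- matrix(0, n, n)
  for (l in seq_len(n)) {
    for (i in seq_len(n)) {
      Up <- U; Up[l, i] <- Up[l, i] + h
      Um <- U; Um[l, i] <- Um[l, i] - h
      G[l, i] <- (grsmf_objective(X, Up, graph, lambda, beta) -
                    grsmf_objective(X, Um, graph, lambda, beta)) / (2 * h)
    }
  }
  G
}

# oracle: graph penalty as the explicit pairwise double sum
# 1/2 * sum_l sum_ij (U[i,l] - U[j,l])^2 S[i,j]
pairwise_graph_penalty <- function(U, S) {
  n <- nrow(U)
  acc <- 0
  for (l in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        acc <- acc + (U[i, l] - U[j, l])^2 * S[i, j]
      }
    }
  }
  acc / 2
}

# oracle: brute-force pair-counting AUC with half-tie convention
brute_auc <- function(pos_scores, neg_scores) {
  acc <- 0
  for (p in pos_scores) {
    for (q in neg_scores) {
      acc <- acc + (p > q) + 0.5 * (p == q)
    }
  }
  acc / (length(pos_scores) * length(neg_scores))
}

# small scenario for fast pipeline tests
small_scenario <- function(seed = 1, ...) {
  synthetic_scenario(n_genes = 60L, n_groups = 4L,
                     sl_group_pairs = list(c(1L, 2L), c(3L, 4L)),
                     p_in = 0.35, p_out = 0.01, seed = seed, ...)
}
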
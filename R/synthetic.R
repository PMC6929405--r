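# Seeded generator of SL networks with planted cross-group structure and a
# correlated within-group similarity matrix.

#' Describe a synthetic SL scenario
#'
#' Genes are partitioned into functional groups. SL edges are planted
#' *between* designated partner groups (compensatory-pathway intuition:
#' losing one member of each of two back-up pathways is lethal), with
#' probability `p_in` for pairs whose groups are designated partners and
#' `p_out` otherwise. Functional similarity is high *within* groups:
#' `S[i,j] = sim_signal * [same group] + Normal(0, sim_noise)`, clipped to
#' \[0, 1\]. So S is informative about the representation structure without
#' directly encoding the interaction matrix.
#'
#' Defaults describe the reference scenario used throughout the test
#' suite: 150 genes in 6 groups of 25, partner pairs (1,2), (3,4), (5,6),
#' `p_in = 0.3`, `p_out = 0.01`, `sim_signal = 0.8`, `sim_noise = 0.1`.
#'
#' @param n_genes Number of genes.
#' @param n_groups Number of groups; sizes default to equal (remainder
#'   spread over the first groups).
#' @param group_sizes Optional explicit sizes, must sum to `n_genes`.
#' @param sl_group_pairs List of length-2 integer vectors naming the
#'   partner group pairs carrying `p_in` edges. Defaults to consecutive
#'   groups (1,2), (3,4), ... — three partner pairs under the default
#'   six groups.
#' @param p_in,p_out Edge probabilities, `0 <= p_out < p_in <= 1`
#'   (`p_in == p_out` is allowed but flagged as uninformative).
#' @param sim_signal Similarity offset for same-group pairs, in \[0, 1\].
#' @param sim_noise Standard deviation of Gaussian perturbation added to
#'   every similarity entry.
#' @param seed Integer seed; same seed gives bitwise-identical output.
#' @return A list of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(n_genes = 150L, n_groups = 6L,
                               group_sizes = NULL,
                               sl_group_pairs = NULL,
                               p_in = 0.3, p_out = 0.01,
                               sim_signal = 0.8, sim_noise = 0.1,
                               seed = 1L) {
  if (is.null(sl_group_pairs)) {
    sl_group_pairs <- lapply(seq_len(n_groups %/% 2L),
                             function(k) c(2L * k - 1L, 2L * k))
  }
  if (is.null(group_sizes)) {
    group_sizes <- rep(n_genes %/% n_groups, n_groups)
    rem <- n_genes %% n_groups
    if (rem > 0) group_sizes[seq_len(rem)] <- group_sizes[seq_len(rem)] + 1L
  }
  if (sum(group_sizes) != n_genes) {
    stop("group sizes sum to ", sum(group_sizes), ", not n_genes = ", n_genes)
  }
  stopifnot(p_out >= 0, p_in <= 1, p_out <= p_in,
            sim_signal >= 0, sim_signal <= 1, sim_noise >= 0)
  if (p_in == p_out) {
    warning("p_in == p_out: scenario carries no planted signal")
  }
  bad <- vapply(sl_group_pairs,
                function(p) length(p) != 2L || any(p < 1 | p > n_groups) ||
                  p[1] == p[2], logical(1))
  if (any(bad)) stop("sl_group_pairs must be pairs of distinct group ids")
  structure(list(n_genes = as.integer(n_genes),
                 n_groups = as.integer(n_groups),
                 group_sizes = as.integer(group_sizes),
                 sl_group_pairs = sl_group_pairs,
                 p_in = p_in, p_out = p_out,
                 sim_signal = sim_signal, sim_noise = sim_noise,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Generate a synthetic SL network and correlated similarity matrix
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with `interactions` (an `"sl_matrix"`), `similarity`
#'   (a `"similarity_graph"`), `groups` (integer group id per gene, named),
#'   and `truth` (data frame of all unordered gene pairs whose groups form
#'   a designated partner pair — the planted high-probability set).
#' @export
generate_synthetic <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n_genes
  genes <- sprintf("g%03d", seq_len(n))
  groups <- rep(seq_len(scenario$n_groups), scenario$group_sizes)
  names(groups) <- genes

  # pairwise design: planted (p_in) vs background (p_out)
  pairkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  designated <- vapply(scenario$sl_group_pairs,
                       function(p) pairkey(p[1], p[2]), character(1))
  gi <- matrix(groups, n, n)
  gj <- t(gi)
  planted <- matrix(pairkey(gi, gj) %in% designated, n, n)
  same_group <- gi == gj

  ut <- upper.tri(planted)
  out <- with_seed(scenario$seed, {
    P <- ifelse(planted, scenario$p_in, scenario$p_out)
    edges <- matrix(0L, n, n)
    edges[ut] <- as.integer(stats::runif(sum(ut)) < P[ut])
    S <- matrix(0, n, n)
    S[ut] <- scenario$sim_signal * same_group[ut] +
      stats::rnorm(sum(ut), 0, scenario$sim_noise)
    list(edges = edges, S = S)
  })
  X <- out$edges + t(out$edges)
  dimnames(X) <- list(genes, genes)
  S <- out$S + t(out$S)  # upper triangle mirrored; diagonal stays 0
  S[S < 0] <- 0
  S[S > 1] <- 1
  dimnames(S) <- list(genes, genes)

  idx <- which(planted & ut, arr.ind = TRUE)
  truth <- data.frame(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
                      stringsAsFactors = FALSE)
  list(interactions = new_sl_matrix(X, gene_index(genes)),
       similarity = build_similarity_graph(S, genes),
       groups = groups,
       truth = truth)
}
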
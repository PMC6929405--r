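# Core domain types: gene index, SL interaction matrix, similarity graph.

#' Construct a gene index
#'
#' An ordered set of unique gene identifiers defining the row/column order
#' of every matrix in the package. Identifiers are sorted lexicographically
#' (byte order, `LC_COLLATE = "C"`) so that all derived matrices are
#' reproducible across platforms and runs.
#'
#' @param genes Character vector of gene identifiers. Duplicates are
#'   collapsed; leading/trailing whitespace is trimmed.
#' @param sort Sort identifiers lexicographically (default) or preserve
#'   first-appearance order.
#' @return A character vector of class `"gene_index"`.
#' @export
gene_index <- function(genes, sort = TRUE) {
  if (!is.character(genes)) genes <- as.character(genes)
  genes <- trimws(genes)
  if (length(genes) == 0L) stop("gene set is empty")
  if (any(is.na(genes) | genes == "")) {
    stop("gene identifiers must be non-empty, non-missing strings")
  }
  genes <- unique(genes)
  if (sort) {
    # C collation: stable across locales
    genes <- genes[order(genes, method = "radix")]
  }
  structure(genes, class = "gene_index")
}

#' @export
print.gene_index <- function(x, ...) {
  cat("gene_index with", length(x), "genes:",
      paste(utils::head(unclass(x), 5), collapse = ", "),
      if (length(x) > 5) "..." else "", "\n")
  invisible(x)
}

#' Build the symmetric binary SL interaction matrix from a pair list
#'
#' Gene pairs are unordered: (a, b) and (b, a) are the same interaction and
#' duplicates collapse to a single 1. Self-pairs are dropped with a warning
#' because the diagonal is zero by definition (a gene has no SL interaction
#' with itself).
#'
#' @param pairs Two-column matrix or data frame of gene identifiers
#'   (extra columns are ignored).
#' @param genes Optional gene universe (character vector or [gene_index()]).
#'   Defaults to the genes appearing in `pairs`. Pairs mentioning a gene
#'   outside a supplied universe are an error.
#' @return An object of class `"sl_matrix"`: a list with elements `X`
#'   (n x n integer 0/1 matrix, symmetric, zero diagonal, dimnames = genes)
#'   and `genes` (the [gene_index()]).
#' @examples
#' m <- build_interaction_matrix(rbind(c("A", "B"), c("B", "A"), c("A", "C")))
#' m$X
#' @export
build_interaction_matrix <- function(pairs, genes = NULL) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) < 2L) stop("`pairs` must have two columns (gene_a, gene_b)")
  pairs <- pairs[, 1:2, drop = FALSE]
  storage.mode(pairs) <- "character"
  pairs[] <- trimws(pairs)
  if (nrow(pairs) == 0L) stop("`pairs` is empty")
  if (any(is.na(pairs) | pairs == "")) {
    stop("gene identifiers must be non-empty strings (whitespace-only names found)")
  }
  self <- pairs[, 1] == pairs[, 2]
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped: the diagonal of X is fixed at 0")
    pairs <- pairs[!self, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) stop("no valid gene pairs left after dropping self-pairs")
  if (is.null(genes)) {
    genes <- gene_index(as.vector(pairs))
  } else {
    genes <- gene_index(genes)
    missing <- setdiff(unique(as.vector(pairs)), unclass(genes))
    if (length(missing) > 0L) {
      stop("pair list mentions genes outside the supplied universe: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  n <- length(genes)
  X <- matrix(0L, n, n, dimnames = list(unclass(genes), unclass(genes)))
  i <- match(pairs[, 1], unclass(genes))
  j <- match(pairs[, 2], unclass(genes))
  X[cbind(i, j)] <- 1L
  X[cbind(j, i)] <- 1L
  new_sl_matrix(X, genes)
}

new_sl_matrix <- function(X, genes) {
  structure(list(X = X, genes = genes), class = "sl_matrix")
}

#' Validate an SL interaction matrix
#'
#' Checks symmetry, zero diagonal and 0/1 entries; errors otherwise.
#'
#' @param m An `"sl_matrix"`.
#' @return `m`, invisibly.
#' @export
validate_sl_matrix <- function(m) {
  stopifnot(inherits(m, "sl_matrix"))
  X <- m$X
  n <- length(m$genes)
  if (!is.matrix(X) || nrow(X) != n || ncol(X) != n) {
    stop("X must be an n x n matrix matching the gene index (n = ", n, ")")
  }
  if (!all(X %in% c(0L, 1L))) stop("X entries must be 0 or 1")
  if (any(diag(X) != 0L)) stop("X must have a zero diagonal")
  if (!identical(X == 1L, t(X) == 1L)) stop("X must be symmetric")
  invisible(m)
}

#' @export
print.sl_matrix <- function(x, ...) {
  cat("sl_matrix:", length(x$genes), "genes,",
      sum(x$X[upper.tri(x$X)]), "known SL pairs\n")
  invisible(x)
}

#' Build the similarity graph (S, degree, Laplacian) from a raw matrix
#'
#' The raw matrix is symmetrized as (S + t(S))/2 and its diagonal zeroed
#' (self-similarity cancels in the Laplacian quadratic form, so this is a
#' no-op on the regularizer while keeping the degree interpretable as a
#' weighted degree). Entries are clipped to \[0, 1\]; negative entries beyond
#' `neg_tol` are an error. The Laplacian is L = D - S with
#' D\[i,i\] = sum_j S\[i,j\], so L has zero row sums and is positive
#' semidefinite.
#'
#' @param S_raw Square numeric matrix of similarities, size matching
#'   `genes`. If it carries dimnames they must cover `genes`; rows/columns
#'   are then aligned to the index and genes absent from `S_raw` receive
#'   all-zero similarity (neutral under the graph penalty).
#' @param genes Gene universe (character vector or [gene_index()]).
#' @param neg_tol Negative entries below `-neg_tol` raise an error;
#'   small negative noise within tolerance is clipped to 0.
#' @return An object of class `"similarity_graph"`: list with `S` (n x n),
#'   `degree` (length-n vector of weighted degrees), `L` (n x n Laplacian)
#'   and `genes`.
#' @export
build_similarity_graph <- function(S_raw, genes, neg_tol = 1e-8) {
  genes <- gene_index(genes)
  n <- length(genes)
  S_raw <- as.matrix(S_raw)
  if (nrow(S_raw) != ncol(S_raw)) {
    stop("similarity matrix must be square; got ",
         nrow(S_raw), " x ", ncol(S_raw))
  }
  if (!is.null(rownames(S_raw))) {
    # align by name; genes without similarity entries get zero rows/cols
    S <- matrix(0, n, n, dimnames = list(unclass(genes), unclass(genes)))
    keep <- intersect(unclass(genes), rownames(S_raw))
    S[keep, keep] <- S_raw[keep, keep]
    S_raw <- S
  } else if (nrow(S_raw) != n) {
    stop("similarity matrix size (", nrow(S_raw),
         ") does not match gene index size (", n, ")")
  }
  if (any(!is.finite(S_raw))) stop("similarity matrix has non-finite entries")
  if (min(S_raw) < -neg_tol) {
    stop("similarity matrix has negative entries (min = ",
         format(min(S_raw)), ")")
  }
  S <- (S_raw + t(S_raw)) / 2
  S[S < 0] <- 0
  S[S > 1] <- 1
  diag(S) <- 0
  dimnames(S) <- list(unclass(genes), unclass(genes))
  degree <- rowSums(S)
  L <- -S
  diag(L) <- degree
  structure(list(S = S, degree = degree, L = L, genes = genes),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity_graph:", length(x$genes), "genes, mean degree",
      format(mean(x$degree), digits = 4), "\n")
  invisible(x)
}

# --- TSV readers (External Interfaces) ---------------------------------------

#' Read an SL pair list from a headered TSV
#'
#' Expects columns `gene_a` and `gene_b`; extra columns are ignored.
#'
#' @param path Path to a TSV file.
#' @return Two-column character data frame (`gene_a`, `gene_b`).
#' @export
read_sl_pairs <- function(path) {
  if (!file.exists(path)) stop("SL pair file not found: ", path)
  d <- utils::read.delim(path, header = TRUE, colClasses = "character",
                         check.names = FALSE)
  need <- c("gene_a", "gene_b")
  if (!all(need %in% names(d))) {
    stop("SL pair file must have columns gene_a and gene_b; found: ",
         paste(names(d), collapse = ", "))
  }
  d[need]
}

#' Read a gene similarity matrix from TSV
#'
#' Two dialects are auto-detected by column count:
#' a square matrix whose first row and first column are gene identifiers,
#' or a long-form table `gene_a`, `gene_b`, `similarity` (one pair per
#' line; unlisted pairs default to similarity 0).
#'
#' @param path Path to a TSV file.
#' @return A named square numeric matrix (not yet symmetrized/validated;
#'   pass it to [build_similarity_graph()]).
#' @export
read_similarity <- function(path) {
  if (!file.exists(path)) stop("similarity file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) == 3L && all(c("gene_a", "gene_b") %in% header)) {
    d <- utils::read.delim(path, header = TRUE, check.names = FALSE)
    valcol <- setdiff(names(d), c("gene_a", "gene_b"))[1]
    genes <- gene_index(c(d$gene_a, d$gene_b))
    n <- length(genes)
    S <- matrix(0, n, n, dimnames = list(unclass(genes), unclass(genes)))
    i <- match(d$gene_a, unclass(genes))
    j <- match(d$gene_b, unclass(genes))
    S[cbind(i, j)] <- d[[valcol]]
    S[cbind(j, i)] <- d[[valcol]]
    S
  } else {
    d <- utils::read.delim(path, header = TRUE, row.names = 1L,
                           check.names = FALSE)
    as.matrix(d)
  }
}

#' Write an SL pair list as TSV
#' @param pairs Two-column data frame (`gene_a`, `gene_b`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sl_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a similarity matrix as square TSV
#' @param S Named square matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(S, path) {
  d <- data.frame(gene = rownames(S), S, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
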
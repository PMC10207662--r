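#' Coverage of a gene set
#'
#' The number of samples mutated in at least one member of the set,
#' normalized by the largest single-gene mutation support in the whole
#' matrix (not just the set). Because the denominator is a fixed property
#' of the dataset, coverage of a multi-gene set can legitimately exceed 1.
#'
#' @param A a `mutation_matrix`.
#' @param genes character vector of gene symbols, all present in `A`.
#' @return A single non-negative number.
#' @export
coverage <- function(A, genes) {
  A <- as_mutation_matrix_strict(A)
  genes <- check_gene_set(A, genes, min_size = 1)
  m <- unclass(A)
  covered <- sum(rowSums(m[, genes, drop = FALSE]) > 0L)
  covered / max(colSums(m))
}

check_gene_set <- function(A, genes, min_size = 1, need_support = FALSE) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    stop("duplicate gene in set: ", genes[duplicated(genes)][1],
         call. = FALSE)
  }
  missing <- setdiff(genes, colnames(A))
  if (length(missing)) {
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(genes) < min_size) {
    stop("gene set must contain at least ", min_size, " gene(s)",
         call. = FALSE)
  }
  if (need_support) {
    supp <- colSums(unclass(A)[, genes, drop = FALSE])
    if (any(supp == 0L)) {
      stop("gene(s) with empty mutation support: ",
           paste(genes[supp == 0L], collapse = ", "),
           "; filter the matrix first", call. = FALSE)
    }
  }
  genes
}

#' Relative Hamming distance between two genes
#'
#' The fraction of the first gene's mutated samples in which the second
#' gene is not mutated: `|support(g_j) \\ support(g_k)| / |support(g_j)|`.
#' Asymmetric in general; 0 exactly when `support(g_j)` is contained in
#' `support(g_k)` (an "inclusion" relationship), and 1 exactly when the
#' two supports are disjoint.
#'
#' @param A a `mutation_matrix`.
#' @param g_j,g_k distinct gene symbols; `g_j` must have nonempty support.
#' @return A number in \[0, 1\].
#' @export
rhd_pair <- function(A, g_j, g_k) {
  A <- as_mutation_matrix_strict(A)
  stopifnot(g_j != g_k)
  check_gene_set(A, c(g_j, g_k), min_size = 2)
  m <- unclass(A)
  nj <- sum(m[, g_j])
  if (nj == 0L) {
    stop("gene '", g_j, "' has empty support; RHD is undefined",
         call. = FALSE)
  }
  sum(m[, g_j] == 1L & m[, g_k] == 0L) / nj
}

#' Relative Hamming distance between a gene and a gene set
#'
#' The mean pairwise distance from `g_j` to each of the other members of
#' the set.
#'
#' @inheritParams rhd_pair
#' @param genes a gene set of size at least 2 containing `g_j`.
#' @return A number in \[0, 1\].
#' @export
rhd_set <- function(A, g_j, genes) {
  A <- as_mutation_matrix_strict(A)
  genes <- check_gene_set(A, genes, min_size = 2)
  if (!g_j %in% genes) {
    stop("'", g_j, "' is not a member of the gene set", call. = FALSE)
  }
  others <- setdiff(genes, g_j)
  mean(vapply(others, function(g) rhd_pair(A, g_j, g), numeric(1)))
}

#' Mutual exclusivity of a gene set
#'
#' The average, over members of the set, of the relative Hamming distance
#' from each gene to the rest of the set. Equals 1 when all supports are
#' pairwise disjoint (perfect exclusivity) and 0 when all supports are
#' identical. Unlike coverage-overlap scores, this measure penalizes
#' "inclusion" relationships where one gene's mutated samples are swallowed
#' by another's.
#'
#' @param A a `mutation_matrix`.
#' @param genes at least two genes, each with nonempty support.
#' @return A number in \[0, 1\].
#' @export
mutual_exclusivity <- function(A, genes) {
  A <- as_mutation_matrix_strict(A)
  genes <- check_gene_set(A, genes, min_size = 2, need_support = TRUE)
  mean(vapply(genes, function(g) rhd_set(A, g, genes), numeric(1)))
}

#' Network connectivity score of a gene set
#'
#' The mean of all ordered off-diagonal entries of the correlation
#' submatrix restricted to the set: `sum(W[genes, genes]) / (k * (k - 1))`
#' with a zero diagonal. For a symmetric `W` this equals the arithmetic
#' mean of the `choose(k, 2)` pairwise weights.
#'
#' @param W a `correlation_matrix` (gene x gene, entries in \[0, 1\]).
#' @param genes at least two gene symbols present in `W`.
#' @return A number in \[0, 1\].
#' @export
network_score <- function(W, genes) {
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(W))
  if (length(missing)) {
    stop("gene(s) not in correlation matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  k <- length(genes)
  if (k < 2) stop("network score needs at least 2 genes", call. = FALSE)
  sub <- unclass(W)[genes, genes, drop = FALSE]
  diag(sub) <- 0
  sum(sub) / (k * (k - 1))
}

#' Score a gene set: coverage + mutual exclusivity + network connectivity
#'
#' The parameter-free submatrix objective: the sum of [coverage()],
#' [mutual_exclusivity()] and [network_score()]. Setting
#' `use_network = FALSE` drops the network term, giving the
#' coverage-and-exclusivity-only variant of the model.
#'
#' @param A a `mutation_matrix`.
#' @param W a `correlation_matrix`, or `NULL` when `use_network = FALSE`.
#' @param genes at least two genes with nonempty supports.
#' @param use_network include the network connectivity term?
#' @return A `gene_set_score` object with fields `genes`, `coverage`,
#'   `mutual_exclusivity`, `network`, `total` and `covered_samples`.
#' @examples
#' B <- example_inclusion_matrix()
#' score_gene_set(B, genes = c("g1", "g2", "g3"), use_network = FALSE)
#' @export
score_gene_set <- function(A, W = NULL, genes, use_network = !is.null(W)) {
  A <- as_mutation_matrix_strict(A)
  genes <- check_gene_set(A, genes, min_size = 2, need_support = TRUE)
  if (use_network && is.null(W)) {
    stop("use_network = TRUE requires a correlation matrix", call. = FALSE)
  }
  co <- coverage(A, genes)
  me <- mutual_exclusivity(A, genes)
  nw <- if (use_network) network_score(W, genes) else 0
  m <- unclass(A)
  covered <- rownames(A)[rowSums(m[, genes, drop = FALSE]) > 0L]
  structure(
    list(genes = genes, coverage = co, mutual_exclusivity = me,
         network = nw, total = co + me + nw, covered_samples = covered,
         use_network = use_network),
    class = "gene_set_score")
}

#' @export
print.gene_set_score <- function(x, ...) {
  cat(sprintf("<gene_set_score: {%s}>\n", paste(x$genes, collapse = ", ")))
  cat(sprintf("  coverage            %.4f\n", x$coverage))
  cat(sprintf("  mutual exclusivity  %.4f\n", x$mutual_exclusivity))
  if (x$use_network) {
    cat(sprintf("  network             %.4f\n", x$network))
  }
  cat(sprintf("  total               %.4f\n", x$total))
  cat(sprintf("  covered samples     %d\n", length(x$covered_samples)))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.gene_set_score <- function(x, ...) {
  tibble::tibble(
    genes = paste(x$genes, collapse = ","),
    k = length(x$genes),
    coverage = x$coverage,
    mutual_exclusivity = x$mutual_exclusivity,
    network = x$network,
    total = x$total,
    n_covered = length(x$covered_samples)
  )
}

#' Classical maximum-weight-submatrix score
#'
#' The baseline weight `2 * |union of supports| - sum of |supports|`, i.e.
#' coverage rewarded and every co-mutated (or doubly counted) sample
#' penalized. Unlike the mutual-exclusivity measure used in this package,
#' it cannot distinguish a set whose genes are nested inside one dominant
#' gene from a set with evenly distributed coverage.
#'
#' @param A a `mutation_matrix`.
#' @param genes a nonempty gene set.
#' @return An integer.
#' @export
mwsm_weight <- function(A, genes) {
  A <- as_mutation_matrix_strict(A)
  genes <- check_gene_set(A, genes, min_size = 1)
  m <- unclass(A)[, genes, drop = FALSE]
  2L * sum(rowSums(m) > 0L) - sum(m)
}

#' Detect inclusion relationships within a gene set
#'
#' Gene `g` is included in gene `h` when every sample mutating `g` also
#' mutates `h`, i.e. the relative Hamming distance from `g` to `h` is 0.
#' Genes with identical supports are reported in both orientations.
#'
#' @param A a `mutation_matrix`.
#' @param genes genes to examine (default: all genes of `A`); each must
#'   have nonempty support.
#' @return A tibble with columns `gene` and `included_in`, one row per
#'   ordered inclusion pair.
#' @export
detect_inclusions <- function(A, genes = colnames(A)) {
  A <- as_mutation_matrix_strict(A)
  genes <- check_gene_set(A, genes, min_size = 1, need_support = TRUE)
  pairs <- expand.grid(gene = genes, included_in = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$gene != pairs$included_in, , drop = FALSE]
  hit <- vapply(seq_len(nrow(pairs)), function(i) {
    rhd_pair(A, pairs$gene[i], pairs$included_in[i]) == 0
  }, logical(1))
  out <- pairs[hit, , drop = FALSE]
  out <- out[order(out$gene, out$included_in), , drop = FALSE]
  tibble::as_tibble(out)
}

# ---- fast scoring context (internal) ---------------------------------------
#
# Precomputes, once per (A, W) pair, everything needed to score arbitrary
# K-subsets in O(K^2 + K|P|): per-gene support sizes, the dataset-wide
# maximum support (the coverage denominator), and the full pairwise RHD
# matrix R where R[j, k] = |supp(j) \ supp(k)| / |supp(j)|. The subset
# objective then reduces to sums over the R and W submatrices:
#   ME(M) = sum(offdiag R[idx, idx]) / (K * (K - 1))
#   N(M)  = sum(offdiag W[idx, idx]) / (K * (K - 1))
# Used by the genetic search and the permutation test; the exported
# definitional functions above stay the slow reference path.
make_score_ctx <- function(A, W = NULL, use_network = !is.null(W)) {
  A <- as_mutation_matrix_strict(A)
  m <- unclass(A)
  supp <- colSums(m)
  if (any(supp == 0L)) {
    stop("gene(s) with empty mutation support: ",
         paste(colnames(m)[supp == 0L], collapse = ", "),
         "; filter the matrix first", call. = FALSE)
  }
  overlap <- crossprod(m)                      # |supp(j) n supp(k)|
  R <- (supp - overlap) / supp                 # row-wise: (s_j - O_jk)/s_j
  diag(R) <- 0
  if (use_network) {
    stopifnot(!is.null(W))
    if (length(setdiff(colnames(m), rownames(W)))) {
      stop("correlation matrix lacks gene(s) present in the mutation ",
           "matrix", call. = FALSE)
    }
    Wm <- unclass(W)[colnames(m), colnames(m), drop = FALSE]
    diag(Wm) <- 0
  } else {
    Wm <- NULL
  }
  list(m = m, genes = colnames(m), supp = supp, max_supp = max(supp),
       R = R, W = Wm, use_network = use_network)
}

# idx: integer column indices of the subset
score_subset_ctx <- function(ctx, idx) {
  k <- length(idx)
  covered <- sum(rowSums(ctx$m[, idx, drop = FALSE]) > 0L)
  co <- covered / ctx$max_supp
  me <- sum(ctx$R[idx, idx]) / (k * (k - 1))
  nw <- if (ctx$use_network) sum(ctx$W[idx, idx]) / (k * (k - 1)) else 0
  co + me + nw
}
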
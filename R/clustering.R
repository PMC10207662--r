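#' Per-gene candidate clusters for search-space pruning
#'
#' Before the genetic search, two candidate sets are built for every gene
#' `g`: `c1(g)`, the genes at relative Hamming distance at least `mu` from
#' `g` (mutation profiles sufficiently exclusive of `g`'s), and `c2(g)`,
#' the genes with association weight at least `nu` to `g` (sufficiently
#' connected in the network). Gene combinations outside these clusters are
#' never proposed, which prunes the combinatorial search space.
#'
#' The RHD direction is taken from the cluster owner toward the candidate,
#' `RHD(g, h) >= mu`; the measure is asymmetric and the direction is kept
#' as defined, not symmetrized.
#'
#' @param A a `mutation_matrix` whose genes all have nonempty support.
#' @param W a `correlation_matrix` over the same genes.
#' @param mu RHD threshold in \[0, 1\] for `c1`.
#' @param nu association-weight threshold in \[0, 1\] for `c2`.
#' @return `gene_cluster_index()` returns an object of class
#'   `gene_cluster_index`: a list with named-list fields `c1` and `c2`
#'   (gene -> character vector of genes) and the thresholds `mu`, `nu`.
#' @export
gene_cluster_index <- function(A, W, mu = 0.7, nu = 0.5) {
  structure(
    list(c1 = build_rhd_clusters(A, mu),
         c2 = build_correlation_clusters(W, nu),
         mu = mu, nu = nu),
    class = "gene_cluster_index")
}

#' @rdname gene_cluster_index
#' @return `build_rhd_clusters()` and `build_correlation_clusters()` each
#'   return a named list mapping every gene to its candidate gene set
#'   (never containing the gene itself).
#' @export
build_rhd_clusters <- function(A, mu) {
  stopifnot(mu >= 0, mu <= 1)
  ctx <- make_score_ctx(A)        # errors on empty supports
  R <- ctx$R
  diag(R) <- NA_real_
  out <- lapply(seq_along(ctx$genes), function(j) {
    ctx$genes[which(R[j, ] >= mu)]
  })
  names(out) <- ctx$genes
  out
}

#' @rdname gene_cluster_index
#' @export
build_correlation_clusters <- function(W, nu) {
  stopifnot(nu >= 0, nu <= 1)
  genes <- rownames(W)
  Wm <- unclass(W)
  diag(Wm) <- NA_real_
  out <- lapply(seq_along(genes), function(j) {
    genes[which(Wm[j, ] >= nu)]
  })
  names(out) <- genes
  out
}

#' Candidate pool for extending a partial chromosome
#'
#' The genes eligible to join a partial gene set `X`: the intersection of
#' the exclusivity clusters `c1` over all members of `X`, further
#' intersected with the union of the connectivity clusters `c2` over `X`,
#' minus the members of `X` themselves. An empty pool signals that `X`
#' cannot be extended under the current thresholds.
#'
#' @param X character vector, the current (partial) gene set; nonempty.
#' @param index a `gene_cluster_index`.
#' @return Character vector of candidate genes (possibly empty).
#' @export
candidate_pool <- function(X, index) {
  stopifnot(length(X) >= 1)
  c1_int <- Reduce(intersect, index$c1[X])
  c2_uni <- Reduce(union, index$c2[X])
  setdiff(intersect(c1_int, c2_uni), X)
}

#' @export
print.gene_cluster_index <- function(x, ...) {
  cat(sprintf(
    "<gene_cluster_index: %d genes, mu = %g (RHD), nu = %g (network)>\n",
    length(x$c1), x$mu, x$nu))
  cat(sprintf("  mean |c1| = %.1f, mean |c2| = %.1f\n",
              mean(lengths(x$c1)), mean(lengths(x$c2))))
  invisible(x)
}
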
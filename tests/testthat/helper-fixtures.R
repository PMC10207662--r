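# Shared fixtures and independent set-algebra oracles used across tests.
# The oracles work on explicit support sets, never through the package's
# matrix algebra, so they can certify it.

mm <- function(..., samples = NULL) {
  # build a mutation_matrix from named support index vectors,
  # e.g. mm(a = 1:2, b = 3, samples = 4)
  supports <- list(...)
  n <- max(c(unlist(supports), samples %||% 0))
  m <- matrix(0L, n, length(supports),
              dimnames = list(paste0("s", seq_len(n)), names(supports)))
  for (g in names(supports)) m[supports[[g]], g] <- 1L
  as_mutation_matrix(m)
}

sym_w <- function(genes, pairs = list(), default = 0) {
  # symmetric correlation matrix from a list of c(geneA, geneB, weight)
  W <- matrix(default, length(genes), length(genes),
              dimnames = list(genes, genes))
  for (p in pairs) {
    W[p[[1]], p[[2]]] <- as.numeric(p[[3]])
    W[p[[2]], p[[1]]] <- as.numeric(p[[3]])
  }
  diag(W) <- 0
  W
}

supports_of <- function(A) {
  m <- unclass(A)
  lapply(seq_len(ncol(m)), function(j) which(m[, j] == 1L)) |>
    stats::setNames(colnames(m))
}

rhd_oracle <- function(supports, j, k) {
  length(setdiff(supports[[j]], supports[[k]])) / length(supports[[j]])
}

me_oracle <- function(supports, genes) {
  mean(vapply(genes, function(g) {
    mean(vapply(setdiff(genes, g),
                function(h) rhd_oracle(supports, g, h), numeric(1)))
  }, numeric(1)))
}

mwsm_oracle <- function(supports, genes) {
  2L * length(Reduce(union, supports[genes])) - sum(lengths(supports[genes]))
}

random_mutation_matrix <- function(n_samples, n_genes, prob = 0.3) {
  # every gene guaranteed a nonempty support
  m <- matrix(rbinom(n_samples * n_genes, 1L, prob), n_samples, n_genes,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              sprintf("g%02d", seq_len(n_genes))))
  empty <- colSums(m) == 0L
  m[cbind(sample.int(n_samples, sum(empty), replace = TRUE), which(empty))] <- 1L
  as_mutation_matrix(m)
}

random_correlation_matrix <- function(genes) {
  W <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  up <- upper.tri(W)
  W[up] <- runif(sum(up))
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- 0
  W
}

exhaustive_best <- function(A, W, K, use_network = TRUE) {
  # brute-force optimum of the objective over all K-subsets
  combs <- utils::combn(colnames(A), K)
  scores <- apply(combs, 2, function(g) {
    score_gene_set(A, W, g, use_network = use_network)$total
  })
  list(genes = combs[, which.max(scores)], total = max(scores))
}
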
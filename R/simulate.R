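#' Worked-example matrix with inclusion structure
#'
#' A small 10-sample x 3-gene binary mutation matrix in which one dominant
#' gene (`g2`, mutated in samples 1-9) fully contains the supports of two
#' minor genes (`g1` in samples 1-2, `g3` in samples 3-4; sample 10 is
#' mutation-free). The set \{g1, g2, g3\} therefore carries two inclusion
#' relationships while still scoring the classical
#' maximum-weight-submatrix weight 5 — the situation the RHD-based mutual
#' exclusivity measure is designed to penalize.
#'
#' @return A `mutation_matrix`.
#' @examples
#' B <- example_inclusion_matrix()
#' mutual_exclusivity(B, c("g1", "g2", "g3"))   # 16/27
#' mwsm_weight(B, c("g1", "g2", "g3"))          # 5
#' detect_inclusions(B)
#' @export
example_inclusion_matrix <- function() {
  m <- matrix(0L, nrow = 10, ncol = 3,
              dimnames = list(paste0("s", 1:10), c("g1", "g2", "g3")))
  m[1:2, "g1"] <- 1L
  m[1:9, "g2"] <- 1L
  m[3:4, "g3"] <- 1L
  new_mutation_matrix(m)
}

#' Simulate a mutation dataset with a planted driver module
#'
#' Generates a binary mutation matrix and a matching correlation matrix in
#' which `k_true` planted genes behave like a driver pathway: together
#' they cover `coverage_frac` of the samples, the covered samples are
#' partitioned round-robin among the planted genes (so coverage is
#' balanced and mutations nearly mutually exclusive), pairwise co-mutation
#' is injected at rate `overlap_rate`, and the planted genes are strongly
#' connected in the network (`within_weight`). All entries of the
#' remaining background genes are independent Bernoulli noise at
#' `background_rate`, and background association weights are independent
#' Uniform(0, `background_weight`), symmetrized with zero diagonal.
#' Planted genes are scattered at random positions in the gene order.
#'
#' Background genes may end up with empty supports (always, when
#' `background_rate = 0`); run [filter_low_frequency_genes()] before
#' scoring or searching. Planted genes always survive that filter by
#' construction.
#'
#' @param n_samples,n_genes dimensions of the matrix.
#' @param k_true number of planted driver genes (at least 2).
#' @param coverage_frac fraction of samples covered by the planted module.
#' @param overlap_rate per-cell probability of injected co-mutation
#'   between planted genes on covered samples.
#' @param background_rate per-cell mutation probability of background
#'   genes.
#' @param within_weight association weight between planted gene pairs.
#' @param background_weight upper bound of the Uniform background
#'   association weights.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return An object of class `driver_instance`: a list with the
#'   `mutation_matrix` `A`, the `correlation_matrix` `W`, the character
#'   vector `planted_genes`, and `params` (all arguments).
#' @export
simulate_driver_instance <- function(n_samples = 200, n_genes = 50,
                                     k_true = 3, coverage_frac = 0.6,
                                     overlap_rate = 0.02,
                                     background_rate = 0.03,
                                     within_weight = 0.9,
                                     background_weight = 0.3,
                                     seed = 7L) {
  stopifnot(k_true >= 2, n_genes > k_true,
            coverage_frac > 0, coverage_frac <= 1,
            overlap_rate >= 0, overlap_rate <= 1,
            background_rate >= 0, background_rate <= 1,
            within_weight >= 0, within_weight <= 1,
            background_weight >= 0, background_weight <= 1)
  n_cov <- round(coverage_frac * n_samples)
  if (n_cov < k_true) {
    stop("coverage_frac * n_samples must be at least k_true", call. = FALSE)
  }
  params <- list(n_samples = n_samples, n_genes = n_genes, k_true = k_true,
                 coverage_frac = coverage_frac, overlap_rate = overlap_rate,
                 background_rate = background_rate,
                 within_weight = within_weight,
                 background_weight = background_weight,
                 seed = as.integer(seed))
  width <- nchar(as.character(n_genes))
  genes <- sprintf(paste0("g%0", width, "d"), seq_len(n_genes))
  samples <- sprintf("s%03d", seq_len(n_samples))

  withr::with_seed(as.integer(seed), {
    planted <- sort(sample(genes, k_true))
    background <- setdiff(genes, planted)
    m <- matrix(0L, n_samples, n_genes, dimnames = list(samples, genes))

    # planted module: partition covered samples round-robin, then inject
    # pairwise co-mutation at overlap_rate
    covered <- sample.int(n_samples, n_cov)
    owner <- rep_len(seq_len(k_true), n_cov)
    m[cbind(covered, match(planted[owner], genes))] <- 1L
    if (overlap_rate > 0) {
      for (j in seq_len(k_true)) {
        other <- covered[owner != j]
        extra <- other[stats::runif(length(other)) < overlap_rate]
        m[extra, match(planted[j], genes)] <- 1L
      }
    }

    # background noise
    if (length(background) && background_rate > 0) {
      bg <- matrix(stats::rbinom(n_samples * length(background), 1L,
                                 background_rate),
                   n_samples, length(background))
      m[, match(background, genes)] <- bg
    }

    # correlation matrix
    W <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
    up <- upper.tri(W)
    W[up] <- stats::runif(sum(up), 0, background_weight)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    pj <- match(planted, genes)
    W[pj, pj] <- within_weight
    diag(W) <- 0
  })

  structure(
    list(A = new_mutation_matrix(m),
         W = structure(W, class = c("correlation_matrix", "matrix",
                                    "array")),
         planted_genes = planted,
         params = params),
    class = "driver_instance")
}

#' @export
print.driver_instance <- function(x, ...) {
  cat(sprintf(
    "<driver_instance: %d samples x %d genes, planted module {%s}>\n",
    nrow(x$A), ncol(x$A), paste(x$planted_genes, collapse = ", ")))
  invisible(x)
}

#' Write a simulated instance to disk
#'
#' Emits `A.tsv` (the mutation matrix, sample-ID first column), `F.tsv`
#' and `E.tsv` (STRING-style edge lists with raw scores reconstructed as
#' `round(w * 999)`, identical in both channels so the max-with-gate
#' combination rule restores `W` up to rounding), and `truth.json` with
#' the planted genes and generator parameters.
#'
#' @param instance a `driver_instance`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_driver_instance <- function(instance, dir) {
  stopifnot(inherits(instance, "driver_instance"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(A = file.path(dir, "A.tsv"),
             F = file.path(dir, "F.tsv"),
             E = file.path(dir, "E.tsv"),
             truth = file.path(dir, "truth.json"))

  m <- unclass(instance$A)
  df <- data.frame(sample = rownames(m), as.data.frame(m),
                   check.names = FALSE)
  readr::write_tsv(df, paths[["A"]], progress = FALSE)

  W <- unclass(instance$W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- tibble::tibble(geneA = rownames(W)[idx[, 1]],
                          geneB = colnames(W)[idx[, 2]],
                          score = as.integer(round(W[idx] * 999)))
  edges <- edges[edges$score > 0, , drop = FALSE]
  readr::write_tsv(edges, paths[["F"]], col_names = FALSE, progress = FALSE)
  readr::write_tsv(edges, paths[["E"]], col_names = FALSE, progress = FALSE)

  jsonlite::write_json(
    list(planted_genes = instance$planted_genes,
         params = instance$params),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
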
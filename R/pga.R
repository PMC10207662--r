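#' Control parameters for the partheno-genetic search
#'
#' Bundles every tunable of [find_driver_set()]. The defaults are the
#' standard operating point of the method: population size one quarter of
#' the gene universe, a hard cap of 1000 generations with early stopping
#' after 100 stagnant generations, per-individual recombination
#' probability 0.3, exclusivity threshold `mu = 0.7` and connectivity
#' threshold `nu = 0.5`.
#'
#' @param K target gene-set size (at least 2).
#' @param pop_size population size `N`; `NULL` means `ceiling(|G| / 4)`
#'   (at least 2), resolved against the mutation matrix at run time.
#' @param maxg maximum number of generations.
#' @param maxt early-stop patience: stop after this many consecutive
#'   generations without improvement of the best fitness.
#' @param rr per-individual probability of undergoing recombination in a
#'   generation, in \[0, 1\].
#' @param mu RHD threshold for the exclusivity clusters `c1`.
#' @param nu association-weight threshold for the connectivity clusters
#'   `c2` and for the mean-correlation constraint on added genes.
#' @param seed integer seed; all randomness of a run flows from it.
#' @param use_network include the network connectivity term in the
#'   objective? (The clusters and constraints use the network either way.)
#' @return A list of class `pga_control`.
#' @export
pga_control <- function(K, pop_size = NULL, maxg = 1000, maxt = 100,
                        rr = 0.3, mu = 0.7, nu = 0.5, seed = 1L,
                        use_network = TRUE) {
  stopifnot(K >= 2, K == round(K),
            is.null(pop_size) || pop_size >= 2,
            maxg >= 0, maxt >= 1,
            rr >= 0, rr <= 1, mu >= 0, mu <= 1, nu >= 0, nu <= 1)
  structure(
    list(K = as.integer(K), pop_size = pop_size,
         maxg = as.integer(maxg), maxt = as.integer(maxt),
         rr = rr, mu = mu, nu = nu, seed = as.integer(seed),
         use_network = isTRUE(use_network)),
    class = "pga_control")
}

# roulette draw of one element; prob must be positive for at least one entry
sample_one <- function(x, prob) {
  if (length(x) == 1L) return(x)
  x[sample.int(length(x), 1L, prob = prob)]
}

#' Build one chromosome by cluster-guided roulette initialization
#'
#' The first gene is drawn with probability proportional to its mutation
#' support. Each subsequent gene is drawn (again support-proportional)
#' from the [candidate_pool()] of the partial set, restricted to genes
#' whose mean association weight to the current members is at least `nu`.
#' If at any step no candidate is eligible, initialization of this
#' chromosome fails and `NULL` is returned so the caller can retry.
#'
#' @param A a `mutation_matrix` (all supports nonempty).
#' @param W a `correlation_matrix` over the genes of `A`.
#' @param index a `gene_cluster_index` built with the same `mu`, `nu`.
#' @param control a [pga_control()].
#' @return A character vector of `K` distinct genes, or `NULL` on failure.
#' @export
init_chromosome <- function(A, W, index, control) {
  supp <- colSums(unclass(as_mutation_matrix_strict(A)))
  genes <- names(supp)
  Wm <- unclass(W)
  X <- sample_one(genes, prob = supp)
  while (length(X) < control$K) {
    pool <- candidate_pool(X, index)
    if (length(pool) == 0L) return(NULL)
    mean_w <- colMeans(Wm[X, pool, drop = FALSE])
    eligible <- pool[mean_w >= control$nu]
    if (length(eligible) == 0L) return(NULL)
    X <- c(X, sample_one(eligible, prob = supp[eligible]))
  }
  X
}

#' Initialize a population of chromosomes
#'
#' Repeatedly calls [init_chromosome()], retrying on failure, until `N`
#' chromosomes exist. Duplicates are allowed. Errors after
#' `max_retries * N` consecutive failures, which signals that the
#' thresholds `mu`/`nu` (or `K`) are too strict for the instance.
#'
#' @inheritParams init_chromosome
#' @param max_retries failure budget multiplier.
#' @return A list of `N` chromosomes.
#' @export
init_population <- function(A, W, index, control, max_retries = 100L) {
  N <- control$pop_size
  if (is.null(N)) N <- max(2L, as.integer(ceiling(ncol(A) / 4)))
  pop <- vector("list", N)
  failures <- 0L
  i <- 1L
  while (i <= N) {
    X <- init_chromosome(A, W, index, control)
    if (is.null(X)) {
      failures <- failures + 1L
      if (failures >= max_retries * N) {
        stop("could not initialize a population: the cluster thresholds ",
             "mu = ", control$mu, ", nu = ", control$nu,
             " (or K = ", control$K, ") leave too few feasible gene sets; ",
             "lower mu/nu or K", call. = FALSE)
      }
    } else {
      pop[[i]] <- X
      i <- i + 1L
      failures <- 0L
    }
  }
  pop
}

#' Fitness of a chromosome
#'
#' The fitness of a gene set is its objective value: coverage plus mutual
#' exclusivity plus (optionally) network connectivity — see
#' [score_gene_set()].
#'
#' @inheritParams score_gene_set
#' @return A single positive number.
#' @export
fitness <- function(A, W = NULL, genes, use_network = !is.null(W)) {
  score_gene_set(A, W, genes, use_network = use_network)$total
}

#' Roulette selection with elitism
#'
#' Draws `N` individuals with replacement, with probability proportional
#' to fitness, then overwrites the first drawn slot with the incumbent
#' best chromosome so the best-so-far always survives.
#'
#' @param population list of chromosomes.
#' @param fitnesses numeric vector of their (positive) fitness values.
#' @param best the incumbent best chromosome.
#' @param best_fitness its fitness.
#' @return A list with elements `population` and `fitnesses`.
#' @export
select_population <- function(population, fitnesses, best, best_fitness) {
  N <- length(population)
  idx <- sample.int(N, N, replace = TRUE, prob = fitnesses)
  pop <- population[idx]
  fit <- fitnesses[idx]
  pop[[1L]] <- best
  fit[1L] <- best_fitness
  list(population = pop, fitnesses = fit)
}

#' Greedy single-parent recombination
#'
#' With probability one half the member with the smallest mutation support
#' is dropped, otherwise a uniformly random member is dropped. The
#' replacement is chosen greedily from the intersection of the exclusivity
#' clusters `c1` of the remaining members: the candidate with the largest
#' support whose mean association weight to the remaining members is at
#' least `nu` (ties broken toward the lexicographically smallest gene
#' symbol). If no candidate is eligible the chromosome is returned
#' unchanged.
#'
#' @inheritParams init_chromosome
#' @param X a chromosome (character vector of `K` distinct genes).
#' @return A chromosome of the same size.
#' @export
recombine <- function(X, A, W, index, control) {
  supp <- colSums(unclass(as_mutation_matrix_strict(A)))
  recombine_impl(X, supp, unclass(W), index, control$nu)
}

# internal work-horse shared with find_driver_set (avoids re-deriving supp)
recombine_impl <- function(X, supp, Wm, index, nu) {
  if (stats::runif(1) < 0.5) {
    sx <- supp[X]
    drop <- sort(X[sx == min(sx)])[1L]       # min support, ties -> smallest id
  } else {
    drop <- sample_one(X, prob = NULL)
  }
  Xhat <- setdiff(X, drop)
  pool <- Reduce(intersect, index$c1[Xhat])
  pool <- setdiff(pool, Xhat)
  if (length(pool) == 0L) return(X)
  mean_w <- colMeans(Wm[Xhat, pool, drop = FALSE])
  eligible <- pool[mean_w >= nu]
  if (length(eligible) == 0L) return(X)
  add <- sort(eligible[supp[eligible] == max(supp[eligible])])[1L]
  c(Xhat, add)
}

#' Find a driver gene set with the clustering-seeded partheno-genetic search
#'
#' Maximizes the coverage + mutual-exclusivity (+ network connectivity)
#' objective over gene sets of size `K`. The search seeds its population
#' through per-gene candidate clusters ([gene_cluster_index()]), evolves
#' it by roulette selection with elitism and greedy single-parent
#' recombination, and stops at `maxg` generations or after `maxt`
#' generations without improvement.
#'
#' @param A a `mutation_matrix`; run [filter_low_frequency_genes()] first
#'   so every gene has nonempty support.
#' @param W a `correlation_matrix` over the genes of `A`, or `NULL` for a
#'   network-free run (then `use_network` and the connectivity constraint
#'   threshold `nu` are forced to `FALSE`/0).
#' @param control a [pga_control()].
#' @return An object of class `driver_fit`: a list with the best gene set
#'   (`genes`), its `gene_set_score` (`score`), `fitness`,
#'   `generations_run`, the per-generation best-fitness `history`
#'   (entry 1 is the initial population's best), `converged` (`TRUE` when
#'   stopped by stagnation rather than the generation cap) and the
#'   resolved `control`.
#' @examples
#' inst <- simulate_driver_instance(n_samples = 60, n_genes = 12, seed = 3)
#' A <- filter_low_frequency_genes(inst$A)
#' fit <- find_driver_set(A, inst$W, pga_control(K = 3, seed = 1))
#' fit$genes
#' @export
find_driver_set <- function(A, W = NULL, control) {
  stopifnot(inherits(control, "pga_control"))
  A <- as_mutation_matrix_strict(A)
  if (is.null(W)) {
    W <- matrix(0, ncol(A), ncol(A),
                dimnames = list(colnames(A), colnames(A)))
    control$use_network <- FALSE
    control$nu <- 0
  }
  if (control$K > ncol(A)) {
    stop("K = ", control$K, " exceeds the number of genes (", ncol(A), ")",
         call. = FALSE)
  }
  missing <- setdiff(colnames(A), rownames(W))
  if (length(missing)) {
    stop("correlation matrix lacks gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  W <- structure(unclass(W)[colnames(A), colnames(A), drop = FALSE],
                 class = c("correlation_matrix", "matrix", "array"))
  if (is.null(control$pop_size)) {
    control$pop_size <- max(2L, as.integer(ceiling(ncol(A) / 4)))
  }
  ctx <- make_score_ctx(A, W, use_network = control$use_network)
  supp <- ctx$supp
  Wm <- unclass(W)[ctx$genes, ctx$genes, drop = FALSE]
  fit_of <- function(X) score_subset_ctx(ctx, match(X, ctx$genes))

  withr::with_seed(control$seed, {
    index <- gene_cluster_index(A, W, mu = control$mu, nu = control$nu)
    pop <- init_population(A, W, index, control)
    fit <- vapply(pop, fit_of, numeric(1))
    b <- which.max(fit)
    best <- pop[[b]]
    best_fit <- fit[b]
    history <- best_fit
    stagnant <- 0L
    gens <- 0L
    converged <- FALSE
    while (gens < control$maxg) {
      gens <- gens + 1L
      sel <- select_population(pop, fit, best, best_fit)
      pop <- sel$population
      fit <- sel$fitnesses
      for (i in seq_along(pop)[-1L]) {       # slot 1 is the elite
        if (stats::runif(1) < control$rr) {
          Y <- recombine_impl(pop[[i]], supp, Wm, index, control$nu)
          if (!setequal(Y, pop[[i]])) {
            pop[[i]] <- Y
            fit[i] <- fit_of(Y)
          }
        }
      }
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_fit) {
        best <- pop[[gen_best]]
        best_fit <- fit[gen_best]
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }
      history <- c(history, best_fit)
      if (stagnant >= control$maxt) {
        converged <- TRUE
        break
      }
    }
  })

  best <- sort(best)
  structure(
    list(genes = best,
         score = score_gene_set(A, if (control$use_network) W else NULL,
                                best, use_network = control$use_network),
         fitness = best_fit,
         generations_run = gens,
         history = history,
         converged = converged,
         control = control),
    class = "driver_fit")
}

#' @export
print.driver_fit <- function(x, ...) {
  cat(sprintf("<driver_fit: K = %d, %d generations%s>\n",
              x$control$K, x$generations_run,
              if (x$converged) " (early stop)" else ""))
  cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  cat(sprintf("  fitness: %.4f (CO %.4f + ME %.4f + N %.4f)\n",
              x$fitness, x$score$coverage, x$score$mutual_exclusivity,
              x$score$network))
  invisible(x)
}

#' Tidy the evolution history of a driver fit
#'
#' @param x a `driver_fit`.
#' @param ... unused.
#' @return A tibble with columns `generation` (0 = initial population) and
#'   `best_fitness`.
#' @exportS3Method generics::tidy
tidy.driver_fit <- function(x, ...) {
  tibble::tibble(generation = seq_along(x$history) - 1L,
                 best_fitness = x$history)
}

#' One-row summary of a driver fit
#'
#' @param x a `driver_fit`.
#' @param ... unused.
#' @return A tibble with the gene set, its score components, total
#'   fitness, generations run and convergence flag.
#' @exportS3Method generics::glance
glance.driver_fit <- function(x, ...) {
  dplyr::mutate(glance(x$score),
                generations_run = x$generations_run,
                converged = x$converged,
                seed = x$control$seed)
}

#' Plot the best-fitness trajectory of a driver fit
#'
#' @param object a `driver_fit`.
#' @param ... unused.
#' @return A ggplot object; the trajectory is non-decreasing by elitism.
#' @exportS3Method ggplot2::autoplot
autoplot.driver_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$generation,
                               y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best fitness") +
    ggplot2::theme_minimal()
}
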
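#' Random-set permutation test for an identified gene set
#'
#' Draws `n_draws` gene sets of the same size uniformly at random (without
#' replacement within a draw) from the full gene universe of `A`, scores
#' each with the same objective used to find the observed set, and reports
#' the fraction of null sets whose weight strictly exceeds the observed
#' weight. Ties do not count against the observed set, and the p-value
#' resolution is `1 / n_draws`.
#'
#' @param A a `mutation_matrix` (all supports nonempty).
#' @param W a `correlation_matrix`, or `NULL` for the network-free
#'   objective.
#' @param genes the observed gene set (at least 2 genes).
#' @param n_draws number of null draws; default 1000.
#' @param use_network include the network term in the objective?
#' @param seed optional integer seed for reproducible draws; `NULL` uses
#'   the current RNG state.
#' @return An object of class `significance_test` with fields `p_value`,
#'   `n_draws`, `observed_weight`, `null_weights` and `genes`.
#' @examples
#' inst <- simulate_driver_instance(n_samples = 60, n_genes = 12, seed = 3)
#' A <- filter_low_frequency_genes(inst$A)
#' random_set_test(A, inst$W, inst$planted_genes, n_draws = 200, seed = 1)
#' @export
random_set_test <- function(A, W = NULL, genes, n_draws = 1000,
                            use_network = !is.null(W), seed = NULL) {
  A <- as_mutation_matrix_strict(A)
  genes <- check_gene_set(A, genes, min_size = 2, need_support = TRUE)
  stopifnot(n_draws >= 1)
  K <- length(genes)
  if (K > ncol(A)) stop("gene set larger than the gene universe",
                        call. = FALSE)
  ctx <- make_score_ctx(A, W, use_network = use_network)
  observed <- score_subset_ctx(ctx, match(genes, ctx$genes))
  draw_all <- function() {
    vapply(seq_len(n_draws), function(i) {
      score_subset_ctx(ctx, sample.int(length(ctx$genes), K))
    }, numeric(1))
  }
  null_weights <- if (is.null(seed)) draw_all() else {
    withr::with_seed(seed, draw_all())
  }
  structure(
    list(p_value = sum(null_weights > observed) / n_draws,
         n_draws = as.integer(n_draws),
         observed_weight = observed,
         null_weights = null_weights,
         genes = genes),
    class = "significance_test")
}

#' @export
print.significance_test <- function(x, ...) {
  cat(sprintf("<significance_test: {%s}>\n", paste(x$genes, collapse = ", ")))
  cat(sprintf("  observed weight %.4f, %d random draws\n",
              x$observed_weight, x$n_draws))
  cat(sprintf("  p-value %s (resolution %.3g)\n",
              format(x$p_value), 1 / x$n_draws))
  invisible(x)
}

#' Tidy the null distribution of a significance test
#'
#' @param x a `significance_test`.
#' @param ... unused.
#' @return A tibble with columns `draw` and `weight`.
#' @exportS3Method generics::tidy
tidy.significance_test <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$null_weights),
                 weight = x$null_weights)
}

#' One-row summary of a significance test
#'
#' @param x a `significance_test`.
#' @param ... unused.
#' @return A tibble with the observed weight, p-value and draw count.
#' @exportS3Method generics::glance
glance.significance_test <- function(x, ...) {
  tibble::tibble(genes = paste(x$genes, collapse = ","),
                 observed_weight = x$observed_weight,
                 p_value = x$p_value,
                 n_draws = x$n_draws)
}

#' Histogram of the permutation null with the observed weight marked
#'
#' @param object a `significance_test`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.significance_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$weight)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_weight,
                        colour = "#B2182B", linewidth = 0.8) +
    ggplot2::labs(x = "null gene-set weight", y = "count",
                  subtitle = sprintf("p = %s (%d draws)",
                                     format(object$p_value),
                                     object$n_draws)) +
    ggplot2::theme_minimal()
}
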
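#' Binary somatic mutation matrices
#'
#' A `mutation_matrix` is an integer samples x genes matrix with entries in
#' \{0, 1\}, sample identifiers as row names and gene symbols as column
#' names. It is the container every scoring and search function in the
#' package consumes. Use [build_binary_matrix()] to merge a somatic (SNV)
#' matrix with an optional copy-number call matrix, or
#' [as_mutation_matrix()] to construct one directly from a matrix or a
#' data frame whose first column holds sample identifiers.
#'
#' @param x a numeric matrix with dimnames, or a data frame whose first
#'   column contains sample identifiers and whose remaining columns are
#'   0/1 gene indicators.
#' @return An object of class `mutation_matrix`.
#' @examples
#' df <- data.frame(sample = c("s1", "s2"), TP53 = c(1, 0), EGFR = c(0, 1))
#' as_mutation_matrix(df)
#' @export
as_mutation_matrix <- function(x) {
  m <- coerce_sample_gene_table(x, what = "mutation matrix")
  check_entries(m, allowed = c(0L, 1L), what = "mutation matrix")
  new_mutation_matrix(m)
}

new_mutation_matrix <- function(m) {
  storage.mode(m) <- "integer"
  structure(m, class = c("mutation_matrix", "matrix", "array"))
}

# Shared coercion: data frame (first column = sample ids) or named matrix.
coerce_sample_gene_table <- function(x, what) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- ids
  } else if (is.matrix(x)) {
    m <- x
  } else {
    stop("cannot build a ", what, " from a ", class(x)[1], call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " requires sample row names and gene column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate sample identifier: ",
         rownames(m)[duplicated(rownames(m))][1], call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate gene symbol: ",
         colnames(m)[duplicated(colnames(m))][1], call. = FALSE)
  }
  m
}

check_entries <- function(m, allowed, what) {
  bad <- which(!(m %in% allowed) | is.na(m))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(m))
    stop(sprintf(
      "%s entry '%s' at sample '%s', gene '%s' is not in {%s}",
      what, as.character(m[bad[1]]), rownames(m)[i[1]], colnames(m)[i[2]],
      paste(allowed, collapse = ",")), call. = FALSE)
  }
  invisible(m)
}

#' Read a mutation or copy-number matrix from TSV
#'
#' Reads a tab-delimited file with a header row of gene symbols and a first
#' column of sample identifiers. Lines starting with `#` are ignored.
#' Somatic matrices must be strictly 0/1; copy-number call matrices (e.g.
#' thresholded GISTIC output) must have entries in \{-1, 0, 1\}.
#'
#' @param path path to a TSV file.
#' @param kind `"somatic"` for a 0/1 single-nucleotide variant matrix,
#'   `"cnv"` for a -1/0/1 copy-number call matrix.
#' @return For `kind = "somatic"` a `mutation_matrix`; for `kind = "cnv"`
#'   an integer matrix of class `cnv_matrix`.
#' @seealso [build_binary_matrix()] to merge the two channels.
#' @export
read_mutation_matrix <- function(path, kind = c("somatic", "cnv")) {
  kind <- match.arg(kind)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        name_repair = "minimal", progress = FALSE)
  if (ncol(df) < 2) {
    stop("'", path, "' has no gene columns", call. = FALSE)
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicate gene symbol in '", path, "': ",
         names(df)[-1][duplicated(names(df)[-1])][1], call. = FALSE)
  }
  if (kind == "somatic") {
    as_mutation_matrix(as.data.frame(df))
  } else {
    m <- coerce_sample_gene_table(as.data.frame(df), what = "copy-number matrix")
    check_entries(m, allowed = c(-1L, 0L, 1L), what = "copy-number matrix")
    storage.mode(m) <- "integer"
    structure(m, class = c("cnv_matrix", "matrix", "array"))
  }
}

#' Merge somatic and copy-number channels into one binary matrix
#'
#' An entry of the merged matrix is 1 when the gene is altered in the
#' sample through either channel: a somatic point mutation (`s != 0`) or a
#' significant copy-number call (`c != 0`). With no copy-number matrix the
#' somatic matrix is returned unchanged (already binary). When both are
#' given they are aligned on the intersection of their sample and gene
#' universes, in the somatic matrix's order.
#'
#' @param S a `mutation_matrix` (or coercible 0/1 matrix).
#' @param C optionally, a `cnv_matrix` with entries in \{-1, 0, 1\}.
#' @return A `mutation_matrix`.
#' @examples
#' S <- as_mutation_matrix(matrix(c(1L, 0L, 0L, 0L), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("g1", "g2"))))
#' build_binary_matrix(S)
#' @export
build_binary_matrix <- function(S, C = NULL) {
  if (!inherits(S, "mutation_matrix")) S <- as_mutation_matrix(S)
  if (is.null(C)) {
    return(S)
  }
  samples <- intersect(rownames(S), rownames(C))
  genes <- intersect(colnames(S), colnames(C))
  if (length(genes) == 0) {
    stop("somatic and copy-number matrices share no genes", call. = FALSE)
  }
  if (length(samples) == 0) {
    stop("somatic and copy-number matrices share no samples", call. = FALSE)
  }
  s <- unclass(S)[samples, genes, drop = FALSE]
  cc <- unclass(C)[samples, genes, drop = FALSE]
  a <- (s != 0L) | (cc != 0L)
  m <- matrix(as.integer(a), nrow(a), ncol(a), dimnames = dimnames(a))
  new_mutation_matrix(m)
}

#' Per-gene mutation supports
#'
#' The support of a gene is the set of samples in which it is mutated in
#' the binary matrix.
#'
#' @param A a `mutation_matrix`.
#' @return A named list mapping each gene to the character vector of
#'   sample identifiers in its support.
#' @export
gene_support <- function(A) {
  A <- as_mutation_matrix_strict(A)
  apply(unclass(A), 2, function(col) rownames(A)[col == 1L],
        simplify = FALSE)
}

# internal: validate without re-copying
as_mutation_matrix_strict <- function(A) {
  if (inherits(A, "mutation_matrix")) A else as_mutation_matrix(A)
}

#' Drop genes mutated in too few samples
#'
#' Removes genes whose mutation frequency is strictly below `min_frac` of
#' the samples; genes exactly at the threshold are retained. The sample
#' set is unchanged.
#'
#' @param A a `mutation_matrix`.
#' @param min_frac minimum fraction of mutated samples; default 0.005
#'   (0.5 percent).
#' @return A `mutation_matrix` restricted to the retained genes.
#' @export
filter_low_frequency_genes <- function(A, min_frac = 0.005) {
  A <- as_mutation_matrix_strict(A)
  stopifnot(min_frac >= 0, min_frac <= 1)
  frac <- colSums(unclass(A)) / nrow(A)
  keep <- frac >= min_frac
  if (!any(keep)) {
    stop("all genes fall below the ", min_frac, " mutation-frequency ",
         "threshold", call. = FALSE)
  }
  new_mutation_matrix(unclass(A)[, keep, drop = FALSE])
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("<mutation_matrix: %d samples x %d genes, %d mutations>\n",
              nrow(x), ncol(x), sum(unclass(x))))
  invisible(x)
}

#' Tidy a mutation matrix into long form
#'
#' @param x a `mutation_matrix`.
#' @param ... unused.
#' @return A tibble with columns `sample`, `gene`, `mutated` (integer 0/1),
#'   one row per cell.
#' @exportS3Method generics::tidy
tidy.mutation_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    sample = rep(rownames(m), times = ncol(m)),
    gene = rep(colnames(m), each = nrow(m)),
    mutated = as.integer(m)
  )
}

#' Oncoprint-style plot of a mutation matrix
#'
#' Tiles samples (rows) against genes (columns), shading mutated cells.
#' Samples are ordered by a waterfall sort (memo-style) so exclusivity
#' structure is visible.
#'
#' @param object a `mutation_matrix`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mutation_matrix <- function(object, ...) {
  m <- unclass(object)
  gene_order <- names(sort(colSums(m), decreasing = TRUE))
  m <- m[, gene_order, drop = FALSE]
  key <- do.call(order, c(lapply(seq_len(ncol(m)), function(j) -m[, j])))
  m <- m[key, , drop = FALSE]
  df <- tidy.mutation_matrix(new_mutation_matrix(m))
  df$sample <- factor(df$sample, levels = rownames(m))
  df$gene <- factor(df$gene, levels = rev(gene_order))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$gene,
                                   fill = factor(.data$mutated))) +
    ggplot2::geom_tile(colour = "grey90", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "#2166AC"),
                               guide = "none") +
    ggplot2::labs(x = "sample", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
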
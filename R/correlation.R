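#' Normalize raw association scores
#'
#' STRING-style association channels report integer confidence scores from
#' 0 to 999; dividing by the maximum printable score 999 maps them onto
#' \[0, 1\] with the top score exactly 1.
#'
#' @param raw integer vector of raw channel scores in \[0, 999\].
#' @return Numeric vector of normalized scores in \[0, 1\].
#' @export
normalize_scores <- function(raw) {
  if (any(is.na(raw)) || any(raw < 0) || any(raw > 999)) {
    stop("raw association scores must lie in [0, 999]", call. = FALSE)
  }
  as.numeric(raw) / 999
}

#' Read a gene-association edge list
#'
#' Reads a 3-column tab-delimited edge list (`geneA<TAB>geneB<TAB>score`)
#' with raw integer scores in \[0, 999\], as exported per channel from the
#' STRING database. `#`-prefixed lines are ignored. Self-pairs and
#' duplicate unordered pairs are format errors.
#'
#' @param path path to the TSV edge list.
#' @return A tibble with columns `geneA`, `geneB`, `score`.
#' @export
read_association_edges <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_names = c("geneA", "geneB", "score"),
                        col_types = readr::cols(
                          geneA = readr::col_character(),
                          geneB = readr::col_character(),
                          score = readr::col_double()),
                        progress = FALSE)
  if (any(df$geneA == df$geneB)) {
    stop("self-pair in '", path, "': ",
         df$geneA[df$geneA == df$geneB][1], call. = FALSE)
  }
  if (any(df$score < 0) || any(df$score > 999) || any(df$score %% 1 != 0)) {
    stop("scores in '", path, "' must be integers in [0, 999]",
         call. = FALSE)
  }
  key <- paste(pmin(df$geneA, df$geneB), pmax(df$geneA, df$geneB))
  if (anyDuplicated(key)) {
    stop("duplicate gene pair in '", path, "': ",
         key[duplicated(key)][1], call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Build a normalized per-channel association matrix
#'
#' Expands an edge list into a symmetric gene x gene matrix of normalized
#' scores over a fixed gene universe. Genes absent from the edge list get
#' all-zero rows; the diagonal is zero.
#'
#' @param edges a tibble as returned by [read_association_edges()].
#' @param gene_ids character vector of the gene universe (typically the
#'   columns of the mutation matrix).
#' @return A symmetric numeric matrix with entries in \[0, 1\].
#' @export
association_matrix <- function(edges, gene_ids) {
  W <- matrix(0, length(gene_ids), length(gene_ids),
              dimnames = list(gene_ids, gene_ids))
  keep <- edges$geneA %in% gene_ids & edges$geneB %in% gene_ids
  e <- edges[keep, , drop = FALSE]
  if (nrow(e)) {
    w <- normalize_scores(e$score)
    W[cbind(e$geneA, e$geneB)] <- w
    W[cbind(e$geneB, e$geneA)] <- w
  }
  diag(W) <- 0
  W
}

#' Combine literature and experimental channels into one correlation matrix
#'
#' The combined weight of a gene pair is the larger of the two normalized
#' channel scores when the experimental channel supports the pair at all,
#' and 0 otherwise: `w = max(f, e)` if `e != 0`, else 0. The experimental
#' channel therefore acts as a gate — literature co-mentions alone never
#' create an edge.
#'
#' @param F_mat,E_mat symmetric normalized channel matrices over the same
#'   gene universe (see [association_matrix()]): `F_mat` the literature
#'   channel, `E_mat` the experimental channel.
#' @return A symmetric `correlation_matrix` with zero diagonal, entries in
#'   \[0, 1\].
#' @export
combine_correlation <- function(F_mat, E_mat) {
  stopifnot(identical(dimnames(F_mat), dimnames(E_mat)))
  if (any(F_mat < 0) || any(F_mat > 1) || any(E_mat < 0) || any(E_mat > 1)) {
    stop("channel scores must be normalized to [0, 1]", call. = FALSE)
  }
  W <- ifelse(E_mat != 0, pmax(F_mat, E_mat), 0)
  diag(W) <- 0
  structure(W, class = c("correlation_matrix", "matrix", "array"))
}

#' Build the combined correlation matrix from two edge lists
#'
#' Convenience wrapper: normalizes both channels over `gene_ids` and
#' applies the max-with-experimental-gate combination rule of
#' [combine_correlation()].
#'
#' @param f_edges,e_edges edge tibbles for the literature and experimental
#'   channels (see [read_association_edges()]).
#' @inheritParams association_matrix
#' @return A `correlation_matrix`.
#' @export
build_correlation_matrix <- function(f_edges, e_edges, gene_ids) {
  combine_correlation(association_matrix(f_edges, gene_ids),
                      association_matrix(e_edges, gene_ids))
}

#' Read / write a correlation matrix as TSV
#'
#' A square gene x gene TSV with a gene-symbol header row and first
#' column. Values must already be in \[0, 1\].
#'
#' @param path file path.
#' @return `read_correlation_matrix()` returns a `correlation_matrix`.
#' @export
read_correlation_matrix <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        name_repair = "minimal", progress = FALSE)
  genes <- as.character(df[[1]])
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- genes
  if (!identical(rownames(W), colnames(W))) {
    stop("'", path, "' is not a square gene x gene matrix", call. = FALSE)
  }
  storage.mode(W) <- "double"
  if (any(W < 0) || any(W > 1)) {
    stop("correlation entries in '", path, "' must lie in [0, 1]",
         call. = FALSE)
  }
  if (max(abs(W - t(W))) > 1e-9) {
    stop("correlation matrix in '", path, "' is not symmetric",
         call. = FALSE)
  }
  diag(W) <- 0
  structure(W, class = c("correlation_matrix", "matrix", "array"))
}

#' @rdname read_correlation_matrix
#' @param W a `correlation_matrix` (or symmetric numeric matrix).
#' @export
write_correlation_matrix <- function(W, path) {
  df <- data.frame(gene = rownames(W), as.data.frame(unclass(W)),
                   check.names = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
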
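#' Cell-level count matrix container
#'
#' Wraps a cells x genes nonnegative count matrix together with a cell ->
#' sample map, the structure needed to build pseudo-bulk profiles.
#' [simulate_cells()] returns a subclass of this container.
#'
#' @param counts cells x genes numeric matrix (nonnegative), with cell IDs
#'   as rownames and gene symbols as colnames.
#' @param sample_of named character vector mapping every cell ID to a
#'   sample ID.
#' @return A list of class `cell_counts`.
#' @export
cell_counts <- function(counts, sample_of) {
  if (!is.matrix(counts) || any(counts < 0)) {
    stop("`counts` must be a nonnegative cells x genes matrix", call. = FALSE)
  }
  missing <- setdiff(rownames(counts), names(sample_of))
  if (length(missing) > 0) {
    stop("cells without a sample assignment: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(counts = counts,
                 sample_of = sample_of[rownames(counts)]),
            class = "cell_counts")
}

#' Aggregate single-cell counts into pseudo-bulk profiles
#'
#' For every sample, sums the raw counts of each gene over all of the
#' sample's cells, producing one bulk-like expression row per sample on the
#' raw count scale. Total counts are conserved exactly.
#'
#' @param c a `cell_counts` (or [simulate_cells()]) object; every sample
#'   must have at least one cell.
#' @return An [expr_matrix()] with `scale = "raw"`, samples x genes.
#' @export
aggregate_to_bulk <- function(c) {
  stopifnot(inherits(c, "cell_counts"))
  if (nrow(c$counts) == 0) stop("no cells to aggregate", call. = FALSE)
  grp <- factor(c$sample_of, levels = unique(c$sample_of))
  agg <- rowsum(c$counts, grp)
  rownames(agg) <- levels(grp)
  expr_matrix(agg, scale = "raw")
}

#' Merge two bulk matrices on their common genes
#'
#' Intersects gene symbols (exact, case-sensitive match), stacks the sample
#' rows of both matrices, and records how many genes each side lost. Sample
#' IDs must not collide; an empty gene intersection is an error.
#'
#' @param bulk_a,bulk_b [expr_matrix()] objects on the raw scale.
#' @return An [expr_matrix()] (`scale = "raw"`) over the common genes, with
#'   `attr(., "dropped")` = named vector of per-side dropped-gene counts.
#' @export
merge_common_genes <- function(bulk_a, bulk_b) {
  stopifnot(inherits(bulk_a, "expr_matrix"), inherits(bulk_b, "expr_matrix"))
  if (bulk_a$scale != "raw" || bulk_b$scale != "raw") {
    stop("both matrices must be on the raw count scale", call. = FALSE)
  }
  common <- intersect(gene_symbols(bulk_a), gene_symbols(bulk_b))
  if (length(common) == 0) stop("no genes in common between the two matrices", call. = FALSE)
  clash <- intersect(sample_ids(bulk_a), sample_ids(bulk_b))
  if (length(clash) > 0) {
    stop("sample IDs present in both matrices: ",
         paste(utils::head(clash, 5), collapse = ", "), call. = FALSE)
  }
  merged <- rbind(bulk_a$values[, common, drop = FALSE],
                  bulk_b$values[, common, drop = FALSE])
  out <- expr_matrix(merged, scale = "raw")
  attr(out, "dropped") <- c(a = ncol(bulk_a$values) - length(common),
                            b = ncol(bulk_b$values) - length(common))
  out
}

#' Median-of-medians normalization and log2 transform
#'
#' Harmonizes sequencing depth between pseudo-bulk samples and a reference
#' bulk training set: compute each sample's median expression, take the
#' median of those medians over the *reference* samples only (call it `c`),
#' bring every sample's median to `c`, then apply `log2(value + 1)`.
#'
#' The default `"multiplicative"` centering rescales each sample by
#' `c / median_i` on the count scale (counts stay nonnegative);
#' `"additive_log"` instead centers the per-sample medians of
#' `log2(count + 1)` additively on the log scale. Both maps are monotone
#' within each sample.
#'
#' @param merged an [expr_matrix()] on the raw scale (e.g. from
#'   [merge_common_genes()]).
#' @param reference_ids sample IDs defining the centering target (subset of
#'   the samples of `merged`).
#' @param method `"multiplicative"` (default) or `"additive_log"`.
#' @return An [expr_matrix()] with `scale = "log2"`.
#' @export
median_center_normalize <- function(merged, reference_ids,
                                    method = c("multiplicative", "additive_log")) {
  method <- match.arg(method)
  stopifnot(inherits(merged, "expr_matrix"))
  if (merged$scale != "raw") stop("input must be on the raw count scale", call. = FALSE)
  missing <- setdiff(reference_ids, sample_ids(merged))
  if (length(missing) > 0) {
    stop("reference samples absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  m <- merged$values
  if (method == "multiplicative") {
    med <- apply(m, 1, stats::median)
    zero <- names(med)[med == 0]
    if (length(zero) > 0) {
      stop("sample(s) with zero median expression: ",
           paste(utils::head(zero, 5), collapse = ", "), call. = FALSE)
    }
    cc <- stats::median(med[reference_ids])
    out <- log2(m * (cc / med) + 1)
  } else {
    lm2 <- log2(m + 1)
    med <- apply(lm2, 1, stats::median)
    cc <- stats::median(med[reference_ids])
    out <- pmax(lm2 + (cc - med), 0)
  }
  expr_matrix(out, scale = "log2")
}

#' Read single-cell counts from MatrixMarket files
#'
#' Expects the layout written by [write_cells_mtx()]: `matrix.mtx` plus
#' `genes.tsv` and `barcodes.tsv` (one ID per line) and a `samples.tsv`
#' mapping `cell_id<TAB>sample_id` (with header).
#'
#' @param dir directory containing the files.
#' @param orientation `"genes_by_cells"` (conventional, default) or
#'   `"cells_by_genes"`.
#' @return A `cell_counts` object.
#' @export
read_cells_mtx <- function(dir, orientation = c("genes_by_cells", "cells_by_genes")) {
  orientation <- match.arg(orientation)
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"), col_names = "gene",
                           col_types = "c", progress = FALSE)$gene
  cells <- readr::read_tsv(file.path(dir, "barcodes.tsv"), col_names = "barcode",
                           col_types = "c", progress = FALSE)$barcode
  if (orientation == "genes_by_cells") m <- t(m)
  dimnames(m) <- list(cells, genes)
  map <- readr::read_tsv(file.path(dir, "samples.tsv"), col_types = "cc",
                         progress = FALSE, show_col_types = FALSE)
  cell_counts(m, stats::setNames(map[[2]], map[[1]]))
}
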
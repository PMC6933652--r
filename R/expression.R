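#' Expression matrix container
#'
#' A light S3 container for a samples x genes expression matrix carrying an
#' explicit scale flag (`"raw"` for normalized read counts, `"log2"` after
#' flooring at 1 and log2-transforming). Sample IDs are rownames, gene
#' symbols colnames; both must be unique. Missing values are permitted on
#' the raw scale (they are removed later by [filter_genes()]).
#'
#' @param values numeric matrix, samples in rows, genes in columns, with
#'   rownames (sample IDs) and colnames (gene symbols).
#' @param scale `"raw"` or `"log2"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x genes)", call. = FALSE)
  }
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("`values` must have rownames (sample IDs) and colnames (gene symbols)",
         call. = FALSE)
  }
  dup_s <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_s) > 0) {
    stop("duplicate sample IDs: ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  }
  dup_g <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_g) > 0) {
    stop("duplicate gene symbols: ", paste(unique(dup_g), collapse = ", "),
         call. = FALSE)
  }
  if (scale == "log2" && any(values < 0, na.rm = TRUE)) {
    stop("log2-scale expression must be >= 0 (raw values are floored at 1 before log2)",
         call. = FALSE)
  }
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d samples x %d genes, scale = %s\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Sample IDs and gene symbols of an expression matrix
#' @param x an `expr_matrix`.
#' @return Character vector of IDs.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
gene_symbols <- function(x) colnames(x$values)

#' Read a delimited expression matrix
#'
#' Reads a TSV (or CSV) matrix with one header row and one leading ID column
#' into an `expr_matrix` in samples x genes orientation on the raw scale.
#' Missing values may be spelled `NA` or left empty; they are retained and
#' should be removed downstream with [filter_genes()].
#'
#' @param path file path.
#' @param orientation `"genes_by_samples"` (header = sample IDs, rows = genes;
#'   the common public-data layout) or `"samples_by_genes"`.
#' @param delim field delimiter; `"\t"` by default, `","` accepted.
#' @param collapse_dup_genes policy for duplicated gene symbols: `"error"`
#'   (default) or `"mean"` (average the duplicated rows/columns).
#' @return An `expr_matrix` with `scale = "raw"`.
#' @export
load_expression <- function(path,
                            orientation = c("genes_by_samples", "samples_by_genes"),
                            delim = "\t",
                            collapse_dup_genes = c("error", "mean")) {
  orientation <- match.arg(orientation)
  collapse_dup_genes <- match.arg(collapse_dup_genes)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          na = c("", "NA"), progress = FALSE,
                          show_col_types = FALSE)
  if (ncol(df) < 2) stop("expression file needs an ID column plus >= 1 data column: ", path,
                         call. = FALSE)
  ids <- as.character(df[[1]])
  num <- df[, -1, drop = FALSE]
  bad <- names(num)[!vapply(num, is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop("non-numeric cells in column(s): ", paste(bad, collapse = ", "),
         " of ", path, call. = FALSE)
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "genes_by_samples") m <- t(m)
  # now samples x genes
  genes <- colnames(m)
  if (anyDuplicated(genes)) {
    if (collapse_dup_genes == "error") {
      stop("duplicate gene symbols: ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "),
           "; pass collapse_dup_genes = \"mean\" to average them", call. = FALSE)
    }
    m <- vapply(split(seq_along(genes), genes),
                function(j) rowMeans(m[, j, drop = FALSE]),
                numeric(nrow(m)))
    m <- m[, unique(genes), drop = FALSE]
  }
  expr_matrix(m, scale = "raw")
}

#' Write an expression matrix as TSV
#'
#' @param x an `expr_matrix`.
#' @param path output file.
#' @param orientation layout to write (see [load_expression()]).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path,
                             orientation = c("genes_by_samples", "samples_by_genes")) {
  orientation <- match.arg(orientation)
  m <- x$values
  if (orientation == "genes_by_samples") {
    df <- tibble::as_tibble(t(m), rownames = "gene")
  } else {
    df <- tibble::as_tibble(m, rownames = "sample_id")
  }
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Floor at 1 and log2-transform raw expression
#'
#' Every raw value `v` is replaced by `log2(max(v, 1))`, so values below 1
#' map to 0 and the transformed matrix is nonnegative. Applying the
#' transform to an already log2-scaled matrix is an error (the scale flag
#' guards against double transformation).
#'
#' @param x an `expr_matrix` with `scale = "raw"` and values >= 0.
#' @return An `expr_matrix` with `scale = "log2"`.
#' @export
log2_floor_transform <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$scale != "raw") {
    stop("input is already on the log2 scale; refusing to transform twice",
         call. = FALSE)
  }
  if (any(x$values < 0, na.rm = TRUE)) {
    stop("raw expression values must be >= 0", call. = FALSE)
  }
  expr_matrix(log2(pmax(x$values, 1)), scale = "log2")
}

#' Drop genes with missing values or zero variance
#'
#' Retains exactly the genes with no missing value and nonzero variance
#' across samples. The removed symbols are recorded in the
#' `"removed_genes"` attribute of the result.
#'
#' @param x an `expr_matrix`.
#' @return A filtered `expr_matrix`; `attr(., "removed_genes")` lists the
#'   dropped symbols.
#' @export
filter_genes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  m <- x$values
  has_na <- apply(m, 2, anyNA)
  v <- rep(NA_real_, ncol(m))
  v[!has_na] <- apply(m[, !has_na, drop = FALSE], 2, stats::var)
  keep <- !has_na & v > 0
  if (!any(keep)) stop("no genes left after filtering", call. = FALSE)
  out <- expr_matrix(m[, keep, drop = FALSE], scale = x$scale)
  attr(out, "removed_genes") <- colnames(m)[!keep]
  out
}

#' Keep one sample per patient
#'
#' When several samples come from the same patient, all but one are removed.
#' The retained sample is the lexicographically smallest sample ID within
#' each patient, a deterministic rule.
#'
#' @param x an `expr_matrix`.
#' @param patient_of named character vector mapping every sample ID of `x`
#'   to a patient ID.
#' @return An `expr_matrix` with at most one sample per patient;
#'   `attr(., "removed_samples")` lists the dropped sample IDs.
#' @export
dedupe_samples <- function(x, patient_of) {
  stopifnot(inherits(x, "expr_matrix"))
  ids <- sample_ids(x)
  if (length(ids) == 0) return(x)
  missing <- setdiff(ids, names(patient_of))
  if (length(missing) > 0) {
    stop("samples without a patient assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- tibble::tibble(sample_id = ids, patient = unname(patient_of[ids])) |>
    dplyr::arrange(.data$sample_id) |>
    dplyr::distinct(.data$patient, .keep_all = TRUE) |>
    dplyr::pull("sample_id")
  keep <- ids[ids %in% keep]  # preserve original sample order
  out <- expr_matrix(x$values[keep, , drop = FALSE], scale = x$scale)
  attr(out, "removed_samples") <- setdiff(ids, keep)
  out
}
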
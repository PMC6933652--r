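#' Simulate bulk tumor expression with a planted stromal signature
#'
#' Generates a samples x genes log2-scale expression matrix whose structure
#' mirrors what purity regression assumes about real tumors: each sample is a
#' mixture of cancer and stromal material, and a minority of "stromal" marker
#' genes have expression that decreases monotonically with tumor purity
#' (immune/stromal genes are high when the sample contains little tumor).
#'
#' The model, all on the log2 scale: purity `p_i ~ Beta(shape1, shape2)`
#' clipped to `[0.01, 0.99]`; gene baselines `mu_g ~ Uniform(2, 10)`; samples
#' are assigned round-robin to `n_types` tumor types, each with a per-type,
#' per-gene batch shift `delta ~ Normal(0, type_shift_sd)`. Non-marker genes:
#' `x_ig = mu_g + delta + eps`; marker genes additionally gain
#' `effect_size * (1 - p_i)`; `eps ~ Normal(0, noise_sd)`.
#'
#' @param n_samples,n_genes,n_markers problem size; `n_markers < n_genes`.
#' @param effect_size log2-units drop of a marker gene from purity 0 to 1.
#' @param noise_sd additive Gaussian noise SD (log2 units).
#' @param n_types number of tumor-type batch groups.
#' @param type_shift_sd SD of the per-type per-gene batch shift (log2 units).
#' @param purity_shape1,purity_shape2 Beta parameters of the purity law.
#' @param seed integer seed; output is deterministic given the seed.
#' @return A list of class `synthetic_bulk` with elements `expression`
#'   (an [expr_matrix()], `scale = "log2"`), `purity` (a [purity_vector()],
#'   original scale) and `truth` (generator parameters plus the planted
#'   `marker_genes` and per-sample `tumor_type`).
#' @export
simulate_bulk <- function(n_samples = 600, n_genes = 2000, n_markers = 20,
                          effect_size = 2, noise_sd = 0.5,
                          n_types = 3, type_shift_sd = 0.5,
                          purity_shape1 = 2, purity_shape2 = 2,
                          seed = 1) {
  if (n_markers >= n_genes) stop("`n_markers` must be < `n_genes`", call. = FALSE)
  if (noise_sd < 0 || type_shift_sd < 0 || effect_size < 0) {
    stop("`noise_sd`, `type_shift_sd` and `effect_size` must be >= 0", call. = FALSE)
  }
  if (n_types < 1) stop("`n_types` must be >= 1", call. = FALSE)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)

  samples <- sprintf("S%04d", seq_len(n_samples))
  genes <- sprintf("G%05d", seq_len(n_genes))
  markers <- sort(sample(genes, n_markers))
  p <- stats::rbeta(n_samples, purity_shape1, purity_shape2)
  p <- pmin(pmax(p, 0.01), 0.99)
  type <- rep_len(seq_len(n_types), n_samples)

  mu <- stats::runif(n_genes, 2, 10)
  delta <- matrix(stats::rnorm(n_types * n_genes, 0, type_shift_sd),
                  n_types, n_genes)
  eps <- matrix(stats::rnorm(n_samples * n_genes, 0, noise_sd),
                n_samples, n_genes)

  x <- matrix(mu, n_samples, n_genes, byrow = TRUE) + delta[type, , drop = FALSE] + eps
  is_marker <- genes %in% markers
  x[, is_marker] <- x[, is_marker] + outer(1 - p, rep(effect_size, sum(is_marker)))
  x <- pmax(x, 0)  # log2 scale is nonnegative by construction of the flooring rule
  dimnames(x) <- list(samples, genes)

  truth <- structure(
    list(n_samples = n_samples, n_genes = n_genes, n_markers = n_markers,
         purity = stats::setNames(p, samples), marker_genes = markers,
         effect_size = effect_size, noise_sd = noise_sd, n_types = n_types,
         type_shift_sd = type_shift_sd, tumor_type = stats::setNames(type, samples),
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
  structure(
    list(expression = expr_matrix(x, scale = "log2"),
         purity = purity_vector(samples, p, scale = "original"),
         truth = truth),
    class = "synthetic_bulk"
  )
}

#' @export
print.synthetic_bulk <- function(x, ...) {
  cat(sprintf("<synthetic_bulk> %d samples x %d genes, %d planted markers, effect %.2g, noise %.2g\n",
              x$truth$n_samples, x$truth$n_genes, x$truth$n_markers,
              x$truth$effect_size, x$truth$noise_sd))
  invisible(x)
}

#' Cancer / stromal expression profiles for the single-cell sampler
#'
#' Builds a pair of per-gene Poisson rate vectors sharing a gene set. Both
#' cell types share Uniform-distributed baseline rates; for the chosen marker
#' genes the stromal rate is `marker_ratio` times the cancer rate, so
#' aggregated expression of those genes falls as the cancer-cell fraction
#' rises.
#'
#' @param n_genes number of genes.
#' @param n_markers number of stromal marker genes.
#' @param marker_ratio stromal/cancer rate ratio at marker genes (>= 1).
#' @param base_range range of baseline per-cell rates (counts per cell).
#' @param seed integer seed.
#' @return A list of class `cell_profiles` with numeric vectors `cancer` and
#'   `stromal` (named by gene) and the `marker_genes` character vector.
#' @export
make_cell_profiles <- function(n_genes = 500, n_markers = 20, marker_ratio = 4,
                               base_range = c(0.5, 5), seed = 1) {
  if (n_markers >= n_genes) stop("`n_markers` must be < `n_genes`", call. = FALSE)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  genes <- sprintf("G%05d", seq_len(n_genes))
  base <- stats::runif(n_genes, base_range[1], base_range[2])
  names(base) <- genes
  markers <- sort(sample(genes, n_markers))
  stromal <- base
  stromal[markers] <- stromal[markers] * marker_ratio
  structure(list(cancer = base, stromal = stromal, marker_genes = markers),
            class = "cell_profiles")
}

#' Simulate single-cell counts with known cancer-cell fractions
#'
#' Each sample receives `cells_per_sample` cells; every cell is labeled
#' cancer with probability equal to its sample's purity (Bernoulli draw) and
#' its gene counts are Poisson around the labeled profile. The recorded
#' ground-truth purity of a sample is the realized cancer-cell fraction,
#' matching how cell-type-derived purity is measured in single-cell studies.
#'
#' @param n_samples number of samples.
#' @param cells_per_sample cells sequenced per sample (>= 1).
#' @param purity numeric vector of length `n_samples` in `[0, 1]` (the
#'   Bernoulli cancer probability per cell), optionally named by sample ID.
#' @param profiles a [make_cell_profiles()] object, or any list with
#'   nonnegative `cancer` and `stromal` rate vectors over a shared gene set.
#' @param seed integer seed.
#' @return A list of class `synthetic_cells` (also `cell_counts`): `counts`
#'   (cells x genes integer matrix), `cell_labels` (`"cancer"`/`"stromal"`),
#'   `sample_of` (named cell -> sample map), `true_purity` (named per-sample
#'   realized cancer-cell fraction).
#' @export
simulate_cells <- function(n_samples, cells_per_sample, purity, profiles,
                           seed = 1) {
  if (cells_per_sample < 1) stop("`cells_per_sample` must be >= 1", call. = FALSE)
  if (length(purity) != n_samples) {
    stop("`purity` must have one value per sample", call. = FALSE)
  }
  if (any(purity < 0 | purity > 1)) stop("purities must lie in [0, 1]", call. = FALSE)
  if (!identical(names(profiles$cancer), names(profiles$stromal))) {
    stop("cancer and stromal profiles must share one gene set", call. = FALSE)
  }
  if (any(profiles$cancer < 0) || any(profiles$stromal < 0)) {
    stop("profile rates must be nonnegative", call. = FALSE)
  }
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)

  samples <- if (!is.null(names(purity))) names(purity) else sprintf("PB%03d", seq_len(n_samples))
  genes <- names(profiles$cancer)
  n_cells <- n_samples * cells_per_sample
  sample_of <- rep(samples, each = cells_per_sample)
  is_cancer <- stats::rbinom(n_cells, 1, rep(purity, each = cells_per_sample)) == 1

  counts <- matrix(0L, n_cells, length(genes))
  if (any(is_cancer)) {
    counts[is_cancer, ] <- stats::rpois(sum(is_cancer) * length(genes),
                                        rep(profiles$cancer, each = sum(is_cancer)))
  }
  if (any(!is_cancer)) {
    counts[!is_cancer, ] <- stats::rpois(sum(!is_cancer) * length(genes),
                                         rep(profiles$stromal, each = sum(!is_cancer)))
  }
  cell_ids <- sprintf("cell%06d", seq_len(n_cells))
  dimnames(counts) <- list(cell_ids, genes)
  true_purity <- vapply(split(is_cancer, sample_of), mean, numeric(1))[samples]

  structure(
    list(counts = counts,
         cell_labels = stats::setNames(ifelse(is_cancer, "cancer", "stromal"), cell_ids),
         sample_of = stats::setNames(sample_of, cell_ids),
         true_purity = true_purity),
    class = c("synthetic_cells", "cell_counts")
  )
}

#' Simulate count-scale reference bulk samples from cell profiles
#'
#' Draws per-gene Poisson counts around a purity-weighted mixture of the
#' cancer and stromal rate profiles, `rate_g = depth * (p * cancer_g +
#' (1 - p) * stromal_g)` — the expectation of summing `depth` cells of a
#' [simulate_cells()] draw. Used to build a raw-count reference training set
#' that shares the count scale with pseudo-bulk samples.
#'
#' @param purity numeric vector of sample purities in `[0, 1]`, optionally
#'   named by sample ID.
#' @param profiles a [make_cell_profiles()] object.
#' @param depth effective number of cells contributing to each bulk sample.
#' @param seed integer seed.
#' @return An [expr_matrix()] with `scale = "raw"` (samples x genes counts).
#' @export
simulate_bulk_counts <- function(purity, profiles, depth = 2000, seed = 1) {
  if (any(purity < 0 | purity > 1)) stop("purities must lie in [0, 1]", call. = FALSE)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  samples <- if (!is.null(names(purity))) names(purity) else sprintf("RB%03d", seq_along(purity))
  genes <- names(profiles$cancer)
  rates <- outer(purity, profiles$cancer) + outer(1 - purity, profiles$stromal)
  counts <- matrix(stats::rpois(length(rates), depth * rates),
                   nrow = length(purity), dimnames = list(samples, genes))
  expr_matrix(counts, scale = "raw")
}

#' Write simulated single-cell data as MatrixMarket + sidecar TSVs
#'
#' Writes `matrix.mtx` (genes x cells, the conventional orientation),
#' `genes.tsv`, `barcodes.tsv`, `labels.tsv` (cell_id, label) and
#' `samples.tsv` (cell_id, sample_id) into `dir`.
#'
#' @param cells a `synthetic_cells` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cells_mtx <- function(cells, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(t(cells$counts), sparse = TRUE)  # genes x cells
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(gene = colnames(cells$counts)),
                   file.path(dir, "genes.tsv"), col_names = FALSE, progress = FALSE)
  readr::write_tsv(tibble::tibble(barcode = rownames(cells$counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE, progress = FALSE)
  readr::write_tsv(tibble::tibble(cell_id = names(cells$cell_labels),
                                  label = unname(cells$cell_labels)),
                   file.path(dir, "labels.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(cell_id = names(cells$sample_of),
                                  sample_id = unname(cells$sample_of)),
                   file.path(dir, "samples.tsv"), progress = FALSE)
  invisible(dir)
}
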
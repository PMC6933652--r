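#' Normalized per-model gene importance
#'
#' Within one boosted model, a gene's importance is the sum of its split-gain
#' contributions over all trees divided by the total split gain over all
#' genes and all trees, so the scores of a model are nonnegative and sum
#' to 1. Genes never used in a split score exactly 0.
#'
#' @param tree_scores nonnegative split-gain sums: either a genes x trees
#'   matrix of per-tree per-gene gains, or a named per-gene total vector.
#' @return Named numeric vector of normalized scores summing to 1.
#' @export
model_importance <- function(tree_scores) {
  totals <- if (is.matrix(tree_scores)) rowSums(tree_scores) else tree_scores
  if (any(totals < 0)) stop("split-gain scores must be nonnegative", call. = FALSE)
  denom <- sum(totals)
  if (denom == 0) stop("model made no splits: all importance scores are zero", call. = FALSE)
  totals / denom
}

#' Aggregate importance scores across an ensemble
#'
#' From the genes x M matrix of per-model normalized scores: a gene is
#' *eligible* iff its score is strictly positive in every one of the M
#' models. Within each model all genes are ranked by descending score
#' (average ranks on ties, so zero-score genes share the bottom rank); each
#' gene's `median_rank` is the median of its M ranks. Eligible genes are
#' ordered by the chosen statistic — ascending `median_rank` (default),
#' or descending `median_score` / `mean_score` — with ties broken by
#' descending mean score, then gene symbol.
#'
#' @param per_model genes x M numeric matrix of normalized per-model scores
#'   (rownames = gene symbols), or a `purity_ensemble` whose `$importance`
#'   matrix is used.
#' @param rank_stat ordering statistic: `"median_rank"`, `"median_score"`,
#'   or `"mean_score"`.
#' @return An `importance_table` tibble with columns `gene`, `mean_score`,
#'   `median_score`, `median_rank`, `eligible`, `final_rank` (NA for
#'   ineligible genes), sorted by `final_rank` then gene; the per-model
#'   matrix is kept in `attr(., "per_model")`.
#' @export
aggregate_importance <- function(per_model,
                                 rank_stat = c("median_rank", "median_score",
                                               "mean_score")) {
  rank_stat <- match.arg(rank_stat)
  if (inherits(per_model, "purity_ensemble")) per_model <- per_model$importance
  if (!is.matrix(per_model) || is.null(rownames(per_model))) {
    stop("`per_model` must be a genes x models matrix with gene rownames", call. = FALSE)
  }
  if (ncol(per_model) < 1) stop("need at least one model", call. = FALSE)

  ranks <- apply(per_model, 2, function(s) rank(-s, ties.method = "average"))
  tbl <- tibble::tibble(
    gene = rownames(per_model),
    mean_score = unname(rowMeans(per_model)),
    median_score = unname(apply(per_model, 1, stats::median)),
    median_rank = unname(apply(ranks, 1, stats::median)),
    eligible = unname(apply(per_model > 0, 1, all))
  )
  key <- switch(rank_stat,
                median_rank = tbl$median_rank,
                median_score = -tbl$median_score,
                mean_score = -tbl$mean_score)
  ord <- order(!tbl$eligible, key, -tbl$mean_score, tbl$gene)
  tbl <- tbl[ord, ]
  tbl$final_rank <- ifelse(tbl$eligible, cumsum(tbl$eligible), NA_integer_)
  class(tbl) <- c("importance_table", class(tbl))
  attr(tbl, "per_model") <- per_model
  attr(tbl, "rank_stat") <- rank_stat
  tbl
}

#' Extract the top-k marker panel
#'
#' @param t an `importance_table`.
#' @param k panel size; must not exceed the number of eligible genes.
#' @return Character vector of the first `k` genes in final order.
#' @export
top_k_panel <- function(t, k) {
  stopifnot(inherits(t, "importance_table"))
  n_elig <- sum(t$eligible)
  if (k > n_elig) {
    stop(sprintf("requested k = %d markers but only %d genes are eligible", k, n_elig),
         call. = FALSE)
  }
  if (k == 0) return(character(0))
  t$gene[!is.na(t$final_rank)][seq_len(k)]
}

#' Write an importance table / marker panel to disk
#'
#' @param t an `importance_table`.
#' @param path output TSV (gene, mean_score, median_score, median_rank,
#'   eligible, final_rank).
#' @return `path`, invisibly.
#' @export
write_importance <- function(t, path) {
  readr::write_tsv(tibble::as_tibble(t)[, c("gene", "mean_score", "median_score",
                                            "median_rank", "eligible", "final_rank")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_importance
#' @param panel character vector of gene symbols.
#' @export
write_panel <- function(panel, path) {
  writeLines(panel, path)
  invisible(path)
}
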
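#' Stochastic gradient boosting configuration
#'
#' Defaults are the tuned pan-cancer parameter set: learning rate 0.05,
#' maximum tree depth 4, minimum leaf weight 1, 65% of genes and 85% of
#' samples drawn for each tree, up to 5000 trees with early stopping once the
#' monitored RMSE has not improved for 5 additional trees. The loss is least
#' squares on logit-scale purity.
#'
#' @param learning_rate shrinkage applied to each tree's contribution.
#' @param max_depth maximum tree depth.
#' @param min_leaf_weight minimum sum of instance weights in a leaf.
#' @param colsample_per_tree fraction of genes sampled per tree, in (0, 1].
#' @param subsample_per_tree fraction of samples sampled per tree, in (0, 1].
#' @param max_trees maximum number of boosting rounds.
#' @param early_stop_patience rounds without improvement before stopping.
#' @param tree_method split-finding algorithm (`"hist"`, `"exact"`,
#'   `"approx"`); `"hist"` with a reduced `max_bin` gives the same accuracy
#'   at a fraction of the cost on expression data.
#' @param max_bin histogram bins per feature for `tree_method = "hist"`.
#' @return A list of class `gbm_config`.
#' @export
gbm_config <- function(learning_rate = 0.05, max_depth = 4, min_leaf_weight = 1,
                       colsample_per_tree = 0.65, subsample_per_tree = 0.85,
                       max_trees = 5000, early_stop_patience = 5,
                       tree_method = "hist", max_bin = 64) {
  stopifnot(learning_rate > 0,
            max_depth >= 1,
            min_leaf_weight >= 0,
            colsample_per_tree > 0, colsample_per_tree <= 1,
            subsample_per_tree > 0, subsample_per_tree <= 1,
            max_trees >= 1,
            early_stop_patience >= 1,
            max_bin >= 2)
  structure(
    list(learning_rate = learning_rate, max_depth = as.integer(max_depth),
         min_leaf_weight = min_leaf_weight,
         colsample_per_tree = colsample_per_tree,
         subsample_per_tree = subsample_per_tree,
         max_trees = as.integer(max_trees),
         early_stop_patience = as.integer(early_stop_patience),
         tree_method = tree_method, max_bin = as.integer(max_bin),
         loss = "least squares"),
    class = "gbm_config"
  )
}

#' @export
print.gbm_config <- function(x, ...) {
  cat(sprintf(paste0("<gbm_config> lr %.3g, depth %d, min leaf weight %.3g, ",
                     "colsample %.2f, subsample %.2f, max trees %d, patience %d\n"),
              x$learning_rate, x$max_depth, x$min_leaf_weight,
              x$colsample_per_tree, x$subsample_per_tree,
              x$max_trees, x$early_stop_patience))
  invisible(x)
}

#' Default tuning grid
#'
#' A compact 24-point grid around the tuned default configuration: learning
#' rate x max depth x column-sample x row-sample. All other fields keep the
#' [gbm_config()] defaults (optionally overridden via `...`).
#'
#' @param ... overrides applied to every grid point (e.g. `max_trees = 300`).
#' @return A list of `gbm_config` objects.
#' @export
default_grid <- function(...) {
  pts <- expand.grid(learning_rate = c(0.05, 0.1),
                     max_depth = c(3, 4, 6),
                     colsample_per_tree = c(0.65, 1.0),
                     subsample_per_tree = c(0.85, 1.0))
  purrr::pmap(pts, function(learning_rate, max_depth, colsample_per_tree,
                            subsample_per_tree) {
    gbm_config(learning_rate = learning_rate, max_depth = max_depth,
               colsample_per_tree = colsample_per_tree,
               subsample_per_tree = subsample_per_tree, ...)
  })
}

# deterministic seed ladder: one integer stream per (master_seed, index),
# kept inside the 32-bit signed range
derive_seeds <- function(master_seed, n, salt = 0L) {
  restore <- local_seed((as.integer(master_seed) %% 1000000L) * 2011L + salt)
  on.exit(restore(), add = TRUE)
  sample.int(2147483646L, n)
}

#' Build a repeated cross-validation plan
#'
#' Each repetition shuffles the samples with its own derived seed and cuts
#' the shuffled order into `n_folds` contiguous blocks whose sizes differ by
#' at most one; every sample sits in exactly one validation fold per
#' repetition. One learner seed per (repetition, fold) model is derived from
#' the same master seed so the full ensemble is reproducible.
#'
#' @param sample_ids character vector of training sample IDs.
#' @param n_repetitions number of shuffles (default 100).
#' @param n_folds folds per repetition (default 10).
#' @param master_seed integer seed for the whole plan.
#' @return A list of class `cv_plan` with `fold_assignment` (an
#'   `n_repetitions` x `n_samples` integer matrix of fold indices),
#'   `shuffle_seeds`, and `model_seeds` (`n_repetitions` x `n_folds`).
#' @export
build_cv_plan <- function(sample_ids, n_repetitions = 100, n_folds = 10,
                          master_seed = 1) {
  n <- length(sample_ids)
  if (n_folds < 2) stop("`n_folds` must be >= 2", call. = FALSE)
  if (n_folds > n) stop("`n_folds` cannot exceed the number of samples", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs", call. = FALSE)

  shuffle_seeds <- derive_seeds(master_seed, n_repetitions, salt = 1L)
  model_seeds <- matrix(derive_seeds(master_seed, n_repetitions * n_folds, salt = 2L),
                        n_repetitions, n_folds)
  # contiguous blocks over each shuffled order; first (n %% k) folds get the
  # extra sample
  base <- n %/% n_folds
  sizes <- rep(base, n_folds) + c(rep(1L, n %% n_folds), rep(0L, n_folds - n %% n_folds))
  block <- rep(seq_len(n_folds), times = sizes)
  fold_assignment <- matrix(NA_integer_, n_repetitions, n,
                            dimnames = list(NULL, sample_ids))
  for (r in seq_len(n_repetitions)) {
    restore <- local_seed(shuffle_seeds[r])
    ord <- sample.int(n)
    restore()
    fold_assignment[r, ord] <- block
  }
  structure(
    list(sample_ids = sample_ids, n_repetitions = as.integer(n_repetitions),
         n_folds = as.integer(n_folds), master_seed = as.integer(master_seed),
         shuffle_seeds = shuffle_seeds, model_seeds = model_seeds,
         fold_assignment = fold_assignment),
    class = "cv_plan"
  )
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("<cv_plan> %d repetitions x %d folds over %d samples (master seed %d)\n",
              x$n_repetitions, x$n_folds, length(x$sample_ids), x$master_seed))
  invisible(x)
}
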
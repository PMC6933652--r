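#' Root mean square error
#'
#' `RMSE(y, yhat) = sqrt(mean((y - yhat)^2))`, evaluated on the original
#' `[0, 1]` purity scale throughout the package.
#'
#' @param y,yhat equal-length finite numeric vectors.
#' @return A single nonnegative number.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("`y` and `yhat` lengths differ", call. = FALSE)
  if (length(y) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(yhat))) stop("non-finite values", call. = FALSE)
  sqrt(mean((y - yhat)^2))
}

#' Pearson and Spearman correlation between observed and predicted purity
#'
#' @param y,yhat equal-length numeric vectors (N >= 3), each with nonzero
#'   variance; a constant vector is an error, not a silent 0.
#' @return Named numeric vector `c(pearson = , spearman = )`.
#' @export
correlations <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("`y` and `yhat` lengths differ", call. = FALSE)
  if (length(y) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  c(pearson = stats::cor(y, yhat, method = "pearson"),
    spearman = stats::cor(y, yhat, method = "spearman"))
}

#' Mean, standard error and median of a per-model metric
#'
#' Standard error is the sample SD divided by `sqrt(M)`; for a single model
#' it is 0 by convention.
#'
#' @param values numeric vector of per-model metric values (length M >= 1).
#' @return A one-row tibble with `mean`, `std_error`, `median`, `n_models`.
#' @export
summarize_models <- function(values) {
  stopifnot(length(values) >= 1)
  se <- if (length(values) == 1) 0 else stats::sd(values) / sqrt(length(values))
  tibble::tibble(mean = mean(values), std_error = se,
                 median = stats::median(values), n_models = length(values))
}

#' Evaluate ensemble predictions against observed purity
#'
#' Computes per-model RMSE / Pearson / Spearman from the per-model prediction
#' matrix, their mean / standard error / median summaries, and the same
#' metrics for the final bagged prediction. All metrics are on the original
#' `[0, 1]` purity scale.
#'
#' @param pred a `purity_prediction` from [predict.purity_ensemble()].
#' @param truth a [purity_vector()] on the original scale covering the
#'   predicted samples.
#' @return A list of class `purity_eval`: `per_model` (tibble: model,
#'   rmse, pearson, spearman), `summary` (tibble: metric, mean, std_error,
#'   median), `final` (named vector: rmse, pearson, spearman), `n`.
#' @export
evaluate_predictions <- function(pred, truth) {
  stopifnot(inherits(pred, "purity_prediction"), inherits(truth, "purity_vec"))
  if (purity_scale(truth) != "original") {
    stop("`truth` must be on the original purity scale", call. = FALSE)
  }
  y <- stats::setNames(truth$purity, truth$sample_id)[pred$sample_id]
  if (anyNA(y)) stop("truth is missing some predicted samples", call. = FALSE)
  pm <- attr(pred, "per_model")
  per_model <- purrr::map_dfr(seq_len(nrow(pm)), function(i) {
    cc <- correlations(y, pm[i, ])
    tibble::tibble(model = i, rmse = rmse(y, pm[i, ]),
                   pearson = cc[["pearson"]], spearman = cc[["spearman"]])
  })
  summary <- dplyr::bind_rows(
    dplyr::mutate(summarize_models(per_model$rmse), metric = "rmse"),
    dplyr::mutate(summarize_models(per_model$pearson), metric = "pearson"),
    dplyr::mutate(summarize_models(per_model$spearman), metric = "spearman")
  ) |> dplyr::select("metric", dplyr::everything())
  cc <- correlations(y, pred$purity_pred)
  structure(
    list(per_model = per_model, summary = summary,
         final = c(rmse = rmse(y, pred$purity_pred),
                   pearson = cc[["pearson"]], spearman = cc[["spearman"]]),
         n = length(y)),
    class = "purity_eval"
  )
}

#' @export
print.purity_eval <- function(x, ...) {
  cat(sprintf("<purity_eval> %d samples, %d models\n", x$n, nrow(x$per_model)))
  cat(sprintf("  bagged predictor: RMSE %.4f, Pearson %.4f, Spearman %.4f\n",
              x$final[["rmse"]], x$final[["pearson"]], x$final[["spearman"]]))
  invisible(x)
}

#' Label-permutation significance test for the trained predictor
#'
#' The observed statistic is the test-set performance (Pearson correlation by
#' default) of the bagged predictor trained on the true training labels. For
#' each of `B` permutations the training purities are shuffled uniformly at
#' random (test labels untouched), the full train-and-predict procedure is
#' re-run at reduced ensemble scale, and the test statistic recorded. The
#' empirical p-value uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, so it is never 0.
#'
#' @param x_train,p_train training expression (`log2`) and purity (original
#'   scale) — purity is logit-transformed internally for fitting.
#' @param x_test,p_test held-out test expression and original-scale purity.
#' @param config a [gbm_config()]; keep `max_trees` modest here, the test
#'   refits the pipeline `B + 1` times.
#' @param n_repetitions,n_folds reduced ensemble plan used for every fit.
#' @param B number of permutations (>= 1).
#' @param master_seed integer seed driving plan, learner seeds and the
#'   permutations.
#' @param statistic `"pearson"` (default) or `"neg_rmse"` (negated RMSE, so
#'   larger is better for both).
#' @return A list of class `permutation_result`: `observed`, `null`
#'   (length-B vector), `p_value`, `B`, `statistic`.
#' @export
permutation_test <- function(x_train, p_train, x_test, p_test,
                             config = gbm_config(max_trees = 100),
                             n_repetitions = 1, n_folds = 3,
                             B = 19, master_seed = 1,
                             statistic = c("pearson", "neg_rmse")) {
  statistic <- match.arg(statistic)
  if (B < 1) stop("`B` must be >= 1", call. = FALSE)
  if (purity_scale(p_train) != "original" || purity_scale(p_test) != "original") {
    stop("purities must be on the original scale", call. = FALSE)
  }
  p_train <- align_purity(x_train, p_train)

  stat_fun <- function(y, yhat) {
    if (statistic == "pearson") stats::cor(y, yhat) else -rmse(y, yhat)
  }
  run_once <- function(train_purity, seed) {
    plan <- build_cv_plan(sample_ids(x_train), n_repetitions = n_repetitions,
                          n_folds = n_folds, master_seed = seed)
    ens <- train_ensemble(x_train, logit_transform(train_purity),
                          config = config, plan = plan)
    pred <- stats::predict(ens, x_test)
    y <- stats::setNames(p_test$purity, p_test$sample_id)[pred$sample_id]
    stat_fun(y, pred$purity_pred)
  }

  observed <- run_once(p_train, master_seed)
  perm_seeds <- derive_seeds(master_seed, B, salt = 3L)
  null_stats <- vapply(seq_len(B), function(b) {
    restore <- local_seed(perm_seeds[b])
    idx <- sample.int(nrow(p_train))
    restore()
    perm <- purity_vector(p_train$sample_id, p_train$purity[idx],
                          scale = "original")
    run_once(perm, perm_seeds[b])
  }, numeric(1))

  structure(
    list(observed = observed, null = null_stats,
         p_value = (1 + sum(null_stats >= observed)) / (B + 1),
         B = as.integer(B), statistic = statistic),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s: observed %.4f vs %d permutations, p = %.4g\n",
              x$statistic, x$observed, x$B, x$p_value))
  invisible(x)
}
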
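#' The ten-gene tumor purity marker panel
#'
#' Marker genes for tumor purity prediction discovered by ranking normalized
#' split-gain importance across a 1000-model pan-cancer ensemble; all are
#' predominantly expressed by stromal/immune cells, so their expression falls
#' as purity rises.
#' @export
purity_marker_panel <- c("CSF2RB", "RHOH", "C1S", "CCDC69", "CCL22",
                         "CYTIP", "POU2AF1", "FGR", "CCL21", "IL7R")

# fit one boosted-tree model on a training partition, monitoring RMSE on a
# held-out fold (or on the training partition itself) for early stopping
fit_one_model <- function(xtr, ytr, xva, yva, config, seed,
                          monitor = c("validation", "training")) {
  monitor <- match.arg(monitor)
  dtrain <- xgboost::xgb.DMatrix(xtr, label = ytr, nthread = 1)
  evals <- if (monitor == "validation") {
    list(mon = xgboost::xgb.DMatrix(xva, label = yva, nthread = 1))
  } else {
    list(mon = dtrain)
  }
  params <- list(objective = "reg:squarederror",
                 eta = config$learning_rate,
                 max_depth = config$max_depth,
                 min_child_weight = config$min_leaf_weight,
                 colsample_bytree = config$colsample_per_tree,
                 subsample = config$subsample_per_tree,
                 tree_method = config$tree_method,
                 max_bin = config$max_bin,
                 nthread = 1)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  model <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = config$max_trees,
                              evals = evals,
                              early_stopping_rounds = config$early_stop_patience,
                              verbose = 0)
  bi <- xgboost::xgb.attr(model, "best_iteration")
  n_trees <- xgboost::xgb.get.num.boosted.rounds(model)
  best_iter <- if (is.null(bi)) n_trees - 1L else as.integer(bi)
  # keep only the rounds actually used for prediction, and round-trip through
  # the serialized form so the booster drops its cached training DMatrix --
  # otherwise native memory accumulates across hundreds of ensemble members
  used <- xgboost::xgb.slice.Booster(model, 1, best_iter + 1L)
  used <- xgboost::xgb.load.raw(xgboost::xgb.save.raw(used))
  rm(model, dtrain, evals)
  gc(verbose = FALSE)
  list(model = used, best_iter = best_iter, n_trees = n_trees)
}

# per-gene total split gain of the trees actually used for prediction
# (rounds 0..best_iter); genes never split on get 0
model_gain <- function(fit, gene_order) {
  dt <- xgboost::xgb.model.dt.tree(model = fit$model)
  dt <- dt[dt$Feature != "Leaf" & dt$Tree <= fit$best_iter, , drop = FALSE]
  gains <- stats::setNames(rep(0, length(gene_order)), gene_order)
  if (nrow(dt) > 0) {
    tot <- tapply(dt$Gain, dt$Feature, sum)
    gains[names(tot)] <- as.numeric(tot)
  }
  gains
}

#' Train a repeated cross-validation ensemble of boosted-tree models
#'
#' Fits one stochastic gradient-boosted regression model per (repetition,
#' fold) of the plan: the model is trained on the ~90% of samples outside the
#' fold, with early stopping monitored on the held-out fold. Per-model
#' validation RMSE and Pearson correlation (on the original purity scale) and
#' per-model normalized split-gain importance scores are recorded. Folds
#' whose training partition has a constant target are skipped with a warning,
#' reducing the model count.
#'
#' @param x an [expr_matrix()], `scale = "log2"`.
#' @param p a [purity_vector()] on the logit scale, aligned with `x`.
#' @param config a [gbm_config()].
#' @param plan a [build_cv_plan()] over the sample IDs of `x`.
#' @param monitor early-stopping monitor: the held-out `"validation"` fold
#'   (default) or the `"training"` partition.
#' @return A list of class `purity_ensemble`: `models`, `plan`, `config`,
#'   `gene_symbols`, `importance` (genes x M normalized score matrix),
#'   `val_metrics` (tibble: model, repetition, fold, n_trees, best_iter,
#'   val_rmse, val_pearson), `skipped`, `target_scale = "logit"`.
#' @export
train_ensemble <- function(x, p, config = gbm_config(), plan,
                           monitor = c("validation", "training")) {
  monitor <- match.arg(monitor)
  stopifnot(inherits(x, "expr_matrix"), inherits(plan, "cv_plan"))
  if (x$scale != "log2") stop("expression must be on the log2 scale", call. = FALSE)
  if (purity_scale(p) != "logit") {
    stop("target purity must be on the logit scale; see logit_transform()", call. = FALSE)
  }
  p <- align_purity(x, p)
  if (!setequal(plan$sample_ids, sample_ids(x))) {
    stop("plan sample IDs do not match the expression matrix", call. = FALSE)
  }
  if (any(!is.finite(p$purity))) stop("non-finite target values", call. = FALSE)
  y <- stats::setNames(p$purity, p$sample_id)[sample_ids(x)]
  xm <- x$values
  genes <- colnames(xm)

  models <- list()
  gain_cols <- list()
  rows <- list()
  skipped <- tibble::tibble(repetition = integer(), fold = integer(), reason = character())
  k <- 0L
  for (r in seq_len(plan$n_repetitions)) {
    fold_of <- plan$fold_assignment[r, sample_ids(x)]
    for (f in seq_len(plan$n_folds)) {
      tr <- fold_of != f
      if (stats::sd(y[tr]) == 0) {
        warning(sprintf("repetition %d fold %d: constant training target; model skipped", r, f))
        skipped <- dplyr::add_row(skipped, repetition = r, fold = f,
                                  reason = "constant training target")
        next
      }
      fit <- fit_one_model(xm[tr, , drop = FALSE], y[tr],
                           xm[!tr, , drop = FALSE], y[!tr],
                           config, plan$model_seeds[r, f], monitor = monitor)
      k <- k + 1L
      pred_va <- inv_logit_num(stats::predict(fit$model, xm[!tr, , drop = FALSE]))
      obs_va <- inv_logit_num(y[!tr])
      models[[k]] <- fit$model
      gain_cols[[k]] <- model_gain(fit, genes)
      rows[[k]] <- tibble::tibble(
        model = k, repetition = r, fold = f,
        n_train = sum(tr), n_valid = sum(!tr),
        n_trees = fit$n_trees, best_iter = fit$best_iter,
        val_rmse = rmse(obs_va, pred_va),
        val_pearson = stats::cor(obs_va, pred_va))
    }
  }
  if (k == 0L) stop("no model could be trained (all folds degenerate)", call. = FALSE)
  gain <- do.call(cbind, gain_cols)
  importance <- apply(gain, 2, model_importance)
  rownames(importance) <- genes

  structure(
    list(models = models, plan = plan, config = config,
         gene_symbols = genes, importance = importance,
         val_metrics = dplyr::bind_rows(rows), skipped = skipped,
         monitor = monitor, target_scale = "logit"),
    class = "purity_ensemble"
  )
}

#' @export
print.purity_ensemble <- function(x, ...) {
  cat(sprintf("<purity_ensemble> %d models (%d reps x %d folds), %d genes\n",
              length(x$models), x$plan$n_repetitions, x$plan$n_folds,
              length(x$gene_symbols)))
  cat(sprintf("  mean validation RMSE %.4f, Pearson %.4f\n",
              mean(x$val_metrics$val_rmse), mean(x$val_metrics$val_pearson)))
  invisible(x)
}

#' Bagged purity prediction
#'
#' Every model of the ensemble predicts on the logit scale; each per-model
#' prediction is mapped through the inverse logit into `(0, 1)` and the final
#' prediction is the per-sample arithmetic mean of the M original-scale
#' values (set `avg_scale = "logit"` to average before back-transforming
#' instead). Either way the final values stay strictly inside `(0, 1)`.
#'
#' @param object a `purity_ensemble`.
#' @param newdata an [expr_matrix()] (`scale = "log2"`) containing at least
#'   all training genes; extra genes are ignored.
#' @param avg_scale `"original"` (default) or `"logit"`.
#' @param ... unused.
#' @return A `purity_prediction` tibble with columns `sample_id`,
#'   `purity_pred`; the M x n per-model original-scale prediction matrix is
#'   in `attr(., "per_model")`.
#' @export
predict.purity_ensemble <- function(object, newdata,
                                    avg_scale = c("original", "logit"), ...) {
  avg_scale <- match.arg(avg_scale)
  stopifnot(inherits(newdata, "expr_matrix"))
  if (newdata$scale != "log2") stop("expression must be on the log2 scale", call. = FALSE)
  absent <- setdiff(object$gene_symbols, gene_symbols(newdata))
  if (length(absent) > 0) {
    stop("genes missing from prediction input: ",
         paste(utils::head(absent, 10), collapse = ", "),
         if (length(absent) > 10) sprintf(" (+%d more)", length(absent) - 10) else "",
         call. = FALSE)
  }
  xm <- newdata$values[, object$gene_symbols, drop = FALSE]
  logit_mat <- do.call(rbind, lapply(object$models, function(m) stats::predict(m, xm)))
  per_model <- inv_logit_num(logit_mat)
  final <- if (avg_scale == "original") {
    colMeans(per_model)
  } else {
    inv_logit_num(colMeans(logit_mat))
  }
  out <- tibble::tibble(sample_id = rownames(xm), purity_pred = unname(final))
  class(out) <- c("purity_prediction", class(out))
  attr(out, "per_model") <- per_model
  attr(out, "avg_scale") <- avg_scale
  out
}

#' Cross-validation tuning of boosting parameters
#'
#' Evaluates every configuration of the grid with a single k-fold
#' cross-validation on the training data (folds shared across
#' configurations), scoring by mean validation RMSE on the original purity
#' scale after the inverse-logit back-transform. Ties are broken toward the
#' smaller `learning_rate * max_trees` product, then the smaller
#' `max_depth`, then grid order.
#'
#' @param x an [expr_matrix()], `scale = "log2"`.
#' @param p a [purity_vector()] on the logit scale.
#' @param grid nonempty list of [gbm_config()] objects.
#' @param n_folds folds for tuning (default 10).
#' @param seed integer seed (fold shuffle + learner seeds).
#' @param monitor early-stopping monitor, as in [train_ensemble()].
#' @return A list of class `grid_search`: `best_config`, `best_id`, and
#'   `summaries` (one row per configuration with mean CV RMSE/Pearson).
#' @export
grid_search <- function(x, p, grid = default_grid(), n_folds = 10, seed = 1,
                        monitor = c("validation", "training")) {
  monitor <- match.arg(monitor)
  if (length(grid) == 0) stop("`grid` must be nonempty", call. = FALSE)
  stopifnot(inherits(x, "expr_matrix"))
  if (purity_scale(p) != "logit") {
    stop("target purity must be on the logit scale", call. = FALSE)
  }
  p <- align_purity(x, p)
  y <- stats::setNames(p$purity, p$sample_id)[sample_ids(x)]
  plan <- build_cv_plan(sample_ids(x), n_repetitions = 1, n_folds = n_folds,
                        master_seed = seed)
  fold_of <- plan$fold_assignment[1, sample_ids(x)]
  xm <- x$values

  summaries <- purrr::imap(grid, function(cfg, i) {
    fold_rmse <- numeric(n_folds)
    fold_r <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold_of != f
      fit <- tryCatch(
        fit_one_model(xm[tr, , drop = FALSE], y[tr],
                      xm[!tr, , drop = FALSE], y[!tr],
                      cfg, plan$model_seeds[1, f], monitor = monitor),
        error = function(e) stop(sprintf("config %d (lr %.3g, depth %d) failed: %s",
                                         i, cfg$learning_rate, cfg$max_depth,
                                         conditionMessage(e)), call. = FALSE))
      pred <- inv_logit_num(stats::predict(fit$model, xm[!tr, , drop = FALSE]))
      obs <- inv_logit_num(y[!tr])
      fold_rmse[f] <- rmse(obs, pred)
      fold_r[f] <- stats::cor(obs, pred)
    }
    tibble::tibble(config_id = i,
                   learning_rate = cfg$learning_rate, max_depth = cfg$max_depth,
                   min_leaf_weight = cfg$min_leaf_weight,
                   colsample_per_tree = cfg$colsample_per_tree,
                   subsample_per_tree = cfg$subsample_per_tree,
                   max_trees = cfg$max_trees,
                   mean_rmse = mean(fold_rmse), mean_pearson = mean(fold_r))
  }) |> dplyr::bind_rows()

  ranked <- summaries |>
    dplyr::arrange(.data$mean_rmse,
                   .data$learning_rate * .data$max_trees,
                   .data$max_depth,
                   .data$config_id)
  best_id <- ranked$config_id[1]
  structure(list(best_config = grid[[best_id]], best_id = best_id,
                 summaries = summaries, n_folds = n_folds,
                 seed = as.integer(seed)),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  b <- x$best_config
  cat(sprintf("<grid_search> %d configs, %d-fold CV; best: lr %.3g depth %d colsample %.2f subsample %.2f (CV RMSE %.4f)\n",
              nrow(x$summaries), x$n_folds, b$learning_rate, b$max_depth,
              b$colsample_per_tree, b$subsample_per_tree,
              x$summaries$mean_rmse[x$summaries$config_id == x$best_id]))
  invisible(x)
}

#' Retrain the pipeline on a restricted gene panel
#'
#' Subsets the expression matrix to `panel`, re-tunes the boosting parameters
#' on the panel with [grid_search()] (a small panel generally prefers
#' different settings than the genome-wide run), then trains a fresh repeated
#' cross-validation ensemble.
#'
#' @param x an [expr_matrix()], `scale = "log2"`.
#' @param p a [purity_vector()] (original or logit scale; transformed
#'   internally if needed).
#' @param panel character vector of gene symbols, all present in `x`;
#'   defaults to [purity_marker_panel].
#' @param grid tuning grid for the panel re-tune.
#' @param n_repetitions,n_folds ensemble plan dimensions.
#' @param tune_folds folds used by the panel grid search.
#' @param master_seed integer seed for tuning and the ensemble plan.
#' @return A `purity_ensemble` trained on the panel, with the panel
#'   [grid_search()] result attached as `$tuning`.
#' @export
restrict_and_retrain <- function(x, p, panel = purity_marker_panel,
                                 grid = default_grid(),
                                 n_repetitions = 100, n_folds = 10,
                                 tune_folds = n_folds, master_seed = 1) {
  stopifnot(inherits(x, "expr_matrix"))
  absent <- setdiff(panel, gene_symbols(x))
  if (length(absent) > 0) {
    stop("panel genes absent from expression matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (purity_scale(p) == "original") p <- logit_transform(p)
  xr <- expr_matrix(x$values[, panel, drop = FALSE], scale = x$scale)
  tuning <- grid_search(xr, p, grid = grid, n_folds = tune_folds,
                        seed = master_seed)
  plan <- build_cv_plan(sample_ids(xr), n_repetitions = n_repetitions,
                        n_folds = n_folds, master_seed = master_seed)
  ens <- train_ensemble(xr, p, config = tuning$best_config, plan = plan)
  ens$tuning <- tuning
  ens
}

#' Save / load a fitted ensemble
#'
#' Writes a directory holding `manifest.json` (config, plan seeds, gene
#' order, per-model validation metrics) and one serialized model file per
#' ensemble member in the learner's native JSON format.
#'
#' @param e a `purity_ensemble`.
#' @param dir target directory.
#' @return [save_ensemble()] returns `dir` invisibly; [load_ensemble()]
#'   returns the restored `purity_ensemble`.
#' @export
save_ensemble <- function(e, dir) {
  stopifnot(inherits(e, "purity_ensemble"))
  dir.create(file.path(dir, "models"), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "puriboost",
    n_models = length(e$models),
    config = unclass(e$config),
    plan = list(sample_ids = e$plan$sample_ids,
                n_repetitions = e$plan$n_repetitions,
                n_folds = e$plan$n_folds,
                master_seed = e$plan$master_seed,
                shuffle_seeds = e$plan$shuffle_seeds,
                model_seeds = as.vector(e$plan$model_seeds),
                fold_assignment = as.vector(e$plan$fold_assignment)),
    gene_symbols = e$gene_symbols,
    monitor = e$monitor,
    target_scale = e$target_scale,
    val_metrics = e$val_metrics,
    skipped = e$skipped,
    importance = list(genes = rownames(e$importance),
                      scores = as.vector(e$importance))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(e$models)) {
    xgboost::xgb.save(e$models[[i]],
                      file.path(dir, "models", sprintf("model_%04d.json", i)))
  }
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  pl <- manifest$plan
  plan <- structure(
    list(sample_ids = pl$sample_ids,
         n_repetitions = as.integer(pl$n_repetitions),
         n_folds = as.integer(pl$n_folds),
         master_seed = as.integer(pl$master_seed),
         shuffle_seeds = as.integer(pl$shuffle_seeds),
         model_seeds = matrix(as.integer(pl$model_seeds),
                              pl$n_repetitions, pl$n_folds),
         fold_assignment = matrix(as.integer(pl$fold_assignment),
                                  pl$n_repetitions, length(pl$sample_ids),
                                  dimnames = list(NULL, pl$sample_ids))),
    class = "cv_plan")
  cfg <- do.call(gbm_config, manifest$config[setdiff(names(manifest$config), "loss")])
  models <- lapply(seq_len(manifest$n_models), function(i) {
    xgboost::xgb.load(file.path(dir, "models", sprintf("model_%04d.json", i)))
  })
  importance <- matrix(manifest$importance$scores,
                       nrow = length(manifest$importance$genes),
                       dimnames = list(manifest$importance$genes, NULL))
  structure(
    list(models = models, plan = plan, config = cfg,
         gene_symbols = manifest$gene_symbols,
         importance = importance,
         val_metrics = tibble::as_tibble(manifest$val_metrics),
         skipped = tibble::as_tibble(manifest$skipped),
         monitor = manifest$monitor,
         target_scale = manifest$target_scale),
    class = "purity_ensemble"
  )
}
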
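test_that("build_cv_plan makes balanced contiguous-block folds, one validation slot per sample", {
  plan <- build_cv_plan(sprintf("s%02d", 1:10), n_repetitions = 3, n_folds = 10,
                        master_seed = 1)
  expect_equal(dim(plan$fold_assignment), c(3L, 10L))
  for (r in 1:3) expect_setequal(plan$fold_assignment[r, ], 1:10)

  plan23 <- build_cv_plan(sprintf("s%02d", 1:23), n_repetitions = 2,
                          n_folds = 10, master_seed = 1)
  sizes <- table(plan23$fold_assignment[1, ])
  expect_equal(sort(as.integer(sizes)), c(2, 2, 2, 2, 2, 2, 2, 3, 3, 3))
  # every sample in exactly one fold per repetition
  expect_false(anyNA(plan23$fold_assignment))
  # repetitions use different permutations
  expect_false(identical(plan23$fold_assignment[1, ], plan23$fold_assignment[2, ]))
  # reproducible given the master seed
  again <- build_cv_plan(sprintf("s%02d", 1:23), n_repetitions = 2,
                         n_folds = 10, master_seed = 1)
  expect_identical(plan23, again)

  expect_error(build_cv_plan(c("a", "b"), 1, n_folds = 1), ">= 2")
  expect_error(build_cv_plan(c("a", "b"), 1, n_folds = 3), "cannot exceed")
})

test_that("train_ensemble fits one model per (repetition, fold) and records metrics", {
  run <- small_run()
  expect_length(run$ens$models, 6)  # 2 reps x 3 folds
  expect_equal(nrow(tidy(run$ens)), 6)
  expect_true(all(tidy(run$ens)$n_trees <= 100))
  expect_equal(ncol(run$ens$importance), 6)
  expect_equal(glance(run$ens)$n_models, 6)

  # per-model validation RMSE matches an independent recomputation
  for (k in c(1, 4)) {
    row <- tidy(run$ens)[k, ]
    fold_of <- run$plan$fold_assignment[row$repetition, sample_ids(run$xtr)]
    va <- fold_of == row$fold
    yv <- puriboost:::inv_logit_num(
      puriboost:::logit_num(run$ptr$purity[match(sample_ids(run$xtr)[va],
                                                 run$ptr$sample_id)]))
    pv <- puriboost:::inv_logit_num(
      predict(run$ens$models[[k]], run$xtr$values[va, , drop = FALSE]))
    expect_equal(row$val_rmse, sqrt(mean((yv - pv)^2)), tolerance = 1e-10)
  }
})

test_that("noise-free planted signal is learned nearly perfectly", {
  sim <- simulate_bulk(n_samples = 150, n_genes = 80, n_markers = 8,
                       effect_size = 4, noise_sd = 0, type_shift_sd = 0,
                       n_types = 1, seed = 13)
  plan <- build_cv_plan(sample_ids(sim$expression), n_repetitions = 1,
                        n_folds = 3, master_seed = 13)
  ens <- train_ensemble(sim$expression, logit_transform(sim$purity),
                        config = gbm_config(max_trees = 400), plan = plan)
  expect_gte(mean(tidy(ens)$val_pearson), 0.99)
})

test_that("degenerate folds are skipped; fully constant targets abort", {
  sim <- simulate_bulk(n_samples = 30, n_genes = 20, n_markers = 2, seed = 1)
  const <- purity_vector(sim$purity$sample_id, rep(0, 30))
  plan <- build_cv_plan(sim$purity$sample_id, 1, 3, master_seed = 1)
  expect_error(
    suppressWarnings(train_ensemble(sim$expression, logit_transform(const),
                                    config = gbm_config(max_trees = 10),
                                    plan = plan)),
    "all folds degenerate")
})

test_that("bagged prediction averages per-model inverse-logit values on the chosen scale", {
  run <- small_run()
  pm <- attr(run$pred, "per_model")
  expect_equal(dim(pm), c(6L, nrow(run$pred)))
  expect_true(all(pm > 0 & pm < 1))
  expect_equal(unname(colMeans(pm)), run$pred$purity_pred, tolerance = 1e-12)
  expect_true(all(run$pred$purity_pred > 0 & run$pred$purity_pred < 1))

  # averaging {0.2, 0.4} on the original scale gives 0.3
  expect_equal(mean(c(0.2, 0.4)), 0.3)

  # logit-scale averaging differs but stays in (0,1)
  pl <- predict(run$ens, run$xte, avg_scale = "logit")
  expect_true(all(pl$purity_pred > 0 & pl$purity_pred < 1))
  expect_false(identical(pl$purity_pred, run$pred$purity_pred))

  # missing genes are a hard error naming symbols
  xbad <- expr_matrix(run$xte$values[, -(1:3)], "log2")
  expect_error(predict(run$ens, xbad), "missing from prediction input")
})

test_that("early stopping never exceeds max_trees and halts after patience stalls", {
  run <- small_run()
  tt <- tidy(run$ens)
  expect_true(all(tt$n_trees <= 100))
  # when stopping triggered before the cap, the overshoot equals the patience
  stopped <- tt[tt$n_trees < 100, ]
  if (nrow(stopped) > 0) {
    expect_true(all(stopped$n_trees - (stopped$best_iter + 1) ==
                      run$ens$config$early_stop_patience))
  }
})

test_that("the full pipeline is bitwise reproducible under a fixed master seed", {
  sim <- simulate_bulk(n_samples = 60, n_genes = 50, n_markers = 5, seed = 3)
  fit_once <- function() {
    plan <- build_cv_plan(sample_ids(sim$expression), 2, 3, master_seed = 11)
    ens <- train_ensemble(sim$expression, logit_transform(sim$purity),
                          config = gbm_config(max_trees = 50), plan = plan)
    predict(ens, sim$expression)$purity_pred
  }
  expect_identical(fit_once(), fit_once())
})

test_that("grid_search picks the config with the lowest recomputed CV RMSE, deterministically", {
  sim <- simulate_bulk(n_samples = 90, n_genes = 60, n_markers = 6,
                       effect_size = 2, noise_sd = 0.5, seed = 17)
  p <- logit_transform(sim$purity)
  grid <- list(gbm_config(max_depth = 2, max_trees = 60),
               gbm_config(max_depth = 4, max_trees = 60))
  gs <- grid_search(sim$expression, p, grid = grid, n_folds = 3, seed = 5)
  expect_equal(gs$best_id, gs$summaries$config_id[which.min(gs$summaries$mean_rmse)])
  expect_equal(gs$best_config$max_depth, grid[[gs$best_id]]$max_depth)

  gs2 <- grid_search(sim$expression, p, grid = grid, n_folds = 3, seed = 5)
  expect_identical(gs$summaries, gs2$summaries)
  expect_identical(gs$best_id, gs2$best_id)

  one <- grid_search(sim$expression, p, grid = grid[1], n_folds = 3, seed = 5)
  expect_equal(one$best_id, 1L)
  expect_error(grid_search(sim$expression, p, grid = list(), n_folds = 3),
               "nonempty")
})

test_that("restrict_and_retrain re-tunes on the panel and rejects unknown genes", {
  sim <- simulate_bulk(n_samples = 100, n_genes = 80, n_markers = 10,
                       effect_size = 3, noise_sd = 0.4, seed = 23)
  grid <- list(gbm_config(max_trees = 60),
               gbm_config(max_depth = 2, max_trees = 60))
  ens <- restrict_and_retrain(sim$expression, sim$purity,
                              panel = sim$truth$marker_genes,
                              grid = grid, n_repetitions = 2, n_folds = 3,
                              tune_folds = 3, master_seed = 9)
  expect_equal(ens$gene_symbols, sim$truth$marker_genes)
  expect_s3_class(ens$tuning, "grid_search")
  expect_length(ens$models, 6)

  expect_error(restrict_and_retrain(sim$expression, sim$purity,
                                    panel = c("NOPE1", sim$truth$marker_genes),
                                    grid = grid, n_repetitions = 1, n_folds = 2),
               "absent.*NOPE1")
})

test_that("ensembles survive a save/load round trip with identical predictions", {
  run <- small_run()
  dir <- withr::local_tempdir()
  save_ensemble(run$ens, dir)
  back <- load_ensemble(dir)
  expect_equal(back$gene_symbols, run$ens$gene_symbols)
  expect_equal(back$val_metrics$val_rmse, tidy(run$ens)$val_rmse)
  expect_equal(predict(back, run$xte)$purity_pred, run$pred$purity_pred,
               tolerance = 1e-12)
})

test_that("the shipped marker panel is the documented ten-gene set", {
  expect_length(purity_marker_panel, 10)
  expect_true(all(c("CSF2RB", "IL7R", "CCL21") %in% purity_marker_panel))
})
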
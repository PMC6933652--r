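# Shared fixtures, built in code. The small trained run is memoized so the
# ensemble / importance / evaluation tests reuse one fit.

tiny_expr <- function(values, samples = NULL, genes = NULL,
                      scale = "log2") {
  m <- as.matrix(values)
  rownames(m) <- samples %||% sprintf("s%d", seq_len(nrow(m)))
  colnames(m) <- genes %||% sprintf("g%d", seq_len(ncol(m)))
  expr_matrix(m, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tiny_expression_tsv <- function(path, genes_by_samples = TRUE) {
  # 3 genes x 2 samples
  lines <- c("gene\ts1\ts2",
             "ACTB\t1\t2",
             "CD3E\t5\t0.5",
             "GZMB\t8\t16")
  if (!genes_by_samples) {
    lines <- c("sample_id\tACTB\tCD3E\tGZMB",
               "s1\t1\t5\t8",
               "s2\t2\t0.5\t16")
  }
  writeLines(lines, path)
  path
}

.fixture_env <- new.env(parent = emptyenv())

# one small but non-trivial trained pipeline shared across test files:
# 120 samples x 300 genes, 10 markers, 2 reps x 3 folds
small_run <- function() {
  if (!is.null(.fixture_env$run)) return(.fixture_env$run)
  sim <- simulate_bulk(n_samples = 120, n_genes = 300, n_markers = 10,
                       effect_size = 2, noise_sd = 0.5, n_types = 3, seed = 42)
  sp <- split_train_test(sim$expression, sim$purity, 2 / 3, seed = 42)
  xtr <- expr_matrix(sim$expression$values[sp$train_ids, , drop = FALSE], "log2")
  xte <- expr_matrix(sim$expression$values[sp$test_ids, , drop = FALSE], "log2")
  ptr <- purity_vector(sp$train_ids,
                       sim$purity$purity[match(sp$train_ids, sim$purity$sample_id)])
  pte <- purity_vector(sp$test_ids,
                       sim$purity$purity[match(sp$test_ids, sim$purity$sample_id)])
  plan <- build_cv_plan(sp$train_ids, n_repetitions = 2, n_folds = 3,
                        master_seed = 7)
  ens <- train_ensemble(xtr, logit_transform(ptr),
                        config = gbm_config(max_trees = 100), plan = plan)
  pred <- predict(ens, xte)
  .fixture_env$run <- list(sim = sim, split = sp, xtr = xtr, xte = xte,
                           ptr = ptr, pte = pte, plan = plan, ens = ens,
                           pred = pred)
  .fixture_env$run
}
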
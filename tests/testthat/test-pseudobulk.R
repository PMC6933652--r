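test_that("aggregate_to_bulk sums counts per sample and conserves totals", {
  counts <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                   dimnames = list(c("c1", "c2", "c3"), c("gA", "gB")))
  cc <- cell_counts(counts, c(c1 = "S", c2 = "S", c3 = "S"))
  bulk <- aggregate_to_bulk(cc)
  expect_equal(unname(bulk$values["S", ]), c(6, 15))
  expect_equal(bulk$scale, "raw")

  # single cell per sample: identity rows
  cc1 <- cell_counts(counts, c(c1 = "A", c2 = "B", c3 = "C"))
  b1 <- aggregate_to_bulk(cc1)
  expect_equal(unname(b1$values["B", ]), unname(counts["c2", ]))

  # random matrix vs a brute-force double loop
  restore <- puriboost:::local_seed(71)
  m <- matrix(rpois(50 * 20, 3), 50, 20,
              dimnames = list(sprintf("c%02d", 1:50), sprintf("g%02d", 1:20)))
  smap <- stats::setNames(sample(c("P1", "P2", "P3"), 50, replace = TRUE),
                          rownames(m))
  restore()
  bulk_r <- aggregate_to_bulk(cell_counts(m, smap))
  brute <- matrix(0, 3, 20, dimnames = list(c("P1", "P2", "P3"), colnames(m)))
  for (cell in rownames(m)) for (g in colnames(m)) {
    brute[smap[[cell]], g] <- brute[smap[[cell]], g] + m[cell, g]
  }
  expect_equal(bulk_r$values[rownames(brute), ], brute)
  expect_equal(sum(bulk_r$values), sum(m))
})

test_that("merge_common_genes intersects genes and stacks samples", {
  a <- tiny_expr(matrix(1:6, 2, 3), samples = c("a1", "a2"),
                 genes = c("A", "B", "C"), scale = "raw")
  b <- tiny_expr(matrix(1:6, 2, 3), samples = c("b1", "b2"),
                 genes = c("B", "C", "D"), scale = "raw")
  m <- merge_common_genes(a, b)
  expect_equal(gene_symbols(m), c("B", "C"))
  expect_equal(sample_ids(m), c("a1", "a2", "b1", "b2"))
  expect_equal(attr(m, "dropped"), c(a = 1L, b = 1L))

  same <- merge_common_genes(a, tiny_expr(matrix(1:6, 2, 3),
                                          samples = c("x1", "x2"),
                                          genes = c("A", "B", "C"),
                                          scale = "raw"))
  expect_equal(attr(same, "dropped"), c(a = 0L, b = 0L))

  d <- tiny_expr(matrix(1:4, 2, 2), samples = c("d1", "d2"),
                 genes = c("X", "Y"), scale = "raw")
  expect_error(merge_common_genes(a, d), "no genes in common")
  expect_error(merge_common_genes(a, log2_floor_transform(b)), "raw count scale")
})

test_that("median centering brings every sample median to the reference median-of-medians", {
  # two samples with medians 2 and 8; reference = both -> c = 5
  m <- rbind(s1 = c(1, 2, 4), s2 = c(4, 8, 16))
  colnames(m) <- c("g1", "g2", "g3")
  x <- expr_matrix(m, "raw")
  norm <- median_center_normalize(x, reference_ids = c("s1", "s2"))
  # invert the log2(v + 1) to inspect the centered counts
  centered <- 2^norm$values - 1
  expect_equal(unname(apply(centered, 1, stats::median)), c(5, 5),
               tolerance = 1e-12)
  expect_equal(norm$scale, "log2")

  # one-sample reference: c is that sample's median (s1 unchanged)
  n1 <- median_center_normalize(x, reference_ids = "s1")
  expect_equal(unname(2^n1$values["s1", ] - 1), unname(m["s1", ]),
               tolerance = 1e-12)

  # monotone within each sample under either variant
  for (meth in c("multiplicative", "additive_log")) {
    nm <- median_center_normalize(x, reference_ids = "s1", method = meth)
    for (s in rownames(m)) {
      expect_equal(order(nm$values[s, ]), order(m[s, ]))
    }
  }

  zm <- matrix(c(0, 1, 0, 2, 1, 3), 2, 3,
               dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
  z <- expr_matrix(zm, "raw")
  expect_error(median_center_normalize(z, "s2"), "zero median.*s1")
})

test_that("pseudo-bulk samples built from cells are predicted by a bulk-trained ensemble", {
  prof <- make_cell_profiles(n_genes = 400, n_markers = 20, marker_ratio = 4,
                             seed = 19)
  restore <- puriboost:::local_seed(19)
  ref_purity <- stats::setNames(pmin(pmax(stats::rbeta(120, 2, 2), 0.02), 0.98),
                                sprintf("REF%03d", 1:120))
  test_purity <- stats::setNames(seq(0.1, 0.9, length.out = 12),
                                 sprintf("PB%03d", 1:12))
  restore()
  ref_bulk <- simulate_bulk_counts(ref_purity, prof, depth = 2000, seed = 20)
  cells <- simulate_cells(12, 2000, test_purity, prof, seed = 21)
  pb <- aggregate_to_bulk(cells)

  merged <- merge_common_genes(ref_bulk, pb)
  norm <- median_center_normalize(merged, reference_ids = names(ref_purity))
  xref <- expr_matrix(norm$values[names(ref_purity), ], "log2")
  xpb <- expr_matrix(norm$values[names(test_purity), ], "log2")

  plan <- build_cv_plan(names(ref_purity), 2, 5, master_seed = 22)
  ens <- train_ensemble(xref, logit_transform(purity_vector(names(ref_purity),
                                                            ref_purity)),
                        config = gbm_config(max_trees = 150), plan = plan)
  pred <- predict(ens, xpb)
  truth <- cells$true_purity[pred$sample_id]
  expect_gte(stats::cor(pred$purity_pred, truth), 0.8)
})
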
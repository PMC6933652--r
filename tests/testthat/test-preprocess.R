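test_that("load_expression returns samples x genes on the raw scale for both orientations", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_expression_tsv(f1, genes_by_samples = TRUE)
  x1 <- load_expression(f1, orientation = "genes_by_samples")
  expect_s3_class(x1, "expr_matrix")
  expect_equal(dim(x1), c(2L, 3L))
  expect_equal(x1$scale, "raw")
  expect_equal(sample_ids(x1), c("s1", "s2"))
  expect_equal(gene_symbols(x1), c("ACTB", "CD3E", "GZMB"))
  expect_equal(x1$values["s2", "CD3E"], 0.5)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_expression_tsv(f2, genes_by_samples = FALSE)
  x2 <- load_expression(f2, orientation = "samples_by_genes")
  expect_equal(x2$values, x1$values)
})

test_that("load_expression enforces the duplicate-gene policy and reports bad cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "ACTB\t1\t2", "ACTB\t3\t4"), f)
  expect_error(load_expression(f), "duplicate gene symbols.*ACTB")
  x <- load_expression(f, collapse_dup_genes = "mean")
  expect_equal(unname(x$values[, "ACTB"]), c(2, 3))

  fb <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "ACTB\t1\toops"), fb)
  expect_error(load_expression(fb), "non-numeric.*s2")

  fna <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "ACTB\t1\tNA", "CD8A\t2\t3"), fna)
  xna <- load_expression(fna)
  expect_true(is.na(xna$values["s2", "ACTB"]))
})

test_that("log2_floor_transform floors at 1, maps exactly, and refuses double transforms", {
  x <- tiny_expr(rbind(c(0.5, 8, 1), c(0, 2, 1024)), scale = "raw")
  lx <- log2_floor_transform(x)
  expect_equal(lx$scale, "log2")
  expect_equal(unname(lx$values[1, ]), c(0, 3, 0))
  expect_equal(unname(lx$values[2, ]), c(0, 1, 10))
  expect_error(log2_floor_transform(lx), "already on the log2 scale")
  neg <- tiny_expr(rbind(c(-1, 2), c(1, 2)), scale = "raw")
  expect_error(log2_floor_transform(neg), ">= 0")
})

test_that("filter_genes keeps exactly the complete, variable genes", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(1, NA, 3),
             d = c(0, 1, 0), e = c(2, 2, NA), f = c(9, 8, 7),
             g = c(4, 4, 4))
  rownames(m) <- c("s1", "s2", "s3")
  x <- expr_matrix(m, "raw")
  fx <- filter_genes(x)
  expect_equal(gene_symbols(fx), c("a", "d", "f"))
  expect_setequal(attr(fx, "removed_genes"), c("b", "c", "e", "g"))
  expect_false(anyNA(fx$values))
  expect_true(all(apply(fx$values, 2, stats::var) > 0))

  # a gene constant except for one missing entry is removed either way
  m2 <- cbind(h = c(1, 1, NA), a = c(1, 2, 3))
  rownames(m2) <- rownames(m)
  expect_equal(gene_symbols(filter_genes(expr_matrix(m2, "raw"))), "a")

  # identity on clean input
  clean <- filter_genes(expr_matrix(m[, c("a", "f")], "raw"))
  expect_equal(clean$values, m[, c("a", "f")])
  expect_length(attr(clean, "removed_genes"), 0)

  expect_error(filter_genes(expr_matrix(m[, "b", drop = FALSE], "raw")),
               "no genes left")
})

test_that("dedupe_samples keeps the lexicographically smallest sample per patient", {
  m <- matrix(1:8, 4, 2, dimnames = list(c("s4", "s1", "s2", "s3"), c("a", "b")))
  x <- expr_matrix(m, "raw")
  d <- dedupe_samples(x, c(s1 = "P1", s2 = "P1", s3 = "P2", s4 = "P1"))
  expect_setequal(sample_ids(d), c("s1", "s3"))
  expect_setequal(attr(d, "removed_samples"), c("s2", "s4"))

  # all-distinct patients: identity
  d2 <- dedupe_samples(x, c(s1 = "P1", s2 = "P2", s3 = "P3", s4 = "P4"))
  expect_equal(d2$values, x$values)

  expect_error(dedupe_samples(x, c(s1 = "P1")), "without a patient assignment")
})

test_that("logit transform applies boundary reassignment and round-trips", {
  p <- purity_vector(c("a", "b", "c", "d"), c(0.5, 1, 0.9975, 0))
  lp <- logit_transform(p)
  expect_equal(lp$purity[1], 0)
  expect_equal(lp$purity[2], log(0.9975 / 0.0025))
  expect_equal(lp$purity[2], lp$purity[3])  # 1.00 and 0.9975 collide
  expect_equal(lp$purity[4], -log(0.9975 / 0.0025))  # symmetric at 0
  expect_equal(lp$purity[2], 5.98896, tolerance = 1e-5)

  back <- inverse_logit(lp)
  expect_equal(attr(back, "scale"), "original")
  expect_equal(back$purity, c(0.5, 0.9975, 0.9975, 0.0025), tolerance = 1e-12)

  # round trip over a dense grid of the admissible range
  g <- seq(0.0025, 0.9975, length.out = 10000)
  pg <- purity_vector(sprintf("x%05d", seq_along(g)), g)
  expect_equal(inverse_logit(logit_transform(pg))$purity, g, tolerance = 1e-12)

  expect_error(purity_vector("a", 1.2), "\\[0, 1\\]")
  expect_error(logit_transform(lp), "already on the logit scale")
  expect_error(inverse_logit(p), "not on the logit scale")
  # no overflow to exactly 1 for large logits
  expect_lt(inverse_logit(purity_vector("a", 20, scale = "logit"))$purity, 1)
})

test_that("split_train_test partitions deterministically at round(fraction * n)", {
  sim <- simulate_bulk(n_samples = 9, n_genes = 20, n_markers = 2, seed = 3)
  sp <- split_train_test(sim$expression, sim$purity, 2 / 3, seed = 5)
  expect_length(sp$train_ids, 6)
  expect_length(sp$test_ids, 3)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), sample_ids(sim$expression))

  sp2 <- split_train_test(sim$expression, sim$purity, 2 / 3, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- split_train_test(sim$expression, sim$purity, 2 / 3, seed = 6)
  expect_false(identical(sp$train_ids, sp3$train_ids))

  # round(fraction * n) sizing at the pan-cancer scale
  expect_equal(round(2 / 3 * 9318), 6212)
  expect_error(split_train_test(sim$expression, sim$purity, 1.2, seed = 1),
               "\\(0, 1\\)")
})
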
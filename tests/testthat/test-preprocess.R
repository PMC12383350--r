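test_that("cell filter boundary: 499 expressed genes removed, 500 retained", {
  d <- 600
  m <- rbind(c(rep(1, 499), rep(0, d - 499)),
             c(rep(1, 500), rep(0, d - 500)),
             rep(1, d), rep(1, d), rep(1, d), rep(1, d))
  ds <- expression_dataset(m, rep("A", 6), rep("control", 6))
  out <- filter_cells_genes(ds, min_genes_per_cell = 500, min_cells_per_gene = 1)
  expect_false("cell_1" %in% rownames(out$matrix))
  expect_true("cell_2" %in% rownames(out$matrix))
})

test_that("gene filter boundary: expressed in 4 cells removed, 5 retained", {
  m <- matrix(1, 10, 30)
  m[5:10, 1] <- 0   # gene 1 in 4 cells
  m[6:10, 2] <- 0   # gene 2 in 5 cells
  ds <- expression_dataset(m, rep("A", 10), rep("control", 10))
  out <- filter_cells_genes(ds, min_genes_per_cell = 1, min_cells_per_gene = 5)
  expect_false("gene_1" %in% colnames(out$matrix))
  expect_true("gene_2" %in% colnames(out$matrix))
})

test_that("filter is a fixed point on clean data (idempotent)", {
  ds <- tiny_dataset()
  ds$matrix[ds$matrix == 0] <- 1
  f1 <- filter_cells_genes(ds, 3, 2)
  f2 <- filter_cells_genes(f1, 3, 2)
  expect_identical(f1$matrix, f2$matrix)
  expect_error(filter_cells_genes(ds, 10000, 1), "all cells")
})

test_that("normalize_log matches hand-computed values and is library-size invariant", {
  m <- rbind(c(1, 1, 2), c(2, 2, 4))
  ds <- expression_dataset(m, c("A", "A"), c("control", "control"))
  out <- normalize_log(ds, target_sum = 4)
  expect_equal(out$matrix[1, ], c(gene_1 = log(2), gene_2 = log(2), gene_3 = log(3)),
               tolerance = 1e-12)
  # [1,1,2] scaled to total 4 stays [1,1,2]: log1p = 0.6931, 0.6931, 1.0986
  expect_equal(unname(out$matrix[1, ]), c(0.6931472, 0.6931472, 1.0986123),
               tolerance = 1e-6)
  # a doubled cell gives identical output
  expect_equal(out$matrix[2, ], out$matrix[1, ], ignore_attr = TRUE)
  expect_identical(out$layer_tag, "normalized_log")
})

test_that("normalize_log keeps zero genes at zero, inverts to target_sum, rejects empty cells", {
  ds <- tiny_dataset()
  ds$matrix[, 2] <- 0
  out <- normalize_log(ds, 1e4)
  expect_true(all(out$matrix[, 2] == 0))
  expect_equal(rowSums(expm1(out$matrix)), rep(1e4, n_cells(ds)),
               ignore_attr = TRUE, tolerance = 1e-8)
  ds$matrix[3, ] <- 0
  expect_error(normalize_log(ds), rownames(ds$matrix)[3])
})

test_that("select_hvg ranks by dispersion, verified against a direct recomputation", {
  set.seed(11)
  n <- 40; d <- 10
  m <- matrix(rpois(n * d, lambda = rep(c(2, 8), length.out = d)), n, d, byrow = FALSE)
  m[, 3] <- m[, 3] * 5 # inflate variability of gene 3
  ds <- normalize_log(expression_dataset(m + 1, rep("A", n), rep("control", n)))
  # independent recomputation of the binned-dispersion score
  x <- expm1(ds$matrix)
  mu <- colMeans(x)
  v <- apply(x, 2, var)
  disp <- v / mu
  brk <- unique(quantile(mu, probs = seq(0, 1, length.out = 21)))
  bin <- cut(mu, brk, include.lowest = TRUE)
  z <- disp
  for (b in levels(bin)) {
    i <- which(bin == b)
    s <- sd(disp[i]); if (!is.finite(s) || s == 0) s <- 1
    z[i] <- (disp[i] - mean(disp[i])) / s
  }
  want <- sort(colnames(ds$matrix)[order(z, decreasing = TRUE)[1:3]])
  got <- select_hvg(ds, 3)
  expect_identical(sort(colnames(got$matrix)), want)
  expect_equal(hvg_score(ds$matrix), z, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("select_hvg trivial cases: n_top >= d unchanged; variable gene dominates constant", {
  ds <- tiny_dataset(layer = "normalized_log")
  expect_identical(select_hvg(ds, 1000)$matrix, ds$matrix)
  m <- cbind(rep(1, 20), log1p(rpois(20, 10)))
  ds2 <- expression_dataset(m, rep("A", 20), rep("control", 20), "normalized_log")
  expect_identical(colnames(select_hvg(ds2, 1)$matrix), "gene_2")
  expect_error(select_hvg(ds2, 0), "n_top")
})

test_that("holdout_split withholds exactly the (type, stimulated) cells", {
  ds <- tiny_dataset(n_per = 5)
  sp <- holdout_split(ds, "A")
  expect_equal(n_cells(sp$train), n_cells(ds) - n_cells(sp$test_stimulated))
  expect_true(all(sp$test_stimulated$obs$cell_type == "A"))
  expect_true(all(sp$test_stimulated$obs$condition == "stimulated"))
  # defining property: train has zero (holdout, stimulated) cells
  expect_equal(sum(sp$train$obs$cell_type == "A" &
                     sp$train$obs$condition == "stimulated"), 0L)
  # disjointness by cell id
  expect_length(intersect(rownames(sp$train$matrix),
                          rownames(sp$test_stimulated$matrix)), 0)
  # holdout-type control cells stay in train by default, not under strict
  expect_true(all(rownames(sp$test_control$matrix) %in% rownames(sp$train$matrix)))
  sps <- holdout_split(ds, "A", strict = TRUE)
  expect_length(intersect(rownames(sps$train$matrix),
                          rownames(sps$test_control$matrix)), 0)
  expect_error(holdout_split(ds, "C"), "absent")
})

test_that("holdout_split errors when the type is missing from one condition", {
  ds <- tiny_dataset()
  keep <- !(ds$obs$cell_type == "B" & ds$obs$condition == "stimulated")
  expect_error(holdout_split(ds[keep, ], "B"), "stimulated")
})

test_that("subsample_train is stratified, deterministic, and exact at fraction 1", {
  ds <- tiny_dataset(n_per = 50)
  expect_identical(subsample_train(ds, 1, seed = 1)$matrix, ds$matrix)
  half <- subsample_train(ds, 0.5, seed = 1)
  tab <- table(half$obs$cell_type, half$obs$condition)
  expect_true(all(tab == 25))
  expect_identical(subsample_train(ds, 0.5, seed = 1)$matrix, half$matrix)
  expect_false(identical(subsample_train(ds, 0.5, seed = 2)$matrix, half$matrix))
  # stratum floor: a tiny stratum keeps one cell with a warning
  one <- expression_dataset(matrix(1:6, 2), c("A", "A"), rep("control", 2))
  expect_warning(out <- subsample_train(one, 0.1, seed = 1), "stratum")
  expect_equal(n_cells(out), 1L)
  multi <- tiny_dataset(n_per = 2)
  out2 <- suppressWarnings(subsample_train(multi, 0.1, seed = 1))
  expect_true(all(table(out2$obs$cell_type, out2$obs$condition) >= 1))
  expect_error(subsample_train(ds, 0), "fraction")
})
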
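test_that("similarity weights: self-match, orthogonality, and scale invariance", {
  Ztr <- rbind(c(1, 0, 0), c(0, 1, 0), c(0.6, 0.8, 0))
  # test cell equals training cell 2
  sw <- similarity_weights(c(0, 1, 0), Ztr, top_k = 1)
  expect_equal(sw$indices[1, ], 2L)
  expect_equal(sw$weights[1, ], 1)
  # aligned with the first of two orthogonal cells -> weights (1, 0)
  sw2 <- similarity_weights(c(2, 0), rbind(c(1, 0), c(0, 1)), top_k = 2)
  expect_equal(sort(sw2$weights[1, ]), c(0, 1))
  expect_equal(sw2$indices[1, which(sw2$weights[1, ] == 1)], 1L)
  # scale invariance
  a <- similarity_weights(c(0.3, 0.7, 0.1), Ztr, top_k = 2)
  b <- similarity_weights(17 * c(0.3, 0.7, 0.1), Ztr, top_k = 2)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("similarity weights are a valid convex combination with uniform fallback", {
  set.seed(41)
  Ztr <- matrix(rnorm(60), 20, 3)
  Zte <- matrix(rnorm(15), 5, 3)
  sw <- similarity_weights(Zte, Ztr, top_k = 7)
  expect_equal(dim(sw$weights), c(5, 7))
  expect_equal(rowSums(sw$weights), rep(1, 5), tolerance = 1e-12)
  expect_true(all(sw$weights >= 0))
  # all-negative similarities: anti-aligned single training cell
  swf <- similarity_weights(c(1, 0), rbind(c(-1, 0), c(-1, -0.1)), top_k = 2)
  expect_equal(swf$weights[1, ], c(0.5, 0.5))
  expect_error(similarity_weights(c(0, 0, 0), Ztr), "zero-norm")
  expect_error(similarity_weights(c(1, 0, 0), rbind(c(0, 0, 0))), "zero-norm")
})

test_that("aggregate_delta takes exact convex combinations", {
  deltas <- rbind(c(1, 0), c(0, 1), c(2, 2))
  class(deltas) <- c("delta_matrix", class(deltas))
  w <- structure(list(indices = matrix(c(1L, 2L), 1), weights = matrix(c(0.5, 0.5), 1)),
                 class = "similarity_weights")
  expect_equal(aggregate_delta(w, deltas)[1, ], c(0.5, 0.5))
  w1 <- structure(list(indices = matrix(3L), weights = matrix(1)),
                  class = "similarity_weights")
  expect_equal(aggregate_delta(w1, deltas)[1, ], c(2, 2))
  # all rows equal -> any weights give that row
  same <- deltas; same[] <- rep(c(5, -1), each = 3)
  w2 <- structure(list(indices = matrix(c(1L, 2L, 3L), 1),
                       weights = matrix(c(0.2, 0.3, 0.5), 1)),
                  class = "similarity_weights")
  expect_equal(aggregate_delta(w2, same)[1, ], c(5, -1), tolerance = 1e-12)
})

test_that("delta_pred stays in the convex hull of the selected rows", {
  set.seed(42)
  deltas <- matrix(rnorm(30), 10, 3)
  sw <- similarity_weights(matrix(rnorm(9), 3), matrix(rnorm(30), 10, 3), top_k = 4)
  agg <- aggregate_delta(sw, deltas)
  for (i in 1:3) {
    sel <- deltas[sw$indices[i, ], ]
    expect_true(all(agg[i, ] <= apply(sel, 2, max) + 1e-12))
    expect_true(all(agg[i, ] >= apply(sel, 2, min) - 1e-12))
  }
})

test_that("shift_and_decode equals the decoder applied to the shifted latent", {
  fit <- small_fit()
  z <- encode(fit$model, fit$split$test_control$matrix)$mu
  zero <- matrix(0, nrow(z), ncol(z))
  expect_equal(shift_and_decode(z, zero, fit$model), decode(fit$model, z))
  d <- matrix(0.3, nrow(z), ncol(z))
  expect_equal(shift_and_decode(z, d, fit$model), decode(fit$model, z + d))
  expect_error(shift_and_decode(z, d[, -1], fit$model), "shapes differ")
})

test_that("predict_perturbed conserves cells, is deterministic and order-invariant", {
  fit <- small_fit()
  pred <- predict_perturbed(fit$split$test_control, fit$model, fit$deltas,
                            fit$pops$z_ctrl, fit$cfg)
  expect_equal(n_cells(pred), n_cells(fit$split$test_control))
  expect_true(all(pred$obs$condition == "predicted"))
  pred2 <- predict_perturbed(fit$split$test_control, fit$model, fit$deltas,
                             fit$pops$z_ctrl, fit$cfg)
  expect_identical(pred$matrix, pred2$matrix)
  # permuting the training cells (rows of deltas and latents together)
  # leaves predictions unchanged
  set.seed(43)
  perm <- sample(nrow(fit$deltas))
  d_p <- fit$deltas[perm, ]
  class(d_p) <- class(fit$deltas)
  pred3 <- predict_perturbed(fit$split$test_control, fit$model, d_p,
                             fit$pops$z_ctrl[perm, ], fit$cfg)
  expect_equal(pred$matrix, pred3$matrix, tolerance = 1e-10)
  expect_error(predict_perturbed(fit$split$test_control[integer(0), ],
                                 fit$model, fit$deltas, fit$pops$z_ctrl, fit$cfg),
               "empty")
})

test_that("with all deltas equal the predicted latent is exactly z + delta*", {
  fit <- small_fit()
  z <- encode_dataset(fit$model, fit$split$test_control)
  dstar <- rnorm(ncol(z))
  same <- matrix(dstar, nrow(fit$deltas), ncol(fit$deltas), byrow = TRUE)
  class(same) <- class(fit$deltas)
  pred <- predict_perturbed(fit$split$test_control, fit$model, same,
                            fit$pops$z_ctrl, fit$cfg)
  want <- decode(fit$model, sweep(z, 2, dstar, "+"))
  expect_equal(pred$matrix, want, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("predicted mean shift tracks the simulator's programmed response", {
  fit <- small_fit()
  pred <- predict_perturbed(fit$split$test_control, fit$model, fit$deltas,
                            fit$pops$z_ctrl, fit$cfg)
  shift_pred <- gene_stats(pred)$means - gene_stats(fit$split$test_control)$means
  truth_shift <- ground_truth_shift(fit$truth, "type1")
  truth_shift <- truth_shift[colnames(pred$matrix)]
  # positive association is all the tiny fixture supports (15 epochs, k = 8)
  expect_gt(cor(shift_pred, truth_shift), 0.2)
})
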
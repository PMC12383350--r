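test_that("cost_matrix is the exact pairwise squared Euclidean distance", {
  expect_equal(cost_matrix(c(0, 0), c(0, 0)), matrix(0, 1, 1))
  zc <- rbind(c(0, 0))
  zs <- rbind(c(1, 0), c(1, 1))
  expect_equal(cost_matrix(zc, zs), matrix(c(1, 2), 1, 2), tolerance = 1e-12)
  set.seed(31)
  Z <- matrix(rnorm(12), 4, 3)
  expect_equal(cost_matrix(Z, Z), t(cost_matrix(Z, Z)), tolerance = 1e-12)
  expect_equal(diag(cost_matrix(Z, Z)), rep(0, 4), tolerance = 1e-12)
  expect_error(cost_matrix(Z, matrix(0, 2, 2)), "dimensions differ")
})

test_that("solve_emd handles the 1x1 and the enumerable 2x2 worked case", {
  r1 <- solve_emd(matrix(3.5, 1, 1))
  expect_equal(r1$coupling, matrix(1, 1, 1))
  expect_equal(r1$objective, 3.5)
  zc <- rbind(c(0, 0), c(1, 0))
  zs <- rbind(c(0, 0.1), c(1, 0))
  res <- solve_emd(cost_matrix(zc, zs))
  # identity assignment (cost 0.005) beats the swap (cost 1.005)
  expect_equal(res$coupling, diag(0.5, 2), tolerance = 1e-12)
  expect_equal(res$objective, 0.005, tolerance = 1e-12)
  d <- delta_matrix(res, zc, zs)
  expect_equal(d[1, ], c(0, 0.1), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("solve_emd matches the permutation oracle on random square instances", {
  set.seed(32)
  for (rep in 1:8) {
    n <- sample(2:6, 1)
    C <- matrix(runif(n * n), n)
    res <- solve_emd(C)
    expect_equal(res$objective, emd_perm_oracle(C), tolerance = 1e-10)
    expect_lt(max(abs(rowSums(res$coupling) - 1 / n)), 1e-8)
    expect_lt(max(abs(colSums(res$coupling) - 1 / n)), 1e-8)
  }
})

test_that("solve_emd satisfies marginals and never exceeds permutation couplings (rectangular)", {
  set.seed(33)
  n <- 7; m <- 5; k <- 3
  Zc <- matrix(rnorm(n * k), n)
  Zs <- matrix(rnorm(m * k), m)
  res <- solve_emd(cost_matrix(Zc, Zs))
  expect_lt(max(abs(rowSums(res$coupling) - 1 / n)), 1e-8)
  expect_lt(max(abs(colSums(res$coupling) - 1 / m)), 1e-8)
  expect_true(all(res$coupling >= -1e-15))
  expect_equal(sum(res$coupling * res$cost), res$objective, tolerance = 1e-10)
  # any feasible product coupling is an upper bound
  expect_lte(res$objective, sum(outer(rep(1 / n, n), rep(1 / m, m)) * res$cost) + 1e-12)
  expect_error(solve_emd(matrix(c(1, -1), 1, 2)), "nonnegative")
})

test_that("identical populations transport at zero cost with all-zero deltas", {
  set.seed(34)
  Z <- matrix(rnorm(18), 6, 3)
  res <- solve_emd(cost_matrix(Z, Z))
  expect_equal(res$objective, 0, tolerance = 1e-12)
  d <- delta_matrix(res, Z, Z)
  expect_equal(max(abs(d)), 0, tolerance = 1e-10)
})

test_that("delta_matrix closed forms: identity and product couplings", {
  set.seed(35)
  n <- 5; k <- 3
  Zc <- matrix(rnorm(n * k), n)
  Zs <- matrix(rnorm(n * k), n)
  C <- cost_matrix(Zc, Zs)
  id_res <- structure(list(cost = C, coupling = diag(1 / n, n),
                           source_marginal = rep(1 / n, n),
                           target_marginal = rep(1 / n, n),
                           objective = sum(diag(C)) / n, method = "exact"),
                      class = "transport_result")
  expect_equal(delta_matrix(id_res, Zc, Zs), Zs - Zc,
               ignore_attr = TRUE, tolerance = 1e-12)
  prod_res <- id_res
  prod_res$coupling <- matrix(1 / n^2, n, n)
  prod_res$objective <- sum(prod_res$coupling * C)
  dp <- delta_matrix(prod_res, Zc, Zs)
  bary <- colMeans(Zs)
  for (i in 1:n) expect_equal(dp[i, ], bary - Zc[i, ],
                              ignore_attr = TRUE, tolerance = 1e-12)
  # the literal (unnormalized) variant scales the barycenter by the row mass
  dl <- delta_matrix(id_res, Zc, Zs, literal = TRUE)
  expect_equal(dl, Zs / n - Zc, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("deltas shift by exactly v when the stimulated population is translated", {
  set.seed(36)
  Zc <- matrix(rnorm(15), 5, 3)
  Zs <- matrix(rnorm(15), 5, 3)
  v <- c(10, -3, 0.5)
  r1 <- solve_emd(cost_matrix(Zc, Zs))
  Zs2 <- sweep(Zs, 2, v, "+")
  # translation does not change the optimal coupling for squared costs here;
  # reuse the same coupling on the translated points
  d1 <- delta_matrix(r1, Zc, Zs)
  r1b <- r1; r1b$cost <- cost_matrix(Zc, Zs2)
  r1b$objective <- sum(r1b$coupling * r1b$cost)
  d2 <- delta_matrix(r1b, Zc, Zs2)
  expect_equal(sweep(d2, 2, v, "-"), d1, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("sinkhorn approximates the exact plan and validates at looser tolerance", {
  set.seed(37)
  C <- cost_matrix(matrix(rnorm(12), 4, 3), matrix(rnorm(12), 4, 3))
  exact <- solve_emd(C)
  sk <- solve_emd(C, method = "sinkhorn", reg = 0.01)
  expect_lt(abs(sk$objective - exact$objective), 0.05 * (1 + exact$objective))
  # sinkhorn marginals are only met to its convergence tolerance, so its
  # objective may undercut the exact optimum by a sliver
  expect_gte(sk$objective, exact$objective - 1e-3 * (1 + exact$objective))
})

test_that("latent_populations subsamples deterministically and keeps shapes", {
  fit <- small_fit()
  pops <- latent_populations(fit$model, fit$split$train, max_cells = 50, seed = 2)
  expect_lte(nrow(pops$z_ctrl), 50)
  expect_lte(nrow(pops$z_stim), 50)
  expect_equal(ncol(pops$z_ctrl), fit$cfg$latent_dim)
  pops2 <- latent_populations(fit$model, fit$split$train, max_cells = 50, seed = 2)
  expect_identical(pops, pops2)
  # cap above the population size uses every cell
  all_pop <- latent_populations(fit$model, fit$split$train, max_cells = 1e6, seed = 2)
  expect_equal(nrow(all_pop$z_ctrl),
               sum(fit$split$train$obs$condition == "control"))
})
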
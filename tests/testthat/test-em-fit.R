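test_that("EM recovers a planted block support and is bitwise reproducible", {
  sim <- tiny_planted_dataset()
  rg <- region_map_chunks(sim$data$channel_names, 4)
  fit <- em_fit(sim$data, rg, fit_config(tau = 0.1, center = FALSE))
  expect_setequal(which(fit$gamma > 0.1), sim$support)
  # identical rerun gives a bitwise-identical trace
  fit2 <- em_fit(sim$data, rg, fit_config(tau = 0.1, center = FALSE))
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$gamma, fit2$gamma)
})

test_that("EM state invariants hold along the trajectory", {
  sim <- tiny_planted_dataset(seed = 7)
  rg <- region_map_chunks(sim$data$channel_names, 4)
  fit <- em_fit(sim$data, rg, fit_config(tau = 0.1, center = FALSE))
  tr <- fit$trace
  # gamma never negative; pruned blocks stay at zero forever
  gmat <- do.call(rbind, tr$gamma)
  expect_true(all(gmat >= 0))
  for (it in seq_len(nrow(tr))) {
    for (b in tr$pruned[[it]]) {
      expect_true(all(gmat[it:nrow(gmat), b] == 0))
    }
  }
  # active count is non-increasing
  expect_true(all(diff(tr$n_active) <= 0))
  # noise variance stays positive
  expect_true(all(tr$sigma2 > 0))
  # final posterior covariance blocks are symmetric PSD
  for (S in fit$Sigma_blocks) {
    expect_equal(S, t(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
  # constrained correlation matrices are exact AR(1) Toeplitz
  for (B in fit$B) {
    r <- B[1, 2]
    expect_equal(B, outer(seq_len(nrow(B)), seq_len(ncol(B)),
                          function(i, j) r^abs(i - j)))
  }
})

test_that("one EM iteration reproduces the straight-line oracle", {
  # 3-block toy problem, one region, no centering, no pruning
  set.seed(31)
  d <- 3
  n_b <- 3
  sim <- gen_block_sparse(block_sparse_spec(
    n_blocks = n_b, block_size = d, n_active_blocks = 2,
    active_blocks = c(1, 3), n_samples = 20, seed = 31))
  rg <- region_map_single(sim$data$channel_names)
  fit <- em_fit(sim$data, rg,
                fit_config(tau = 1e-12, max_iter = 1, center = FALSE))
  s2_init <- max(0.1 * stats::var(sim$data$labels), 1e-10)
  oracle <- oracle_em_step(
    sim$data$features, sim$data$labels,
    gamma = rep(1, n_b), B_of_block = replicate(n_b, diag(d), simplify = FALSE),
    block_region = rep(1L, n_b), sigma2 = s2_init, block_size = d)
  expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-10)
  expect_equal(fit$gamma, oracle$gamma, tolerance = 1e-10)
  expect_equal(fit$B[[1]], oracle$B[[1]], tolerance = 1e-10)
})

test_that("both posterior routes agree inside the EM (N < D and N >= D)", {
  # same toy, sample counts on either side of the active dimension
  for (n in c(6, 40)) {   # D = 3 * 4 = 12
    sim <- gen_block_sparse(block_sparse_spec(
      n_blocks = 3, block_size = 4, n_active_blocks = 1,
      active_blocks = 2, n_samples = n, seed = 13))
    rg <- region_map_single(sim$data$channel_names)
    fit <- em_fit(sim$data, rg,
                  fit_config(tau = 1e-12, max_iter = 1, center = FALSE))
    expect_equal(fit$trace$path, if (n >= 12) "direct" else "woodbury")
    oracle <- oracle_em_step(
      sim$data$features, sim$data$labels,
      gamma = rep(1, 3), B_of_block = replicate(3, diag(4), simplify = FALSE),
      block_region = rep(1L, 3),
      sigma2 = max(0.1 * stats::var(sim$data$labels), 1e-10), block_size = 4)
    expect_equal(fit$gamma, oracle$gamma, tolerance = 1e-9)
  }
})

test_that("with d_b = 1 and identity mode the update reduces to classical SBL", {
  set.seed(17)
  X <- matrix(rnorm(30 * 5), 30)
  y <- rnorm(30)
  data <- epoch_dataset(X, rep(1, 30), paste0("F", 1:5), 1)
  data$labels <- y
  fit <- em_fit(data, NULL, fit_config(tau = 1e-12, max_iter = 1,
                                       b_mode = "identity", center = FALSE))
  s2 <- max(0.1 * stats::var(y), 1e-10)
  Sw <- solve(crossprod(X) / s2 + diag(5))
  mu <- drop(Sw %*% crossprod(X, y)) / s2
  expect_equal(fit$gamma, diag(Sw) + mu^2, tolerance = 1e-10)
})

test_that("degenerate and non-convergent fits are reported as specified", {
  sim <- tiny_planted_dataset(seed = 3)
  rg <- region_map_chunks(sim$data$channel_names, 4)
  # a huge threshold prunes everything -> informative error
  expect_error(em_fit(sim$data, rg, fit_config(tau = 1e6, center = FALSE)),
               "degenerate")
  # max_iter exhaustion returns a flagged fit, not an exception
  fit <- em_fit(sim$data, rg, fit_config(tau = 1e-12, max_iter = 2, center = FALSE))
  expect_false(fit$converged)
  expect_equal(fit$n_iter, 2L)
})

test_that("a vanishing threshold prunes nothing on well-conditioned data", {
  sim <- tiny_planted_dataset(seed = 9)
  rg <- region_map_chunks(sim$data$channel_names, 4)
  fit <- em_fit(sim$data, rg, fit_config(tau = 1e-12, center = FALSE))
  expect_equal(fit$removal_order, integer(0))
  expect_true(all(fit$active))
})

test_that("regional mode requires a region map and unequal blocks are rejected", {
  sim <- tiny_planted_dataset()
  expect_error(em_fit(sim$data, NULL, fit_config(b_mode = "regional")),
               "region map")
})
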
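test_that("assemble_sigma0 builds the block-diagonal prior and drops pruned blocks", {
  st <- block_structure(2, 2)
  h <- hyper_state(c(1, 1), list(diag(2)), 1)
  expect_equal(assemble_sigma0(h, st), diag(4))
  # pruning removes coordinates
  h2 <- hyper_state(c(2, 0), list(diag(2)), 1)
  expect_equal(assemble_sigma0(h2, st), diag(c(2, 2)))
  # single block with explicit correlation
  st1 <- block_structure(1, 2)
  B <- stats::toeplitz(c(1, 0.5))
  h3 <- hyper_state(1, list(B), 1)
  expect_equal(assemble_sigma0(h3, st1), B)
  # dimension mismatch is a structural error naming the block
  h4 <- hyper_state(c(1, 1), list(diag(3)), 1)
  expect_error(assemble_sigma0(h4, st), "block 1")
})

test_that("posterior routes satisfy their closed forms", {
  # no data term: posterior equals the prior
  S0 <- diag(c(1, 2, 3, 4))
  z <- posterior_direct(matrix(0, 5, 4), rnorm(5), S0, 1)
  expect_equal(z$mu, rep(0, 4))
  expect_equal(z$Sigma, S0)
  zw <- posterior_woodbury(matrix(0, 5, 4), rnorm(5), S0, 1)
  expect_equal(zw$mu, rep(0, 4))
  expect_equal(zw$Sigma, S0)
  # X = I, Sigma0 = I, sigma2 = 1: Sigma_w = I/2, mu = y/2
  y <- c(2, -4, 6)
  p <- posterior_direct(diag(3), y, diag(3), 1)
  expect_equal(p$Sigma, diag(3) / 2)
  expect_equal(p$mu, y / 2)
  # random instance against the naive oracle
  set.seed(11)
  X <- matrix(rnorm(8 * 6), 8)
  yy <- rnorm(8)
  S <- crossprod(matrix(rnorm(36), 6)) + diag(6)
  o <- oracle_posterior(X, yy, S, 0.6)
  pd <- posterior_direct(X, yy, S, 0.6)
  expect_equal(pd$mu, o$mu, tolerance = 1e-10)
  expect_equal(pd$Sigma, o$Sigma, tolerance = 1e-10)
})

test_that("Woodbury route handles zero-variance blocks the direct route cannot", {
  set.seed(3)
  X <- matrix(rnorm(6 * 4), 6)
  y <- rnorm(6)
  S0 <- diag(c(1, 1, 0, 0))   # second block has gamma = 0
  expect_error(posterior_direct(X, y, S0, 1), "singular")
  pw <- posterior_woodbury(X, y, S0, 1)
  expect_equal(pw$mu[3:4], c(0, 0))
  expect_equal(pw$Sigma[3:4, 3:4], matrix(0, 2, 2))
})

test_that("posterior path equivalence holds over random instances", {
  set.seed(202)
  worst <- 0
  for (i in 1:100) {
    n <- sample(5:40, 1)
    d <- sample(4:60, 1)
    X <- matrix(rnorm(n * d), n)
    y <- rnorm(n)
    A <- matrix(rnorm(d * d), d)
    S0 <- crossprod(A) + diag(d) * 0.1
    s2 <- runif(1, 0.1, 2)
    p1 <- posterior_direct(X, y, S0, s2)
    p2 <- posterior_woodbury(X, y, S0, s2)
    rel_mu <- max(abs(p1$mu - p2$mu)) / max(max(abs(p1$mu)), 1e-12)
    rel_S <- max(abs(p1$Sigma - p2$Sigma)) / max(abs(p1$Sigma))
    worst <- max(worst, rel_mu, rel_S)
  }
  expect_lt(worst, 1e-8)
})

test_that("the posterior route choice keys on sample vs active feature count", {
  expect_equal(choose_posterior_path(7560, 2048), "direct")
  expect_equal(choose_posterior_path(864, 1770), "woodbury")
  expect_equal(choose_posterior_path(100, 100), "direct")  # boundary: N >= D
})

test_that("noise-variance update matches its closed form and oracle", {
  # X = 0: trace term is exactly D, so sigma2 = ||y||^2 / N
  y <- c(1, 2, 3)
  S0 <- diag(4)
  post <- posterior_direct(matrix(0, 3, 4), y, S0, 1)
  expect_equal(update_sigma2(matrix(0, 3, 4), y, post, S0, 1), sum(y^2) / 3)
  # random instance against a hand transcription
  set.seed(8)
  X <- matrix(rnorm(10 * 4), 10)
  yy <- rnorm(10)
  S <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  p <- posterior_direct(X, yy, S, 0.5)
  expected <- (sum((yy - X %*% p$mu)^2) +
                 0.5 * (4 - sum(diag(solve(S) %*% p$Sigma)))) / 10
  expect_equal(update_sigma2(X, yy, p, S, 0.5), expected, tolerance = 1e-12)
  # collapse clamps to the floor with a warning
  perfect <- p
  perfect$Sigma <- matrix(0, 4, 4)
  perfect$mu <- solve(crossprod(X) + diag(4) * 1e-12, crossprod(X, yy))
  expect_warning(
    s2 <- update_sigma2(X, drop(X %*% perfect$mu), perfect, S, 1e-12, floor = 1e-10),
    "floor")
  expect_equal(s2, 1e-10)
})

test_that("relevance update follows Eq-style trace formula", {
  st <- block_structure(1, 4)
  h <- hyper_state(1, list(diag(4)), 1)
  # B = I, mu = 0, Sigma = I -> gamma = 1
  p <- make_post(rep(0, 4), diag(4))
  expect_equal(update_gamma(p, h, st), 1)
  # B = I, mu = (2, 0), Sigma = 0 -> gamma = |mu|^2 / d = 2
  st2 <- block_structure(1, 2)
  h2 <- hyper_state(1, list(diag(2)), 1)
  p2 <- make_post(c(2, 0), matrix(0, 2, 2))
  expect_equal(update_gamma(p2, h2, st2), 2)
  # non-trivial B against the oracle
  set.seed(21)
  B <- stats::toeplitz(0.6^(0:2))
  st3 <- block_structure(2, 3)
  h3 <- hyper_state(c(1, 1), list(B), 1)
  mu <- rnorm(6)
  S <- crossprod(matrix(rnorm(36), 6)) / 6
  p3 <- make_post(mu, S)
  g <- update_gamma(p3, h3, st3)
  for (b in 1:2) {
    idx <- (b - 1) * 3 + 1:3
    M2 <- S[idx, idx] + mu[idx] %*% t(mu[idx])
    expect_equal(g[b], sum(diag(solve(B) %*% M2)) / 3, tolerance = 1e-12)
  }
  # pruned blocks stay at zero
  h4 <- hyper_state(c(1, 0), list(B), 1)
  p4 <- make_post(mu[1:3], S[1:3, 1:3])
  expect_equal(update_gamma(p4, h4, st3)[2], 0)
})

test_that("correlation update averages block moments within groups", {
  st <- block_structure(1, 3)
  C <- crossprod(matrix(rnorm(9, 2), 3)) / 3
  h <- hyper_state(1, list(diag(3)), 1)
  p <- make_post(rep(0, 3), C)
  # single block, gamma 1, mu 0: raw B equals the block covariance
  expect_equal(update_B(p, h, st, b_mode = "shared")[[1]], (C + t(C)) / 2)
  # two identical blocks: the mean equals either contribution
  st2 <- block_structure(2, 3)
  h2 <- hyper_state(c(1, 1), list(diag(3)), 1)
  p2 <- make_post(rep(0, 6), rbind(cbind(C, matrix(0, 3, 3)),
                                       cbind(matrix(0, 3, 3), C)))
  expect_equal(update_B(p2, h2, st2, b_mode = "shared")[[1]], (C + t(C)) / 2)
  # three blocks in one region against the oracle mean
  set.seed(5)
  st3 <- block_structure(3, 3)
  gam <- c(0.5, 1.2, 2)
  h3 <- hyper_state(gam, list(diag(3)), 1)
  mu <- rnorm(9)
  S <- crossprod(matrix(rnorm(81), 9)) / 9
  p3 <- make_post(mu, S)
  got <- update_B(p3, h3, st3, regions = rep(1L, 3), b_mode = "regional",
                  gamma = gam)[[1]]
  acc <- matrix(0, 3, 3)
  for (b in 1:3) {
    idx <- (b - 1) * 3 + 1:3
    acc <- acc + (S[idx, idx] + mu[idx] %*% t(mu[idx])) / gam[b]
  }
  expect_equal(got, acc / 3, tolerance = 1e-12)
  # per_block mode gives every block its own matrix
  pb <- update_B(p3, h3, st3, b_mode = "per_block", gamma = gam)
  expect_length(pb, 3)
  # identity mode skips the update entirely
  expect_identical(update_B(p3, h3, st3, b_mode = "identity"), h3$B)
})

test_that("Toeplitz constraint produces the exact AR(1) form, clamped and PD", {
  expect_equal(toeplitz_constrain(diag(3)), diag(3))
  B <- stats::toeplitz(c(1, 0.5, 0))
  expect_equal(toeplitz_constrain(B), stats::toeplitz(c(1, 0.5, 0.25)))
  # |m1/m0| beyond the clamp is clipped and the result stays PD
  Bover <- stats::toeplitz(c(1, 1.3, 0))
  out <- toeplitz_constrain(Bover, ar_clamp = 0.99)
  expect_equal(out, stats::toeplitz(0.99^(0:2)))
  expect_gt(min(eigen(out, symmetric = TRUE, only.values = TRUE)$values), 0)
  # degenerate diagonal falls back to the identity
  expect_warning(ident <- toeplitz_constrain(matrix(0, 3, 3)), "identity")
  expect_equal(ident, diag(3))
  # property: random symmetric inputs always yield exact r^|i-j|, PD
  set.seed(9)
  for (i in 1:50) {
    d <- sample(2:8, 1)
    A <- matrix(rnorm(d * d), d)
    Braw <- (A + t(A)) / 2 + diag(d) * runif(1, 0.5, 3)
    m0 <- mean(diag(Braw))
    if (m0 <= 0) next
    out <- toeplitz_constrain(Braw, 0.98)
    r <- max(-0.98, min(0.98, mean(Braw[cbind(2:d, 1:(d - 1))]) / m0))
    expect_equal(out, outer(1:d, 1:d, function(i, j) r^abs(i - j)))
    expect_gt(min(eigen(out, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("pruning keeps the cap, the order and the permanence of zeros", {
  st_gam <- function(g) hyper_state(g, list(diag(2)), 1)
  # all above threshold: nothing pruned
  h <- prune_blocks(st_gam(c(0.5, 0.3)), tau = 0.1)
  expect_equal(attr(h, "pruned"), integer(0))
  expect_equal(h$gamma, c(0.5, 0.3))
  # seven sub-threshold blocks, cap 5: exactly the five lowest indices
  h2 <- prune_blocks(st_gam(rep(1e-9, 7)), tau = 1e-3, max_prune_per_iter = 5)
  expect_equal(attr(h2, "pruned"), 1:5)
  expect_equal(h2$gamma, c(rep(0, 5), rep(1e-9, 2)))
  expect_equal(h2$active, c(rep(FALSE, 5), rep(TRUE, 2)))
  # threshold rule below the cap
  h3 <- prune_blocks(st_gam(c(0.2, 1e-8, 0.3, 1e-9)), tau = 1e-3)
  expect_setequal(attr(h3, "pruned"), c(2L, 4L))
  # smallest gamma pruned first
  expect_equal(attr(h3, "pruned"), c(4L, 2L))
})
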
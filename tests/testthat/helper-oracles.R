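# Independent straight-line oracles used across the suite. These are kept
# deliberately naive (plain solve(), explicit loops) so they share no code
# path with the package implementation they check.

# block-diagonal prior covariance, naive assembly
oracle_sigma0 <- function(gamma, B_of_block) {
  mats <- lapply(seq_along(gamma), function(b) gamma[b] * B_of_block[[b]])
  d <- vapply(mats, nrow, 1L)
  out <- matrix(0, sum(d), sum(d))
  at <- 0
  for (b in seq_along(mats)) {
    idx <- at + seq_len(d[b])
    out[idx, idx] <- mats[[b]]
    at <- at + d[b]
  }
  out
}

# posterior by the textbook direct formulas
oracle_posterior <- function(X, y, Sigma0, sigma2) {
  Sw <- solve(crossprod(X) / sigma2 + solve(Sigma0))
  list(mu = drop(Sw %*% t(X) %*% y) / sigma2, Sigma = Sw)
}

# one full EM hyperparameter update, transcribed line by line:
# noise variance, then per-block relevance from the previous B, then the
# per-region average second moment from the new relevance, then the AR(1)
# Toeplitz constraint.
oracle_em_step <- function(X, y, gamma, B_of_block, block_region, sigma2,
                           block_size, ar_clamp = 0.98) {
  n <- nrow(X)
  n_b <- length(gamma)
  d <- block_size
  Sigma0 <- oracle_sigma0(gamma, B_of_block)
  D <- ncol(X)
  if (n >= D) {
    post <- oracle_posterior(X, y, Sigma0, sigma2)
  } else {
    H <- sigma2 * diag(n) + X %*% Sigma0 %*% t(X)
    mu <- drop(Sigma0 %*% t(X) %*% solve(H, y))
    Sw <- Sigma0 - Sigma0 %*% t(X) %*% solve(H, X %*% Sigma0)
    post <- list(mu = mu, Sigma = Sw)
  }
  resid <- y - drop(X %*% post$mu)
  tr <- sum(diag(solve(Sigma0) %*% post$Sigma))
  sigma2_new <- (sum(resid^2) + sigma2 * (D - tr)) / n

  gamma_new <- numeric(n_b)
  moments <- vector("list", n_b)
  for (b in seq_len(n_b)) {
    idx <- (b - 1) * d + seq_len(d)
    M2 <- post$Sigma[idx, idx] + post$mu[idx] %*% t(post$mu[idx])
    moments[[b]] <- M2
    gamma_new[b] <- sum(diag(solve(B_of_block[[b]]) %*% M2)) / d
  }

  B_new <- list()
  for (re in sort(unique(block_region))) {
    members <- which(block_region == re)
    acc <- matrix(0, d, d)
    for (b in members) acc <- acc + moments[[b]] / gamma_new[b]
    Braw <- acc / length(members)
    m0 <- mean(diag(Braw))
    m1 <- mean(Braw[cbind(2:d, 1:(d - 1))])
    r <- max(-ar_clamp, min(ar_clamp, m1 / m0))
    B_new[[re]] <- outer(seq_len(d), seq_len(d), function(i, j) r^abs(i - j))
  }
  list(sigma2 = sigma2_new, gamma = gamma_new, B = B_new, posterior = post)
}

# exact two-sided signed-rank p-value by enumerating all sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu))
}

make_post <- function(mu, Sigma) {
  structure(list(mu = mu, Sigma = Sigma), class = "bsbl_posterior")
}

support_f1 <- function(selected, truth) {
  tp <- length(intersect(selected, truth))
  2 * tp / (length(selected) + length(truth))
}

# small labelled dataset with a planted informative block
tiny_planted_dataset <- function(n = 120, n_blocks = 12, d = 4,
                                 active = c(2, 7, 11), seed = 42) {
  sim <- gen_block_sparse(block_sparse_spec(
    n_blocks = n_blocks, block_size = d, n_active_blocks = length(active),
    active_blocks = active, n_samples = n, seed = seed))
  sim
}
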
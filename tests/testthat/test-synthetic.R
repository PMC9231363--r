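test_that("block-sparse generator is seed-reproducible and honours its model", {
  spec <- block_sparse_spec(n_blocks = 10, block_size = 4, n_active_blocks = 3,
                            n_samples = 60, seed = 12)
  a <- gen_block_sparse(spec)
  b <- gen_block_sparse(spec)
  expect_identical(a$data$features, b$data$features)
  expect_identical(a$w_true, b$w_true)
  # weights vanish off the support
  st <- a$data$structure
  off <- setdiff(seq_len(10), a$support)
  for (blk in off) expect_true(all(a$w_true[(blk - 1) * 4 + 1:4] == 0))
  # noiseless instance: y = X w exactly
  nl <- gen_block_sparse(block_sparse_spec(n_blocks = 6, block_size = 3,
                                           n_active_blocks = 2, n_samples = 30,
                                           sigma2_true = 0, seed = 5))
  expect_equal(nl$data$labels, drop(nl$data$features %*% nl$w_true))
  # empty support: pure noise
  z <- gen_block_sparse(block_sparse_spec(n_blocks = 6, block_size = 3,
                                          n_active_blocks = 0, n_samples = 30,
                                          sigma2_true = 1, seed = 5))
  expect_true(all(z$w_true == 0))
  expect_error(block_sparse_spec(n_blocks = 4, n_active_blocks = 5), "<=")
  expect_error(block_sparse_spec(r_true = 1), "r_true")
})

test_that("planted weights show the intra-block AR(1) correlation", {
  spec <- block_sparse_spec(n_blocks = 80, block_size = 8,
                            n_active_blocks = 80, r_true = 0.8,
                            n_samples = 5, seed = 33)
  sim <- gen_block_sparse(spec)
  w <- matrix(sim$w_true, nrow = 8)
  lag1 <- cor(as.vector(w[-8, ]), as.vector(w[-1, ]))
  expect_lt(abs(lag1 - 0.8), 0.1)
})

test_that("the SNR parameterization sets the noise variance it promises", {
  sim <- gen_block_sparse(block_sparse_spec(seed = 2))
  expect_equal(sim$sigma2, sum(sim$w_true^2) / 10)   # 10 dB default
})

test_that("speller sessions satisfy the trial-structure invariants", {
  sess <- gen_p300_session(p300_sim_spec(n_characters = 4, seed = 9))
  tr <- sess$trials
  expect_equal(nrow(tr), 4 * 4 * 12)
  counts <- dplyr::count(tr, trial, epoch, code)
  expect_true(all(counts$n == 1))
  per_epoch <- dplyr::count(dplyr::distinct(tr, trial, epoch, code), trial, epoch)
  expect_true(all(per_epoch$n == 12))
  # exactly two target codes per epoch: 2 of 12 rows labelled +1
  lab <- dplyr::count(tr[tr$label == 1, ], trial, epoch)
  expect_true(all(lab$n == 2))
  # labels match the layout geometry
  for (i in sample(nrow(tr), 20)) {
    codes <- p300bsbl:::target_codes(sess$layout, tr$target[i])
    expect_equal(tr$label[i] == 1, tr$code[i] %in% codes)
  }
  # reproducibility
  sess2 <- gen_p300_session(p300_sim_spec(n_characters = 4, seed = 9))
  expect_identical(sess$data$features, sess2$data$features)
})

test_that("planted channels carry the target separation, others do not", {
  sess <- gen_p300_session(p300_sim_spec(n_characters = 12, seed = 15))
  X <- sess$data$features
  lab <- sess$data$labels
  st <- sess$data$structure
  sep <- vapply(seq_len(st$n_blocks), function(b) {
    cols <- st$offsets[b] + seq_len(30)
    blk <- rowMeans(X[, cols[10:20]])    # window around the bump
    mean(blk[lab == 1]) - mean(blk[lab == -1])
  }, numeric(1))
  inf <- sess$truth$informative
  expect_gt(min(sep[inf]), max(sep[-inf]))
})

test_that("a zero-amplitude ERP leaves targets and non-targets exchangeable", {
  pvals <- sapply(1:20, function(s) {
    sess <- gen_p300_session(p300_sim_spec(erp_amplitude = 0, n_characters = 3,
                                           seed = 100 + s))
    X <- rowMeans(sess$data$features)
    stats::t.test(X[sess$data$labels == 1], X[sess$data$labels == -1])$p.value
  })
  # at alpha = 0.01 under the null, 20 draws rarely all reject; demand most do not
  expect_gte(sum(pvals > 0.01), 18)
})

test_that("noise-free sessions decode perfectly from a single epoch", {
  sess <- gen_p300_session(p300_sim_spec(noise_sd = 1e-9, n_characters = 4,
                                         n_epochs_per_trial = 1, seed = 3))
  # score = projection on the bump of the most informative channel
  inf <- sess$truth$informative[1]
  cols <- sess$data$structure$offsets[inf] + seq_len(30)
  sc <- rowSums(sess$data$features[, cols])
  dec <- decode_characters(sc, sess$trials, sess$layout)
  expect_equal(dec$predicted, sess$targets)
  expect_equal(accuracy(dec$predicted, sess$targets), 100)
})

test_that("invalid session specifications are rejected", {
  expect_error(p300_sim_spec(erp_latency = 2), "window")
  expect_error(p300_sim_spec(noise_ar = 1), "noise_ar")
  expect_error(p300_sim_spec(erp_amplitude = -1), "amplitude")
  expect_error(p300_sim_spec(informative_channels = "NOPE"), "unknown")
})
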
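#' Fitting configuration for the block-sparse Bayesian EM engine
#'
#' @param tau Shear threshold: blocks whose relevance scale `gamma` falls
#'   below `tau` are pruned to exactly zero during fitting, and the final
#'   channel set keeps blocks with `gamma > tau`. Must be positive; the
#'   recommended cross-validation range is `[1e-6, 1e-1]` on unit-scale
#'   features.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance: relative L2 change of the active
#'   `gamma` vector between iterations.
#' @param b_mode Intra-block correlation mode: `"regional"` (one AR(1)
#'   Toeplitz matrix shared per spatial region, the full method),
#'   `"identity"` (no temporal correlation), `"shared"` (one matrix for all
#'   channels), `"per_block"` (one matrix per channel, no spatial
#'   smoothing).
#' @param max_prune_per_iter At most this many blocks are pruned per
#'   iteration (default 5, the practicality cap).
#' @param ar_clamp Bound on the magnitude of the AR(1) coefficient used in
#'   the Toeplitz constraint; must lie in (0, 1) so the constrained matrix
#'   stays positive definite.
#' @param sigma2_floor Lower clamp for the noise variance update (guards
#'   against collapse on separable data).
#' @param center Center the feature columns and the labels before fitting
#'   (default `TRUE`). The regression model has no intercept, so with
#'   imbalanced target/non-target labels the class-frequency offset would
#'   otherwise sit in the residual forever and inflate the relevance of
#'   noise channels; centering absorbs it, exactly as an intercept would.
#' @param seed Integer seed recorded with the fit (the EM itself is
#'   deterministic; the seed covers any randomized downstream use).
#' @return A `fit_config` list.
#' @export
fit_config <- function(tau = 1e-4, max_iter = 200L, tol = 1e-4,
                       b_mode = c("regional", "identity", "shared", "per_block"),
                       max_prune_per_iter = 5L, ar_clamp = 0.98,
                       sigma2_floor = 1e-10, center = TRUE, seed = 1L) {
  b_mode <- match.arg(b_mode)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) abort("`tau` must be > 0.")
  if (max_iter < 1) abort("`max_iter` must be >= 1.")
  if (tol <= 0) abort("`tol` must be > 0.")
  if (ar_clamp <= 0 || ar_clamp >= 1) abort("`ar_clamp` must be in (0, 1).")
  if (max_prune_per_iter < 1) abort("`max_prune_per_iter` must be >= 1.")
  if (sigma2_floor <= 0) abort("`sigma2_floor` must be > 0.")
  structure(
    list(tau = tau, max_iter = as.integer(max_iter), tol = tol, b_mode = b_mode,
         max_prune_per_iter = as.integer(max_prune_per_iter),
         ar_clamp = ar_clamp, sigma2_floor = sigma2_floor,
         center = isTRUE(center), seed = as.integer(seed)),
    class = "fit_config"
  )
}

#' Hyperparameter state of the block-sparse prior
#'
#' Bundles the per-block relevance scales `gamma`, the per-group
#' correlation matrices `B`, the noise variance `sigma2` and the active
#' mask. `block_group` maps each block to its entry of `B` (all blocks in a
#' spatial region share one matrix under regional smoothing).
#'
#' @param gamma Non-negative numeric vector, one relevance scale per block.
#' @param B List of symmetric positive-definite matrices, one per group.
#' @param sigma2 Positive noise variance.
#' @param block_group Integer vector mapping block -> index into `B`
#'   (default: all blocks share `B[[1]]`).
#' @param active Logical mask of unpruned blocks; defaults to `gamma > 0`.
#'   Pruned blocks must have `gamma` exactly 0.
#' @return A `hyper_state` list.
#' @export
hyper_state <- function(gamma, B, sigma2,
                        block_group = rep(1L, length(gamma)),
                        active = gamma > 0) {
  gamma <- as.numeric(gamma)
  if (any(gamma < 0)) abort("`gamma` must be non-negative.")
  if (!is.list(B)) B <- list(B)
  if (sigma2 <= 0) abort("`sigma2` must be > 0.")
  block_group <- as.integer(block_group)
  if (length(block_group) != length(gamma)) abort("`block_group` length mismatch.")
  if (any(block_group < 1 | block_group > length(B))) abort("`block_group` out of range.")
  if (any(active & gamma == 0) || any(!active & gamma != 0)) {
    abort("pruned blocks must have gamma exactly 0 and active FALSE.")
  }
  structure(list(gamma = gamma, B = B, sigma2 = sigma2,
                 block_group = block_group, active = active),
            class = "hyper_state")
}

# block -> group lookup from a region_map, integer vector, or NULL
as_block_group <- function(regions, n_blocks) {
  if (is.null(regions)) return(rep(1L, n_blocks))
  if (inherits(regions, "region_map")) {
    if (length(regions$block_region) != n_blocks) {
      abort("region map covers a different number of channels than the data.")
    }
    return(regions$block_region)
  }
  bg <- as.integer(regions)
  if (length(bg) != n_blocks) abort("block-group vector has wrong length.")
  bg
}

#' Assemble the block-diagonal prior covariance over active coordinates
#'
#' The prior for the weight vector is zero-mean Gaussian with
#' block-diagonal covariance: block `b` contributes `gamma[b] * B[[g(b)]]`
#' where `g(b)` is the block's region/group. Pruned blocks contribute no
#' rows or columns.
#'
#' @param hyper A [hyper_state()].
#' @param structure A [block_structure()].
#' @param regions A `region_map`, an integer block->group vector, or `NULL`
#'   (all blocks share `hyper$B[[1]]`). Overrides `hyper$block_group` when
#'   given.
#' @return Dense block-diagonal matrix over the active coordinates.
#' @export
assemble_sigma0 <- function(hyper, structure, regions = NULL) {
  bg <- if (is.null(regions)) hyper$block_group
        else as_block_group(regions, structure$n_blocks)
  act <- which(hyper$active)
  sizes <- structure$block_sizes[act]
  D <- sum(sizes)
  out <- matrix(0, D, D)
  at <- 0L
  for (i in seq_along(act)) {
    b <- act[i]
    d <- structure$block_sizes[b]
    Bb <- hyper$B[[bg[b]]]
    if (!is.matrix(Bb) || nrow(Bb) != d || ncol(Bb) != d) {
      abort(sprintf("B matrix for block %d has dimension %s, expected %dx%d.",
                    b, paste(dim(Bb), collapse = "x"), d, d))
    }
    idx <- at + seq_len(d)
    out[idx, idx] <- hyper$gamma[b] * Bb
    at <- at + d
  }
  out
}

#' Posterior mean and covariance of the block-sparse weights
#'
#' Two algebraically equivalent routes to the Gaussian posterior
#' `N(mu_w, Sigma_w)` of the weights given data and prior. The direct form
#' inverts a `D x D` matrix and requires an invertible prior:
#' `Sigma_w = (X'X / sigma2 + Sigma0^-1)^-1`,
#' `mu_w = Sigma_w X' y / sigma2`.
#' The Woodbury form inverts an `N x N` matrix instead and never inverts
#' `Sigma0`, so it also covers priors with zero-variance blocks:
#' `Sigma_w = Sigma0 - Sigma0 X' (sigma2 I + X Sigma0 X')^-1 X Sigma0`,
#' `mu_w = Sigma0 X' (sigma2 I + X Sigma0 X')^-1 y`.
#'
#' @param X Design matrix (rows = stimuli, columns = active features).
#' @param y Response vector (+1/-1 labels).
#' @param Sigma0 Prior covariance (see [assemble_sigma0()]).
#' @param sigma2 Noise variance.
#' @return A `bsbl_posterior` list with elements `mu`, `Sigma`.
#' @export
posterior_direct <- function(X, y, Sigma0, sigma2) {
  check_posterior_inputs(X, y, Sigma0, sigma2)
  S0inv <- tryCatch(chol2inv(chol(Sigma0)), error = function(e) {
    d <- diag(Sigma0)
    abort(sprintf("prior covariance is singular (first zero-variance coordinate: %d); use posterior_woodbury().",
                  if (any(d == 0)) which(d == 0)[1] else NA_integer_))
  })
  A <- crossprod(X) / sigma2 + S0inv
  Sw <- chol2inv(chol(A))
  Sw <- (Sw + t(Sw)) / 2
  mu <- drop(Sw %*% crossprod(X, y)) / sigma2
  new_posterior(mu, Sw)
}

#' @rdname posterior_direct
#' @export
posterior_woodbury <- function(X, y, Sigma0, sigma2) {
  check_posterior_inputs(X, y, Sigma0, sigma2)
  S0Xt <- Sigma0 %*% t(X)
  M <- X %*% S0Xt
  diag(M) <- diag(M) + sigma2
  K <- chol2inv(chol(M))
  mu <- drop(S0Xt %*% (K %*% y))
  Sw <- Sigma0 - S0Xt %*% K %*% t(S0Xt)
  Sw <- (Sw + t(Sw)) / 2
  if (!all(is.finite(Sw)) || !all(is.finite(mu))) {
    abort("non-finite values in the Woodbury posterior update.")
  }
  new_posterior(mu, Sw)
}

new_posterior <- function(mu, Sigma, log_evidence = NULL) {
  structure(list(mu = mu, Sigma = Sigma, log_evidence = log_evidence),
            class = "bsbl_posterior")
}

check_posterior_inputs <- function(X, y, Sigma0, sigma2) {
  if (!all(is.finite(X)) || !all(is.finite(y))) abort("non-finite values in X or y.")
  if (length(y) != nrow(X)) abort("length(y) must equal nrow(X).")
  if (ncol(X) != nrow(Sigma0)) abort("ncol(X) must match dim(Sigma0).")
  if (sigma2 <= 0) abort("`sigma2` must be > 0.")
  invisible(TRUE)
}

#' Choose the posterior computation route by problem shape
#'
#' The direct form inverts a `D x D` matrix, the Woodbury form an `N x N`
#' one; picking direct when `N >= D` (active feature count) and Woodbury
#' otherwise means the matrix inverted is never larger than `min(N, D)`.
#'
#' @param n_samples Number of stimuli `N`.
#' @param n_active_features Current active feature count `D`.
#' @return `"direct"` or `"woodbury"`.
#' @export
choose_posterior_path <- function(n_samples, n_active_features) {
  stopifnot(n_samples > 0, n_active_features > 0)
  if (n_samples >= n_active_features) "direct" else "woodbury"
}

#' EM update of the noise variance
#'
#' `sigma2 = (||y - X mu_w||^2 + sigma2_old * (D - Tr(Sigma_w Sigma0^-1))) / N`
#' where `D` is the active feature count. The result is clamped below at
#' `floor` (with a warning) since at a perfect fit the update collapses to
#' zero.
#'
#' @param X,y Active design matrix and response.
#' @param posterior A `bsbl_posterior` computed under `Sigma0` and
#'   `sigma2_old`.
#' @param Sigma0 Prior covariance the posterior was computed under.
#' @param sigma2_old Previous noise variance.
#' @param floor Lower clamp.
#' @return Updated noise variance (scalar).
#' @export
update_sigma2 <- function(X, y, posterior, Sigma0, sigma2_old, floor = 1e-10) {
  n <- length(y)
  resid <- y - drop(X %*% posterior$mu)
  tr <- sum(diag(solve(Sigma0, posterior$Sigma)))
  d_active <- ncol(Sigma0)
  s2 <- (sum(resid^2) + sigma2_old * (d_active - tr)) / n
  if (!is.finite(s2) || s2 < floor) {
    warn(sprintf("noise variance update %.3g clamped to floor %.3g.", s2, floor))
    s2 <- floor
  }
  s2
}

#' EM update of the per-block relevance scales
#'
#' `gamma_b = Tr[B_b^-1 (Sigma_w^b + mu_w^b mu_w^b')] / d_b` for each
#' active block; pruned blocks keep `gamma = 0`.
#'
#' @param posterior A `bsbl_posterior` over the active coordinates.
#' @param hyper Current [hyper_state()] (provides `B` and the active mask).
#' @param structure Block structure of the full problem.
#' @param regions Region map / block-group vector (see
#'   [assemble_sigma0()]).
#' @return Updated full-length `gamma` vector.
#' @export
update_gamma <- function(posterior, hyper, structure, regions = NULL) {
  bg <- if (is.null(regions)) hyper$block_group
        else as_block_group(regions, structure$n_blocks)
  act <- which(hyper$active)
  gamma <- hyper$gamma
  at <- 0L
  for (b in act) {
    d <- structure$block_sizes[b]
    idx <- at + seq_len(d)
    Bb <- hyper$B[[bg[b]]]
    Binv <- tryCatch(chol2inv(chol(Bb)), error = function(e) {
      abort(sprintf("correlation matrix of group %d is singular.", bg[b]))
    })
    Sb <- posterior$Sigma[idx, idx, drop = FALSE]
    mb <- posterior$mu[idx]
    gamma[b] <- sum(Binv * (Sb + tcrossprod(mb))) / d
    at <- at + d
  }
  pmax(gamma, 0)
}

#' EM update of the intra-block correlation matrices
#'
#' For each group (region) the raw update averages the normalized
#' second-moment matrices of its active blocks:
#' `B_re = (1/g_re) * sum_{b in G_re} (Sigma_w^b + mu_w^b mu_w^b') / gamma_b`,
#' where `g_re` counts the blocks actually entering the average. A group
#' whose blocks are all pruned keeps its previous matrix. Grouping follows
#' `b_mode`: `"identity"` skips the update, `"shared"` pools all active
#' blocks, `"per_block"` gives every block its own matrix, `"regional"`
#' uses the supplied region map.
#'
#' @inheritParams update_gamma
#' @param gamma Relevance scales to normalize by (typically the
#'   same-iteration update).
#' @param b_mode Correlation mode (see [fit_config()]).
#' @return List of raw (unconstrained) symmetric matrices, one per group.
#' @export
update_B <- function(posterior, hyper, structure, regions = NULL,
                     b_mode = "regional", gamma = hyper$gamma) {
  if (b_mode == "identity") return(hyper$B)
  n_b <- structure$n_blocks
  bg <- switch(b_mode,
    shared = rep(1L, n_b),
    per_block = seq_len(n_b),
    regional = as_block_group(regions, n_b),
    abort(sprintf("unknown b_mode '%s'.", b_mode))
  )
  n_groups <- max(bg)
  acc <- vector("list", n_groups)
  cnt <- integer(n_groups)
  act <- which(hyper$active)
  at <- 0L
  for (b in act) {
    d <- structure$block_sizes[b]
    idx <- at + seq_len(d)
    g <- bg[b]
    if (gamma[b] > 0) {
      contrib <- (posterior$Sigma[idx, idx, drop = FALSE] +
                    tcrossprod(posterior$mu[idx])) / gamma[b]
      acc[[g]] <- if (is.null(acc[[g]])) contrib else acc[[g]] + contrib
      cnt[g] <- cnt[g] + 1L
    }
    at <- at + d
  }
  out <- vector("list", n_groups)
  for (g in seq_len(n_groups)) {
    if (cnt[g] > 0) {
      Bg <- acc[[g]] / cnt[g]
      out[[g]] <- (Bg + t(Bg)) / 2
    } else {
      # every block of the group pruned: freeze the previous matrix
      prev <- if (length(hyper$B) >= g) hyper$B[[g]] else NULL
      out[[g]] <- prev %||% diag(structure$block_sizes[1])
    }
  }
  out
}

#' Constrain a raw correlation matrix to AR(1) Toeplitz form
#'
#' The empirical AR(1) coefficient is `r = m1 / m0` with `m0` the mean of
#' the main diagonal and `m1` the mean of the first sub-diagonal; `r` is
#' clipped to `[-ar_clamp, ar_clamp]` and the constrained matrix is
#' `Toeplitz(1, r, r^2, ..., r^(d-1))`, symmetric positive definite for
#' `|r| < 1`. A non-positive `m0` falls back to the identity.
#'
#' @param B_raw Square symmetric matrix (the raw group average).
#' @param ar_clamp Bound on `|r|` in (0, 1).
#' @return Constrained Toeplitz matrix of the same dimension.
#' @export
toeplitz_constrain <- function(B_raw, ar_clamp = 0.98) {
  d <- nrow(B_raw)
  if (d == 1) return(matrix(1, 1, 1))
  m0 <- mean(diag(B_raw))
  if (!is.finite(m0) || m0 <= 0) {
    warn("non-positive diagonal mean in correlation update; using identity.")
    return(diag(d))
  }
  m1 <- mean(B_raw[cbind(2:d, 1:(d - 1))])
  r <- max(-ar_clamp, min(ar_clamp, m1 / m0))
  stats::toeplitz(r^(0:(d - 1)))
}

#' Prune low-relevance blocks
#'
#' Among active blocks with `gamma < tau`, at most `max_prune_per_iter`
#' are pruned per call -- those with the smallest `gamma`, ties broken by
#' lower block index. Pruned blocks get `gamma` exactly 0 and leave the
#' active set permanently.
#'
#' @param hyper A [hyper_state()].
#' @param tau Shear threshold.
#' @param max_prune_per_iter Per-call pruning cap (default 5).
#' @return The updated `hyper_state`, with an integer attribute `"pruned"`
#'   listing the block indices pruned by this call (in pruning order).
#' @export
prune_blocks <- function(hyper, tau, max_prune_per_iter = 5L) {
  stopifnot(tau > 0)
  cand <- which(hyper$active & hyper$gamma < tau)
  if (length(cand)) {
    ord <- cand[order(hyper$gamma[cand], cand)]
    ord <- head(ord, max_prune_per_iter)
    hyper$gamma[ord] <- 0
    hyper$active[ord] <- FALSE
  } else {
    ord <- integer(0)
  }
  attr(hyper, "pruned") <- ord
  hyper
}
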
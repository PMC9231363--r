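#' Fit the regionally smoothed block-sparse Bayesian model by EM
#'
#' Iterates: posterior of the weights over the currently active channel
#' blocks (direct or Woodbury route, whichever inverts the smaller matrix),
#' then EM updates of the noise variance, the per-channel relevance scales
#' `gamma` and the per-region intra-block correlation matrices `B`
#' (constrained to AR(1) Toeplitz form), then pruning of up to
#' `max_prune_per_iter` blocks whose `gamma` fell below the shear
#' threshold `tau`. Pruned coordinates are physically removed from the
#' problem, so the matrix inverted shrinks as channels drop out. The loop
#' stops when the relative L2 change of the `gamma` vector falls below
#' `tol` with no block pruned in that iteration, or at `max_iter`.
#'
#' Within one iteration the noise variance is updated from the previous
#' iteration's prior, `gamma` from the previous iteration's `B`, and `B`
#' from the same-iteration `gamma` -- the natural EM ordering for this
#' model.
#'
#' @param data An [epoch_dataset()].
#' @param regions A `region_map` over the data's channels (required for
#'   `b_mode = "regional"`; ignored by the other modes).
#' @param config A [fit_config()].
#' @return A `bsbl_fit` object: full-length `gamma`, `active` mask,
#'   posterior mean `mu` (full length, zeros on pruned coordinates),
#'   per-block posterior covariance blocks, constrained `B` list,
#'   `sigma2`, `removal_order` (channel indices in pruning order),
#'   `converged` flag, and a per-iteration `trace` tibble.
#' @examples
#' sim <- gen_block_sparse(block_sparse_spec(
#'   n_blocks = 12, block_size = 4, n_active_blocks = 3,
#'   n_samples = 120, seed = 1))
#' fit <- em_fit(sim$data, region_map_chunks(sim$data$channel_names, 4),
#'               fit_config(tau = 1e-2))
#' which(fit$gamma > 1e-2)
#' @export
em_fit <- function(data, regions = NULL, config = fit_config()) {
  stopifnot(inherits(data, "epoch_dataset"), inherits(config, "fit_config"))
  st <- data$structure
  n_b <- st$n_blocks
  X <- data$features
  y <- data$labels
  n <- nrow(X)
  if (config$center) {
    X <- sweep(X, 2, colMeans(X))
    y <- y - mean(y)
  }

  block_group <- switch(config$b_mode,
    identity  = rep(1L, n_b),
    shared    = rep(1L, n_b),
    per_block = seq_len(n_b),
    regional  = {
      if (is.null(regions)) abort("b_mode = 'regional' needs a region map.")
      as_block_group(regions, n_b)
    }
  )
  n_groups <- max(block_group)
  if (length(unique(st$block_sizes)) != 1) {
    # shared/regional averaging assumes equal block sizes, the EEG case
    if (config$b_mode %in% c("shared", "regional")) {
      abort("shared/regional correlation requires equal block sizes.")
    }
  }

  gamma <- rep(1, n_b)
  active <- rep(TRUE, n_b)
  B <- lapply(seq_len(n_groups), function(g) {
    diag(st$block_sizes[which(block_group == g)[1]])
  })
  sigma2 <- max(0.1 * stats::var(y), config$sigma2_floor)

  removal_order <- integer(0)
  trace_rows <- vector("list", config$max_iter)
  converged <- FALSE
  it <- 0L

  repeat {
    it <- it + 1L
    act <- which(active)
    if (!length(act)) break
    cols <- unlist(lapply(act, function(b) block_cols(st, b)))
    Xa <- X[, cols, drop = FALSE]
    d_act <- st$block_sizes[act]
    d_total <- length(cols)
    path <- choose_posterior_path(n, d_total)

    Binv <- lapply(B, function(Bg) chol2inv(chol(Bg)))
    post <- posterior_blocks(Xa, y, act, d_act, gamma, B, Binv,
                             block_group, sigma2, path)

    # noise variance (Eq-13 style; D = active feature count after pruning)
    resid2 <- sum((y - drop(Xa %*% post$mu))^2)
    sigma2_new <- (resid2 + sigma2 * (d_total - post$tr_SwS0inv)) / n
    if (!is.finite(sigma2_new) || sigma2_new < config$sigma2_floor) {
      sigma2_new <- config$sigma2_floor
    }

    # gamma from the previous iteration's (constrained) B
    gamma_new <- gamma
    for (i in seq_along(act)) {
      b <- act[i]
      M2 <- post$Sigma_blocks[[i]] + tcrossprod(post$mu_blocks[[i]])
      gamma_new[b] <- max(0, sum(Binv[[block_group[b]]] * M2) / d_act[i])
    }

    # B from the same-iteration gamma, then the AR(1) Toeplitz constraint
    if (config$b_mode != "identity") {
      acc <- vector("list", n_groups)
      cnt <- integer(n_groups)
      for (i in seq_along(act)) {
        b <- act[i]
        g <- block_group[b]
        if (gamma_new[b] > 0) {
          contrib <- (post$Sigma_blocks[[i]] +
                        tcrossprod(post$mu_blocks[[i]])) / gamma_new[b]
          acc[[g]] <- if (is.null(acc[[g]])) contrib else acc[[g]] + contrib
          cnt[g] <- cnt[g] + 1L
        }
      }
      for (g in seq_len(n_groups)) {
        if (cnt[g] > 0) {
          B[[g]] <- toeplitz_constrain(acc[[g]] / cnt[g], config$ar_clamp)
        } # empty group: keep previous matrix
      }
    }

    rel_change <- sqrt(sum((gamma_new[act] - gamma[act])^2)) /
      max(sqrt(sum(gamma[act]^2)), .Machine$double.eps)

    # prune: smallest sub-threshold gammas first, at most the cap, ties by index
    cand <- act[gamma_new[act] < config$tau]
    pruned <- integer(0)
    if (length(cand)) {
      pruned <- head(cand[order(gamma_new[cand], cand)], config$max_prune_per_iter)
      gamma_new[pruned] <- 0
      active[pruned] <- FALSE
      removal_order <- c(removal_order, pruned)
    }

    trace_rows[[it]] <- tibble(
      iteration = it, path = path, sigma2 = sigma2_new,
      n_active = sum(active), rel_change = rel_change,
      log_evidence = post$log_evidence,
      pruned = list(pruned), gamma = list(gamma_new)
    )

    gamma <- gamma_new
    sigma2 <- sigma2_new

    if (!any(active)) {
      abort(paste0("degenerate selection: every channel was pruned. ",
                   "Lower `tau` (or raise the data scale) and refit."))
    }
    if (rel_change < config$tol && length(pruned) == 0) { converged <- TRUE; break }
    if (it >= config$max_iter) break
  }

  # final posterior under the final hyperparameters (for weights/selection)
  act <- which(active)
  cols <- unlist(lapply(act, function(b) block_cols(st, b)))
  Xa <- X[, cols, drop = FALSE]
  d_act <- st$block_sizes[act]
  path <- choose_posterior_path(n, length(cols))
  Binv <- lapply(B, function(Bg) chol2inv(chol(Bg)))
  post <- posterior_blocks(Xa, y, act, d_act, gamma, B, Binv,
                           block_group, sigma2, path)
  mu_full <- numeric(st$n_features)
  mu_full[cols] <- post$mu

  structure(
    list(
      gamma = gamma, active = active, sigma2 = sigma2,
      B = B, block_group = block_group, b_mode = config$b_mode,
      mu = mu_full, mu_active = post$mu, Sigma_blocks = post$Sigma_blocks,
      active_cols = cols, removal_order = removal_order,
      converged = converged, n_iter = it,
      log_evidence = post$log_evidence,
      trace = dplyr::bind_rows(trace_rows[seq_len(it)]),
      structure = st, channel_names = data$channel_names,
      region_name = if (inherits(regions, "region_map")) regions$name else config$b_mode,
      config = config, n_samples = n
    ),
    class = "bsbl_fit"
  )
}

#' @export
print.bsbl_fit <- function(x, ...) {
  cat("<bsbl_fit> ", sum(x$active), "/", x$structure$n_blocks,
      " channels active after ", x$n_iter, " iterations (",
      if (x$converged) "converged" else "max_iter reached",
      "), sigma2 = ", signif(x$sigma2, 4),
      ", b_mode = ", x$b_mode, "\n", sep = "")
  invisible(x)
}

# Posterior mean plus per-block diagonal covariance blocks, by either
# route. All EM updates need only the diagonal blocks of Sigma_w, so the
# full D x D covariance is never formed here (the exported
# posterior_direct/posterior_woodbury return the full matrix).
posterior_blocks <- function(Xa, y, act, d_act, gamma, B, Binv,
                             block_group, sigma2, path) {
  n <- nrow(Xa)
  d_total <- ncol(Xa)
  ends <- cumsum(d_act)
  starts <- ends - d_act + 1L
  idx_of <- function(i) starts[i]:ends[i]

  if (path == "direct") {
    A <- crossprod(Xa) / sigma2
    logdet_S0 <- 0
    for (i in seq_along(act)) {
      b <- act[i]
      idx <- idx_of(i)
      A[idx, idx] <- A[idx, idx] + Binv[[block_group[b]]] / gamma[b]
      logdet_S0 <- logdet_S0 + d_act[i] * log(gamma[b]) +
        determinant(B[[block_group[b]]], logarithm = TRUE)$modulus
    }
    cA <- chol(A)
    Sw <- chol2inv(cA)
    Sw <- (Sw + t(Sw)) / 2
    Xty <- crossprod(Xa, y)
    mu <- drop(Sw %*% Xty) / sigma2
    Sigma_blocks <- lapply(seq_along(act), function(i) Sw[idx_of(i), idx_of(i), drop = FALSE])
    mu_blocks <- lapply(seq_along(act), function(i) mu[idx_of(i)])
    tr <- 0
    for (i in seq_along(act)) {
      b <- act[i]
      tr <- tr + sum(Binv[[block_group[b]]] * Sigma_blocks[[i]]) / gamma[b]
    }
    # log evidence via logdet(C) = logdet(Sigma0) + logdet(A) + N log sigma2
    logdet_A <- 2 * sum(log(diag(cA)))
    quad <- (sum(y^2) - sum(Xty * mu)) / sigma2
    log_ev <- -0.5 * (n * log(2 * pi) + logdet_S0 + logdet_A +
                        n * log(sigma2) + quad)
  } else {
    S0Xt <- matrix(0, d_total, n)
    for (i in seq_along(act)) {
      b <- act[i]
      idx <- idx_of(i)
      S0Xt[idx, ] <- (gamma[b] * B[[block_group[b]]]) %*% t(Xa[, idx, drop = FALSE])
    }
    M <- Xa %*% S0Xt
    diag(M) <- diag(M) + sigma2
    cM <- chol(M)
    K <- chol2inv(cM)
    Ky <- drop(K %*% y)
    mu <- drop(S0Xt %*% Ky)
    KS <- K %*% t(S0Xt)            # N x D
    Sigma_blocks <- vector("list", length(act))
    tr <- 0
    for (i in seq_along(act)) {
      b <- act[i]
      idx <- idx_of(i)
      Sb <- gamma[b] * B[[block_group[b]]] -
        S0Xt[idx, , drop = FALSE] %*% KS[, idx, drop = FALSE]
      Sb <- (Sb + t(Sb)) / 2
      Sigma_blocks[[i]] <- Sb
      tr <- tr + sum(Binv[[block_group[b]]] * Sb) / gamma[b]
    }
    mu_blocks <- lapply(seq_along(act), function(i) mu[idx_of(i)])
    log_ev <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(cM))) + sum(y * Ky))
  }
  if (!all(is.finite(mu))) abort("non-finite posterior mean in EM iteration.")
  list(mu = mu, mu_blocks = mu_blocks, Sigma_blocks = Sigma_blocks,
       tr_SwS0inv = tr, log_evidence = as.numeric(log_ev))
}
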
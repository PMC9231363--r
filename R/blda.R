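#' Bayesian linear discriminant analysis
#'
#' The downstream classifier of the P300 pipeline: Bayesian linear
#' regression on class-balanced targets (`+N/N1` for targets, `-N/N2` for
#' non-targets) with a zero-mean Gaussian prior on the weights. The prior
#' precision `alpha` and the noise precision `beta` are estimated by
#' evidence maximization (MacKay fixed-point updates), so no
#' regularization parameter needs hand-tuning. Features and targets are
#' centered internally; the bias is recovered from the means. Fitting is
#' fully deterministic.
#'
#' @param features Numeric matrix, one row per stimulus.
#' @param labels Vector in `{+1, -1}` (or `{1, 0}`), both classes present.
#' @param prior `"isotropic"` (one `alpha` for all weights, the default)
#'   or `"ard"` (one precision per feature).
#' @param tol Relative-change convergence tolerance for the
#'   hyperparameters.
#' @param max_iter Maximum fixed-point iterations.
#' @return A `blda_model` with fields `weights`, `bias`, `alpha`, `beta`,
#'   `n_iter`, `converged`.
#' @examples
#' x <- rbind(matrix(rnorm(40, 1), 20), matrix(rnorm(40, -1), 20))
#' m <- blda_fit(x, rep(c(1, -1), each = 20))
#' table(sign(blda_score(m, x)), rep(c(1, -1), each = 20))
#' @export
blda_fit <- function(features, labels, prior = c("isotropic", "ard"),
                     tol = 1e-6, max_iter = 500L) {
  prior <- match.arg(prior)
  X <- as.matrix(features)
  labels <- as.numeric(labels)
  if (all(labels %in% c(0, 1))) labels <- ifelse(labels == 1, 1, -1)
  if (!all(labels %in% c(-1, 1))) abort("labels must be {+1,-1} or {1,0}.")
  n <- nrow(X)
  n1 <- sum(labels == 1); n2 <- sum(labels == -1)
  if (n1 == 0 || n2 == 0) abort("both classes must be present.")
  t_vec <- ifelse(labels == 1, n / n1, -n / n2)

  xm <- colMeans(X)
  tm <- mean(t_vec)
  Xc <- sweep(X, 2, xm)
  tc <- t_vec - tm

  beta <- 1 / max(stats::var(tc), 1e-12)
  converged <- FALSE

  if (prior == "isotropic") {
    sv <- svd(Xc, nu = min(n, ncol(X)), nv = min(n, ncol(X)))
    d2 <- sv$d^2
    Uty <- drop(crossprod(sv$u, tc))
    alpha <- 1
    it <- 0L
    repeat {
      it <- it + 1L
      coef <- sv$d * beta / (beta * d2 + alpha)   # V-space coefficients
      w_v <- coef * Uty
      w <- drop(sv$v %*% w_v)
      gamma_eff <- sum(beta * d2 / (beta * d2 + alpha))
      resid2 <- sum((tc - drop(Xc %*% w))^2)
      alpha_new <- gamma_eff / max(sum(w^2), 1e-300)
      beta_new <- max(n - gamma_eff, 1e-12) / max(resid2, 1e-300)
      rel <- abs(alpha_new - alpha) / alpha + abs(beta_new - beta) / beta
      alpha <- alpha_new; beta <- beta_new
      if (rel < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
    }
    coef <- sv$d * beta / (beta * d2 + alpha)
    w <- drop(sv$v %*% (coef * Uty))
  } else {
    p <- ncol(X)
    alpha <- rep(1, p)
    XtX <- crossprod(Xc)
    Xty <- drop(crossprod(Xc, tc))
    it <- 0L
    w <- numeric(p)
    repeat {
      it <- it + 1L
      A <- beta * XtX
      diag(A) <- diag(A) + alpha
      Sigma <- chol2inv(chol(A))
      w <- beta * drop(Sigma %*% Xty)
      g <- 1 - alpha * diag(Sigma)
      resid2 <- sum((tc - drop(Xc %*% w))^2)
      alpha_new <- pmin(g / pmax(w^2, 1e-300), 1e12)
      beta_new <- max(n - sum(g), 1e-12) / max(resid2, 1e-300)
      rel <- sum(abs(alpha_new - alpha)) / sum(alpha) + abs(beta_new - beta) / beta
      alpha <- alpha_new; beta <- beta_new
      if (rel < tol) { converged <- TRUE; break }
      if (it >= max_iter) break
    }
  }

  structure(
    list(weights = w, bias = tm - sum(w * xm), alpha = alpha, beta = beta,
         prior = prior, n_features = ncol(X), n_iter = it,
         converged = converged),
    class = "blda_model"
  )
}

#' @rdname blda_fit
#' @param model A fitted `blda_model`.
#' @return `blda_score()`: numeric score per row, higher = more
#'   target-like.
#' @export
blda_score <- function(model, features) {
  stopifnot(inherits(model, "blda_model"))
  X <- as.matrix(features)
  if (ncol(X) != model$n_features) {
    abort(sprintf("model expects %d features, got %d.", model$n_features, ncol(X)))
  }
  drop(X %*% model$weights) + model$bias
}

#' @export
predict.blda_model <- function(object, newdata, ...) blda_score(object, newdata)

#' @export
print.blda_model <- function(x, ...) {
  cat("<blda_model> ", x$n_features, " features, ", x$prior, " prior, ",
      "beta = ", signif(x$beta, 4), ", ", x$n_iter, " iterations\n", sep = "")
  invisible(x)
}

#' @describeIn tidy.bsbl_fit One row per weight of a BLDA model.
#' @export
tidy.blda_model <- function(x, ...) {
  tibble(term = c(paste0("w", seq_len(x$n_features)), "bias"),
         estimate = c(x$weights, x$bias))
}

#' @describeIn glance.bsbl_fit One-row summary of a BLDA model.
#' @export
glance.blda_model <- function(x, ...) {
  tibble(n_features = x$n_features, prior = x$prior,
         alpha = if (length(x$alpha) == 1) x$alpha else NA_real_,
         beta = x$beta, n_iter = x$n_iter, converged = x$converged)
}

#' Serialize / restore a BLDA model
#'
#' Writes the model as a versioned JSON file (plain text, round-trips to
#' full double precision).
#'
#' @param model A `blda_model`.
#' @param path Output path.
#' @return `read_blda()` returns the restored model.
#' @export
write_blda <- function(model, path) {
  obj <- unclass(model)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_blda
#' @export
read_blda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    abort("unrecognized BLDA model file version.")
  }
  obj$format_version <- NULL
  structure(obj, class = "blda_model")
}
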
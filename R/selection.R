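#' Channel selection from a fitted block-sparse model
#'
#' `select_auto()` keeps the channels whose final relevance scale exceeds
#' the shear threshold (`gamma > tau`) and attaches the posterior-mean
#' weights restricted to those channels; relevance drives the keep/prune
#' decision, while the per-channel importance score (sum of absolute
#' weights) drives rankings.
#'
#' @param fit A [em_fit()] result.
#' @param tau Shear threshold; defaults to the one the model was fitted
#'   with.
#' @return A `channel_selection` object with fields `selected` (channel
#'   indices), `importance` (length `N_c`), `weights` (full-length sparse
#'   weight vector, nonzero only on selected channels), `removal_order`,
#'   `channel_names`, `tau`.
#' @examples
#' sim <- gen_block_sparse(block_sparse_spec(
#'   n_blocks = 12, block_size = 4, n_active_blocks = 3,
#'   n_samples = 120, seed = 1))
#' fit <- em_fit(sim$data, region_map_chunks(sim$data$channel_names, 4))
#' sel <- select_auto(fit)
#' sel$selected
#' @export
select_auto <- function(fit, tau = fit$config$tau) {
  stopifnot(inherits(fit, "bsbl_fit"))
  selected <- which(fit$active & fit$gamma > tau)
  if (!length(selected)) {
    abort("no channel satisfies gamma > tau; lower `tau` and reselect.")
  }
  st <- fit$structure
  weights <- numeric(st$n_features)
  sel_cols <- unlist(lapply(selected, function(b) block_cols(st, b)))
  weights[sel_cols] <- fit$mu[sel_cols]
  importance <- channel_importance(fit$mu, st)
  importance[!fit$active] <- 0
  structure(
    list(selected = selected, importance = importance, weights = weights,
         removal_order = fit$removal_order,
         channel_names = fit$channel_names, tau = tau,
         structure = st),
    class = "channel_selection"
  )
}

#' @export
print.channel_selection <- function(x, ...) {
  cat("<channel_selection> ", length(x$selected), "/",
      length(x$channel_names), " channels (tau = ", format(x$tau), "): ",
      paste(x$channel_names[x$selected], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-channel importance: sum of absolute feature weights
#'
#' `score_c = sum_t |w_{c,t}|` over the channel's block of the weight
#' vector; channels with no weight (pruned) score zero. This is the
#' ranking statistic used for fixed-M selection and for thresholding
#' dense-weight baselines.
#'
#' @param weights Full-length weight vector (channel-major).
#' @param structure The [block_structure()].
#' @return Non-negative numeric vector of length `n_blocks`.
#' @export
channel_importance <- function(weights, structure) {
  vapply(seq_len(structure$n_blocks), function(b) {
    sum(abs(weights[block_cols(structure, b)]))
  }, numeric(1))
}

#' Fixed-size channel subsets with backfill
#'
#' Returns exactly `M` channels. If the automatic selection kept at least
#' `M`, the top `M` by importance are returned (descending, ties by lower
#' channel index). If it kept only `M' < M`, the selection is topped up
#' with the last-pruned `M - M'` channels in reverse pruning order (the
#' most recently deleted first).
#'
#' @param selection A [select_auto()] result.
#' @param m Number of channels to return (`1 <= m <= N_c`).
#' @return Integer vector of channel indices, length `m`.
#' @export
select_top_m <- function(selection, m) {
  stopifnot(inherits(selection, "channel_selection"))
  n_c <- length(selection$channel_names)
  m <- as.integer(m)
  if (m < 1 || m > n_c) abort(sprintf("`m` must be in [1, %d].", n_c))
  sel <- selection$selected
  if (length(sel) >= m) {
    ord <- sel[order(-selection$importance[sel], sel)]
    head(ord, m)
  } else {
    backfill <- rev(selection$removal_order)
    need <- m - length(sel)
    if (need > length(backfill)) {
      abort("not enough pruned channels to backfill to `m`.")
    }
    c(sel, head(backfill, need))
  }
}

#' Mean-minus-half-SD thresholding of an importance vector
#'
#' The automatic-selection rule used for dense-weight baselines (LASSO- or
#' SBL-style importance vectors): keep channels whose importance reaches
#' `mean(importance) - 0.5 * sd(importance)`. Scores exactly at the
#' threshold are kept, so a constant importance vector selects every
#' channel.
#'
#' @param importance Non-negative numeric vector, one score per channel.
#' @return Integer vector of selected channel indices.
#' @export
baseline_auto_threshold <- function(importance) {
  thr <- mean(importance) - 0.5 * sd(importance)
  which(importance >= thr)
}

#' @describeIn tidy.bsbl_fit Per-channel table for a selection: channel,
#'   importance, selected flag and removal rank (NA if never pruned).
#' @export
tidy.channel_selection <- function(x, ...) {
  n_c <- length(x$channel_names)
  removal_rank <- rep(NA_integer_, n_c)
  removal_rank[x$removal_order] <- seq_along(x$removal_order)
  tibble(
    channel = x$channel_names,
    channel_index = seq_len(n_c),
    importance = x$importance,
    selected = seq_len(n_c) %in% x$selected,
    removal_rank = removal_rank
  )
}

#' Write a selection to plain text
#'
#' Writes a table (channel, importance, selected, removal_rank) as CSV and
#' optionally the bare list of selected channel names, one per line.
#'
#' @param selection A [select_auto()] result.
#' @param path CSV output path.
#' @param names_path Optional path for the one-name-per-line list.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path, names_path = NULL) {
  write.csv(tidy(selection), path, row.names = FALSE)
  if (!is.null(names_path)) {
    writeLines(selection$channel_names[selection$selected], names_path)
  }
  invisible(path)
}
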
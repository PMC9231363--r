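#' Block structure of a flattened channel-by-time feature vector
#'
#' Epoched P300 features are stored channel-major: the weight vector over
#' `D = n_channels * n_time` features splits into one block per channel,
#' each holding that channel's `n_time` consecutive coefficients. The block
#' structure records the split so the BSBL engine can address per-channel
#' blocks of the posterior.
#'
#' @param n_blocks Number of blocks (channels).
#' @param block_size Number of features per block (time points per channel).
#'   Either a scalar (all blocks equal, the EEG case) or a vector of length
#'   `n_blocks`.
#' @return An object of class `block_structure` with fields `n_blocks`,
#'   `block_sizes` and zero-based `offsets` into the flattened vector.
#' @examples
#' block_structure(3, 4)
#' @export
block_structure <- function(n_blocks, block_size) {
  stopifnot(is.numeric(n_blocks), length(n_blocks) == 1, n_blocks >= 1)
  n_blocks <- as.integer(n_blocks)
  sizes <- as.integer(if (length(block_size) == 1) rep(block_size, n_blocks) else block_size)
  if (length(sizes) != n_blocks || any(sizes < 1)) {
    abort("`block_size` must be a positive scalar or a vector of length `n_blocks`.")
  }
  offsets <- c(0L, cumsum(sizes)[-n_blocks])
  structure(
    list(n_blocks = n_blocks, block_sizes = sizes, offsets = offsets,
         n_features = sum(sizes)),
    class = "block_structure"
  )
}

#' @export
print.block_structure <- function(x, ...) {
  cat("<block_structure> ", x$n_blocks, " blocks, ",
      x$n_features, " features\n", sep = "")
  invisible(x)
}

# column indices of block b in the flattened feature vector
block_cols <- function(structure, b) {
  structure$offsets[b] + seq_len(structure$block_sizes[b])
}

#' Labelled epoched feature set for BSBL fitting
#'
#' Bundles the `N x D` per-stimulus feature matrix (one row per stimulus,
#' channel-major column order), the +1/-1 target labels and the
#' channel-block structure. Labels coded `{1, 0}` (target / non-target, the
#' convention of speller datasets) are mapped to `{+1, -1}`.
#'
#' @param features Numeric matrix, one row per stimulus.
#' @param labels Numeric vector in `{+1, -1}` (or `{1, 0}`, which is
#'   recoded) with one entry per row of `features`.
#' @param channel_names Character vector of channel names; its length fixes
#'   the number of blocks.
#' @param n_time Time points per channel; `ncol(features)` must equal
#'   `length(channel_names) * n_time`.
#' @return An `epoch_dataset` object.
#' @export
epoch_dataset <- function(features, labels, channel_names, n_time) {
  features <- as.matrix(features)
  if (!is.numeric(features) || anyNA(features) || !all(is.finite(features))) {
    abort("`features` must be a finite numeric matrix.")
  }
  labels <- as.numeric(labels)
  if (anyNA(labels) || !all(is.finite(labels))) abort("`labels` must be finite.")
  if (length(labels) != nrow(features)) {
    abort(sprintf("%d labels for %d feature rows.", length(labels), nrow(features)))
  }
  if (all(labels %in% c(0, 1))) labels <- ifelse(labels == 1, 1, -1)
  if (!all(labels %in% c(-1, 1))) {
    abort("`labels` must be coded {+1, -1} (or {1, 0}).")
  }
  n_time <- as.integer(n_time)
  structure_ <- block_structure(length(channel_names), n_time)
  if (structure_$n_features != ncol(features)) {
    abort(sprintf(
      "feature dimension %d != %d channels x %d time points.",
      ncol(features), length(channel_names), n_time
    ))
  }
  structure(
    list(features = features, labels = labels, structure = structure_,
         channel_names = as.character(channel_names), n_time = n_time),
    class = "epoch_dataset"
  )
}

#' @export
print.epoch_dataset <- function(x, ...) {
  cat("<epoch_dataset> ", nrow(x$features), " stimuli (",
      sum(x$labels == 1), " target), ",
      x$structure$n_blocks, " channels x ", x$n_time, " time points\n", sep = "")
  invisible(x)
}

#' @export
dim.epoch_dataset <- function(x) dim(x$features)

#' Restrict an epoch dataset to a subset of channels
#'
#' @param data An [epoch_dataset()].
#' @param channels Integer channel indices (or channel names) to keep, in
#'   the given order.
#' @return A new `epoch_dataset` over the kept channels.
#' @export
subset_channels <- function(data, channels) {
  stopifnot(inherits(data, "epoch_dataset"))
  if (is.character(channels)) {
    idx <- match(channels, data$channel_names)
    if (anyNA(idx)) abort(paste0("unknown channels: ",
                                 paste(channels[is.na(idx)], collapse = ", ")))
  } else {
    idx <- as.integer(channels)
    if (any(idx < 1 | idx > data$structure$n_blocks)) abort("channel index out of range.")
  }
  cols <- unlist(lapply(idx, function(b) block_cols(data$structure, b)))
  epoch_dataset(data$features[, cols, drop = FALSE], data$labels,
                data$channel_names[idx], data$n_time)
}
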
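#' Pre-process a continuous multichannel recording into epoched features
#'
#' Zero-phase band-pass filtering (4th-order Butterworth, forward-backward
#' so no phase distortion), integer decimation, and per-stimulus window
#' extraction. The band must stay below the post-decimation Nyquist
#' frequency (the band-pass acts as the anti-alias filter). Each stimulus
#' yields one channel-major feature row of `n_channels * n_time` values;
#' with the defaults a 240 Hz recording decimated by 5 and windowed
#' 0-667 ms gives 32 points per channel, and a 250-to-50 Hz pipeline with
#' a 0-600 ms window gives 30.
#'
#' @param raw Numeric matrix, samples x channels, at `sampling_rate` Hz.
#' @param sampling_rate Input sampling rate in Hz.
#' @param onsets Stimulus onset sample indices (1-based, original rate).
#' @param labels Per-stimulus labels, `{+1,-1}` or `{1,0}`.
#' @param channel_names Channel names (defaults to `Ch1..`).
#' @param band Band-pass edges in Hz (default 0.5-20).
#' @param decim Integer decimation factor (default 5).
#' @param window Analysis window `[start, end)` in seconds after onset
#'   (default `c(0, 0.667)`).
#' @param filter_order Butterworth order (default 4).
#' @return An [epoch_dataset()].
#' @export
preprocess <- function(raw, sampling_rate, onsets, labels,
                       channel_names = NULL, band = c(0.5, 20),
                       decim = 5L, window = c(0, 0.667), filter_order = 4L) {
  raw <- as.matrix(raw)
  n_c <- ncol(raw)
  channel_names <- channel_names %||% paste0("Ch", seq_len(n_c))
  decim <- as.integer(decim)
  fs_new <- sampling_rate / decim
  if (band[2] >= fs_new / 2) {
    abort(sprintf("band edge %.3g Hz is not below the post-decimation Nyquist %.3g Hz.",
                  band[2], fs_new / 2))
  }
  bf <- signal::butter(filter_order, band / (sampling_rate / 2), type = "pass")
  filtered <- apply(raw, 2, function(ch) signal::filtfilt(bf, ch))
  dec <- filtered[seq(1, nrow(filtered), by = decim), , drop = FALSE]

  off0 <- floor(window[1] * fs_new)
  n_t <- floor(window[2] * fs_new) - off0
  if (n_t < 1) abort("analysis window is empty at the decimated rate.")
  features <- matrix(0, length(onsets), n_c * n_t)
  for (i in seq_along(onsets)) {
    start <- floor((onsets[i] - 1) / decim) + 1L + off0
    idx <- start:(start + n_t - 1L)
    if (start < 1 || max(idx) > nrow(dec)) {
      abort(sprintf("window for stimulus %d exceeds the recording.", i))
    }
    features[i, ] <- as.vector(dec[idx, , drop = FALSE])
  }
  epoch_dataset(features, labels, channel_names, n_t)
}

#' Decode spelled characters by row/column score accumulation
#'
#' Sums the classifier scores of each stimulus code over the first
#' `n_epochs_used` epochs of every trial; the predicted character sits at
#' the intersection of the best row code (1-6) and the best column code
#' (7-12), ties broken by the lower code.
#'
#' @param scores Numeric score per stimulus row (from [blda_score()]),
#'   aligned with `trials`.
#' @param trials Tibble with one row per stimulus: columns `trial`,
#'   `epoch`, `code` (1-12).
#' @param layout A [speller_layout()].
#' @param n_epochs_used Number of epochs per trial to accumulate
#'   (default: all available).
#' @return A tibble with one row per trial: `trial`, `predicted`.
#' @export
decode_characters <- function(scores, trials, layout = speller_layout(),
                              n_epochs_used = NULL) {
  stopifnot(length(scores) == nrow(trials))
  n_epochs_used <- n_epochs_used %||% max(trials$epoch)
  keep <- trials$epoch <= n_epochs_used
  tr <- trials[keep, , drop = FALSE]
  sc <- scores[keep]
  # every retained epoch must flash each of the 12 codes exactly once
  chk <- dplyr::count(tr, .data$trial, .data$epoch, .data$code)
  per_ep <- dplyr::count(dplyr::distinct(chk, .data$trial, .data$epoch, .data$code),
                         .data$trial, .data$epoch)
  if (any(chk$n != 1L) || any(per_ep$n != 12L)) {
    abort("each epoch must contain each of the 12 stimulus codes exactly once.")
  }
  out <- tr |>
    dplyr::mutate(score = sc) |>
    dplyr::group_by(.data$trial, .data$code) |>
    dplyr::summarise(total = sum(.data$score), .groups = "drop_last") |>
    dplyr::summarise(predicted = {
      tot <- setNames(.data$total, .data$code)
      row_best <- best_code(tot, 1:6)
      col_best <- best_code(tot, 7:12)
      layout$grid[row_best, col_best - 6L]
    }, .groups = "drop")
  out
}

best_code <- function(totals, codes) {
  v <- totals[as.character(codes)]
  codes[which.max(v)]   # which.max takes the first maximum: lower code wins ties
}

#' @rdname decode_characters
#' @details `decode_character()` decodes a single trial and returns the
#'   character.
#' @export
decode_character <- function(scores, trials, layout = speller_layout(),
                             n_epochs_used = NULL) {
  res <- decode_characters(scores, trials, layout, n_epochs_used)
  if (nrow(res) != 1) abort("decode_character() expects a single trial.")
  res$predicted
}

#' Character recognition accuracy
#'
#' `100 * (#correct) / (#total)` over paired predicted and true character
#' sequences.
#'
#' @param predicted,truth Equal-length character vectors.
#' @return Percentage in `[0, 100]`.
#' @examples
#' accuracy(c("A", "B", "C"), c("A", "B", "D"))
#' @export
accuracy <- function(predicted, truth) {
  if (!length(predicted)) abort("empty prediction sequence.")
  if (length(predicted) != length(truth)) abort("length mismatch.")
  100 * mean(predicted == truth)
}

# rank-based AUC of scores for the +1 class
auc_score <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Cross-validate the shear threshold
#'
#' Stratified k-fold cross-validation over stimuli (stratified by
#' target/non-target label): for each candidate `tau` the block-sparse
#' model is fitted on the training folds, channels are selected, a BLDA
#' classifier is trained on the selected channels, and the held-out
#' stimuli are scored by AUC (target vs non-target separation). The best
#' `tau` maximizes the mean validation AUC; ties go to the larger `tau`
#' (fewer channels). Deterministic given `seed`. Note the fold unit is the
#' stimulus, not the trial, so epochs of one character can straddle folds;
#' see the vignette for the implications.
#'
#' @param data An [epoch_dataset()].
#' @param regions Region map for the fit.
#' @param tau_grid Candidate thresholds in (0, 1).
#' @param k Number of folds (default 10).
#' @param config Base [fit_config()]; its `tau` is replaced per candidate.
#' @param seed Seed for the fold assignment.
#' @return A list: `best_tau`, `folds` (tibble `tau`, `fold`, `auc`,
#'   `n_selected`), `summary` (mean AUC per `tau`).
#' @export
crossvalidate_tau <- function(data, regions, tau_grid, k = 10L,
                              config = fit_config(), seed = 1L) {
  if (any(tau_grid <= 0 | tau_grid >= 1)) abort("tau_grid values must lie in (0, 1).")
  k <- as.integer(k)
  if (k < 2) abort("need k >= 2 folds.")
  n <- nrow(data$features)
  folds <- with_local_seed(seed, function() {
    f <- integer(n)
    for (cls in c(1, -1)) {
      idx <- which(data$labels == cls)
      if (length(idx) < k) {
        abort(sprintf("class %+d has %d stimuli, fewer than k = %d folds.",
                      cls, length(idx), k))
      }
      f[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  rows <- list()
  for (tau in sort(tau_grid)) {
    cfg <- config
    cfg$tau <- tau
    for (fold in seq_len(k)) {
      test <- folds == fold
      train <- epoch_dataset(data$features[!test, , drop = FALSE],
                             data$labels[!test], data$channel_names, data$n_time)
      fit <- em_fit(train, regions, cfg)
      sel <- select_auto(fit)
      keep_cols <- unlist(lapply(sel$selected,
                                 function(b) block_cols(data$structure, b)))
      model <- blda_fit(train$features[, keep_cols, drop = FALSE], train$labels)
      sc <- blda_score(model, data$features[test, keep_cols, drop = FALSE])
      rows[[length(rows) + 1L]] <- tibble(
        tau = tau, fold = fold, auc = auc_score(sc, data$labels[test]),
        n_selected = length(sel$selected)
      )
    }
  }
  folds_tbl <- dplyr::bind_rows(rows)
  summary_tbl <- folds_tbl |>
    dplyr::group_by(.data$tau) |>
    dplyr::summarise(mean_auc = mean(.data$auc),
                     mean_selected = mean(.data$n_selected), .groups = "drop")
  best <- summary_tbl |>
    dplyr::filter(.data$mean_auc == max(.data$mean_auc)) |>
    dplyr::slice_max(.data$tau, n = 1)
  list(best_tau = best$tau, folds = folds_tbl, summary = summary_tbl)
}

#' Sweep the shear threshold and record the selected-channel count
#'
#' Refits the model for each `tau` on the same data and counts surviving
#' channels. A fit where every channel is pruned (possible at large `tau`)
#' is recorded as 0 selected with `degenerate = TRUE` rather than an
#' error, so the whole sweep always completes. The count is non-increasing
#' in `tau`; at thresholds below the smallest relevance scale in the data
#' nothing is pruned.
#'
#' @param data An [epoch_dataset()].
#' @param regions Region map for the fit.
#' @param tau_grid Thresholds to sweep (any positive values).
#' @param config Base [fit_config()]; `tau` is replaced per grid point.
#' @return A tibble: `tau`, `n_selected`, `n_pruned_during_fit`,
#'   `converged`, `degenerate`.
#' @export
tau_sweep <- function(data, regions, tau_grid, config = fit_config()) {
  rows <- lapply(sort(tau_grid), function(tau) {
    cfg <- config
    cfg$tau <- tau
    fit <- tryCatch(em_fit(data, regions, cfg), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(tau = tau, n_selected = 0L, n_pruned_during_fit = NA_integer_,
                    converged = NA, degenerate = TRUE))
    }
    tibble(tau = tau, n_selected = sum(fit$active & fit$gamma > tau),
           n_pruned_during_fit = length(fit$removal_order),
           converged = fit$converged, degenerate = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Pairwise Wilcoxon signed-rank comparison of method accuracies
#'
#' Takes a participants x methods accuracy table and runs the two-sided
#' Wilcoxon signed-rank test on every method pair. Non-numeric columns
#' (e.g. a participant id) are ignored. With fewer than 6 paired
#' observations the test has little power and a warning is issued;
#' all-identical pairs return p = 1 with a warning.
#'
#' @param acc_table Data frame, one row per participant, one numeric
#'   column per method.
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble: `method1`, `method2`, `p_value`, `significant`.
#' @export
compare_methods <- function(acc_table, alpha = 0.05) {
  num <- acc_table[vapply(acc_table, is.numeric, TRUE)]
  if (ncol(num) < 2) abort("need at least two numeric method columns.")
  if (nrow(num) < 6) {
    warn("fewer than 6 paired observations; the signed-rank test has little power.")
  }
  pairs <- utils::combn(names(num), 2)
  rows <- apply(pairs, 2, function(pr) {
    d <- num[[pr[1]]] - num[[pr[2]]]
    if (all(d == 0)) {
      warn(sprintf("'%s' and '%s' are identical; p = 1.", pr[1], pr[2]))
      p <- 1
    } else {
      p <- suppressWarnings(
        wilcox.test(num[[pr[1]]], num[[pr[2]]], paired = TRUE)$p.value)
    }
    tibble(method1 = pr[1], method2 = pr[2], p_value = p,
           significant = p < alpha)
  })
  dplyr::bind_rows(rows)
}
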
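#' Tidy summaries of fitted objects
#'
#' broom-style accessors: `tidy()` returns one row per channel (or term),
#' `glance()` a one-row model summary.
#'
#' @param x A fitted object (`bsbl_fit`, `channel_selection`,
#'   `blda_model`, `region_map`).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bsbl_fit <- function(x, ...) {
  n_c <- x$structure$n_blocks
  removal_rank <- rep(NA_integer_, n_c)
  removal_rank[x$removal_order] <- seq_along(x$removal_order)
  tibble(
    channel = x$channel_names,
    channel_index = seq_len(n_c),
    gamma = x$gamma,
    active = x$active,
    region = x$block_group,
    importance = channel_importance(x$mu, x$structure),
    removal_rank = removal_rank
  )
}

#' One-row summaries of fitted objects
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.bsbl_fit <- function(x, ...) {
  tibble(
    n_channels = x$structure$n_blocks,
    n_active = sum(x$active),
    n_iter = x$n_iter,
    converged = x$converged,
    sigma2 = x$sigma2,
    log_evidence = x$log_evidence,
    b_mode = x$b_mode,
    tau = x$config$tau
  )
}

#' Plot the relevance-scale trajectory of a fit
#'
#' One line per channel: `gamma` across EM iterations (log10 scale), with
#' pruned channels ending where they leave the active set. A quick visual
#' check of which channels the model keeps and how fast the rest decay.
#'
#' @param object A `bsbl_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bsbl_fit <- function(object, ...) {
  tr <- object$trace
  long <- purrr::map2_dfr(tr$iteration, tr$gamma, function(it, g) {
    tibble(iteration = it, channel = object$channel_names,
           gamma = g, final_active = object$active)
  })
  long <- dplyr::filter(long, .data$gamma > 0)
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$gamma,
                                     group = .data$channel,
                                     colour = .data$final_active)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "EM iteration", y = expression(gamma[b]),
                  colour = "kept") +
    ggplot2::theme_minimal()
}

#' Importance bar chart of a channel selection
#'
#' @param object A `channel_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.channel_selection <- function(object, ...) {
  td <- tidy(object)
  td$channel <- factor(td$channel, levels = td$channel[order(td$importance)])
  ggplot2::ggplot(td, ggplot2::aes(.data$channel, .data$importance,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "sum |w| per channel", fill = "selected") +
    ggplot2::theme_minimal()
}

#' Scalp map of a selection (or of contribution counts)
#'
#' Draws the montage as a 2-D disk with points sized by importance (or any
#' supplied value) and colored by selection status.
#'
#' @param selection A `channel_selection`.
#' @param montage Montage tibble with `channel`, `x`, `y` matching the
#'   selection's channels.
#' @return A ggplot.
#' @export
plot_selection_map <- function(selection, montage) {
  td <- tidy(selection)
  df <- dplyr::inner_join(td, montage, by = "channel")
  if (nrow(df) != nrow(td)) abort("montage does not cover the selection's channels.")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::annotate("path", x = cos(seq(0, 2 * pi, length.out = 200)) * 1.15,
                      y = sin(seq(0, 2 * pi, length.out = 200)) * 1.15,
                      colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$importance,
                                     colour = .data$selected)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$channel),
                       size = 2.4, vjust = -1.2) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "selected", size = "importance")
}

#' Count how often each channel is selected across participants
#'
#' The contribution value of a channel is the number of supplied
#' selections (one per participant/run) that retained it.
#'
#' @param selections List of `channel_selection` objects over the same
#'   montage.
#' @return A tibble `channel`, `contribution`, sorted descending.
#' @export
channel_contributions <- function(selections) {
  stopifnot(length(selections) >= 1)
  names_ref <- selections[[1]]$channel_names
  counts <- integer(length(names_ref))
  for (s in selections) {
    if (!identical(s$channel_names, names_ref)) {
      abort("all selections must share one channel set.")
    }
    counts[s$selected] <- counts[s$selected] + 1L
  }
  dplyr::arrange(tibble(channel = names_ref, contribution = counts),
                 dplyr::desc(.data$contribution))
}
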
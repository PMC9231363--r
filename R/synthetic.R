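# run fn() under a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, fn) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Specification for a synthetic block-sparse regression instance
#'
#' Mirrors the generative model the block-sparse prior assumes: weights of
#' the active blocks are drawn `N(0, gamma_true * Toeplitz(r_true))`,
#' inactive blocks are exactly zero, the design matrix has independent
#' standard-normal entries and the response adds isotropic Gaussian noise.
#' Defaults match the support-recovery study conditions: 40 blocks of 8
#' points, 8 active, AR(1) coefficient 0.8, 500 samples, 10 dB SNR.
#'
#' @param n_blocks Number of blocks (channels).
#' @param block_size Points per block.
#' @param n_active_blocks Number of blocks with nonzero weights.
#' @param r_true Intra-block AR(1) coefficient, `|r_true| < 1`.
#' @param gamma_true Variance scale of the active blocks.
#' @param n_samples Number of rows of the design matrix.
#' @param snr_db Signal-to-noise ratio in dB; the noise variance is set to
#'   `||w||^2 / 10^(snr_db/10)` (ignored when `sigma2_true` is given).
#' @param sigma2_true Explicit noise variance (0 allowed for a noiseless
#'   instance); overrides `snr_db`.
#' @param active_blocks Optional explicit indices of the active blocks
#'   (default: drawn uniformly without replacement).
#' @param seed RNG seed; the generator is bitwise reproducible per seed.
#' @return A `block_sparse_spec` list.
#' @export
block_sparse_spec <- function(n_blocks = 40L, block_size = 8L,
                              n_active_blocks = 8L, r_true = 0.8,
                              gamma_true = 1, n_samples = 500L,
                              snr_db = 10, sigma2_true = NULL,
                              active_blocks = NULL, seed = 1L) {
  if (n_active_blocks > n_blocks) abort("n_active_blocks must be <= n_blocks.")
  if (abs(r_true) >= 1) abort("|r_true| must be < 1.")
  if (!is.null(active_blocks) && length(active_blocks) != n_active_blocks) {
    abort("active_blocks length must equal n_active_blocks.")
  }
  if (!is.null(sigma2_true) && sigma2_true < 0) abort("sigma2_true must be >= 0.")
  structure(
    list(n_blocks = as.integer(n_blocks), block_size = as.integer(block_size),
         n_active_blocks = as.integer(n_active_blocks), r_true = r_true,
         gamma_true = gamma_true, n_samples = as.integer(n_samples),
         snr_db = snr_db, sigma2_true = sigma2_true,
         active_blocks = if (!is.null(active_blocks)) as.integer(active_blocks),
         seed = as.integer(seed)),
    class = "block_sparse_spec"
  )
}

#' Generate a block-sparse regression instance with planted ground truth
#'
#' @param spec A [block_sparse_spec()].
#' @return A list: `data` (an [epoch_dataset()] with generic block names
#'   `B1..`), `w_true` (full-length weight vector), `support` (indices of
#'   the active blocks), `sigma2` (the noise variance actually used).
#' @examples
#' sim <- gen_block_sparse(block_sparse_spec(n_blocks = 10, block_size = 4,
#'                                           n_active_blocks = 2, n_samples = 50))
#' sim$support
#' @export
gen_block_sparse <- function(spec) {
  stopifnot(inherits(spec, "block_sparse_spec"))
  with_local_seed(spec$seed, function() {
    d <- spec$block_size
    D <- spec$n_blocks * d
    support <- spec$active_blocks %||%
      sort(sample.int(spec$n_blocks, spec$n_active_blocks))
    Btrue <- stats::toeplitz(spec$r_true^(0:(d - 1)))
    L <- chol(spec$gamma_true * Btrue)
    w <- numeric(D)
    for (b in support) {
      w[(b - 1) * d + seq_len(d)] <- drop(t(L) %*% rnorm(d))
    }
    X <- matrix(rnorm(spec$n_samples * D), spec$n_samples, D)
    sigma2 <- spec$sigma2_true %||% (sum(w^2) / 10^(spec$snr_db / 10))
    y <- drop(X %*% w) + if (sigma2 > 0) rnorm(spec$n_samples, sd = sqrt(sigma2)) else 0
    # regression targets are continuous; wrap without the +/-1 label check
    data <- epoch_dataset(X, rep(1, spec$n_samples),
                          paste0("B", seq_len(spec$n_blocks)), d)
    data$labels <- y
    list(data = data, w_true = w, support = support, sigma2 = sigma2)
  })
}

#' The 6x6 row/column speller layout
#'
#' A six-by-six matrix of 26 letters and 10 digits. Stimulus codes 1-6
#' intensify rows 1-6 and codes 7-12 intensify columns 1-6; each character
#' is addressed by exactly one (row, column) pair.
#'
#' @return A `speller_layout` object with fields `grid` (6x6 character
#'   matrix, filled row-wise A..Z, 0..9) and helpers used by the decoding
#'   pipeline.
#' @export
speller_layout <- function() {
  grid <- matrix(c(LETTERS, as.character(0:9)), 6, 6, byrow = TRUE)
  structure(list(grid = grid, n_codes = 12L), class = "speller_layout")
}

#' @export
print.speller_layout <- function(x, ...) {
  cat("<speller_layout> 6x6 grid, codes 1-6 = rows, 7-12 = columns\n")
  print(x$grid, quote = FALSE)
  invisible(x)
}

# the two codes (row, column) that flash a character
target_codes <- function(layout, char) {
  pos <- which(layout$grid == char, arr.ind = TRUE)
  if (nrow(pos) != 1) abort(sprintf("character '%s' not in the layout.", char))
  c(pos[1, "row"], 6L + pos[1, "col"])
}

#' Specification for a simulated P300 speller session
#'
#' Emulates the oddball structure of a row/column speller recording: every
#' epoch flashes each of the 12 stimulus codes once in random order; the
#' two codes containing the attended character are targets (2 of 12, the
#' rare class) and receive an ERP deflection -- a Gaussian-in-time bump
#' around 300 ms -- on a planted subset of informative channels, with
#' spatially smooth amplitudes (a Gaussian function of electrode distance
#' from the centroid of the informative set). All channels carry AR(1)
#' temporal noise; optional distractor channels carry inflated noise.
#' Defaults mirror a full lab session: 59 channels, 36 characters,
#' 4 epochs per character, 30 time points per stimulus at 50 Hz.
#'
#' @param montage Montage tibble or builtin name (default `"cap59"`).
#' @param informative_channels Channel names (or indices) carrying the ERP.
#' @param erp_amplitude Peak bump amplitude at the centroid of the
#'   informative set (same units as the noise sd).
#' @param spatial_scale Length scale of the spatial amplitude falloff, in
#'   montage coordinate units.
#' @param erp_latency,erp_width Bump center and sd, in seconds; the latency
#'   must lie inside the analysis window.
#' @param latency_gradient Posterior-to-anterior latency shift in seconds
#'   per montage y-unit: each informative channel's bump peaks at
#'   `erp_latency + latency_gradient * (y_c - mean(y_informative))`,
#'   mimicking the earlier visual components over occipital sites and
#'   giving each channel a partly channel-specific time course.
#' @param noise_sd Stationary sd of the AR(1) channel noise.
#' @param noise_ar AR(1) coefficient of the channel noise, `|phi| < 1`.
#' @param distractor_channels Channels whose noise sd is multiplied by
#'   `distractor_scale` (none by default).
#' @param distractor_scale Noise inflation for distractor channels.
#' @param n_characters Characters spelled (trials).
#' @param n_epochs_per_trial Epochs (repetition blocks of 12 flashes) per
#'   character.
#' @param sampling_rate Post-decimation sampling rate in Hz.
#' @param window Analysis window in seconds after stimulus onset.
#' @param seed RNG seed.
#' @return A `p300_sim_spec` list.
#' @export
p300_sim_spec <- function(montage = "cap59",
                          informative_channels = c("P3", "Pz", "P4", "PO3",
                                                   "POz", "PO4", "O1", "Oz"),
                          erp_amplitude = 1.5, spatial_scale = 0.45,
                          erp_latency = 0.3, erp_width = 0.06,
                          latency_gradient = 0.3,
                          noise_sd = 1, noise_ar = 0.5,
                          distractor_channels = NULL, distractor_scale = 3,
                          n_characters = 36L, n_epochs_per_trial = 4L,
                          sampling_rate = 50, window = c(0, 0.6),
                          seed = 1L) {
  if (is.character(montage) && length(montage) == 1) {
    montage <- builtin_montage(montage)
  }
  if (erp_latency < window[1] || erp_latency > window[2]) {
    abort("erp_latency must lie inside the analysis window.")
  }
  if (abs(noise_ar) >= 1) abort("|noise_ar| must be < 1.")
  if (erp_amplitude < 0) abort("erp_amplitude must be >= 0.")
  if (n_epochs_per_trial < 1) abort("n_epochs_per_trial must be >= 1.")
  resolve <- function(ch) {
    if (is.null(ch)) return(integer(0))
    if (is.character(ch)) {
      i <- match(ch, montage$channel)
      if (anyNA(i)) abort(paste0("unknown channels: ",
                                 paste(ch[is.na(i)], collapse = ", ")))
      i
    } else as.integer(ch)
  }
  structure(
    list(montage = montage, informative = resolve(informative_channels),
         erp_amplitude = erp_amplitude, spatial_scale = spatial_scale,
         erp_latency = erp_latency, erp_width = erp_width,
         latency_gradient = latency_gradient,
         noise_sd = noise_sd, noise_ar = noise_ar,
         distractors = resolve(distractor_channels),
         distractor_scale = distractor_scale,
         n_characters = as.integer(n_characters),
         n_epochs_per_trial = as.integer(n_epochs_per_trial),
         sampling_rate = sampling_rate, window = window,
         seed = as.integer(seed)),
    class = "p300_sim_spec"
  )
}

# spatially smooth per-channel bump amplitudes: Gaussian falloff from the
# centroid of the informative set, zero outside it
erp_amplitudes <- function(spec) {
  amps <- numeric(nrow(spec$montage))
  if (!length(spec$informative)) return(amps)
  xy <- cbind(spec$montage$x, spec$montage$y)
  center <- colMeans(xy[spec$informative, , drop = FALSE])
  d2 <- rowSums((xy - matrix(center, nrow(xy), 2, byrow = TRUE))^2)
  amps[spec$informative] <-
    spec$erp_amplitude * exp(-d2[spec$informative] / (2 * spec$spatial_scale^2))
  amps
}

#' Simulate a P300 speller session with planted informative channels
#'
#' @param spec A [p300_sim_spec()].
#' @param layout A [speller_layout()].
#' @param targets Optional character vector of attended characters (length
#'   `n_characters`); drawn uniformly from the grid by default.
#' @return A list: `data` (an [epoch_dataset()], one row per stimulus,
#'   channel-major features), `trials` (tibble with `trial`, `epoch`,
#'   `code`, `label`, `target` per stimulus row), `targets`, `truth`
#'   (informative channel indices and their bump amplitudes), `layout`,
#'   `spec`.
#' @examples
#' sess <- gen_p300_session(p300_sim_spec(n_characters = 2, seed = 7))
#' sess$data
#' @export
gen_p300_session <- function(spec, layout = speller_layout(), targets = NULL) {
  stopifnot(inherits(spec, "p300_sim_spec"))
  with_local_seed(spec$seed, function() {
    n_c <- nrow(spec$montage)
    n_t <- floor(spec$window[2] * spec$sampling_rate) -
      floor(spec$window[1] * spec$sampling_rate)
    tgrid <- spec$window[1] + (seq_len(n_t) - 0.5) / spec$sampling_rate
    amps <- erp_amplitudes(spec)
    # per-channel bump: latency shifts along the anterior-posterior axis
    lat <- rep(spec$erp_latency, n_c)
    if (length(spec$informative)) {
      ybar <- mean(spec$montage$y[spec$informative])
      lat <- spec$erp_latency +
        spec$latency_gradient * (spec$montage$y - ybar)
    }
    erp <- vapply(seq_len(n_c), function(c) {
      amps[c] * exp(-(tgrid - lat[c])^2 / (2 * spec$erp_width^2))
    }, numeric(n_t))                      # n_t x n_c, zero off the support
    ch_sd <- rep(spec$noise_sd, n_c)
    ch_sd[spec$distractors] <- ch_sd[spec$distractors] * spec$distractor_scale

    targets <- targets %||% sample(as.vector(layout$grid), spec$n_characters,
                                   replace = TRUE)
    if (length(targets) != spec$n_characters) {
      abort("`targets` must have n_characters entries.")
    }
    n_stim <- spec$n_characters * spec$n_epochs_per_trial * 12L

    # AR(1) noise, stationary sd 1, one column per (stimulus, channel)
    z <- matrix(rnorm(n_t * n_stim * n_c), n_t)
    phi <- spec$noise_ar
    noise <- z
    if (phi != 0) {
      innov <- sqrt(1 - phi^2)
      noise[1, ] <- z[1, ]
      for (tt in 2:n_t) noise[tt, ] <- phi * noise[tt - 1, ] + innov * z[tt, ]
    }

    features <- matrix(0, n_stim, n_c * n_t)
    trial_id <- integer(n_stim); epoch_id <- integer(n_stim)
    code_id <- integer(n_stim); label <- integer(n_stim)
    target_of <- character(n_stim)
    row <- 0L
    for (tr in seq_len(spec$n_characters)) {
      codes_hit <- target_codes(layout, targets[tr])
      for (ep in seq_len(spec$n_epochs_per_trial)) {
        order12 <- sample.int(12L)
        for (code in order12) {
          row <- row + 1L
          is_target <- code %in% codes_hit
          # noise columns for this stimulus: channel-major
          ncol_idx <- ((row - 1L) * n_c) + seq_len(n_c)
          sig <- noise[, ncol_idx, drop = FALSE] *
            matrix(ch_sd, n_t, n_c, byrow = TRUE)
          if (is_target) sig <- sig + erp
          features[row, ] <- as.vector(sig)   # column-major = channel-major blocks
          trial_id[row] <- tr; epoch_id[row] <- ep
          code_id[row] <- code; label[row] <- if (is_target) 1L else -1L
          target_of[row] <- targets[tr]
        }
      }
    }
    data <- epoch_dataset(features, label, spec$montage$channel, n_t)
    list(
      data = data,
      trials = tibble(trial = trial_id, epoch = epoch_id, code = code_id,
                      label = label, target = target_of),
      targets = targets,
      truth = list(informative = spec$informative, amplitudes = amps,
                   distractors = spec$distractors),
      layout = layout, spec = spec
    )
  })
}
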
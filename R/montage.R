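#' Electrode montages (10-20 / 10-10 naming with 2-D scalp coordinates)
#'
#' A montage is a tibble with columns `channel`, `x`, `y`: unique channel
#' names plus a 2-D disk projection of their scalp positions (nose up,
#' left ear at negative x). Coordinates are idealized positions computed
#' from the 10-10 label structure -- accurate enough for spatial region
#' grouping and topographic summaries, not for source modelling.
#'
#' Two montages ship with the package: `"cap64"`, the 64-channel cap layout
#' used by the public P300 competition recordings, and `"cap59"`, a
#' 59-EEG-channel layout typical of 64-electrode lab systems that reserve
#' electrodes for EOG/ECG.
#'
#' @param name `"cap64"` or `"cap59"`.
#' @return A tibble with columns `channel`, `x`, `y`.
#' @examples
#' builtin_montage("cap64")
#' @export
builtin_montage <- function(name = c("cap64", "cap59")) {
  name <- match.arg(name)
  montage_from_names(if (name == "cap64") cap64_names() else cap59_names())
}

cap64_names <- function() {
  c("FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FT8", "T7", "T8", "T9", "T10", "TP7", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz")
}

cap59_names <- function() {
  c("Fp1", "Fpz", "Fp2", "AF3", "AFz", "AF4",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2")
}

#' Build a montage tibble from 10-10 channel labels
#'
#' Positions are computed from the label alone: the row letters (Fp, AF, F,
#' FC, C, CP, P, PO, O, I) set the anterior-posterior coordinate, the digit
#' sets the lateral rank (odd = left, even = right, z = midline). Temporal
#' labels are treated as the lateral extremes of their row (T7 ~ C7 etc.).
#'
#' @param names Character vector of 10-10 style labels.
#' @return A tibble with columns `channel`, `x`, `y`.
#' @export
montage_from_names <- function(names) {
  names <- as.character(names)
  if (anyDuplicated(names)) abort("montage channel names must be unique.")
  pos <- t(vapply(names, position_1010, numeric(2)))
  tibble(channel = names, x = unname(pos[, 1]), y = unname(pos[, 2]))
}

# idealized 2-D disk position for one 10-10 label
position_1010 <- function(label) {
  lab <- toupper(label)
  # temporal rows are the lateral extremes of the corresponding coronal row
  alias <- c(T7 = "C7", T8 = "C8", T9 = "C9", T10 = "C10",
             FT7 = "FC7", FT8 = "FC8", FT9 = "FC9", FT10 = "FC10",
             TP7 = "CP7", TP8 = "CP8", TP9 = "CP9", TP10 = "CP10")
  if (lab %in% names(alias)) lab <- alias[[lab]]
  m <- regmatches(lab, regexec("^(FP|AF|FC|CP|PO|F|C|P|O|I)(Z|[0-9]+)$", lab))[[1]]
  if (length(m) == 0) abort(sprintf("cannot parse 10-10 label '%s'.", label))
  row_y <- c(FP = 0.9, AF = 0.7, F = 0.5, FC = 0.25, C = 0,
             CP = -0.25, P = -0.5, PO = -0.7, O = -0.9, I = -1.05)
  y <- row_y[[m[2]]]
  if (m[3] == "Z") {
    x <- 0
  } else {
    n <- as.integer(m[3])
    side <- if (n %% 2 == 1) -1 else 1
    rank <- ceiling(n / 2)
    half_width <- sqrt(pmax(0, 1.1^2 - y^2))
    x <- side * rank / 5 * half_width
  }
  c(x, y)
}

#' Read a montage from a plain-text file
#'
#' Format: one channel per line, `name x y`, whitespace-separated. Lines
#' starting with `#` are ignored.
#'
#' @param path Path to the montage file.
#' @return A tibble with columns `channel`, `x`, `y`.
#' @export
read_montage <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:],]+")
  bad <- lengths(parts) != 3
  if (any(bad)) abort(sprintf("montage line %d is not 'name x y'.", which(bad)[1]))
  out <- tibble(
    channel = vapply(parts, `[[`, "", 1),
    x = as.numeric(vapply(parts, `[[`, "", 2)),
    y = as.numeric(vapply(parts, `[[`, "", 3))
  )
  if (anyDuplicated(out$channel)) abort("duplicate channel names in montage file.")
  if (anyNA(out$x) || anyNA(out$y) || !all(is.finite(out$x + out$y))) {
    abort("montage coordinates must be finite numbers.")
  }
  out
}

#' Write a montage to the plain-text format read by [read_montage()]
#' @param montage Montage tibble (`channel`, `x`, `y`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  writeLines(sprintf("%s %.6f %.6f", montage$channel, montage$x, montage$y), path)
  invisible(path)
}
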
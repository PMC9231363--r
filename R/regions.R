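#' Spatial region maps: grouping channels that share one correlation matrix
#'
#' Regional smoothing ties the intra-block (temporal) correlation matrix of
#' all channels in a spatial electrode region together. A `region_map` is a
#' strict partition of the channel set into named regions, each with at
#' least `min_size` channels (default 3, the size floor the method assumes
#' so every region has enough blocks to average over).
#'
#' @param regions Named list of character vectors (channel names) or
#'   integer vectors (channel indices into `channel_names`).
#' @param channel_names Character vector: the full channel set, in block
#'   order.
#' @param name Scheme identifier.
#' @param min_size Minimum region size (default 3).
#' @return A `region_map` object with fields `regions` (list of integer
#'   index vectors), `sizes`, `block_region` (channel -> region lookup),
#'   `region_names`, `channel_names`, `name`.
#' @export
region_map <- function(regions, channel_names, name = "custom", min_size = 3) {
  channel_names <- as.character(channel_names)
  n_c <- length(channel_names)
  if (length(regions) < 1) abort("need at least one region.")
  if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
    names(regions) <- paste0("R", seq_along(regions))
  }
  idx <- lapply(regions, function(g) {
    if (is.character(g)) {
      i <- match(g, channel_names)
      if (anyNA(i)) abort(paste0("unknown channels in region map: ",
                                 paste(g[is.na(i)], collapse = ", ")))
      i
    } else {
      i <- as.integer(g)
      if (any(i < 1 | i > n_c)) abort("channel index out of range in region map.")
      i
    }
  })
  all_idx <- unlist(idx)
  dup <- unique(all_idx[duplicated(all_idx)])
  if (length(dup)) {
    abort(paste0("channels assigned to more than one region: ",
                 paste(channel_names[dup], collapse = ", ")))
  }
  missing <- setdiff(seq_len(n_c), all_idx)
  if (length(missing)) {
    abort(paste0("channels missing from the region map: ",
                 paste(channel_names[missing], collapse = ", ")))
  }
  sizes <- lengths(idx)
  if (any(sizes < min_size)) {
    abort(sprintf("region '%s' has %d channels; every region needs >= %d.",
                  names(idx)[which.min(sizes)], min(sizes), min_size))
  }
  block_region <- integer(n_c)
  for (r in seq_along(idx)) block_region[idx[[r]]] <- r
  structure(
    list(regions = idx, sizes = sizes, block_region = block_region,
         region_names = names(idx), channel_names = channel_names, name = name),
    class = "region_map"
  )
}

#' @export
print.region_map <- function(x, ...) {
  cat("<region_map '", x$name, "'> ", length(x$regions), " regions over ",
      length(x$channel_names), " channels (sizes ",
      paste(x$sizes, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @rdname tidy.bsbl_fit
#' @export
tidy.region_map <- function(x, ...) {
  tibble(
    channel = x$channel_names,
    channel_index = seq_along(x$channel_names),
    region = x$region_names[x$block_region]
  )
}

#' Built-in 13-region schemes for the shipped montages
#'
#' Both schemes partition their montage into 13 regions of at least three
#' channels following standard 10-20 neighborhoods (prefrontal, frontal
#' left/midline/right, frontocentral strips, temporal, central,
#' centro-parietal, parietal, parieto-occipital). They approximate the
#' regional grouping a P300 practitioner would draw on the scalp; exact
#' memberships are a modelling choice and are user-replaceable via
#' [load_region_map()].
#'
#' @param name `"cap64"` or `"cap59"`.
#' @return A `region_map`.
#' @export
builtin_region_map <- function(name = c("cap64", "cap59")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("regions_", name, ".txt"),
                      package = "p300bsbl", mustWork = TRUE)
  load_region_map(path, builtin_montage(name), name = name)
}

#' Read a region map from a plain-text file
#'
#' Format: one region per line, comma-separated channel names, optionally
#' prefixed `regionname:`. Lines starting with `#` are ignored. The listed
#' channels must form a strict partition of the montage.
#'
#' @param path Path to the region file.
#' @param montage Montage tibble (or any object with a `channel` column /
#'   character vector of channel names).
#' @param name Scheme identifier (defaults to the file name).
#' @param min_size Minimum region size.
#' @return A `region_map`.
#' @export
load_region_map <- function(path, montage, name = NULL, min_size = 3) {
  if (!file.exists(path)) abort(sprintf("region file '%s' not found.", path))
  channel_names <- if (is.character(montage)) montage else montage$channel
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort("region file is empty.")
  rnames <- character(length(lines))
  groups <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl(":", ln, fixed = TRUE)) {
      rnames[i] <- trimws(sub(":.*$", "", ln))
      ln <- sub("^[^:]*:", "", ln)
    } else {
      rnames[i] <- paste0("R", i)
    }
    groups[[i]] <- trimws(strsplit(ln, ",")[[1]])
  }
  names(groups) <- rnames
  region_map(groups, channel_names,
             name = name %||% basename(path), min_size = min_size)
}

#' Write a region map to the plain-text format read by [load_region_map()]
#' @param map A `region_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_map <- function(map, path) {
  writeLines(vapply(seq_along(map$regions), function(r) {
    paste0(map$region_names[r], ": ",
           paste(map$channel_names[map$regions[[r]]], collapse = ","))
  }, ""), path)
  invisible(path)
}

#' Single-region and sequential-chunk maps
#'
#' `region_map_single()` puts every channel in one region (the
#' shared-correlation ablation); `region_map_chunks()` splits the block
#' sequence into `k` nearly equal consecutive chunks, handy for generic
#' block-sparse problems without scalp geometry.
#'
#' @param channel_names Channel (block) names.
#' @param k Number of chunks.
#' @return A `region_map`.
#' @export
region_map_single <- function(channel_names) {
  region_map(list(all = seq_along(channel_names)), channel_names, name = "single")
}

#' @rdname region_map_single
#' @export
region_map_chunks <- function(channel_names, k) {
  n <- length(channel_names)
  k <- as.integer(k)
  if (k < 1 || n < 3 * k) abort("need at least 3*k channels for k chunks.")
  grp <- sort(rep_len(seq_len(k), n))
  region_map(split(seq_len(n), grp), channel_names,
             name = sprintf("chunks%d", k))
}

#' Automatic spatial region map by clustering electrode coordinates
#'
#' Deterministically k-means-clusters the montage coordinates (fixed
#' internal seed) into `k_regions` groups, then merges any group smaller
#' than `min_size` into the group with the nearest centroid until all
#' regions satisfy the size floor.
#'
#' @param montage Montage tibble (`channel`, `x`, `y`).
#' @param k_regions Requested number of regions (the result may have fewer
#'   after merging).
#' @param min_size Minimum region size.
#' @param seed Seed for the k-means initialization.
#' @return A `region_map`.
#' @export
auto_region_map <- function(montage, k_regions, min_size = 3, seed = 1L) {
  n <- nrow(montage)
  k_regions <- as.integer(k_regions)
  if (k_regions < 1 || n < min_size * k_regions) {
    abort(sprintf("%d channels cannot form %d regions of >= %d.",
                  n, k_regions, min_size))
  }
  xy <- cbind(montage$x, montage$y)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  km <- kmeans(xy, centers = min(k_regions, n), nstart = 10, iter.max = 50)
  cl <- km$cluster
  # merge undersized clusters into the nearest (by centroid) other cluster
  repeat {
    tab <- table(cl)
    small <- names(tab)[tab < min_size]
    if (!length(small) || length(tab) == 1) break
    s <- small[1]
    cent <- do.call(rbind, lapply(names(tab), function(g) colMeans(xy[cl == g, , drop = FALSE])))
    rownames(cent) <- names(tab)
    d <- sqrt(rowSums((cent - matrix(cent[s, ], nrow(cent), 2, byrow = TRUE))^2))
    d[s] <- Inf
    cl[cl == s] <- names(which.min(d))
  }
  cl <- as.integer(factor(cl))
  region_map(split(seq_len(n), cl), montage$channel,
             name = sprintf("auto%d", k_regions), min_size = min_size)
}
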
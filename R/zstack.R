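#' Image plane container
#'
#' A single 2-D bright-field (or fluorescence) intensity plane together with
#' its physical metadata. Pixels are stored as a base matrix in (x, y) order:
#' `pixels[i, j]` is the intensity at x index `i`, y index `j`, with pixel
#' centres at `(i - 0.5, j - 0.5) * pixel_size` micrometres. Invalid pixels
#' (e.g. resampled from outside the frame) are `NA`.
#'
#' @param pixels numeric matrix of intensities.
#' @param pixel_size pixel pitch in micrometres per pixel.
#' @param focal_offset focal plane offset in micrometres.
#' @param tag acquisition tag, `"background"` or `"signal"`.
#' @param timepoint integer timepoint index.
#' @return An object of class `raft_plane`.
#' @export
image_plane <- function(pixels, pixel_size, focal_offset = 0,
                        tag = c("signal", "background"), timepoint = 1L) {
  tag <- match.arg(tag)
  stopifnot(is.matrix(pixels), is.numeric(pixels), pixel_size > 0)
  if (any(is.infinite(pixels)))
    stop("image_plane: intensities must be finite or NA")
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         focal_offset = focal_offset, tag = tag,
         timepoint = as.integer(timepoint)),
    class = "raft_plane")
}

#' Z-stack container
#'
#' An ordered set of co-registered planes acquired at strictly increasing
#' focal offsets, sharing pixel size and acquisition tag. Stored as a 3-D
#' array `[x, y, plane]`.
#'
#' @param data 3-D numeric array, third dimension indexing focal planes.
#' @param pixel_size micrometres per pixel.
#' @param focal_offsets numeric vector of per-plane focal offsets (um),
#'   strictly increasing.
#' @param tag acquisition tag.
#' @param timepoint integer timepoint index.
#' @return An object of class `raft_zstack`.
#' @export
zstack <- function(data, pixel_size, focal_offsets,
                   tag = c("signal", "background"), timepoint = 1L) {
  tag <- match.arg(tag)
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(focal_offsets))
  if (dim(data)[3] < 2) stop("zstack: at least two planes are required")
  if (any(diff(focal_offsets) <= 0))
    stop("zstack: focal offsets must be strictly increasing")
  structure(
    list(data = data, pixel_size = pixel_size,
         focal_offsets = as.numeric(focal_offsets), tag = tag,
         timepoint = as.integer(timepoint)),
    class = "raft_zstack")
}

#' @export
print.raft_zstack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("raft_zstack: %d x %d px, %d planes (%s), %.3f um/px, offsets [%s] um\n",
              d[1], d[2], d[3], x$tag, x$pixel_size,
              paste(format(x$focal_offsets), collapse = ", ")))
  invisible(x)
}

#' Extract one plane of a z-stack as an image plane
#' @param stack a `raft_zstack`.
#' @param k plane index.
#' @return a `raft_plane`.
#' @export
stack_plane <- function(stack, k) {
  image_plane(stack$data[, , k], stack$pixel_size, stack$focal_offsets[k],
              stack$tag, stack$timepoint)
}

n_planes <- function(stack) dim(stack$data)[3]

#' Write a z-stack to a multi-page TIFF with a JSON metadata sidecar
#'
#' One TIFF page per focal plane (32-bit float); pixel size, focal offsets
#' and the acquisition tag go to `<path>.json`. Intensities are written
#' unquantized.
#'
#' @param stack a `raft_zstack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  # TIFF storage is defined on [0, 1]: map intensities affinely onto
  # [0.05, 1] (the mapping goes to the sidecar) and reserve 0 for NA
  rng <- range(stack$data, na.rm = TRUE)
  span <- max(rng[2] - rng[1], 1e-12)
  pages <- lapply(seq_len(n_planes(stack)), function(k) {
    m <- 0.05 + 0.95 * (stack$data[, , k] - rng[1]) / span
    m[is.na(m)] <- 0
    t(m) # tiff expects [row = y, col = x]
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(pixel_size_um = stack$pixel_size,
               focal_offsets_um = stack$focal_offsets,
               tag = stack$tag, timepoint = stack$timepoint,
               intensity_min = rng[1], intensity_span = span)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a z-stack written by [write_zstack()]
#' @param path TIFF path (with `<path>.json` sidecar alongside).
#' @return a `raft_zstack`.
#' @export
read_zstack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- array(NA_real_, c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) {
    m <- t(pages[[k]])
    m[m < 0.025] <- NA_real_ # reserved NA code
    data[, , k] <- (m - 0.05) / 0.95 * meta$intensity_span +
      meta$intensity_min
  }
  zstack(data, meta$pixel_size_um, meta$focal_offsets_um, meta$tag,
         meta$timepoint)
}
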
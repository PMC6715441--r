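# Background-subtracted standard-deviation-projection (B-SDP) colony
# segmentation: the contrast-enhancement and filter chain that turns
# focus-varying cell texture into colony masks.

#' B-SDP filter chain parameters
#'
#' All structuring-element sizes are physical (micrometres) and are
#' converted to pixels at the working pixel size when the chain runs, so
#' the chain behaves consistently across magnifications.
#'
#' @param tophat_width,tophat_length rectangular top-hat structuring
#'   element, um; applied at 0 and 90 degrees and combined by pixelwise
#'   minimum.
#' @param entropy_radius local-entropy disk radius, um.
#' @param entropy_levels gray-level alphabet for the entropy filter (the
#'   image is min-max scaled and quantized to this many levels).
#' @param recon_radius disk radius for opening-by-reconstruction, um.
#' @param fill_min_radius only interior holes of at least this radius (um)
#'   are filled; 0 fills all holes.
#' @param thin_um inward contraction (erosion) of the segmentation, um,
#'   compensating the dilated appearance of cells in SDPs.
#' @param majority_px window edge of the binary majority filter, pixels.
#' @param min_colony_radius debris size-exclusion: components smaller than
#'   a disk of this radius (um) are removed.
#' @param min_contrast minimum Otsu between-class mean separation of the
#'   enhanced image (entropy units, bits); below it the scene is declared
#'   cell-free and the mask is empty.
#' @param std_mode `"population"` or `"sample"` standard deviation for the
#'   z-projection.
#' @param white_tophat use white (bright-feature) top-hats.
#' @return object of class `bsdp_params`.
#' @export
bsdp_params <- function(tophat_width = 2, tophat_length = 33,
                        entropy_radius = 14, entropy_levels = 64,
                        recon_radius = 40, fill_min_radius = 0,
                        thin_um = 8, majority_px = 3,
                        min_colony_radius = 25, min_contrast = 0.8,
                        std_mode = c("population", "sample"),
                        white_tophat = TRUE) {
  std_mode <- match.arg(std_mode)
  stopifnot(tophat_width > 0, tophat_length > 0, entropy_radius > 0,
            recon_radius > 0, thin_um >= 0, min_colony_radius >= 0)
  structure(list(tophat_width = tophat_width, tophat_length = tophat_length,
                 entropy_radius = entropy_radius,
                 entropy_levels = as.integer(entropy_levels),
                 recon_radius = recon_radius,
                 fill_min_radius = fill_min_radius, thin_um = thin_um,
                 majority_px = as.integer(majority_px),
                 min_colony_radius = min_colony_radius,
                 min_contrast = min_contrast, std_mode = std_mode,
                 white_tophat = white_tophat),
            class = "bsdp_params")
}

# um -> odd pixel extent >= 1
um_to_odd_px <- function(um, pixel_size) {
  p <- max(1L, round(um / pixel_size))
  if (p %% 2 == 0) p <- p + 1L
  as.integer(p)
}

um_to_px <- function(um, pixel_size) max(1L, as.integer(round(um / pixel_size)))

box_sum <- function(m, r) .box_sum_cpp(m, as.integer(r))

disc_brush <- function(radius_um, pixel_size) {
  r <- um_to_px(radius_um, pixel_size)
  EBImage::makeBrush(2L * r + 1L, "disc")
}

#' Standard deviation z-projection
#'
#' Per-pixel standard deviation of intensity along the z-stack axis. Pixels
#' invalid (`NA`) in any plane stay invalid.
#'
#' @param stack a `raft_zstack` with at least two planes.
#' @param mode `"population"` (divide by n) or `"sample"` (divide by n-1).
#' @return a `raft_plane` at focal offset 0.
#' @export
sdp <- function(stack, mode = c("population", "sample")) {
  mode <- match.arg(mode)
  n <- n_planes(stack)
  if (n < 2) stop("sdp: at least two planes required")
  s1 <- rowSums(stack$data, dims = 2)
  s2 <- rowSums(stack$data^2, dims = 2)
  v <- s2 / n - (s1 / n)^2
  v[v < 0] <- 0
  if (mode == "sample") v <- v * n / (n - 1)
  image_plane(sqrt(v), stack$pixel_size, 0, stack$tag, stack$timepoint)
}

#' Subtract a background stack from a signal stack
#'
#' The background stack is rigidly transformed onto the signal stack
#' (plane-matched by focal offset) and subtracted pixel-wise; invalid
#' pixels are unioned.
#'
#' @param signal,background `raft_zstack`s with identical focal offsets.
#' @param t a `raft_transform` mapping background onto signal (identity by
#'   default).
#' @return difference `raft_zstack` (tag `"signal"`).
#' @export
subtract_background <- function(signal, background, t = rigid_transform()) {
  if (n_planes(signal) != n_planes(background) ||
      any(signal$focal_offsets != background$focal_offsets))
    stop("subtract_background: focal offsets of the stacks do not match")
  bt <- apply_transform(background, t)
  out <- signal
  out$data <- signal$data - bt$data
  out
}

#' B-SDP contrast enhancement chain
#'
#' Applies, in order: white top-hat with the horizontal and the vertical
#' rectangular structuring element, combined by pixelwise minimum (a long
#' straight edge survives the top-hat parallel to it, so only the minimum
#' suppresses microraft edges in both orientations); local-entropy texture
#' filtering over a disk (associates punctate cell signals into filled
#' patches); and grayscale opening-by-reconstruction with a larger disk
#' (removes debris-scale peaks while preserving surviving shapes).
#'
#' @param b_sdp a `raft_plane`, typically [sdp()] of the
#'   background-subtracted stack; nonnegative.
#' @param params a [bsdp_params()].
#' @param stages also return the per-stage intermediates.
#' @return enhanced `raft_plane` (local entropy units, bits); with
#'   `stages = TRUE`, a list with `enhanced`, `tophat`, `entropy`.
#' @export
enhance <- function(b_sdp, params = bsdp_params(), stages = FALSE) {
  px <- b_sdp$pixel_size
  m <- b_sdp$pixels
  w <- um_to_px(params$tophat_width, px)
  l <- um_to_odd_px(params$tophat_length, px)
  if (l > min(dim(m)) || w > min(dim(m)))
    stop("enhance: structuring element larger than image")
  valid <- !is.na(m)
  mm <- m
  mm[!valid] <- 0
  # EBImage grayscale morphology clamps to [0, 1]: scale in, scale out
  # (the top-hat commutes with positive scaling)
  sc <- max(mm, 1e-12)
  img <- EBImage::Image(mm / sc)
  th_fun <- if (params$white_tophat) EBImage::whiteTopHat else
    EBImage::blackTopHat
  th0 <- EBImage::imageData(th_fun(img, matrix(1, w, l)))
  th90 <- EBImage::imageData(th_fun(img, matrix(1, l, w)))
  th <- pmin(th0, th90) * sc
  # quantize over valid pixels and take local entropy
  rng <- range(th[valid])
  lv <- params$entropy_levels
  q <- if (diff(rng) > 0)
    matrix(pmin(lv - 1, floor((th - rng[1]) / diff(rng) * lv)),
           nrow(th), ncol(th))
  else matrix(0, nrow(th), ncol(th))
  q[!valid] <- -1
  storage.mode(q) <- "integer"
  ent <- .entropy_disk_cpp(q, um_to_px(params$entropy_radius, px), lv)
  # opening by reconstruction (entropy rescaled from bits to [0, 1] for the
  # EBImage erosion, which clamps grayscale to that range)
  ent0 <- ent
  ent0[is.na(ent0)] <- 0
  emax <- log2(lv)
  er <- EBImage::imageData(EBImage::erode(EBImage::Image(ent0 / emax),
                                          disc_brush(params$recon_radius, px)))
  rec <- .reconstruct_cpp(pmin(er * emax, ent0), ent0)
  rec[!valid] <- NA_real_
  out <- image_plane(rec, px, b_sdp$focal_offset, b_sdp$tag, b_sdp$timepoint)
  if (!stages) return(out)
  th[!valid] <- NA_real_
  list(enhanced = out,
       tophat = image_plane(th, px, b_sdp$focal_offset, b_sdp$tag),
       entropy = image_plane(ent, px, b_sdp$focal_offset, b_sdp$tag))
}

# Otsu threshold of a numeric vector: maximizes the between-class variance
# over a 256-bin histogram (same discretization convention as
# EBImage::otsu, against which it is cross-checked in the tests; inlined
# because the EBImage interface is frame-oriented and slow on large
# vectors). Returns the threshold and the between-class mean separation.
otsu_threshold <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  r <- range(v)
  if (diff(r) == 0) return(list(threshold = r[1], contrast = 0))
  h <- as.numeric(tabulate(pmin(levels, floor((v - r[1]) / diff(r) * levels) + 1L),
                           levels))
  mids <- (seq_len(levels) - 0.5) / levels
  w1 <- cumsum(h)
  w2 <- w1[levels] + h - w1
  cm <- h * mids
  m1 <- cumsum(cm)
  m2 <- m1[levels] + cm - m1
  bcv <- w1 * w2 * (m2 / w2 - m1 / w1)^2
  maxi <- which(bcv == max(bcv, na.rm = TRUE))
  thr_mid <- (mids[maxi[1]] + mids[maxi[length(maxi)]]) / 2
  thr <- r[1] + thr_mid * diff(r)
  fg <- v > thr
  contrast <- if (any(fg) && any(!fg)) mean(v[fg]) - mean(v[!fg]) else 0
  list(threshold = thr, contrast = contrast)
}

#' Segment colonies from an enhanced plane
#'
#' Otsu binarization, interior hole filling, inward contraction by the
#' thinning distance, a binary majority filter, connected-component
#' labelling and debris size exclusion. A minimum-contrast guard declares
#' the mask empty when the Otsu classes of the enhanced image are not
#' meaningfully separated (blank scenes).
#'
#' @param enhanced a `raft_plane` from [enhance()].
#' @param params a [bsdp_params()].
#' @return object of class `colony_mask`: list with `labels` (integer
#'   matrix, 0 = background), `pixel_size`, and `params`.
#' @export
segment_colonies <- function(enhanced, params = bsdp_params()) {
  px <- enhanced$pixel_size
  m <- enhanced$pixels
  valid <- !is.na(m)
  if (!any(valid)) stop("segment_colonies: all pixels invalid")
  ot <- otsu_threshold(m[valid])
  bw <- matrix(FALSE, nrow(m), ncol(m))
  if (ot$contrast >= params$min_contrast)
    bw[valid] <- m[valid] > ot$threshold
  if (any(bw)) {
    img <- EBImage::Image(bw * 1)
    if (params$fill_min_radius <= 0) {
      img <- EBImage::fillHull(img)
    } else {
      # fill only holes not containing a disk of the minimum radius:
      # open the hole set and restore large holes
      filled <- EBImage::fillHull(img)
      holes <- EBImage::imageData(filled) > 0.5 & !bw
      keep <- EBImage::opening(EBImage::Image(holes * 1),
                               disc_brush(params$fill_min_radius, px))
      img <- EBImage::Image((EBImage::imageData(filled) > 0.5 &
                               !(EBImage::imageData(keep) > 0.5)) * 1)
    }
    if (params$thin_um > 0)
      img <- EBImage::erode(img, disc_brush(params$thin_um, px))
    k <- params$majority_px
    cnt <- box_sum(EBImage::imageData(img), (k - 1L) %/% 2L)
    img <- EBImage::Image((cnt > k^2 / 2) * 1)
    lab <- EBImage::bwlabel(img)
    area <- tabulate(EBImage::imageData(lab))
    min_area <- pi * (params$min_colony_radius / px)^2
    drop <- which(area < min_area)
    if (length(drop)) lab <- EBImage::rmObjects(lab, drop, reenumerate = TRUE)
    labels <- EBImage::imageData(lab)
    storage.mode(labels) <- "integer"
  } else {
    labels <- matrix(0L, nrow(m), ncol(m))
  }
  labels[!valid] <- 0L
  structure(list(labels = labels, pixel_size = px, params = params),
            class = "colony_mask")
}

#' @export
print.colony_mask <- function(x, ...) {
  cat(sprintf("colony_mask: %d x %d px, %d colonies, %.3f um/px\n",
              nrow(x$labels), ncol(x$labels), max(x$labels), x$pixel_size))
  invisible(x)
}

#' Full B-SDP colony segmentation pipeline
#'
#' Composes the whole chain on raw stacks: per-plane flat-field correction
#' and normalization, rigid registration of the background onto the signal
#' (estimated on the middle focal plane, one transform per stack),
#' pixel-wise background subtraction, standard deviation z-projection,
#' contrast enhancement, and segmentation.
#'
#' @param signal,background raw `raft_zstack`s with matching focal offsets.
#' @param params a [bsdp_params()].
#' @param correct apply flat-field correction (disable if the stacks are
#'   already corrected).
#' @param diagnostics keep per-stage intermediate images.
#' @return list with `mask` (a `colony_mask`), `transform` (the estimated
#'   `raft_transform`), and if requested `diagnostics` (corrected stacks,
#'   difference stack, B-SDP, enhanced plane, and the predicted-mask SNR
#'   gain of the enhanced plane over the raw SDP).
#' @export
run_pipeline <- function(signal, background, params = bsdp_params(),
                         correct = TRUE, diagnostics = FALSE) {
  if (correct) {
    ref <- mean(signal$data[, , 1], na.rm = TRUE)
    signal <- correct_stack(signal, ref_mean = ref)
    background <- correct_stack(background, ref_mean = ref)
  }
  mid <- (n_planes(signal) + 1) %/% 2
  t <- register_rigid(stack_plane(background, mid), stack_plane(signal, mid))
  diff <- subtract_background(signal, background, t)
  b_sdp <- sdp(diff, params$std_mode)
  b_sdp$pixels <- abs(b_sdp$pixels)
  enh <- enhance(b_sdp, params)
  mask <- segment_colonies(enh, params)
  out <- list(mask = mask, transform = t)
  if (diagnostics) {
    pred <- mask$labels > 0
    gain <- if (any(pred) && !all(pred))
      snr_gain(stack_plane(signal, mid), enh, pred) else NA_real_
    out$diagnostics <- list(b_sdp = b_sdp, enhanced = enh, difference = diff,
                            snr_gain = gain)
  }
  out
}
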
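# Flat-field / illumination correction and subpixel rigid registration of
# background scans onto signal scans.

fmean <- function(x) if (anyNA(x)) mean(x, na.rm = TRUE) else mean(x)

# pad a matrix by r cells on every side, extrapolating linearly from the
# two outermost cells of each row/column
pad_linear <- function(m, r) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(0, nx + 2 * r, ny + 2 * r)
  out[(r + 1):(r + nx), (r + 1):(r + ny)] <- m
  for (k in seq_len(r)) {
    out[r + 1 - k, (r + 1):(r + ny)] <- m[1, ] + k * (m[1, ] - m[2, ])
    out[r + nx + k, (r + 1):(r + ny)] <- m[nx, ] + k * (m[nx, ] - m[nx - 1, ])
  }
  for (k in seq_len(r)) {
    out[, r + 1 - k] <- out[, r + 1] + k * (out[, r + 1] - out[, r + 2])
    out[, r + ny + k] <- out[, r + ny] + k * (out[, r + ny] - out[, r + ny - 1])
  }
  out
}

#' Rigid transform
#' @param dx,dy translation in pixels (subpixel).
#' @param dtheta rotation in degrees, about the image centre.
#' @return object of class `raft_transform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, dtheta = 0) {
  structure(list(dx = dx, dy = dy, dtheta = dtheta),
            class = "raft_transform")
}

#' @export
print.raft_transform <- function(x, ...) {
  cat(sprintf("raft_transform: dx=%.3f px, dy=%.3f px, dtheta=%.3f deg\n",
              x$dx, x$dy, x$dtheta))
  invisible(x)
}

#' Estimate the illumination flat field of a plane
#'
#' Approximates the smooth illumination/optical response by mean-filtering
#' the image in square blocks, Gaussian-smoothing at block resolution, and
#' interpolating bilinearly back to full resolution (the mean filter is
#' already a low-pass at the block scale, so smoothing below it carries no
#' extra information). Blocks larger than the image are clipped to the
#' image.
#'
#' @param plane a `raft_plane`.
#' @param block_px block edge for the mean filter, pixels.
#' @param sigma_px Gaussian kernel standard deviation, pixels.
#' @return a `raft_plane` holding the strictly positive smooth field; its
#'   mean equals the mean of the input.
#' @export
estimate_flat_field <- function(plane, block_px = 256, sigma_px = 100) {
  m <- plane$pixels
  mu <- fmean(m)
  if (!is.finite(mu) || mu <= 0)
    stop("estimate_flat_field: flat field undefined for non-positive image")
  nx <- nrow(m); ny <- ncol(m)
  bx <- min(block_px, nx); by <- min(block_px, ny)
  bm <- .block_mean_cpp(m, bx, by, mu)
  # smooth at block resolution; pad by linear extrapolation first so the
  # smoothing does not flatten illumination gradients at the field edges
  sg <- sigma_px / mean(c(bx, by))
  r <- ceiling(3 * sg)
  if (r > 0 && min(dim(bm)) >= 2) {
    bm <- pad_linear(bm, r)
    bm <- .sepgauss_cpp(bm, sg)
    bm <- bm[(r + 1):(nrow(bm) - r), (r + 1):(ncol(bm) - r), drop = FALSE]
  }
  sm <- .upsample_bilinear_cpp(bm, bx, by, nx, ny)
  sm <- pmax(sm, mu * 1e-6)
  sm <- sm * (mu / mean(sm))
  image_plane(sm, plane$pixel_size, plane$focal_offset, plane$tag,
              plane$timepoint)
}

#' Flat-field correct and normalize a plane
#'
#' Divides the plane by its flat field and rescales so the output mean
#' equals `ref_mean` (the mean intensity of the first image of the
#' time-series, by convention).
#'
#' @param plane a `raft_plane`.
#' @param flat a `raft_plane` from [estimate_flat_field()].
#' @param ref_mean target mean intensity (> 0).
#' @return corrected `raft_plane`.
#' @export
correct_plane <- function(plane, flat, ref_mean = 1) {
  stopifnot(all(dim(plane$pixels) == dim(flat$pixels)))
  if (ref_mean <= 0) stop("correct_plane: ref_mean must be positive")
  if (any(flat$pixels <= 0, na.rm = TRUE))
    stop("correct_plane: flat field must be strictly positive")
  out <- plane$pixels / flat$pixels
  out <- out * (ref_mean / fmean(out))
  image_plane(out, plane$pixel_size, plane$focal_offset, plane$tag,
              plane$timepoint)
}

# cross-correlation surface peak via FFT; returns list(shift, peak, norm)
# shift such that moving displaced by `shift` best matches fixed; `norm` is
# the peak normalized by the image energies (comparable across candidate
# rotations, where interpolation smoothing changes the raw peak)
xcorr_peak <- function(fixed, moving) {
  f <- fixed; m <- moving
  f[is.na(f)] <- 0; m[is.na(m)] <- 0
  f <- f - mean(f); m <- m - mean(m)
  # pad to 5-smooth sizes: fft is very slow on large prime factors
  nx0 <- nrow(f); ny0 <- ncol(f)
  nx <- stats::nextn(nx0, c(2, 3, 5)); ny <- stats::nextn(ny0, c(2, 3, 5))
  if (nx != nx0 || ny != ny0) {
    fp <- matrix(0, nx, ny); fp[1:nx0, 1:ny0] <- f; f <- fp
    mp <- matrix(0, nx, ny); mp[1:nx0, 1:ny0] <- m; m <- mp
  }
  Ff <- stats::fft(f); Fm <- stats::fft(m)
  cc <- Re(stats::fft(Ff * Conj(Fm), inverse = TRUE))
  i <- which.max(cc)
  ix <- (i - 1) %% nx; iy <- (i - 1) %/% nx
  if (ix > nx / 2) ix <- ix - nx
  if (iy > ny / 2) iy <- iy - ny
  en <- sqrt(sum(f^2) * sum(m^2))
  list(shift = c(ix, iy), peak = max(cc),
       norm = if (en > 0) max(cc) / en else 0)
}

# upsampled cross-correlation in a small neighbourhood of `shift` via
# matrix-multiply DFT (single-step subpixel refinement)
xcorr_refine <- function(fixed, moving, shift, upsample) {
  f <- fixed; m <- moving
  f[is.na(f)] <- 0; m[is.na(m)] <- 0
  f <- f - mean(f); m <- m - mean(m)
  nx0 <- nrow(f); ny0 <- ncol(f)
  nx <- stats::nextn(nx0, c(2, 3, 5)); ny <- stats::nextn(ny0, c(2, 3, 5))
  if (nx != nx0 || ny != ny0) {
    fp <- matrix(0, nx, ny); fp[1:nx0, 1:ny0] <- f; f <- fp
    mp <- matrix(0, nx, ny); mp[1:nx0, 1:ny0] <- m; m <- mp
  }
  X <- stats::fft(f) * Conj(stats::fft(m))
  # sample the correlation at points shift + [-0.75, 0.75] / step 1/upsample
  half <- ceiling(0.75 * upsample)
  sx <- shift[1] + (-half:half) / upsample
  sy <- shift[2] + (-half:half) / upsample
  kx <- c(0:floor((nx - 1) / 2), -(ceiling((nx - 1) / 2):1)) / nx
  ky <- c(0:floor((ny - 1) / 2), -(ceiling((ny - 1) / 2):1)) / ny
  Ex <- exp(2i * pi * outer(sx, kx))        # length(sx) x nx
  Ey <- exp(2i * pi * outer(ky, sy))        # ny x length(sy)
  cc <- Re(Ex %*% X %*% Ey)
  i <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  list(shift = c(sx[i[1]], sy[i[2]]), peak = max(cc))
}

# 2x block binning (for the rotation search)
bin2 <- function(m) {
  nx <- 2 * (nrow(m) %/% 2); ny <- 2 * (ncol(m) %/% 2)
  m <- m[seq_len(nx), seq_len(ny)]
  (m[seq(1, nx, 2), seq(1, ny, 2)] + m[seq(2, nx, 2), seq(1, ny, 2)] +
     m[seq(1, nx, 2), seq(2, ny, 2)] + m[seq(2, nx, 2), seq(2, ny, 2)]) / 4
}

#' Register a moving plane onto a fixed plane (rigid, subpixel)
#'
#' Grid search over rotation (applied about the image centre), with the
#' translation at each angle scored by the FFT cross-correlation peak; the
#' winning angle's translation is refined to `1/upsample` pixel by a
#' single-step upsampled discrete Fourier transform. The angle search runs
#' on 2x-binned images; the final translation uses full resolution.
#'
#' @param moving,fixed `raft_plane`s of identical shape.
#' @param theta_range half-range of the rotation search, degrees.
#' @param theta_step rotation step, degrees.
#' @param upsample translation upsampling factor (default 20, i.e. 0.05 px).
#' @return a `raft_transform` `t` such that `apply_transform(moving, t)`
#'   aligns onto `fixed`.
#' @export
register_rigid <- function(moving, fixed, theta_range = 0.5,
                           theta_step = 0.05, upsample = 20) {
  stopifnot(all(dim(moving$pixels) == dim(fixed$pixels)))
  mv <- moving$pixels; fx <- fixed$pixels
  if (stats::sd(mv, na.rm = TRUE) == 0 || stats::sd(fx, na.rm = TRUE) == 0)
    stop("register_rigid: constant image, registration undefined")
  mv_s <- bin2(mv); fx_s <- bin2(fx)
  cx_s <- nrow(mv_s) / 2; cy_s <- ncol(mv_s) / 2
  # cache the fixed image's padded FFT across the angle grid
  fxz <- fx_s
  fxz[is.na(fxz)] <- 0
  fxz <- fxz - mean(fxz)
  pnx <- stats::nextn(nrow(fxz), c(2, 3, 5))
  pny <- stats::nextn(ncol(fxz), c(2, 3, 5))
  fpad <- matrix(0, pnx, pny)
  fpad[seq_len(nrow(fxz)), seq_len(ncol(fxz))] <- fxz
  Ff <- stats::fft(fpad)
  ef <- sqrt(sum(fxz^2))
  mmean <- mean(mv_s, na.rm = TRUE)
  score <- function(th) {
    rot <- if (th == 0) mv_s else {
      r <- .warp_rigid_cpp(mv_s, 0, 0, th, cx_s, cy_s)
      r[is.na(r)] <- mmean
      r
    }
    rot[is.na(rot)] <- mmean
    rot <- rot - mean(rot)
    mpad <- matrix(0, pnx, pny)
    mpad[seq_len(nrow(rot)), seq_len(ncol(rot))] <- rot
    cc <- Re(stats::fft(Ff * Conj(stats::fft(mpad)), inverse = TRUE))
    max(cc) / (ef * sqrt(sum(rot^2)))
  }
  th <- 0
  if (theta_range > 0) {
    # coarse grid at twice the step, then refine the midpoints around the
    # winner, resolving the full step at ~60% of the evaluations
    coarse <- seq(-theta_range, theta_range, 2 * theta_step)
    sc <- vapply(coarse, score, numeric(1))
    th <- coarse[which.max(sc)]
    best <- max(sc)
    for (cand in th + c(-theta_step, theta_step)) {
      if (abs(cand) > theta_range + 1e-9) next
      s <- score(cand)
      if (s > best) { best <- s; th <- cand }
    }
  }
  rot <- if (th == 0) mv else {
    r <- .warp_rigid_cpp(mv, 0, 0, th, nrow(mv) / 2, ncol(mv) / 2)
    r[is.na(r)] <- mean(mv, na.rm = TRUE)
    r
  }
  co <- xcorr_peak(fx, rot)
  fine <- xcorr_refine(fx, rot, co$shift, upsample)
  rigid_transform(fine$shift[1], fine$shift[2], th)
}

#' Apply a rigid transform to a z-stack or plane
#'
#' Every plane is resampled (bilinear) by the same transform; pixels drawn
#' from outside the frame become `NA` and are excluded downstream.
#'
#' @param x a `raft_zstack` or `raft_plane`.
#' @param t a `raft_transform`.
#' @return transformed object of the same class.
#' @export
apply_transform <- function(x, t) {
  stopifnot(inherits(t, "raft_transform"))
  warp1 <- function(m) {
    if (t$dx == 0 && t$dy == 0 && t$dtheta == 0) return(m)
    .warp_rigid_cpp(m, t$dx, t$dy, t$dtheta, nrow(m) / 2, ncol(m) / 2)
  }
  if (inherits(x, "raft_plane")) {
    out <- x
    out$pixels <- warp1(x$pixels)
    return(out)
  }
  stopifnot(inherits(x, "raft_zstack"))
  out <- x
  for (k in seq_len(n_planes(x))) out$data[, , k] <- warp1(x$data[, , k])
  out
}

#' Invert a rigid transform
#' @param t a `raft_transform`.
#' @return the inverse `raft_transform` (exact for rotation about centre).
#' @export
invert_transform <- function(t) {
  th <- -t$dtheta * pi / 180
  dx <- -(cos(th) * t$dx - sin(th) * t$dy)
  dy <- -(sin(th) * t$dx + cos(th) * t$dy)
  rigid_transform(dx, dy, -t$dtheta)
}

#' Flat-field correct every plane of a z-stack
#'
#' Per-plane flat-field estimation and correction, normalized to a common
#' reference mean.
#'
#' @param stack a `raft_zstack`.
#' @param ref_mean reference mean; default the mean of the first plane.
#' @param block_px,sigma_px passed to [estimate_flat_field()].
#' @return corrected `raft_zstack`.
#' @export
correct_stack <- function(stack, ref_mean = NULL, block_px = 256,
                          sigma_px = 100) {
  if (is.null(ref_mean)) ref_mean <- fmean(stack$data[, , 1])
  out <- stack
  for (k in seq_len(n_planes(stack))) {
    pl <- stack_plane(stack, k)
    ff <- estimate_flat_field(pl, block_px, sigma_px)
    out$data[, , k] <- correct_plane(pl, ff, ref_mean)$pixels
  }
  out
}
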
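# Synthetic quad microraft array renderer.
#
# Scenes are generated in a canonical "array frame" (no rotation, no scan
# offset) and mapped into the background or signal scan frame by a rigid
# transform; the smooth lattice distortion lives in the array frame. Region
# identity (raft interior / rim / intra-quad gap / barrier) and the cell
# mask are computed analytically per pixel through the inverse map, so
# ground truth is exact as drawn.

# intensity model (bright-field-like, background mean ~1)
.int_raft <- 1.00
.int_rim  <- 0.90
.int_pdms <- 0.78
.tex_sd       <- 0.03 # static background texture amplitude
.tex_scale_um <- 3    # texture correlation length
.cell_amp     <- 0.25 # focus-varying cell speckle amplitude
.cell_scale_um <- 5   # speckle correlation length
.halo_amp     <- 0.20 # perimeter halo amplitude
.halo_width_um <- 6.5
# focal decorrelation length of cell appearance, um: planes further apart
# than this show (nearly) independent punctate patterns; closer planes look
# alike, so the standard-deviation projection loses contrast as plane
# spacing shrinks (roughly half the objective depth of focus)
.cell_decor_um <- 15

# electro-luminescent release imaging intensities
.el_raft  <- 0.55
.el_empty <- 0.95
.el_pdms  <- 0.35

with_seed <- function(seed, code) {
  force(seed) # evaluate before snapshotting: the caller may draw it inline
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sub_seed <- function(seed, i) (as.numeric(seed) * 1013 + i * 7919) %% 2147483647

eb_gblur <- function(m, sigma) .sepgauss_cpp(m, sigma)

# smooth unit-variance random field
random_field <- function(nx, ny, scale_px, seed) {
  w <- with_seed(seed, matrix(stats::rnorm(nx * ny), nx, ny))
  f <- eb_gblur(w, max(scale_px, 0.5))
  f / stats::sd(f)
}

# sinusoidal lattice distortion, array-frame um coordinates -> displacement um
distortion_field <- function(spec, ax, ay) {
  A <- spec$distortion_amplitude
  if (A <= 0) return(list(dx = 0, dy = 0))
  lam <- spec$distortion_wavelength
  ph <- with_seed(sub_seed(spec$seed, 11), stats::runif(2, 0, 2 * pi))
  list(dx = A * sin(2 * pi * ay / lam + ph[1]),
       dy = A * sin(2 * pi * ax / lam + ph[2]))
}

quad_jitter <- function(spec) {
  g <- spec$geometry
  n <- g$quad_rows * g$quad_cols
  if (spec$jitter_sd <= 0) return(matrix(0, n, 2))
  with_seed(sub_seed(spec$seed, 12),
            matrix(stats::rnorm(2 * n, sd = spec$jitter_sd), n, 2))
}

# pixel-centre coordinate grids, um
pixel_grids <- function(dim_px, pixel_size) {
  x <- (seq_len(dim_px[1]) - 0.5) * pixel_size
  y <- (seq_len(dim_px[2]) - 0.5) * pixel_size
  list(ax = matrix(x, dim_px[1], dim_px[2]),
       ay = matrix(y, dim_px[1], dim_px[2], byrow = TRUE))
}

# inverse rigid map: scan-frame um -> array-frame um (before distortion)
inverse_rigid <- function(px, py, theta_deg, tx, ty, cx, cy) {
  th <- theta_deg * pi / 180
  ux <- px - tx - cx; uy <- py - ty - cy
  list(ax = cos(th) * ux + sin(th) * uy + cx,
       ay = -sin(th) * ux + cos(th) * uy + cy)
}

# forward rigid map: array-frame um -> scan-frame um
forward_rigid <- function(ax, ay, theta_deg, tx, ty, cx, cy) {
  th <- theta_deg * pi / 180
  ux <- ax - cx; uy <- ay - cy
  list(x = cos(th) * ux - sin(th) * uy + cx + tx,
       y = sin(th) * ux + cos(th) * uy + cy + ty)
}

# Resolve every pixel of a scan frame into array structure.
# Returns quad row/col (0-based, NA outside), within-quad coords wx/wy (um),
# and region code: 0 PDMS field/barrier, 1 raft interior, 2 intra-quad gap,
# 3 raft rim.
resolve_array <- function(spec, frame = c("background", "signal")) {
  frame <- match.arg(frame)
  g <- spec$geometry
  dpx <- geometry_image_dim(g)
  pg <- pixel_grids(dpx, g$pixel_size)
  cx <- dpx[1] * g$pixel_size / 2
  cy <- dpx[2] * g$pixel_size / 2
  off <- if (frame == "signal") spec$background_signal_offset else c(0, 0, 0)
  inv <- inverse_rigid(pg$ax, pg$ay, spec$rotation + off[3], off[1], off[2],
                       cx, cy)
  d <- distortion_field(spec, inv$ax, inv$ay)
  ax <- inv$ax - d$dx
  ay <- inv$ay - d$dy

  o <- lattice_origin_um(g)
  pitch <- g$quad_pitch
  colf <- floor((ax - o + pitch / 2) / pitch)
  rowf <- floor((ay - o + pitch / 2) / pitch)
  inside <- colf >= 0 & colf < g$quad_cols & rowf >= 0 & rowf < g$quad_rows
  colf[!inside] <- NA; rowf[!inside] <- NA
  wx <- ax - o - colf * pitch
  wy <- ay - o - rowf * pitch
  jit <- quad_jitter(spec)
  if (any(jit != 0)) {
    q <- rowf * g$quad_cols + colf + 1
    ok <- !is.na(q)
    wx[ok] <- wx[ok] - jit[q[ok], 1]
    wy[ok] <- wy[ok] - jit[q[ok], 2]
  }

  g2 <- g$intra_quad_gap / 2
  half <- g$quad_side / 2
  rim <- 2 * g$pixel_size # rendered rim line width, um
  axq <- abs(wx); ayq <- abs(wy)
  in_quad <- inside & axq <= half & ayq <= half
  in_gap <- in_quad & (axq <= g2 | ayq <= g2)
  in_raft <- in_quad & !in_gap
  near_edge <- in_raft &
    (pmin(axq - g2, half - axq) <= rim | pmin(ayq - g2, half - ayq) <= rim)
  region <- matrix(0L, dpx[1], dpx[2])
  region[in_raft] <- 1L
  region[in_gap] <- 2L
  region[near_edge] <- 3L
  list(row = rowf, col = colf, wx = wx, wy = wy, region = region,
       dim = dpx, centre = c(cx, cy))
}

# cell mask from the colony table, given a resolved frame
draw_cells <- function(spec, res) {
  g <- spec$geometry
  mask <- matrix(FALSE, res$dim[1], res$dim[2])
  labels <- matrix(0L, res$dim[1], res$dim[2])
  if (!nrow(spec$colonies)) return(list(mask = mask, labels = labels))
  g2 <- g$intra_quad_gap / 2
  rs <- g$raft_side
  qid <- res$row * g$quad_cols + res$col
  for (k in seq_len(nrow(spec$colonies))) {
    cl <- spec$colonies[k, ]
    sel <- !is.na(qid) & qid == cl$row * g$quad_cols + cl$col
    if (!any(sel)) next
    wx <- res$wx[sel]; wy <- res$wy[sel]
    f <- c(cl$cov_nw, cl$cov_ne, cl$cov_sw, cl$cov_se)
    p <- cl$pdms
    covered <- logical(length(wx))
    # raft strips anchored at the intra-quad gap
    inL <- wx < -g2 & wx >= -g2 - rs # raft column left of the gap
    inR <- wx >  g2 & wx <=  g2 + rs
    covered <- covered |
      (inL & wy < -g2 & wy >= -g2 - f[1] * rs) |  # NW
      (inR & wy < -g2 & wy >= -g2 - f[2] * rs) |  # NE
      (inL & wy >  g2 & wy <=  g2 + f[3] * rs) |  # SW
      (inR & wy >  g2 & wy <=  g2 + f[4] * rs)    # SE
    if (p > 0) {
      bw <- g2 * min(1, p) # covered half-width of the gap bands
      covered <- covered |
        (abs(wx) <= bw & wy < -g2 & min(f[1], f[2]) > 0 &
           wy >= -g2 - min(f[1], f[2]) * rs) |
        (abs(wx) <= bw & wy >  g2 & min(f[3], f[4]) > 0 &
           wy <=  g2 + min(f[3], f[4]) * rs) |
        (abs(wy) <= bw & wx < -g2 & wx >= -g2 - rs & min(f[1], f[3]) > 0) |
        (abs(wy) <= bw & wx >  g2 & wx <=  g2 + rs & min(f[2], f[4]) > 0) |
        (abs(wx) <= bw & abs(wy) <= bw & min(f) > 0)
    }
    idx <- which(sel)[covered]
    mask[idx] <- TRUE
    labels[idx] <- k
  }
  list(mask = mask, labels = labels)
}

# canonical (unwarped) static background image incl. texture, no
# illumination or noise; computed in the requested frame directly since the
# region map is analytic
background_image <- function(spec, frame) {
  res <- resolve_array(spec, frame)
  base <- matrix(.int_pdms, res$dim[1], res$dim[2])
  base[res$region == 1L] <- .int_raft
  base[res$region == 3L] <- .int_rim
  tex <- random_field(res$dim[1], res$dim[2],
                      .tex_scale_um / spec$geometry$pixel_size,
                      sub_seed(spec$seed, 1)) * .tex_sd
  # texture is attached to the array: generate in array frame and warp when
  # the frames differ
  if (frame == "signal" &&
      any(spec$background_signal_offset != 0)) {
    off <- spec$background_signal_offset
    tex <- .warp_rigid_cpp(tex, off[1] / spec$geometry$pixel_size,
                           off[2] / spec$geometry$pixel_size, off[3],
                           res$dim[1] / 2, res$dim[2] / 2)
    tex[is.na(tex)] <- 0
  }
  list(img = base + tex, res = res)
}

illumination_ramp <- function(spec, dim_px, which_scan) {
  if (spec$illumination_gradient <= 0) return(1)
  ph <- with_seed(sub_seed(spec$seed, 13), stats::runif(2, 0, 2 * pi))
  phi <- if (which_scan == "background") ph[1] else ph[2]
  pg <- pixel_grids(dim_px, 1)
  1 + spec$illumination_gradient *
    ((pg$ax / dim_px[1] - 0.5) * cos(phi) + (pg$ay / dim_px[2] - 0.5) * sin(phi))
}

add_noise <- function(img, spec, seed) {
  if (spec$noise_sd <= 0) return(img)
  img + with_seed(seed, matrix(stats::rnorm(length(img), sd = spec$noise_sd),
                               nrow(img), ncol(img)))
}

#' Render the pre-seeding background z-stack of a scene
#'
#' The microraft array before any cells: raft interiors, rim lines and PDMS
#' rendered at distinct mean intensities with a fine static texture that is
#' identical across focal offsets (the background is focus-invariant); a
#' linear illumination ramp and per-plane sensor noise are applied on top.
#'
#' @param spec a [scene_spec()].
#' @return a `raft_zstack` tagged `"background"`.
#' @export
render_array_background <- function(spec) {
  stopifnot(inherits(spec, "raft_scene_spec"))
  bg <- background_image(spec, "background")
  ramp <- illumination_ramp(spec, bg$res$dim, "background")
  nk <- length(spec$focal_offsets)
  data <- array(NA_real_, c(bg$res$dim, nk))
  for (k in seq_len(nk))
    data[, , k] <- add_noise(bg$img * ramp, spec, sub_seed(spec$seed, 100 + k))
  zstack(data, spec$geometry$pixel_size, spec$focal_offsets, "background")
}

#' Render the cell-laden signal z-stack of a scene, with ground truth
#'
#' The background component is the same array as
#' [render_array_background()], rigidly shifted/rotated by the scene's
#' background/signal scan offset. Cells are rendered only inside the
#' ground-truth mask, as punctate speckle plus a perimeter halo whose
#' pattern changes between focal offsets (cells are focus-varying; the
#' background is not).
#'
#' @param spec a [scene_spec()].
#' @return list with elements `stack` (a `raft_zstack` tagged `"signal"`)
#'   and `truth` (see [scene_truth()]).
#' @export
render_signal_stack <- function(spec) {
  stopifnot(inherits(spec, "raft_scene_spec"))
  bg <- background_image(spec, "signal")
  res <- bg$res
  cells <- draw_cells(spec, res)
  ramp <- illumination_ramp(spec, res$dim, "signal")
  px <- spec$geometry$pixel_size
  halo <- NULL
  if (any(cells$mask)) {
    r <- max(1, round(.halo_width_um / px))
    er <- EBImage::erode(EBImage::Image(cells$mask * 1),
                         EBImage::makeBrush(2 * r + 1, "disc"))
    halo <- cells$mask & !(EBImage::imageData(er) > 0.5)
  }
  nk <- length(spec$focal_offsets)
  data <- array(NA_real_, c(res$dim, nk))
  # base (in-focus) cell appearance, mixed per plane with an independent
  # field in proportion to the plane's defocus
  if (any(cells$mask)) {
    sp0 <- random_field(res$dim[1], res$dim[2], .cell_scale_um / px,
                        sub_seed(spec$seed, 310))
    hp0 <- random_field(res$dim[1], res$dim[2], .cell_scale_um / px,
                        sub_seed(spec$seed, 410))
  }
  for (k in seq_len(nk)) {
    img <- bg$img
    if (any(cells$mask)) {
      a <- min(1, abs(spec$focal_offsets[k]) / .cell_decor_um)
      sp <- sqrt(1 - a^2) * sp0 +
        a * random_field(res$dim[1], res$dim[2], .cell_scale_um / px,
                         sub_seed(spec$seed, 300 + k))
      img[cells$mask] <- img[cells$mask] + .cell_amp * sp[cells$mask]
      hp <- sqrt(1 - a^2) * hp0 +
        a * random_field(res$dim[1], res$dim[2], .cell_scale_um / px,
                         sub_seed(spec$seed, 400 + k))
      img[halo] <- img[halo] + .halo_amp * abs(hp[halo])
    }
    data[, , k] <- add_noise(img * ramp, spec, sub_seed(spec$seed, 200 + k))
  }
  truth <- scene_truth(spec, res, cells)
  list(stack = zstack(data, px, spec$focal_offsets, "signal"), truth = truth)
}

#' Ground truth of a rendered scene
#'
#' Exact, as-drawn truth for a signal render: the pixelwise cell mask,
#' per-colony labels, per-raft drawn coverage fractions, drawn intra-quad
#' PDMS coverage, and quad/raft centroids in the signal frame.
#'
#' @param spec a [scene_spec()].
#' @param res,cells internal resolved-frame objects; supplied by
#'   [render_signal_stack()]. If `NULL`, recomputed from `spec`.
#' @return list with `cell_mask`, `colony_labels`, `coverage` (data.frame:
#'   `colony`, `row`, `col`, `sub`, `drawn`, `requested`), `pdms`
#'   (data.frame per colony), `quads` (data.frame of quad centroids `row`,
#'   `col`, `x`, `y` um) and `rafts` (per sub-raft centroids).
#' @export
scene_truth <- function(spec, res = NULL, cells = NULL) {
  if (is.null(res)) res <- resolve_array(spec, "signal")
  if (is.null(cells)) cells <- draw_cells(spec, res)
  g <- spec$geometry
  cov <- NULL
  pdms <- NULL
  if (nrow(spec$colonies)) {
    g2 <- g$intra_quad_gap / 2
    qid <- res$row * g$quad_cols + res$col
    sub <- c("NW", "NE", "SW", "SE")
    rows <- list()
    for (k in seq_len(nrow(spec$colonies))) {
      cl <- spec$colonies[k, ]
      sel <- !is.na(qid) & qid == cl$row * g$quad_cols + cl$col
      wx <- res$wx[sel]; wy <- res$wy[sel]
      on <- cells$labels[sel] == k
      raft_of <- ifelse(res$region[sel] %in% c(1L, 3L),
                        ifelse(wy < 0, ifelse(wx < 0, 1L, 2L),
                               ifelse(wx < 0, 3L, 4L)), NA_integer_)
      req <- c(cl$cov_nw, cl$cov_ne, cl$cov_sw, cl$cov_se)
      for (s in 1:4) {
        in_raft <- !is.na(raft_of) & raft_of == s
        rows[[length(rows) + 1]] <- data.frame(
          colony = k, row = cl$row, col = cl$col, sub = sub[s],
          drawn = if (any(in_raft)) mean(on[in_raft]) else NA_real_,
          requested = req[s])
      }
      in_gap <- res$region[sel] == 2L
      pdms <- rbind(pdms, data.frame(
        colony = k, row = cl$row, col = cl$col,
        drawn_pdms = if (any(in_gap)) mean(on[in_gap]) else NA_real_,
        requested_pdms = cl$pdms))
    }
    cov <- do.call(rbind, rows)
  }
  quads <- scene_truth_centroids(spec, "signal")
  list(cell_mask = cells$mask, colony_labels = cells$labels,
       coverage = cov, pdms = pdms, quads = quads$quads, rafts = quads$rafts)
}

#' Analytic quad and raft centroids of a scene
#'
#' Forward-maps the closed-form lattice (plus distortion and jitter) into
#' the requested scan frame. This is the oracle the grid detector is tested
#' against.
#'
#' @param spec a [scene_spec()].
#' @param frame `"signal"` or `"background"`.
#' @return list of data.frames `quads` (`row`, `col`, `x`, `y`) and `rafts`
#'   (`row`, `col`, `sub`, `x`, `y`), um in the scan frame.
#' @export
scene_truth_centroids <- function(spec, frame = c("signal", "background")) {
  frame <- match.arg(frame)
  g <- spec$geometry
  lat <- lattice_centroids(g)
  jit <- quad_jitter(spec)
  q <- lat$row * g$quad_cols + lat$col + 1
  ax <- lat$x + jit[q, 1]
  ay <- lat$y + jit[q, 2]
  d <- distortion_field(spec, ax, ay)
  ax <- ax + d$dx; ay <- ay + d$dy
  dpx <- geometry_image_dim(g)
  cx <- dpx[1] * g$pixel_size / 2; cy <- dpx[2] * g$pixel_size / 2
  off <- if (frame == "signal") spec$background_signal_offset else c(0, 0, 0)
  fw <- forward_rigid(ax, ay, spec$rotation + off[3], off[1], off[2], cx, cy)
  quads <- data.frame(row = lat$row, col = lat$col, x = fw$x, y = fw$y)
  so <- subraft_offsets(g)
  rafts <- do.call(rbind, lapply(1:4, function(s) {
    fo <- forward_rigid(ax + so[s, 1], ay + so[s, 2],
                        spec$rotation + off[3], off[1], off[2], cx, cy)
    data.frame(row = lat$row, col = lat$col, sub = rownames(so)[s],
               x = fo$x, y = fo$y)
  }))
  list(quads = quads, rafts = rafts)
}

#' Render a single electro-luminescent release-imaging frame
#'
#' One microwell viewed in transillumination during microneedle release:
#' remaining raft material blocks light (dark), cleared well area transmits
#' (bright), surrounding PDMS is darkest. A connected region covering
#' `remaining_fraction` of the well, offset by `displacement`, renders at
#' raft intensity.
#'
#' @param geometry a `raft_geometry`.
#' @param remaining_fraction fraction of the well still covered by raft
#'   material, in `[0, 1]`.
#' @param displacement length-2 `(dx, dy)` um offset of the remaining
#'   material from the well centre.
#' @param margin_um PDMS margin rendered around the well footprint.
#' @param noise_sd Gaussian noise added to the frame.
#' @param seed seed for the noise.
#' @return a `raft_plane` (tag `"signal"`) with attribute `well_footprint`,
#'   a logical matrix marking the well.
#' @export
render_el_release_frame <- function(geometry, remaining_fraction = 1,
                                    displacement = c(0, 0), margin_um = 50,
                                    noise_sd = 0.01, seed = 1L) {
  stopifnot(remaining_fraction >= 0, remaining_fraction <= 1)
  px <- geometry$pixel_size
  side <- geometry$raft_side
  dimp <- rep(ceiling((side + 2 * margin_um) / px), 2)
  pg <- pixel_grids(dimp, px)
  cx <- dimp[1] * px / 2; cy <- dimp[2] * px / 2
  well <- abs(pg$ax - cx) <= side / 2 & abs(pg$ay - cy) <= side / 2
  img <- matrix(.el_pdms, dimp[1], dimp[2])
  img[well] <- .el_empty
  if (remaining_fraction > 0) {
    # remaining material: square patch of the right area, centred on the
    # displaced material centroid
    half <- side * sqrt(remaining_fraction) / 2
    mx <- cx + displacement[1]; my <- cy + displacement[2]
    mat <- abs(pg$ax - mx) <= half & abs(pg$ay - my) <= half
    img[mat] <- .el_raft
  }
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img),
                                                     sd = noise_sd),
                                        dimp[1], dimp[2]))
  out <- image_plane(img, px, 0, "signal")
  attr(out, "well_footprint") <- well
  out
}

#' Random colony batch spanning the four raft-count classes
#'
#' Draws `n` colonies at distinct random quads. Covered rafts form a
#' contiguous pattern (single, adjacent pair, L, or full quad) with
#' coverages in `[0.6, 0.95]`; uncovered rafts get `[0, 0.35]`; intra-quad
#' PDMS overgrowth bridges covered rafts.
#'
#' @param geometry a `raft_geometry`.
#' @param n number of colonies.
#' @param seed integer seed.
#' @param classes raft-count classes to sample from.
#' @return colonies data.frame in the [scene_spec()] layout, with an extra
#'   column `class` (the generating raft-count class).
#' @export
random_colonies <- function(geometry, n, seed = 1L, classes = 1:4) {
  nq <- geometry$quad_rows * geometry$quad_cols
  stopifnot(n <= nq)
  with_seed(seed, {
    quads <- sample.int(nq, n) - 1L
    cls <- sample(classes, n, replace = TRUE)
    # contiguous covered patterns by class (indices NW, NE, SW, SE)
    pats <- list(`1` = list(1, 2, 3, 4),
                 `2` = list(c(1, 2), c(3, 4), c(1, 3), c(2, 4)),
                 `3` = list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)),
                 `4` = list(1:4))
    cov <- matrix(0, n, 4)
    for (i in seq_len(n)) {
      ps <- pats[[as.character(cls[i])]]
      on <- ps[[sample.int(length(ps), 1)]]
      cov[i, on] <- stats::runif(length(on), 0.6, 0.95)
      off <- setdiff(1:4, on)
      if (length(off)) cov[i, off] <- stats::runif(length(off), 0, 0.35)
    }
    data.frame(row = quads %/% geometry$quad_cols,
               col = quads %% geometry$quad_cols,
               cov_nw = cov[, 1], cov_ne = cov[, 2], cov_sw = cov[, 3],
               cov_se = cov[, 4],
               pdms = stats::runif(n, 0.4, 0.8), class = cls)
  })
}

#' Multi-day colony growth schedule
#'
#' A simple growth model for time-series fixtures: each colony starts on
#' one raft and spreads over its quad at a per-colony rate, mimicking
#' adherent colonies expanding across the small intra-quad gap.
#'
#' @param geometry a `raft_geometry`.
#' @param n_colonies number of colonies.
#' @param timepoints number of (daily) timepoints.
#' @param seed integer seed.
#' @return list of colonies data.frames, one per timepoint.
#' @export
growth_schedule <- function(geometry, n_colonies, timepoints, seed = 1L) {
  nq <- geometry$quad_rows * geometry$quad_cols
  stopifnot(n_colonies <= nq)
  with_seed(seed, {
    quads <- sample.int(nq, n_colonies) - 1L
    rate <- stats::runif(n_colonies, 0.12, 0.30)  # coverage per day
    start <- sample.int(4, n_colonies, replace = TRUE)
    # spread order: start raft, then its two neighbours, then diagonal
    nbr <- list(c(1, 2, 3, 4), c(2, 1, 4, 3), c(3, 1, 4, 2), c(4, 2, 3, 1))
    lapply(seq_len(timepoints), function(t) {
      cov <- matrix(0, n_colonies, 4)
      for (i in seq_len(n_colonies)) {
        total <- rate[i] * t * 4 # total coverage budget in raft units
        ord <- nbr[[start[i]]]
        for (s in ord) {
          take <- min(0.95, total)
          cov[i, s] <- max(take, 0)
          total <- total - take
          if (total <= 0.05) break
        }
      }
      keep <- rowSums(cov) > 0.05
      data.frame(row = quads %/% geometry$quad_cols,
                 col = quads %% geometry$quad_cols,
                 cov_nw = cov[, 1], cov_ne = cov[, 2], cov_sw = cov[, 3],
                 cov_se = cov[, 4], pdms = 0.6)[keep, , drop = FALSE]
    })
  })
}
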
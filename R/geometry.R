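#' Quad microraft array geometry
#'
#' Physical layout of a quad microraft array: square microrafts arranged in
#' 2x2 clusters ("quads") separated internally by a narrow PDMS gap and from
#' neighbouring quads by a wide PDMS barrier. The quad pitch is
#' `2 * raft_side + intra_quad_gap + barrier_width` (530 um under defaults).
#'
#' @param raft_side microraft side length, um.
#' @param intra_quad_gap PDMS gap between rafts of the same quad, um.
#' @param barrier_width PDMS barrier between neighbouring quads, um.
#' @param quad_rows,quad_cols number of quad rows/columns in the array.
#' @param pixel_size working pixel pitch, um per pixel.
#' @param raft_wall_height microwell wall height, um (informational).
#' @return An object of class `raft_geometry`.
#' @export
array_geometry <- function(raft_side = 200, intra_quad_gap = 30,
                           barrier_width = 100, quad_rows = 41,
                           quad_cols = 41, pixel_size = 1.625,
                           raft_wall_height = 50) {
  stopifnot(raft_side > 0, intra_quad_gap > 0, barrier_width > 0,
            quad_rows >= 1, quad_cols >= 1, pixel_size > 0)
  if (pixel_size > intra_quad_gap / 4)
    stop("array_geometry: pixel_size must be <= intra_quad_gap/4 so the ",
         "intra-quad gaps are resolvable")
  g <- list(raft_side = raft_side, intra_quad_gap = intra_quad_gap,
            barrier_width = barrier_width, quad_rows = as.integer(quad_rows),
            quad_cols = as.integer(quad_cols), pixel_size = pixel_size,
            raft_wall_height = raft_wall_height)
  g$quad_side <- 2 * raft_side + intra_quad_gap
  g$quad_pitch <- g$quad_side + barrier_width
  class(g) <- "raft_geometry"
  g
}

#' @export
print.raft_geometry <- function(x, ...) {
  cat(sprintf("raft_geometry: %dx%d quads, raft %g um, gap %g um, barrier %g um, pitch %g um, %g um/px\n",
              x$quad_rows, x$quad_cols, x$raft_side, x$intra_quad_gap,
              x$barrier_width, x$quad_pitch, x$pixel_size))
  invisible(x)
}

# margin of PDMS field around the array, um
scene_margin_um <- 50

# image dimensions in pixels for a geometry
geometry_image_dim <- function(geometry) {
  w <- geometry$quad_cols * geometry$quad_pitch + 2 * scene_margin_um
  h <- geometry$quad_rows * geometry$quad_pitch + 2 * scene_margin_um
  c(ceiling(w / geometry$pixel_size), ceiling(h / geometry$pixel_size))
}

# centre of the first (row 0, col 0) quad in undistorted array coords, um
lattice_origin_um <- function(geometry) {
  scene_margin_um + geometry$barrier_width / 2 + geometry$quad_side / 2
}

#' Closed-form quad centre positions on the undistorted lattice
#'
#' @param geometry a `raft_geometry`.
#' @return data.frame with columns `row`, `col` (0-based) and `x`, `y` (um).
#' @export
lattice_centroids <- function(geometry) {
  o <- lattice_origin_um(geometry)
  grid <- expand.grid(col = seq_len(geometry$quad_cols) - 1L,
                      row = seq_len(geometry$quad_rows) - 1L)
  data.frame(row = grid$row, col = grid$col,
             x = o + grid$col * geometry$quad_pitch,
             y = o + grid$row * geometry$quad_pitch)
}

# sub-raft centre offsets relative to the quad centre, um
# (x right, y down; rows of the matrix named by sub-raft)
subraft_offsets <- function(geometry) {
  h <- (geometry$raft_side + geometry$intra_quad_gap) / 2
  rbind(NW = c(-h, -h), NE = c(h, -h), SW = c(-h, h), SE = c(h, h))
}

#' Scene specification for the synthetic renderer
#'
#' Defines everything needed to render one background/signal scene pair:
#' array geometry, colonies (per-quad coverage), a smooth sinusoidal
#' distortion of the lattice, global rotation, the rigid misregistration
#' between the background and signal scans, illumination gradient, sensor
#' noise and focal offsets. The same spec plus the same seed renders
#' bit-identical output.
#'
#' @param geometry a `raft_geometry`; the renderer default is a reduced 8x8
#'   array at 3.25 um/px so scene batches stay desk-sized.
#' @param colonies data.frame with columns `row`, `col` (0-based quad
#'   index), `cov_nw`, `cov_ne`, `cov_sw`, `cov_se` (fractions in `[0, 1]`)
#'   and `pdms` (intra-quad PDMS overgrowth fraction). May be empty.
#' @param distortion_amplitude,distortion_wavelength sinusoidal lattice
#'   distortion, um.
#' @param jitter_sd independent centroid jitter, um (applied to lattice
#'   sites, not to pixels).
#' @param rotation global array rotation about the image centre, degrees.
#' @param background_signal_offset length-3 numeric `(dx um, dy um, dtheta
#'   deg)`: rigid offset of the signal scan relative to the background scan.
#' @param illumination_gradient relative amplitude of the linear
#'   illumination ramp across the field.
#' @param noise_sd Gaussian sensor noise, fraction of the mean background
#'   intensity.
#' @param focal_offsets per-plane focal offsets, um; at least two.
#' @param seed integer random seed for all stochastic scene content.
#' @return An object of class `raft_scene_spec`.
#' @export
scene_spec <- function(geometry = array_geometry(quad_rows = 8, quad_cols = 8,
                                                 pixel_size = 3.25),
                       colonies = empty_colonies(),
                       distortion_amplitude = 10,
                       distortion_wavelength = 4000,
                       jitter_sd = 0,
                       rotation = 0,
                       background_signal_offset = c(2.0, -1.5, 0.10),
                       illumination_gradient = 0.10,
                       noise_sd = 0.02,
                       focal_offsets = c(-57, 0, 57),
                       seed = 1L) {
  stopifnot(inherits(geometry, "raft_geometry"),
            length(focal_offsets) >= 2,
            length(unique(focal_offsets)) >= 2,
            length(background_signal_offset) == 3,
            noise_sd >= 0, illumination_gradient >= 0)
  colonies <- as.data.frame(colonies)
  need <- c("row", "col", "cov_nw", "cov_ne", "cov_sw", "cov_se", "pdms")
  if (!all(need %in% names(colonies)))
    stop("scene_spec: colonies must have columns ",
         paste(need, collapse = ", "))
  covs <- as.matrix(colonies[, c("cov_nw", "cov_ne", "cov_sw", "cov_se")])
  if (nrow(colonies) && (any(covs < 0) || any(covs > 1)))
    stop("scene_spec: coverage fractions must lie in [0, 1]")
  if (nrow(colonies) &&
      (any(colonies$row < 0) || any(colonies$row >= geometry$quad_rows) ||
       any(colonies$col < 0) || any(colonies$col >= geometry$quad_cols)))
    stop("scene_spec: colony quad index outside the grid")
  structure(
    list(geometry = geometry, colonies = colonies,
         distortion_amplitude = distortion_amplitude,
         distortion_wavelength = distortion_wavelength,
         jitter_sd = jitter_sd, rotation = rotation,
         background_signal_offset = as.numeric(background_signal_offset),
         illumination_gradient = illumination_gradient,
         noise_sd = noise_sd,
         focal_offsets = sort(as.numeric(focal_offsets)),
         seed = as.integer(seed)),
    class = "raft_scene_spec")
}

#' Empty colony table
#' @return zero-row colonies data.frame in the [scene_spec()] layout.
#' @export
empty_colonies <- function() {
  data.frame(row = integer(), col = integer(), cov_nw = numeric(),
             cov_ne = numeric(), cov_sw = numeric(), cov_se = numeric(),
             pdms = numeric())
}
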
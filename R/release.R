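# Smart biopsy planning and the image-guided microraft release loop.

#' Select release targets from colony records
#'
#' A quad is eligible when more than one of its rafts has detected cell
#' coverage strictly above 0.5. Among that quad's rafts above the coverage
#' threshold, the raft with the least adjacent-PDMS outgrowth is targeted
#' (such rafts release most readily); ties break lexicographically by
#' (row, col, sub-raft).
#'
#' @param records colony records from [colony_records()].
#' @param grid optional `indexed_grid` used to compute expected raft
#'   centroids (um); without it centroids are `NA`.
#' @param coverage_threshold eligibility threshold (strict).
#' @return data.frame of targets: `row`, `col`, `sub`, `coverage`,
#'   `pdms_outgrowth`, `x`, `y`.
#' @export
select_targets <- function(records, grid = NULL, coverage_threshold = 0.5) {
  subs <- c("NW", "NE", "SW", "SE")
  out <- list()
  recs <- records[!is.na(records$row), , drop = FALSE]
  if (nrow(recs)) recs <- recs[order(recs$row, recs$col), , drop = FALSE]
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    cov <- c(r$cov_nw, r$cov_ne, r$cov_sw, r$cov_se)
    pdms <- c(r$pdms_nw, r$pdms_ne, r$pdms_sw, r$pdms_se)
    ok <- which(cov > coverage_threshold)
    if (length(ok) < 2) next
    pick <- ok[order(pdms[ok], ok)][1]
    xy <- c(NA_real_, NA_real_)
    if (!is.null(grid)) {
      e <- grid$entries
      j <- which(e$row == r$row & e$col == r$col)
      if (length(j)) {
        so <- subraft_offsets(grid$geometry)[pick, ]
        u <- rotate_xy(matrix(so, 1), grid$lattice$theta)
        xy <- c(e$x[j[1]] + u[1], e$y[j[1]] + u[2])
      }
    }
    out[[length(out) + 1]] <-
      data.frame(row = r$row, col = r$col, sub = subs[pick],
                 coverage = cov[pick], pdms_outgrowth = pdms[pick],
                 x = xy[1], y = xy[2])
  }
  if (!length(out))
    return(data.frame(row = integer(), col = integer(), sub = character(),
                      coverage = numeric(), pdms_outgrowth = numeric(),
                      x = numeric(), y = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Order release targets by a greedy nearest-neighbour tour
#'
#' From the current position, the next target is the Euclidean-nearest
#' unvisited one; ties break lexicographically by (row, col, sub-raft).
#' This minimizes hardware travel in practice without solving the full
#' travelling-salesman problem.
#'
#' @param targets data.frame from [select_targets()] with `x`, `y` (um).
#' @param start length-2 start position, um; default the scan origin
#'   (top-left corner).
#' @return object of class `release_plan`: list with `targets` (reordered,
#'   with `order` column), `route_length_um`, `start`.
#' @export
order_targets <- function(targets, start = c(0, 0)) {
  n <- nrow(targets)
  sub_rank <- match(targets$sub, c("NW", "NE", "SW", "SE"))
  remaining <- seq_len(n)
  pos <- start
  route <- integer(0)
  len <- 0
  while (length(remaining)) {
    d <- sqrt((targets$x[remaining] - pos[1])^2 +
                (targets$y[remaining] - pos[2])^2)
    o <- order(d, targets$row[remaining], targets$col[remaining],
               sub_rank[remaining])
    pick <- remaining[o[1]]
    len <- len + d[o[1]]
    route <- c(route, pick)
    pos <- c(targets$x[pick], targets$y[pick])
    remaining <- setdiff(remaining, pick)
  }
  ord <- targets[route, , drop = FALSE]
  ord$order <- seq_len(nrow(ord))
  rownames(ord) <- NULL
  structure(list(targets = ord, route_length_um = len, start = start),
            class = "release_plan")
}

#' @export
print.release_plan <- function(x, ...) {
  cat(sprintf("release_plan: %d targets, route %.0f um from (%.0f, %.0f)\n",
              nrow(x$targets), x$route_length_um, x$start[1], x$start[2]))
  invisible(x)
}

#' Measure the dislodgement extent from pre/post release frames
#'
#' Pixels that changed materially between the frames are found by
#' thresholding |post - pre| (Otsu, guarded by a floor at 15% of the
#' pre-frame dynamic range so pure noise never registers as change).
#' Changed pixels inside the well footprint are cleared area; changed
#' pixels outside are material that left the well. The remaining raft
#' material is the unchanged part of the footprint; its centroid is
#' weighted by how far below the cleared-well brightness each pixel sits.
#'
#' @param pre_frame,post_frame `raft_plane`s or matrices covering the well.
#' @param well_footprint logical matrix marking the microwell; defaults to
#'   the `well_footprint` attribute of `pre_frame`.
#' @param nominal_raft_px nominal raft area in pixels for the
#'   outside fraction; defaults to the footprint area.
#' @return list with `extent` (cleared area / well area), `residual_centroid`
#'   (um, `NULL` when extent is 1), `outside_fraction`.
#' @export
dislodgement_extent <- function(pre_frame, post_frame,
                                well_footprint = NULL,
                                nominal_raft_px = NULL) {
  px <- if (inherits(pre_frame, "raft_plane")) pre_frame$pixel_size else 1
  if (is.null(well_footprint))
    well_footprint <- attr(pre_frame, "well_footprint")
  as_mat <- function(x) if (inherits(x, "raft_plane")) x$pixels else x
  pre <- as_mat(pre_frame); post <- as_mat(post_frame)
  stopifnot(all(dim(pre) == dim(post)), !is.null(well_footprint))
  if (is.null(nominal_raft_px)) nominal_raft_px <- sum(well_footprint)
  if (!any(is.finite(post))) stop("dislodgement_extent: degenerate post frame")
  d <- abs(post - pre)
  rng <- diff(range(pre, na.rm = TRUE))
  floor_thr <- 0.15 * max(rng, 1e-12)
  ot <- otsu_threshold(d)
  thr <- max(ot$threshold, floor_thr)
  changed <- d > thr
  cleared <- changed & well_footprint
  outside <- changed & !well_footprint
  extent <- sum(cleared) / sum(well_footprint)
  remaining <- well_footprint & !changed
  centroid <- NULL
  if (extent < 1 && any(remaining)) {
    bright <- max(post[well_footprint], na.rm = TRUE)
    w <- pmax(bright - post, 0)[remaining]
    if (sum(w) == 0) w <- rep(1, sum(remaining))
    ij <- arrayInd(which(remaining), dim(pre))
    centroid <- c(sum((ij[, 1] - 0.5) * w), sum((ij[, 2] - 0.5) * w)) /
      sum(w) * px
  } else {
    extent <- 1
  }
  list(extent = extent, residual_centroid = centroid,
       outside_fraction = sum(outside) / nominal_raft_px)
}

#' Closed-loop image-guided release of one target
#'
#' Iterates aim -> actuate -> measure. Success when the dislodgement
#' extent exceeds the extent threshold; between attempts the needle is
#' re-aimed at the residual-material centroid. The loop halts early when
#' the residual centroid has moved more than the displacement limit from
#' its initial position (cumulative, measured from the first pre-frame) or
#' when more than the outside limit of a raft's area is found outside its
#' microwell; it always terminates within `max_attempts`.
#'
#' @param target one-row data.frame with `x`, `y` (um aim point).
#' @param ejector actuator interface: a list with functions
#'   `image()` (returns the current frame), `aim(x, y)`, and `actuate()`
#'   (performs one ejection and returns the post frame).
#' @param max_attempts attempt cap.
#' @param extent_threshold success threshold on the dislodgement extent.
#' @param displacement_limit_um halting limit on residual-centroid travel.
#' @param outside_limit halting limit on the outside-well fraction.
#' @return data.frame of attempt outcomes: `attempt`, `extent`,
#'   `centroid_x`, `centroid_y`, `centroid_displacement_um`,
#'   `outside_fraction`, `status` (`success`, `retry`,
#'   `halted_displacement`, `halted_outside`, `halted_attempts`).
#' @export
release_loop <- function(target, ejector, max_attempts = 8,
                         extent_threshold = 0.8,
                         displacement_limit_um = 70,
                         outside_limit = 1 / 3) {
  pre <- ejector$image()
  m0 <- dislodgement_extent(pre, pre)
  init_centroid <- m0$residual_centroid
  aim <- c(target$x, target$y)
  out <- list()
  for (a in seq_len(max_attempts)) {
    ejector$aim(aim[1], aim[2])
    post <- tryCatch(ejector$actuate(), error = function(e)
      stop("release_loop: actuator failure at attempt ", a, ": ",
           conditionMessage(e)))
    mm <- dislodgement_extent(pre, post)
    disp <- if (is.null(mm$residual_centroid) || is.null(init_centroid))
      0 else sqrt(sum((mm$residual_centroid - init_centroid)^2))
    status <- if (mm$extent > extent_threshold) "success"
      else if (disp > displacement_limit_um) "halted_displacement"
      else if (mm$outside_fraction > outside_limit) "halted_outside"
      else if (a == max_attempts) "halted_attempts"
      else "retry"
    out[[a]] <- data.frame(
      attempt = a, extent = mm$extent,
      centroid_x = if (is.null(mm$residual_centroid)) NA_real_
        else mm$residual_centroid[1],
      centroid_y = if (is.null(mm$residual_centroid)) NA_real_
        else mm$residual_centroid[2],
      centroid_displacement_um = disp,
      outside_fraction = mm$outside_fraction, status = status)
    if (status != "retry") break
    if (!is.null(mm$residual_centroid)) aim <- mm$residual_centroid
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulated microneedle ejector
#'
#' A stochastic stand-in for the microneedle actuator, rendering frames
#' with the synthetic release renderer. Each actuation clears the whole
#' raft with a probability that depends on the aim offset from the true
#' material centroid; a failed attempt clears a partial fraction and jolts
#' the remaining material. Deterministic under a fixed seed.
#'
#' @param geometry a `raft_geometry`.
#' @param clear_prob function mapping aim offset (um) to the full-clear
#'   probability of one attempt.
#' @param partial_clear fraction of the remaining material removed by a
#'   failed attempt.
#' @param jolt_sd_um standard deviation of the residual-material jolt per
#'   failed attempt, um.
#' @param aim_sd_um needle aiming error, um.
#' @param seed integer seed.
#' @return actuator interface for [release_loop()]; also exposes `state()`
#'   returning the true remaining fraction and displacement.
#' @export
simulate_ejection <- function(geometry,
                              clear_prob = function(offset_um)
                                0.9 * exp(-offset_um / 100),
                              partial_clear = 0.35, jolt_sd_um = 8,
                              aim_sd_um = 3, seed = 1L) {
  p0 <- clear_prob(0)
  if (!is.finite(p0) || p0 < 0 || p0 > 1)
    stop("simulate_ejection: clear_prob must return probabilities in [0, 1]")
  env <- new.env()
  env$remaining <- 1
  env$disp <- c(0, 0)
  env$aim <- NULL
  env$rng <- with_seed(seed, .Random.seed)
  env$frame_seed <- seed
  draw <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$rng, globalenv())
    on.exit({
      env$rng <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
    eval.parent(substitute(expr))
  }
  centre <- rep(ceiling((geometry$raft_side + 100) / geometry$pixel_size), 2) *
    geometry$pixel_size / 2
  render <- function() {
    render_el_release_frame(geometry, env$remaining, env$disp,
                            seed = env$frame_seed)
  }
  list(
    image = function() render(),
    aim = function(x, y) env$aim <- c(x, y),
    actuate = function() {
      if (env$remaining > 0) {
        true_c <- centre + env$disp
        aim <- if (is.null(env$aim)) centre else env$aim
        off <- sqrt(sum((aim - true_c)^2)) +
          abs(draw(stats::rnorm(1, sd = aim_sd_um)))
        p <- clear_prob(off)
        if (draw(stats::runif(1)) < p) {
          env$remaining <- 0
        } else {
          env$remaining <- env$remaining * (1 - partial_clear)
          env$disp <- env$disp + draw(stats::rnorm(2, sd = jolt_sd_um))
        }
        env$frame_seed <- env$frame_seed + 1
      }
      render()
    },
    state = function() list(remaining = env$remaining, disp = env$disp))
}
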
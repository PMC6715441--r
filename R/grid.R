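# Microraft/quad detection, row-column indexing, interpolation of missing
# sites, and tracking across timepoints.

#' Detect quad microrafts in a bright-field plane
#'
#' Otsu thresholding of the (flat-field-corrected) plane, interior hole
#' filling, removal of border-touching objects, morphological closing to
#' merge the four subunits of each quad across the narrow intra-quad gap,
#' and size exclusion against the nominal quad area.
#'
#' @param plane a `raft_plane`, flat-field corrected.
#' @param geometry a `raft_geometry`.
#' @param closing_radius closing disk radius, um; larger than half the
#'   intra-quad gap, smaller than half the barrier, so subunits merge but
#'   neighbouring quads never do.
#' @param size_bounds detected area bounds, as fractions of the nominal
#'   quad area.
#' @return data.frame of detections: `x`, `y` (centroid, um), `side`
#'   (mean bounding extent, um), `area_um2`, `source = "detected"`.
#' @export
detect_quads <- function(plane, geometry, closing_radius = 20,
                         size_bounds = c(0.5, 1.5)) {
  px <- plane$pixel_size
  m <- plane$pixels
  valid <- !is.na(m)
  ot <- otsu_threshold(m[valid])
  if (ot$contrast <= 0)
    stop("detect_quads: degenerate intensity histogram")
  bw <- matrix(FALSE, nrow(m), ncol(m))
  bw[valid] <- m[valid] > ot$threshold
  if (!any(bw)) return(empty_detections())
  img <- EBImage::fillHull(EBImage::Image(bw * 1))
  # remove objects touching the image border
  lab <- EBImage::bwlabel(img)
  ld <- EBImage::imageData(lab)
  border <- unique(c(ld[1, ], ld[nrow(ld), ], ld[, 1], ld[, ncol(ld)]))
  border <- border[border > 0]
  if (length(border)) {
    lab <- EBImage::rmObjects(lab, border, reenumerate = TRUE)
    ld <- EBImage::imageData(lab)
  }
  # debris exclusion before closing: anything far below raft scale is noise
  # speckle, and left in place it can chain quads together across the
  # barrier during closing
  raft_px <- (geometry$raft_side / px)^2
  small <- which(tabulate(ld, max(ld)) < 0.25 * raft_px)
  if (length(small)) lab <- EBImage::rmObjects(lab, small, reenumerate = TRUE)
  img <- EBImage::Image((EBImage::imageData(lab) > 0) * 1)
  img <- EBImage::closing(img, disc_brush(closing_radius, px))
  lab <- EBImage::bwlabel(img)
  ld <- EBImage::imageData(lab)
  n <- max(ld)
  if (n == 0) return(empty_detections())
  area <- tabulate(ld, n)
  nominal <- (geometry$quad_side / px)^2
  keep <- which(area >= size_bounds[1] * nominal &
                  area <= size_bounds[2] * nominal)
  if (!length(keep)) return(empty_detections())
  idx <- which(ld > 0)
  lv <- ld[idx]
  ij <- arrayInd(idx, dim(ld))
  det <- lapply(keep, function(o) {
    sel <- lv == o
    xs <- ij[sel, 1]; ys <- ij[sel, 2]
    data.frame(x = (mean(xs) - 0.5) * px, y = (mean(ys) - 0.5) * px,
               side = ((diff(range(xs)) + 1 + diff(range(ys)) + 1) / 2) * px,
               area_um2 = sum(sel) * px^2, source = "detected")
  })
  do.call(rbind, det)
}

empty_detections <- function() {
  data.frame(x = numeric(), y = numeric(), side = numeric(),
             area_um2 = numeric(), source = character())
}

#' Consolidate duplicate centroids
#'
#' Single-linkage clustering of centroids with the merge distance; each
#' transitively connected cluster is replaced by the mean of its members.
#'
#' @param detections data.frame with `x`, `y` (um); other columns are
#'   averaged (numeric) or taken from the first member.
#' @param min_separation merge distance, um (0.8 quad pitch by default
#'   convention, 430 um).
#' @return consolidated data.frame.
#' @export
consolidate_centroids <- function(detections, min_separation = 430) {
  n <- nrow(detections)
  if (n <= 1) return(detections)
  hc <- stats::hclust(stats::dist(detections[, c("x", "y")]),
                      method = "single")
  grp <- stats::cutree(hc, h = min_separation)
  out <- lapply(split(seq_len(n), grp), function(i) {
    d <- detections[i, , drop = FALSE]
    r <- d[1, , drop = FALSE]
    num <- vapply(d, is.numeric, logical(1))
    r[, num] <- colMeans(d[, num, drop = FALSE])
    r
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# robust lattice fit: orientation (deg), pitch (um) and origin from
# nearest-neighbour displacement vectors; one round of 3-MAD outlier
# rejection
fit_lattice <- function(xy, geometry) {
  n <- nrow(xy)
  if (n < 4) stop("fit_lattice: too few detections to fit a lattice")
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  v <- xy[nn, ] - xy
  len <- sqrt(rowSums(v^2))
  ang <- atan2(v[, 2], v[, 1])
  # fold angles to the lattice axes (mod 90 deg, centred)
  fold <- (ang + pi / 4) %% (pi / 2) - pi / 4
  ok <- len > 0.5 * geometry$quad_pitch & len < 1.5 * geometry$quad_pitch
  if (sum(ok) >= 4) {
    mad_a <- stats::mad(fold[ok]); med_a <- stats::median(fold[ok])
    mad_l <- stats::mad(len[ok]); med_l <- stats::median(len[ok])
    ok2 <- ok & abs(fold - med_a) <= max(3 * mad_a, 1e-6) &
      abs(len - med_l) <= max(3 * mad_l, 1e-6)
    if (sum(ok2) >= 4) ok <- ok2
    theta <- stats::median(fold[ok])
    # snap pitch to multiples (neighbours may be one or more pitches away)
    mult <- pmax(1, round(len[ok] / geometry$quad_pitch))
    pitch <- stats::median(len[ok] / mult)
  } else {
    theta <- 0
    pitch <- geometry$quad_pitch
  }
  list(theta = theta * 180 / pi, pitch = pitch)
}

rotate_xy <- function(xy, theta_deg) {
  th <- theta_deg * pi / 180
  cbind(cos(th) * xy[, 1] + sin(th) * xy[, 2],
        -sin(th) * xy[, 1] + cos(th) * xy[, 2])
}

#' Assign row/column indices to detected quad centroids
#'
#' Fits the lattice orientation and pitch robustly from nearest-neighbour
#' displacements, de-rotates the centroids, refines the origin from the
#' rounding residuals, and assigns each detection to its nearest lattice
#' site. The top-left detection receives index (0, 0). On an index
#' collision the detection nearest the site is kept.
#'
#' @param detections data.frame from [detect_quads()] (consolidated).
#' @param geometry a `raft_geometry`.
#' @return object of class `indexed_grid`: list with `entries` (data.frame
#'   `row`, `col`, `x`, `y`, `side`, `source`), `geometry`, `lattice`
#'   (fit parameters).
#' @export
index_grid <- function(detections, geometry) {
  if (nrow(detections) < 4)
    stop("index_grid: need at least 4 detections")
  xy <- as.matrix(detections[, c("x", "y")])
  fit <- fit_lattice(xy, geometry)
  u <- rotate_xy(xy, -fit$theta)
  ind <- list()
  org <- numeric(2)
  for (a in 1:2) {
    o <- min(u[, a])
    for (it in 1:2) {
      k <- round((u[, a] - o) / fit$pitch)
      res <- u[, a] - k * fit$pitch - o
      o <- o + stats::median(res)
    }
    ind[[a]] <- round((u[, a] - o) / fit$pitch)
    org[a] <- o
  }
  col <- ind[[1]] - min(ind[[1]])
  row <- ind[[2]] - min(ind[[2]])
  org[1] <- org[1] + min(ind[[1]]) * fit$pitch
  org[2] <- org[2] + min(ind[[2]]) * fit$pitch
  entries <- data.frame(row = row, col = col, x = xy[, 1], y = xy[, 2],
                        side = if ("side" %in% names(detections))
                          detections$side else NA_real_,
                        source = "detected")
  # resolve collisions: keep the detection nearest its lattice site
  site <- cbind(org[1] + col * fit$pitch, org[2] + row * fit$pitch)
  err <- rowSums((u - site)^2)
  ordok <- order(err)
  key <- paste(row, col)
  entries <- entries[ordok[!duplicated(key[ordok])], ]
  entries <- entries[order(entries$row, entries$col), ]
  rownames(entries) <- NULL
  structure(list(entries = entries, geometry = geometry,
                 lattice = list(theta = fit$theta, pitch = fit$pitch,
                                origin = org)),
            class = "indexed_grid")
}

#' @export
print.indexed_grid <- function(x, ...) {
  cat(sprintf("indexed_grid: %d entries (%d detected, %d interpolated), pitch %.1f um, theta %.3f deg\n",
              nrow(x$entries), sum(x$entries$source == "detected"),
              sum(x$entries$source == "interpolated"),
              x$lattice$pitch, x$lattice$theta))
  invisible(x)
}

# piecewise-linear prediction of v at targets t from anchors (a, v), fitted
# in segments of `seg` index units; anchors from neighbouring segments are
# borrowed when a segment has fewer than 2 anchors
piecewise_predict <- function(a, v, targets, seg) {
  if (length(a) < 2) return(rep(NA_real_, length(targets)))
  sapply(targets, function(t0) {
    d <- abs(a - t0)
    use <- which(d <= seg / 2)
    if (length(use) < 2) use <- order(d)[1:2]
    fit <- stats::lm.fit(cbind(1, a[use]), v[use])
    sum(fit$coefficients * c(1, t0))
  })
}

#' Fill missing lattice positions by piecewise-linear interpolation
#'
#' Every lattice position without a detection is estimated by
#' piecewise-linear interpolation along its row and along its column in
#' segments of the given physical length (15 quad elements under the
#' defaults), the two estimates averaged with equal weight. Segments with
#' fewer than two anchors borrow the nearest anchors. Positions in an empty
#' row AND empty column with no adjacent anchors are marked unresolvable
#' and omitted.
#'
#' @param grid an `indexed_grid`.
#' @param segment_length_mm interpolation segment length, mm.
#' @return the completed `indexed_grid`; interpolated entries carry
#'   `source = "interpolated"`.
#' @export
interpolate_missing <- function(grid, segment_length_mm = 8) {
  g <- grid$geometry
  e <- grid$entries
  seg_quads <- segment_length_mm * 1000 / g$quad_pitch
  all_sites <- expand.grid(col = 0:(g$quad_cols - 1), row = 0:(g$quad_rows - 1))
  have <- paste(e$row, e$col)
  miss <- all_sites[!(paste(all_sites$row, all_sites$col) %in% have), ]
  if (!nrow(miss)) return(grid)
  det <- e[e$source == "detected", ]
  est <- lapply(seq_len(nrow(miss)), function(i) {
    r <- miss$row[i]; cc <- miss$col[i]
    rowd <- det[det$row == r, ]
    cold <- det[det$col == cc, ]
    xs <- ys <- c()
    if (nrow(rowd) >= 2) {
      xs <- c(xs, piecewise_predict(rowd$col, rowd$x, cc, seg_quads))
      ys <- c(ys, piecewise_predict(rowd$col, rowd$y, cc, seg_quads))
    }
    if (nrow(cold) >= 2) {
      xs <- c(xs, piecewise_predict(cold$row, cold$x, r, seg_quads))
      ys <- c(ys, piecewise_predict(cold$row, cold$y, r, seg_quads))
    }
    if (!length(xs)) return(NULL) # unresolvable
    data.frame(row = r, col = cc, x = mean(xs), y = mean(ys),
               side = NA_real_, source = "interpolated")
  })
  est <- do.call(rbind, est)
  out <- grid
  out$entries <- rbind(e, est)
  out$entries <- out$entries[order(out$entries$row, out$entries$col), ]
  rownames(out$entries) <- NULL
  out
}

#' Track colony sites across timepoints
#'
#' Each timepoint's grid is registered to the first by the median
#' displacement between mutually nearest detected centroids, re-indexed on
#' the first grid's lattice, and completed by interpolation, so one
#' (row, col) identity follows each site through time.
#'
#' @param grids list of `indexed_grid`s, one per timepoint, sharing
#'   geometry.
#' @return data.frame (`timepoint`, `row`, `col`, `x`, `y`, `side`,
#'   `source`).
#' @export
track_timepoints <- function(grids) {
  stopifnot(length(grids) >= 1)
  ref <- grids[[1]]
  refd <- ref$entries[ref$entries$source == "detected", ]
  out <- list()
  for (t in seq_along(grids)) {
    gt <- grids[[t]]
    if (t == 1) {
      comp <- interpolate_missing(gt)
      e <- comp$entries
    } else {
      cur <- gt$entries[gt$entries$source == "detected", ]
      if (!nrow(cur) || !nrow(refd))
        stop("track_timepoints: registration failure at timepoint ", t)
      d <- outer(cur$x, refd$x, "-")^2 + outer(cur$y, refd$y, "-")^2
      j <- apply(d, 1, which.min)
      shift <- c(stats::median(cur$x - refd$x[j]),
                 stats::median(cur$y - refd$y[j]))
      if (sqrt(sum(shift^2)) > 0.5 * ref$geometry$quad_pitch)
        stop("track_timepoints: displacement exceeds half a pitch at ",
             "timepoint ", t)
      # re-index on the reference lattice
      u <- rotate_xy(cbind(cur$x - shift[1], cur$y - shift[2]),
                     -ref$lattice$theta)
      col <- round((u[, 1] - ref$lattice$origin[1]) / ref$lattice$pitch)
      row <- round((u[, 2] - ref$lattice$origin[2]) / ref$lattice$pitch)
      cur$row <- row; cur$col <- col
      key <- paste(row, col)
      cur <- cur[!duplicated(key), ]
      regrid <- structure(list(entries = cur, geometry = gt$geometry,
                               lattice = ref$lattice),
                          class = "indexed_grid")
      e <- interpolate_missing(regrid)$entries
    }
    e$timepoint <- t
    out[[t]] <- e[, c("timepoint", "row", "col", "x", "y", "side", "source")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
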
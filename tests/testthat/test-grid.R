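# Quad detection, centroid consolidation, lattice indexing, interpolation
# and tracking.

test_that("quad detection recovers a small clean array", {
  g <- small_geometry(3, 3)
  sp <- scene_spec(geometry = g, distortion_amplitude = 0,
                   background_signal_offset = c(0, 0, 0), seed = 4)
  plane <- stack_plane(correct_stack(render_array_background(sp)), 2)
  det <- detect_quads(plane, g)
  expect_equal(nrow(det), 9)
  tr <- scene_truth_centroids(sp, "background")$quads
  for (i in seq_len(nrow(tr))) {
    d <- sqrt((det$x - tr$x[i])^2 + (det$y - tr$y[i])^2)
    # rim texture shifts component centroids by up to a pixel or two
    expect_lt(min(d), 3 * g$pixel_size)
  }
  # side length close to the designed quad side (430 um)
  expect_lt(abs(mean(det$side) - g$quad_side), 15)
})

test_that("a blank field yields no detections", {
  g <- small_geometry(2, 2)
  blank <- image_plane(matrix(0.8, 300, 300) +
                         matrix(rnorm(300^2, 0, 0.01), 300), 3.25)
  expect_equal(nrow(detect_quads(blank, g)), 0)
})

test_that("consolidation merges transitively and keeps distant detections", {
  two_close <- data.frame(x = c(0, 100), y = c(0, 0))
  out <- consolidate_centroids(two_close, 430)
  expect_equal(nrow(out), 1)
  expect_equal(out$x, 50)
  two_far <- data.frame(x = c(0, 530), y = c(0, 0))
  expect_equal(nrow(consolidate_centroids(two_far, 430)), 2)
  chain <- data.frame(x = c(0, 300, 600), y = c(0, 0, 0))
  merged <- consolidate_centroids(chain, 430)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$x, 300)
  # random sets match the brute-force single-linkage oracle
  set.seed(13)
  for (rep in 1:5) {
    xy <- matrix(runif(40, 0, 3000), ncol = 2)
    grp <- single_linkage_oracle(xy, 430)
    out <- consolidate_centroids(data.frame(x = xy[, 1], y = xy[, 2]), 430)
    expect_equal(nrow(out), length(unique(grp)))
    orac <- t(sapply(split(seq_len(nrow(xy)), grp),
                     function(i) colMeans(xy[i, , drop = FALSE])))
    orac <- orac[order(orac[, 1], orac[, 2]), , drop = FALSE]
    got <- as.matrix(out[order(out$x, out$y), c("x", "y")])
    expect_equal(unname(got), unname(orac), tolerance = 1e-9)
  }
})

test_that("indexing is exact on a perfect lattice and the top-left is (0,0)", {
  g <- small_geometry(5, 5)
  lat <- lattice_centroids(g)
  det <- data.frame(x = lat$x, y = lat$y, side = 430, source = "detected")
  gr <- index_grid(det, g)
  e <- merge(gr$entries, lat, by = c("row", "col"),
             suffixes = c("", ".true"))
  expect_equal(nrow(e), 25)
  expect_equal(e$x, e$x.true)
  tl <- gr$entries[which.min(gr$entries$x + gr$entries$y), ]
  expect_equal(c(tl$row, tl$col), c(0, 0))
})

test_that("indexing survives rotation and jitter", {
  g <- array_geometry(quad_rows = 8, quad_cols = 8, pixel_size = 3.25)
  sp <- scene_spec(geometry = g, rotation = 0.4, jitter_sd = 10,
                   distortion_amplitude = 0,
                   background_signal_offset = c(0, 0, 0), seed = 6)
  tr <- scene_truth_centroids(sp, "background")$quads
  gr <- index_grid(data.frame(x = tr$x, y = tr$y, side = 430,
                              source = "detected"), g)
  e <- merge(gr$entries, tr, by = c("row", "col"), suffixes = c("", ".t"))
  expect_equal(nrow(e), 64)
  expect_true(all(sqrt((e$x - e$x.t)^2 + (e$y - e$y.t)^2) < 1))
})

test_that("interpolation restores a deleted site exactly on a lattice", {
  g <- small_geometry(5, 5)
  lat <- lattice_centroids(g)
  keep <- !(lat$row == 2 & lat$col == 2)
  gr <- index_grid(data.frame(x = lat$x[keep], y = lat$y[keep], side = 430,
                              source = "detected"), g)
  full <- interpolate_missing(gr)
  got <- full$entries[full$entries$row == 2 & full$entries$col == 2, ]
  expect_equal(got$source, "interpolated")
  truth <- lat[lat$row == 2 & lat$col == 2, ]
  expect_equal(c(got$x, got$y), c(truth$x, truth$y), tolerance = 1e-6)
})

test_that("consolidate-index-interpolate is idempotent", {
  g <- small_geometry(5, 5)
  sp <- scene_spec(geometry = g, distortion_amplitude = 15, jitter_sd = 8,
                   background_signal_offset = c(0, 0, 0), seed = 9)
  tr <- scene_truth_centroids(sp, "background")$quads
  set.seed(30)
  keep <- sample(nrow(tr), 15)
  det <- consolidate_centroids(
    data.frame(x = tr$x[keep], y = tr$y[keep], side = 430,
               source = "detected"))
  g1 <- interpolate_missing(index_grid(det, g))
  g2 <- interpolate_missing(index_grid(g1$entries, g))
  expect_equal(g2$entries[, c("row", "col")], g1$entries[, c("row", "col")])
  expect_equal(g2$entries$x, g1$entries$x, tolerance = 1)
  expect_equal(g2$entries$y, g1$entries$y, tolerance = 1)
})

test_that("interpolation error stays below the chord bound under distortion", {
  # a sinusoid of amplitude A and wavelength L sampled on chords of length s
  # deviates from the chord by at most A * (1 - cos(pi s / L))
  g <- array_geometry()  # 41 x 41
  sp <- scene_spec(geometry = g, distortion_amplitude = 20,
                   distortion_wavelength = 4000, jitter_sd = 0,
                   background_signal_offset = c(0, 0, 0), seed = 12)
  tr <- scene_truth_centroids(sp, "background")$quads
  set.seed(41)
  miss <- sample(nrow(tr), 400)
  det <- data.frame(x = tr$x[-miss], y = tr$y[-miss], side = 430,
                    source = "detected")
  full <- interpolate_missing(index_grid(det, g))
  e <- merge(full$entries[full$entries$source == "interpolated", ],
             tr, by = c("row", "col"), suffixes = c("", ".t"))
  err <- sqrt((e$x - e$x.t)^2 + (e$y - e$y.t)^2)
  # a least-squares chord through samples of a sinusoid of amplitude A
  # deviates from the curve by at most 2A anywhere inside the window
  # (both the fit and the curve lie within [-A, A] per axis)
  A <- 20
  expect_lt(max(err), 2 * sqrt(2) * A)
})

test_that("tracking matches sites across shifted timepoints", {
  g <- small_geometry(5, 5)
  sp <- scene_spec(geometry = g, distortion_amplitude = 0,
                   background_signal_offset = c(0, 0, 0), seed = 3)
  tr <- scene_truth_centroids(sp, "background")$quads
  mk <- function(xy, drop = integer(0)) {
    d <- data.frame(x = xy$x, y = xy$y, side = 430, source = "detected")
    if (length(drop)) d <- d[-drop, ]
    index_grid(d, g)
  }
  # single timepoint
  t1 <- track_timepoints(list(mk(tr)))
  expect_equal(nrow(t1), 25)
  # second timepoint globally shifted by 40 um
  tr2 <- tr; tr2$x <- tr2$x + 40; tr2$y <- tr2$y + 12
  tt <- track_timepoints(list(mk(tr), mk(tr2)))
  m <- merge(tt[tt$timepoint == 1, ], tt[tt$timepoint == 2, ],
             by = c("row", "col"))
  expect_equal(nrow(m), 25)
  expect_equal(m$x.y - m$x.x, rep(40, 25), tolerance = 1e-6)
  # a site missing mid-series comes back as interpolated
  drop_site <- which(tr$row == 2 & tr$col == 3)
  t3 <- track_timepoints(list(mk(tr), mk(tr, drop = drop_site), mk(tr)))
  mid <- t3[t3$timepoint == 2 & t3$row == 2 & t3$col == 3, ]
  expect_equal(mid$source, "interpolated")
})
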
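# Standard-deviation projection, background subtraction, and the
# enhancement/segmentation chain.

test_that("sdp matches closed forms and an elementwise oracle", {
  base <- matrix(runif(400), 20, 20)
  st <- zstack(array(rep(base, 3), c(20, 20, 3)), 1, c(-10, 0, 10))
  expect_equal(sdp(st)$pixels, matrix(0, 20, 20))
  # two planes differing by d at one pixel, sample mode -> d / sqrt(2)
  d2 <- array(rep(base, 2), c(20, 20, 2))
  d2[7, 9, 2] <- d2[7, 9, 2] + 0.6
  st2 <- zstack(d2, 1, c(0, 10))
  s2 <- sdp(st2, "sample")$pixels
  expect_equal(s2[7, 9], 0.6 / sqrt(2))
  expect_equal(sum(s2 > 1e-12), 1)
  set.seed(8)
  r <- array(rnorm(12 * 11 * 5), c(12, 11, 5))
  st5 <- zstack(r, 1, 1:5)
  expect_equal(sdp(st5, "population")$pixels, sdp_oracle(r, "population"),
               tolerance = 1e-12)
  expect_equal(sdp(st5, "sample")$pixels, sdp_oracle(r, "sample"),
               tolerance = 1e-12)
  single <- structure(list(data = array(base, c(20, 20, 1)), pixel_size = 1,
                           focal_offsets = 0, tag = "signal", timepoint = 1L),
                      class = "raft_zstack")
  expect_error(sdp(single), "two planes")
})

test_that("background subtraction nulls identical stacks and keeps offsets", {
  sc <- default_scene()
  d0 <- subtract_background(sc$bg, sc$bg)
  expect_equal(max(abs(d0$data)), 0)
  plusk <- sc$bg
  plusk$data <- plusk$data + 0.37
  dk <- subtract_background(plusk, sc$bg)
  expect_equal(range(dk$data), c(0.37, 0.37))
  other <- sc$bg
  other$focal_offsets <- other$focal_offsets + 1
  expect_error(subtract_background(sc$bg, other), "focal offsets")
})

test_that("difference stack concentrates inside the cell mask", {
  # regression floor frozen from the seeded default scene (observed ~14x)
  sc <- default_scene()
  res <- default_pipeline()
  diff <- subtract_background(correct_stack(sc$sig$stack),
                              correct_stack(sc$bg, ref_mean = mean(sc$sig$stack$data[, , 1])),
                              res$transform)
  mid <- abs(diff$data[, , 2])
  msk <- sc$sig$truth$cell_mask
  expect_gt(mean(mid[msk], na.rm = TRUE) / mean(mid[!msk], na.rm = TRUE), 10)
})

test_that("long straight thin lines are suppressed by the oriented top-hats", {
  px <- 3.25
  m <- matrix(0, 200, 200)
  m[100, ] <- 1 # 1-px-wide full-height line (~3 um wide)
  st <- enhance(image_plane(m, px), stages = TRUE)
  expect_lt(max(st$tophat$pixels[100, ], na.rm = TRUE), 0.1)
})

test_that("entropy of a constant image is constant (zero)", {
  st <- enhance(image_plane(matrix(0.5, 120, 120), 3.25), stages = TRUE)
  expect_equal(max(st$entropy$pixels, na.rm = TRUE), 0)
})

test_that("oversized structuring elements are rejected", {
  expect_error(enhance(image_plane(matrix(1, 6, 6), 3.25)), "larger")
})

test_that("Otsu on a populous two-level image splits the levels", {
  v <- c(rep(0.2, 4000), rep(0.9, 2500))
  ot <- raftsense:::otsu_threshold(v)
  expect_gt(ot$threshold, 0.2)
  expect_lt(ot$threshold, 0.9)
})

test_that("vector Otsu agrees with the EBImage implementation", {
  set.seed(21)
  for (i in 1:5) {
    v <- c(rnorm(4000, 0.25, 0.06), rnorm(sample(300:2500, 1), 0.75, 0.08))
    r <- range(v)
    eb <- EBImage::otsu(EBImage::Image(matrix((v - r[1]) / diff(r), 1)),
                        range = c(0, 1), levels = 256)
    expect_equal(raftsense:::otsu_threshold(v)$threshold,
                 r[1] + eb * diff(r), tolerance = 1e-12)
  }
})

test_that("hole filling and thinning follow the stated geometry", {
  px <- 1.625
  n <- 128
  ctr <- n / 2
  xy <- expand.grid(x = 1:n, y = 1:n)
  r <- sqrt((xy$x - ctr)^2 + (xy$y - ctr)^2) * px
  img <- matrix(0, n, n)
  img[r <= 50] <- 5          # 50 um disk
  img[r <= 5] <- 0           # 5 um interior hole
  mask <- segment_colonies(image_plane(img, px),
                           bsdp_params(min_colony_radius = 10))
  expect_equal(max(mask$labels), 1)
  area <- sum(mask$labels > 0) * px^2
  expect_equal(sqrt(area / pi), 42, tolerance = 1.5)
  # no hole survived
  filled <- EBImage::imageData(EBImage::fillHull(
    EBImage::Image((mask$labels > 0) * 1)))
  expect_equal(sum(filled > 0.5), sum(mask$labels > 0))
})

test_that("the final mask is invariant to affine intensity rescaling", {
  sc <- default_scene()
  res <- default_pipeline()
  b <- res$diagnostics$b_sdp
  m1 <- segment_colonies(enhance(b))
  b2 <- b
  b2$pixels <- 3.7 * b$pixels
  m2 <- segment_colonies(enhance(b2))
  expect_identical(m1$labels, m2$labels)
})

test_that("a cell-free scene segments to zero components", {
  g <- small_geometry()
  for (s in 1:3) {
    sp <- scene_spec(geometry = g, seed = s)
    res <- run_pipeline(render_signal_stack(sp)$stack,
                        render_array_background(sp))
    expect_equal(max(res$mask$labels), 0)
  }
})

test_that("masks agree across pixel sizes on the same scene", {
  make <- function(psz) {
    g <- array_geometry(quad_rows = 2, quad_cols = 2, pixel_size = psz)
    cols <- data.frame(row = c(0, 1), col = c(0, 1),
                       cov_nw = c(0.9, 0.3), cov_ne = c(0.8, 0.9),
                       cov_sw = c(0.2, 0.85), cov_se = c(0, 0.7),
                       pdms = 0.6)
    sp <- scene_spec(geometry = g, colonies = cols, seed = 77)
    res <- run_pipeline(render_signal_stack(sp)$stack,
                        render_array_background(sp))
    list(mask = res$mask$labels > 0, psz = psz)
  }
  fine <- make(1.625)
  coarse <- make(3.25)
  # sample the fine mask at coarse pixel centres
  nxc <- nrow(coarse$mask); nyc <- ncol(coarse$mask)
  ix <- pmin(nrow(fine$mask), pmax(1, round(((1:nxc) - 0.5) * 2)))
  iy <- pmin(ncol(fine$mask), pmax(1, round(((1:nyc) - 0.5) * 2)))
  f2 <- fine$mask[ix, iy]
  iou <- sum(f2 & coarse$mask) / sum(f2 | coarse$mask)
  expect_gt(iou, 0.8)
})

test_that("stage failures name their stage", {
  sc <- default_scene()
  short <- sc$bg
  short$focal_offsets <- short$focal_offsets + 5
  expect_error(run_pipeline(sc$sig$stack, short, correct = FALSE),
               "focal offsets")
})
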
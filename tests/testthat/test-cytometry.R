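# Coverage records, classification, evaluation metrics and growth fits.

# an axis-aligned indexed grid plus a synthetic mask painter, for exact
# footprint arithmetic
toy_grid <- function(g = small_geometry(2, 2)) {
  lat <- lattice_centroids(g)
  structure(list(
    entries = data.frame(row = lat$row, col = lat$col, x = lat$x, y = lat$y,
                         side = g$quad_side, source = "detected"),
    geometry = g,
    lattice = list(theta = 0, pitch = g$quad_pitch,
                   origin = c(lat$x[1], lat$y[1]))),
    class = "indexed_grid")
}

paint <- function(g, rects) {
  d <- raftsense:::geometry_image_dim(g)
  lab <- matrix(0L, d[1], d[2])
  pg <- raftsense:::pixel_grids(d, g$pixel_size)
  for (k in seq_along(rects)) {
    r <- rects[[k]]
    lab[pg$ax > r[1] & pg$ax <= r[2] & pg$ay > r[3] & pg$ay <= r[4]] <- k
  }
  structure(list(labels = lab, pixel_size = g$pixel_size,
                 params = bsdp_params()), class = "colony_mask")
}

test_that("coverage of exact raft footprints is recovered", {
  g <- small_geometry(2, 2)
  grid <- toy_grid(g)
  e <- grid$entries[grid$entries$row == 0 & grid$entries$col == 0, ]
  g2 <- g$intra_quad_gap / 2
  nw <- c(e$x - g2 - 200, e$x - g2, e$y - g2 - 200, e$y - g2)
  rec <- colony_records(paint(g, list(nw)), grid)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$cov_nw, 1, tolerance = 0.02)
  expect_lt(max(rec$cov_ne, rec$cov_sw, rec$cov_se), 0.01)
  expect_equal(rec$raft_class, 1)
  # a full quad including the gaps
  full <- c(e$x - 215, e$x + 215, e$y - 215, e$y + 215)
  rec2 <- colony_records(paint(g, list(full)), grid)
  expect_equal(unlist(rec2[, c("cov_nw", "cov_ne", "cov_sw", "cov_se")]),
               c(cov_nw = 1, cov_ne = 1, cov_sw = 1, cov_se = 1),
               tolerance = 0.02)
  expect_equal(rec2$raft_class, 4)
  expect_gt(rec2$pdms_cov, 0.1) # gap cross is covered
})

test_that("drawn scene coverages are recovered within 0.1", {
  sc <- default_scene()
  res <- default_pipeline()
  plane <- stack_plane(correct_stack(sc$sig$stack), 2)
  grid <- interpolate_missing(index_grid(
    consolidate_centroids(detect_quads(plane, sc$geometry)), sc$geometry))
  rec <- colony_records(res$mask, grid)
  tcov <- sc$sig$truth$coverage
  tq <- unique(tcov[, c("colony", "row", "col")])
  checked <- 0
  for (i in seq_len(nrow(tq))) {
    pr <- rec[!is.na(rec$row) & rec$row == tq$row[i] &
                rec$col == tq$col[i], ]
    if (!nrow(pr)) next
    k <- which.max(pr$area_um2)
    tc <- tcov[tcov$colony == tq$colony[i], ]
    got <- unlist(pr[k, c("cov_nw", "cov_ne", "cov_sw", "cov_se")])
    want <- tc$drawn[match(c("NW", "NE", "SW", "SE"), tc$sub)]
    expect_true(all(abs(got - want) < 0.1))
    checked <- checked + 1
  }
  expect_gte(checked, 12)
})

test_that("coverage is invariant to a global translation of mask and grid", {
  g <- small_geometry(2, 2)
  grid <- toy_grid(g)
  e <- grid$entries[1, ]
  g2 <- g$intra_quad_gap / 2
  nw <- c(e$x - g2 - 200, e$x - g2, e$y - g2 - 200, e$y - g2)
  r1 <- colony_records(paint(g, list(nw)), grid)
  shift <- 3 * g$pixel_size
  grid2 <- grid
  grid2$entries$x <- grid2$entries$x + shift
  grid2$entries$y <- grid2$entries$y + shift
  r2 <- colony_records(paint(g, list(nw + c(shift, shift, shift, shift))),
                       grid2)
  expect_equal(r1$cov_nw, r2$cov_nw, tolerance = 1e-6)
})

test_that("class histograms count every colony exactly once", {
  recs <- data.frame(raft_class = c(1, 1, 2, 4, 3, 1, 0),
                     timepoint = c(1, 1, 1, 1, 2, 2, 2))
  h <- classify_growth(recs)
  expect_equal(h$n, c(4, 3))
  expect_equal(rowSums(h[, c("class_0", "class_1", "class_2", "class_3",
                             "class_4")]), h$n)
  expect_equal(h$class_1, c(2, 1))
  empty <- classify_growth(empty_records())
  expect_equal(nrow(empty), 0)
})

test_that("evaluation metrics satisfy their closed forms", {
  truth <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 6)
  m <- evaluate_mask(truth, truth)
  expect_equal(c(m$sensitivity, m$specificity, m$accuracy, m$precision,
                 m$mcc), rep(1, 5))
  m2 <- evaluate_mask(!truth, truth)
  expect_equal(m2$mcc, -1)
  # direct evaluation of the MCC formula on fixed counts
  m3 <- conf_metrics(tp = 88, fn = 12, tn = 98, fp = 2)
  expect_equal(m3$mcc, (88 * 98 - 2 * 12) /
                 sqrt(90 * 100 * 100 * 110))
  expect_equal(m3$mcc, 0.864, tolerance = 5e-4)
  expect_equal(m3$sensitivity, 0.88)
  expect_equal(m3$specificity, 0.98)
})

test_that("swapping prediction and truth preserves the MCC", {
  set.seed(5)
  a <- matrix(runif(600) > 0.6, 20, 30)
  b <- matrix(runif(600) > 0.4, 20, 30)
  expect_equal(evaluate_mask(a, b)$mcc, evaluate_mask(b, a)$mcc)
})

test_that("snr gain follows ratio algebra", {
  set.seed(6)
  truth <- matrix(rep(c(TRUE, FALSE), each = 500), 1000, 1)
  raw <- matrix(0, 1000, 1)
  raw[truth] <- 1 + rnorm(500, 0, 0.2)
  raw[!truth] <- rnorm(500, 0, 0.2)
  expect_equal(snr_gain(raw, raw, truth), 1)
  half <- raw
  half[!truth] <- raw[!truth] / 2 # halved outside noise, contrast kept
  half[truth] <- mean(raw[truth]) + (raw[truth] - mean(raw[truth]))
  g <- snr_gain(raw, half, truth)
  expect_equal(g, (mean(half[truth]) - mean(half[!truth])) /
                 sd(half[!truth]) /
                 ((mean(raw[truth]) - mean(raw[!truth])) / sd(raw[!truth])))
  expect_gt(g, 1.8)
})

test_that("median area error matches its definition", {
  a <- pi * c(30, 40)^2 # radii comfortably above the 25 um cut
  expect_equal(median_area_error(a, a), 0)
  expect_equal(median_area_error(1.1 * a, a), 0.10)
  # radius restriction: only the large colony qualifies
  big <- pi * 30^2
  expect_equal(median_area_error(c(1.3 * big, 5), c(big, 4), 25), 0.3)
  expect_error(median_area_error(c(5), c(4), 25), "qualifying")
})

test_that("biomarker area ratio divides super-threshold areas", {
  nuc <- matrix(0, 40, 40)
  nuc[1:20, ] <- 1
  mk <- matrix(0, 40, 40)
  mk[1:10, ] <- 1
  expect_equal(biomarker_positive_fraction(mk, nuc, 0.5, 0.5), 0.5)
  expect_equal(biomarker_positive_fraction(nuc, nuc, 0.5, 0.5), 1)
  expect_error(biomarker_positive_fraction(mk, matrix(0, 40, 40), 0.5, 0.5),
               "nuclei")
})

test_that("doubling time is exact on a noiseless doubling series", {
  hours <- seq(0, 68, by = 4)
  areas <- 1000 * 2^(hours / 17)
  fit <- doubling_time(hours, areas)
  expect_true(fit$defined)
  expect_equal(fit$doubling_h, 17, tolerance = 1e-9)
  flat <- doubling_time(hours, rep(1000, length(hours)))
  expect_false(flat$defined)
  expect_true(is.na(flat$doubling_h))
})

test_that("doubling-time confidence intervals cover the generating value", {
  set.seed(99)
  hours <- seq(0, 72, by = 12)
  hit <- 0
  for (i in 1:100) {
    areas <- 1000 * 2^(hours / 17) * 2^rnorm(length(hours), 0, 0.15)
    fit <- doubling_time(hours, areas)
    if (fit$defined && fit$ci_h[1] <= 17 && 17 <= fit$ci_h[2]) hit <- hit + 1
  }
  expect_gte(hit, 90)
})
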
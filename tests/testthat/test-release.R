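# Target selection, nearest-neighbour routing, dislodgement measurement and
# the closed-loop release controller.

test_that("target selection follows the coverage and outgrowth rules", {
  rec <- empty_records()[0, ]
  base <- data.frame(colony_id = 1, row = 0, col = 0, area_um2 = 1e4,
                     equiv_radius_um = 50, cov_nw = 0.9, cov_ne = 0.6,
                     cov_sw = 0.2, cov_se = 0.1, pdms_cov = 0.2,
                     pdms_nw = 0.4, pdms_ne = 0.1, pdms_sw = 0, pdms_se = 0,
                     raft_class = 2L)
  t1 <- select_targets(base)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$sub, "NE") # above threshold, least PDMS outgrowth
  solo <- base
  solo[, c("cov_ne", "cov_sw", "cov_se")] <- c(0.4, 0.2, 0.1)
  expect_equal(nrow(select_targets(solo)), 0) # needs >1 raft above 0.5
  expect_equal(nrow(select_targets(rec)), 0)
})

test_that("selection equals the exhaustive filter-and-argmin oracle", {
  set.seed(17)
  subs <- c("NW", "NE", "SW", "SE")
  for (i in 1:100) {
    cov <- runif(4)
    pdms <- runif(4)
    rec <- data.frame(colony_id = 1, row = 3, col = 5, area_um2 = 1,
                      equiv_radius_um = 1,
                      cov_nw = cov[1], cov_ne = cov[2], cov_sw = cov[3],
                      cov_se = cov[4], pdms_cov = 0,
                      pdms_nw = pdms[1], pdms_ne = pdms[2],
                      pdms_sw = pdms[3], pdms_se = pdms[4], raft_class = 0L)
    want <- select_oracle(cov, pdms)
    got <- select_targets(rec)
    if (is.na(want)) expect_equal(nrow(got), 0)
    else expect_equal(got$sub, subs[want])
  }
})

test_that("never selects below-threshold rafts or one-raft quads", {
  set.seed(18)
  for (i in 1:50) {
    cov <- runif(4)
    rec <- data.frame(colony_id = 1, row = 0, col = 0, area_um2 = 1,
                      equiv_radius_um = 1,
                      cov_nw = cov[1], cov_ne = cov[2], cov_sw = cov[3],
                      cov_se = cov[4], pdms_cov = 0, pdms_nw = runif(1),
                      pdms_ne = runif(1), pdms_sw = runif(1),
                      pdms_se = runif(1), raft_class = 0L)
    got <- select_targets(rec)
    if (nrow(got)) {
      expect_gt(got$coverage, 0.5)
      expect_gte(sum(cov > 0.5), 2)
    } else {
      expect_lt(sum(cov > 0.5), 2)
    }
  }
})

test_that("routing is greedy nearest-neighbour from the start point", {
  one <- data.frame(row = 0, col = 0, sub = "NW", coverage = 1,
                    pdms_outgrowth = 0, x = 300, y = 400)
  p1 <- order_targets(one, start = c(0, 0))
  expect_equal(p1$route_length_um, 500)
  line <- data.frame(row = 0, col = 0:3, sub = "NW", coverage = 1,
                     pdms_outgrowth = 0, x = c(100, 200, 300, 400), y = 0)
  p2 <- order_targets(line, start = c(0, 0))
  expect_equal(p2$targets$x, c(100, 200, 300, 400))
  set.seed(19)
  for (i in 1:20) {
    xy <- matrix(runif(16, 0, 5000), ncol = 2)
    tg <- data.frame(row = seq_len(8), col = 1, sub = "NW", coverage = 1,
                     pdms_outgrowth = 0, x = xy[, 1], y = xy[, 2])
    pl <- order_targets(tg, start = c(0, 0))
    orac <- nn_tour_oracle(xy, c(0, 0))
    expect_equal(pl$targets$x, xy[orac$route, 1])
    expect_equal(pl$route_length_um, orac$length)
    # permutation of the input, translation-invariant route length
    expect_setequal(pl$targets$x, tg$x)
    tg2 <- tg; tg2$x <- tg2$x + 1000; tg2$y <- tg2$y - 500
    pl2 <- order_targets(tg2, start = c(1000, -500))
    expect_equal(pl2$route_length_um, pl$route_length_um, tolerance = 1e-9)
  }
})

test_that("the greedy tour usually beats the row-major scan order", {
  # 16 targets scattered over the full 41x41 array, the regime of a real
  # biopsy run
  set.seed(20)
  wins <- 0
  for (i in 1:200) {
    q <- sample.int(1681, 16) - 1
    xy <- cbind(315 + (q %% 41) * 530, 315 + (q %/% 41) * 530)
    tg <- data.frame(row = q %/% 41, col = q %% 41, sub = "NW", coverage = 1,
                     pdms_outgrowth = 0, x = xy[, 1], y = xy[, 2])
    pl <- order_targets(tg, start = c(0, 0))
    scan <- xy[order(xy[, 2], xy[, 1]), , drop = FALSE]
    scan_len <- sum(sqrt(rowSums(
      (rbind(c(0, 0), scan[-16, , drop = FALSE]) - scan)^2)))
    if (pl$route_length_um <= scan_len) wins <- wins + 1
  }
  expect_gte(wins / 200, 0.95)
})

test_that("dislodgement extent reads rendered frames correctly", {
  g <- small_geometry()
  pre <- render_el_release_frame(g, 1, c(0, 0), seed = 5)
  same <- dislodgement_extent(pre, pre)
  expect_equal(same$extent, 0)
  ctr <- nrow(pre$pixels) * g$pixel_size / 2
  expect_lt(max(abs(same$residual_centroid - ctr)), 5)
  gone <- dislodgement_extent(pre, render_el_release_frame(g, 0, c(0, 0),
                                                           seed = 6))
  expect_equal(gone$extent, 1)
  expect_null(gone$residual_centroid)
  half <- dislodgement_extent(pre, render_el_release_frame(g, 0.5, c(30, 0),
                                                           seed = 7))
  expect_equal(half$extent, 0.5, tolerance = 0.05)
  expect_lt(abs(half$residual_centroid[1] - (ctr + 30)), 5)
})

test_that("the release loop succeeds, caps attempts, and halts on drift", {
  g <- small_geometry()
  ctr <- rep(ceiling((g$raft_side + 100) / g$pixel_size), 2) *
    g$pixel_size / 2
  target <- data.frame(x = ctr[1], y = ctr[2])
  quick <- release_loop(target, stub_always_clear(g))
  expect_equal(nrow(quick), 1)
  expect_equal(quick$status, "success")
  stuck <- release_loop(target, stub_never_change(g))
  expect_equal(nrow(stuck), 8)
  expect_equal(stuck$status[8], "halted_attempts")
  expect_true(all(stuck$status[1:7] == "retry"))
  drift <- release_loop(target, stub_shift_residue(g))
  expect_equal(nrow(drift), 2)
  expect_equal(drift$status[2], "halted_displacement")
})

test_that("the loop terminates within the cap for adversarial actuators", {
  g <- small_geometry()
  ctr <- rep(ceiling((g$raft_side + 100) / g$pixel_size), 2) *
    g$pixel_size / 2
  target <- data.frame(x = ctr[1], y = ctr[2])
  set.seed(23)
  for (i in 1:5) {
    chaotic <- local({
      st <- new.env(); st$n <- 0
      list(image = function() render_el_release_frame(g, 1, c(0, 0), seed = 1),
           aim = function(x, y) NULL,
           actuate = function() {
             st$n <- st$n + 1
             render_el_release_frame(g, runif(1), runif(2, -20, 20),
                                     seed = st$n + i * 100)
           })
    })
    log <- release_loop(target, chaotic)
    expect_lte(nrow(log), 8)
    expect_true(log$status[nrow(log)] != "retry")
  }
})

test_that("the simulated ejector is deterministic and geometric in attempts", {
  g <- small_geometry()
  ctr <- rep(ceiling((g$raft_side + 100) / g$pixel_size), 2) *
    g$pixel_size / 2
  target <- data.frame(x = ctr[1], y = ctr[2])
  l1 <- release_loop(target, simulate_ejection(g, seed = 7))
  l2 <- release_loop(target, simulate_ejection(g, seed = 7))
  expect_identical(l1, l2)
  expect_error(simulate_ejection(g, clear_prob = function(o) 2), "clear_prob")
  # constant clear probability p => attempts ~ geometric, mean 1/p
  set.seed(31)
  n <- replicate(200, {
    ej <- simulate_ejection(g, clear_prob = function(o) 0.7, aim_sd_um = 0,
                            partial_clear = 0, jolt_sd_um = 0,
                            seed = sample.int(1e6, 1))
    nrow(release_loop(target, ej))
  })
  expect_equal(mean(n), 1 / 0.7, tolerance = 0.12)
})
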
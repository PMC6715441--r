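# Shared fixtures and independent oracles. Everything is generated in code;
# expensive renders are memoized for the session.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

small_geometry <- function(rows = 4, cols = 4)
  array_geometry(quad_rows = rows, quad_cols = cols, pixel_size = 3.25)

# one default cell-laden scene + pipeline result, reused across files
default_scene <- function() memo("default_scene", {
  g <- array_geometry(quad_rows = 8, quad_cols = 8, pixel_size = 3.25)
  sp <- scene_spec(geometry = g, colonies = random_colonies(g, 15, seed = 42),
                   seed = 42)
  bg <- render_array_background(sp)
  sig <- render_signal_stack(sp)
  list(geometry = g, spec = sp, bg = bg, sig = sig)
})

default_pipeline <- function() memo("default_pipeline", {
  sc <- default_scene()
  run_pipeline(sc$sig$stack, sc$bg, diagnostics = TRUE)
})

# the acceptance scene batch: 20 seeded scenes, pooled confusion counts and
# per-colony class/area comparisons (used by several acceptance checks)
acceptance_batch <- function(n_scenes = 20, base_seed = 500) {
  memo(paste0("acc_batch_", n_scenes, "_", base_seed), {
    g <- array_geometry(quad_rows = 8, quad_cols = 8, pixel_size = 3.25)
    conf <- c(tp = 0, fp = 0, tn = 0, fn = 0)
    per_colony <- list()
    for (s in seq_len(n_scenes)) {
      seed <- base_seed + s
      sp <- scene_spec(geometry = g,
                       colonies = random_colonies(g, 15, seed = seed),
                       seed = seed)
      bg <- render_array_background(sp)
      sig <- render_signal_stack(sp)
      res <- run_pipeline(sig$stack, bg)
      m <- evaluate_mask(res$mask, sig$truth$cell_mask)
      conf <- conf + c(tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn)
      plane <- stack_plane(correct_stack(sig$stack), 2)
      det <- consolidate_centroids(detect_quads(plane, g))
      grid <- interpolate_missing(index_grid(det, g))
      rec <- colony_records(res$mask, grid)
      tcov <- sig$truth$coverage
      tq <- unique(tcov[, c("colony", "row", "col")])
      for (i in seq_len(nrow(tq))) {
        tc <- tcov[tcov$colony == tq$colony[i], ]
        pr <- rec[!is.na(rec$row) & rec$row == tq$row[i] &
                    rec$col == tq$col[i], ]
        true_area <- sum(sig$truth$colony_labels == tq$colony[i]) *
          g$pixel_size^2
        row <- data.frame(
          scene = s,
          true_class = sum(tc$drawn >= 0.5, na.rm = TRUE),
          true_area = true_area,
          pred_class = NA_integer_, pred_area = NA_real_)
        if (nrow(pr)) {
          k <- which.max(pr$area_um2)
          row$pred_class <- pr$raft_class[k]
          row$pred_area <- pr$area_um2[k]
        }
        per_colony[[length(per_colony) + 1]] <- row
      }
    }
    list(conf = conf, colonies = do.call(rbind, per_colony))
  })
}

# ---- independent oracles ----------------------------------------------------

# per-pixel standard deviation by direct summation
sdp_oracle <- function(data, mode = "population") {
  nx <- dim(data)[1]; ny <- dim(data)[2]; nk <- dim(data)[3]
  out <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    v <- data[i, j, ]
    mu <- sum(v) / nk
    ss <- sum((v - mu)^2)
    out[i, j] <- sqrt(ss / if (mode == "population") nk else nk - 1)
  }
  out
}

# brute-force single-linkage clustering by repeated pair merging
single_linkage_oracle <- function(xy, cutoff) {
  grp <- seq_len(nrow(xy))
  repeat {
    merged <- FALSE
    for (a in seq_len(nrow(xy))) for (b in seq_len(nrow(xy))) {
      if (grp[a] != grp[b] &&
          sqrt(sum((xy[a, ] - xy[b, ])^2)) <= cutoff) {
        grp[grp == grp[b]] <- grp[a]
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  grp
}

# independently coded greedy nearest-neighbour tour
nn_tour_oracle <- function(xy, start) {
  left <- seq_len(nrow(xy))
  pos <- start
  route <- integer(0)
  total <- 0
  while (length(left)) {
    d <- sqrt((xy[left, 1] - pos[1])^2 + (xy[left, 2] - pos[2])^2)
    k <- left[which.min(d)]
    total <- total + min(d)
    route <- c(route, k)
    pos <- xy[k, ]
    left <- setdiff(left, k)
  }
  list(route = route, length = total)
}

# exhaustive release-target selection rule
select_oracle <- function(cov, pdms, thr = 0.5) {
  ok <- which(cov > thr)
  if (length(ok) < 2) return(NA_integer_)
  ok[order(pdms[ok], ok)][1]
}

# scripted actuator stubs for the release loop
stub_always_clear <- function(geometry) {
  frame <- function(rf, d) render_el_release_frame(geometry, rf, d, seed = 1)
  st <- new.env(); st$rf <- 1
  list(image = function() frame(st$rf, c(0, 0)),
       aim = function(x, y) NULL,
       actuate = function() { st$rf <- 0; frame(0, c(0, 0)) })
}

stub_never_change <- function(geometry) {
  f <- render_el_release_frame(geometry, 1, c(0, 0), seed = 1)
  list(image = function() f, aim = function(x, y) NULL,
       actuate = function() f)
}

# barely dents the raft on the first attempt, then shoves the nearly intact
# raft 150 um sideways (residual centroid drifts past the 70 um limit while
# the well is still mostly occupied)
stub_shift_residue <- function(geometry) {
  st <- new.env(); st$n <- 0
  frame <- function(rf, d) render_el_release_frame(geometry, rf, d, seed = 1)
  list(image = function() frame(1, c(0, 0)),
       aim = function(x, y) NULL,
       actuate = function() {
         st$n <- st$n + 1
         if (st$n == 1) frame(0.95, c(0, 0)) else frame(0.95, c(150, 0))
       })
}
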
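# Colony-coverage cytometry: combining colony masks with the indexed grid
# into per-colony, per-raft records, growth classification, segmentation
# metrics, biomarker ratios and doubling-time fits.

#' Per-colony, per-raft coverage records
#'
#' Each labelled component of the mask is assigned to the quad containing
#' its centroid. Per-raft coverage is the fraction of that raft's footprint
#' (the quad split into four raft squares, the intra-quad cross assigned to
#' PDMS) covered by the component; PDMS coverage is measured over the
#' intra-quad gap plus the half-barrier ring around the quad. Component
#' pixels outside the assigned quad's footprint count as PDMS overgrowth.
#'
#' @param mask a `colony_mask`.
#' @param grid an `indexed_grid` in the same coordinate frame.
#' @return data.frame with one row per colony: `colony_id`, `row`, `col`
#'   (NA when the centroid lies outside all quads), `area_um2`,
#'   `equiv_radius_um`, `cov_nw`, `cov_ne`, `cov_sw`, `cov_se`,
#'   `pdms_cov`, per-raft adjacent-PDMS outgrowth `pdms_nw` .. `pdms_se`,
#'   and `raft_class` (number of rafts with coverage >= 0.5).
#' @export
colony_records <- function(mask, grid) {
  px <- mask$pixel_size
  g <- grid$geometry
  lab <- mask$labels
  n <- max(lab)
  if (n == 0) return(empty_records())
  th <- grid$lattice$theta
  e <- grid$entries
  g2 <- g$intra_quad_gap / 2
  half <- g$quad_side / 2
  halfb <- half + g$barrier_width / 2
  rs <- g$raft_side
  idx <- which(lab > 0)
  lv <- lab[idx]
  ij <- arrayInd(idx, dim(lab))
  pxx <- (ij[, 1] - 0.5) * px
  pyy <- (ij[, 2] - 0.5) * px
  # footprint pixel counts per raft and for the PDMS ring (same for all
  # quads up to quantization; use the analytic areas)
  raft_area <- (rs / px)^2
  pdms_area <- (((2 * halfb)^2 - 4 * rs^2) / px^2)
  recs <- lapply(seq_len(n), function(id) {
    sel <- lv == id
    cx <- mean(pxx[sel]); cy <- mean(pyy[sel])
    area <- sum(sel) * px^2
    d2 <- (e$x - cx)^2 + (e$y - cy)^2
    j <- which.min(d2)
    rec <- data.frame(colony_id = id, row = NA_integer_, col = NA_integer_,
                      area_um2 = area, equiv_radius_um = sqrt(area / pi),
                      cov_nw = 0, cov_ne = 0, cov_sw = 0, cov_se = 0,
                      pdms_cov = 0, pdms_nw = 0, pdms_ne = 0, pdms_sw = 0,
                      pdms_se = 0, raft_class = 0L)
    if (!length(j) || sqrt(d2[j]) > g$quad_pitch / sqrt(2)) return(rec)
    rec$row <- e$row[j]; rec$col <- e$col[j]
    u <- rotate_xy(cbind(pxx[sel] - e$x[j], pyy[sel] - e$y[j]), -th)
    ax <- abs(u[, 1]); ay <- abs(u[, 2])
    in_raft <- ax > g2 & ax <= half & ay > g2 & ay <= half
    sub <- ifelse(u[, 2] < 0, ifelse(u[, 1] < 0, 1L, 2L),
                  ifelse(u[, 1] < 0, 3L, 4L))
    cov <- vapply(1:4, function(s) sum(in_raft & sub == s) / raft_area,
                  numeric(1))
    # PDMS: inside the half-barrier ring but not on a raft; off-quad pixels
    # of the component also count as overgrowth
    in_ring <- ax <= halfb & ay <= halfb
    pd <- (in_ring & !in_raft) | !in_ring
    pdsub <- vapply(1:4, function(s) sum(pd & sub == s) / (pdms_area / 4),
                    numeric(1))
    rec$cov_nw <- cov[1]; rec$cov_ne <- cov[2]
    rec$cov_sw <- cov[3]; rec$cov_se <- cov[4]
    rec$pdms_cov <- sum(pd) / pdms_area
    rec$pdms_nw <- pdsub[1]; rec$pdms_ne <- pdsub[2]
    rec$pdms_sw <- pdsub[3]; rec$pdms_se <- pdsub[4]
    rec$raft_class <- sum(cov >= 0.5)
    rec
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

empty_records <- function() {
  data.frame(colony_id = integer(), row = integer(), col = integer(),
             area_um2 = numeric(), equiv_radius_um = numeric(),
             cov_nw = numeric(), cov_ne = numeric(), cov_sw = numeric(),
             cov_se = numeric(), pdms_cov = numeric(), pdms_nw = numeric(),
             pdms_ne = numeric(), pdms_sw = numeric(), pdms_se = numeric(),
             raft_class = integer())
}

#' Per-timepoint raft-count class histograms
#'
#' Counts colonies by the number of microrafts covered (classes 1-4;
#' class-0 components, typically debris below the coverage threshold, are
#' reported separately).
#'
#' @param records data.frame of colony records carrying a `timepoint`
#'   column.
#' @return data.frame (`timepoint`, `class_0` .. `class_4`, `n`).
#' @export
classify_growth <- function(records) {
  if (!nrow(records))
    return(data.frame(timepoint = integer(), class_0 = integer(),
                      class_1 = integer(), class_2 = integer(),
                      class_3 = integer(), class_4 = integer(),
                      n = integer()))
  if (!"timepoint" %in% names(records)) records$timepoint <- 1L
  out <- lapply(split(records, records$timepoint), function(d) {
    h <- tabulate(d$raft_class + 1L, 5L)
    data.frame(timepoint = d$timepoint[1], class_0 = h[1], class_1 = h[2],
               class_2 = h[3], class_3 = h[4], class_4 = h[5], n = nrow(d))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pixelwise segmentation metrics
#'
#' Confusion counts over valid pixels and the derived rates, including the
#' Matthews correlation coefficient.
#'
#' @param predicted a `colony_mask` or logical matrix.
#' @param truth logical matrix of the same shape.
#' @return list with `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `accuracy`, `precision`, `mcc`.
#' @export
evaluate_mask <- function(predicted, truth) {
  p <- if (inherits(predicted, "colony_mask")) predicted$labels > 0
       else predicted
  stopifnot(all(dim(p) == dim(truth)))
  valid <- !is.na(p) & !is.na(truth)
  p <- p[valid]; tr <- truth[valid]
  conf_metrics(tp = sum(p & tr), fp = sum(p & !tr),
               tn = sum(!p & !tr), fn = sum(!p & tr))
}

#' Metrics from confusion counts
#' @param tp,fp,tn,fn pixel counts.
#' @return same structure as [evaluate_mask()].
#' @export
conf_metrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       mcc = if (den > 0) (tp * tn - fp * fn) / den else NA_real_)
}

#' Signal-to-noise gain of a processed image over a raw image
#'
#' SNR of each image is (mean inside the mask - mean outside) / sd outside;
#' the gain is their ratio.
#'
#' @param raw,processed `raft_plane`s or matrices.
#' @param truth logical matrix with both classes present.
#' @return numeric gain.
#' @export
snr_gain <- function(raw, processed, truth) {
  as_mat <- function(x) if (inherits(x, "raft_plane")) x$pixels else x
  r <- as_mat(raw); p <- as_mat(processed)
  stopifnot(any(truth), !all(truth))
  one <- function(m) {
    inside <- m[truth]; outside <- m[!truth]
    s <- stats::sd(outside, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("snr_gain: zero outside-mask sd")
    (mean(inside, na.rm = TRUE) - mean(outside, na.rm = TRUE)) / s
  }
  one(p) / one(r)
}

#' Median relative colony-area error
#'
#' Median over matched colony pairs of |A_pred - A_true| / A_true,
#' restricted to truth colonies of at least the minimum equivalent radius.
#'
#' @param pred_area,true_area matched numeric vectors, um^2.
#' @param min_radius minimum truth equivalent radius, um.
#' @return fraction.
#' @export
median_area_error <- function(pred_area, true_area, min_radius = 25) {
  stopifnot(length(pred_area) == length(true_area))
  keep <- sqrt(true_area / pi) >= min_radius
  if (!any(keep)) stop("median_area_error: no qualifying colony pairs")
  stats::median(abs(pred_area[keep] - true_area[keep]) / true_area[keep])
}

#' Biomarker-positive area fraction
#'
#' Area of biomarker fluorescence above threshold divided by the total
#' nuclear (e.g. Hoechst) area above threshold. Thresholds default to Otsu
#' per channel.
#'
#' @param marker,nuclei `raft_plane`s or matrices of the two channels.
#' @param marker_thresh,nuclei_thresh absolute thresholds; `NULL` for Otsu.
#' @return fraction.
#' @export
biomarker_positive_fraction <- function(marker, nuclei,
                                        marker_thresh = NULL,
                                        nuclei_thresh = NULL) {
  as_mat <- function(x) if (inherits(x, "raft_plane")) x$pixels else x
  m <- as_mat(marker); nu <- as_mat(nuclei)
  stopifnot(all(dim(m) == dim(nu)))
  if (is.null(marker_thresh)) marker_thresh <- otsu_threshold(m)$threshold
  if (is.null(nuclei_thresh)) nuclei_thresh <- otsu_threshold(nu)$threshold
  na <- sum(nu > nuclei_thresh, na.rm = TRUE)
  if (na == 0) stop("biomarker_positive_fraction: zero nuclei area")
  sum(m > marker_thresh, na.rm = TRUE) / na
}

#' Doubling time from log-linear area growth
#'
#' Least-squares fit of log2(area) against time over the fitting window;
#' the doubling time is the reciprocal slope, with its confidence interval
#' from the slope interval at the given significance level.
#'
#' @param hours numeric time, hours.
#' @param areas colony areas (positive) at those times.
#' @param window_h fitting window from the first observation, hours.
#' @param alpha significance level for the confidence interval.
#' @return list with `doubling_h`, `ci_h` (length 2), `slope`, `defined`
#'   (FALSE when the slope is not positive, in which case `doubling_h` is
#'   `NA` rather than an infinite time).
#' @export
doubling_time <- function(hours, areas, window_h = 72, alpha = 0.05) {
  stopifnot(length(hours) == length(areas))
  keep <- is.finite(areas) & areas > 0 & hours <= min(hours) + window_h
  if (sum(keep) < 3)
    stop("doubling_time: need at least 3 positive areas within the window")
  fit <- stats::lm(log2(areas[keep]) ~ hours[keep])
  sl <- stats::coef(fit)[2]
  # noiseless series fit exactly; silence the "perfect fit" note
  ci <- suppressWarnings(stats::confint(fit, level = 1 - alpha)[2, ])
  if (!is.finite(sl) || sl <= 0)
    return(list(doubling_h = NA_real_, ci_h = c(NA_real_, NA_real_),
                slope = unname(sl), defined = FALSE))
  ci_h <- sort(1 / ci)
  ci_h[ci_h < 0] <- Inf
  list(doubling_h = unname(1 / sl), ci_h = unname(ci_h),
       slope = unname(sl), defined = TRUE)
}
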
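# Shared fixture builders: everything is generated in code at test time.

# Tiny stack with one rendered Gaussian spot per entry of `spots`
# (list of list(pos = c(z, y, x) 0-based, h, sigma)).
render_spot_stack <- function(dim_zyx, spots, spacing = c(200, 80, 80),
                              channel = "RAD-51", emission = 647,
                              baseline = 0) {
  vol <- array(baseline, dim = dim_zyx)
  for (sp in spots) {
    sigma <- if (is.null(sp$sigma)) c(1.1, 1.3, 1.3) else sp$sigma
    for (z in 1:dim_zyx[1]) for (y in 1:dim_zyx[2]) for (x in 1:dim_zyx[3]) {
      g <- exp(-0.5 * (((z - 1 - sp$pos[1]) / sigma[1])^2 +
                       ((y - 1 - sp$pos[2]) / sigma[2])^2 +
                       ((x - 1 - sp$pos[3]) / sigma[3])^2))
      vol[z, y, x] <- vol[z, y, x] + sp$h * g
    }
  }
  arr <- array(0, dim = c(1, dim_zyx))
  arr[1, , , ] <- vol
  image_stack(arr, spacing, list(channel_meta(channel, emission)))
}

square_roi <- function(id, x0, y0, side) {
  nucleus_roi(id, cbind(c(x0, x0 + side, x0 + side, x0),
                        c(y0, y0, y0 + side, y0 + side)))
}

# (y, x) pixel mask of regions in xy farther than `clearance` voxels from
# every true focus -- what careful manual background sampling achieves.
focus_free_background <- function(scene, clearance = 4) {
  d <- dim(scene$stack$voxels)
  m <- matrix(TRUE, d[3], d[4])
  tr <- scene$truth$foci
  for (i in seq_len(nrow(tr))) {
    ys <- max(1L, floor(tr$y_vox[i] - clearance) + 1L)
    ye <- min(d[3], ceiling(tr$y_vox[i] + clearance) + 1L)
    xs <- max(1L, floor(tr$x_vox[i] - clearance) + 1L)
    xe <- min(d[4], ceiling(tr$x_vox[i] + clearance) + 1L)
    m[ys:ye, xs:xe] <- FALSE
  }
  m
}

# Greedy matching of detections to ground truth within a voxel tolerance.
match_detections <- function(truth, detected, tol_vox = 3) {
  matched <- logical(nrow(truth))
  fp <- 0L
  for (i in seq_len(nrow(detected))) {
    dd <- sqrt((truth$z_vox - detected$z_vox[i])^2 +
               (truth$y_vox - detected$y_vox[i])^2 +
               (truth$x_vox - detected$x_vox[i])^2)
    j <- which.min(dd)
    if (length(j) && dd[j] <= tol_vox && !matched[j]) {
      matched[j] <- TRUE
    } else {
      fp <- fp + 1L
    }
  }
  list(recall = mean(matched),
       precision = if (nrow(detected)) (nrow(detected) - fp) / nrow(detected)
                   else NA_real_,
       n_true = nrow(truth), n_detected = nrow(detected))
}

# Detection study under controlled SNR (= spot peak / background sd).
# min_peak_height follows the empirical workflow: start at the maximum of
# the sampled (focus-free) background, then iterate the detector at
# increasing thresholds and keep the value minimizing false positives plus
# false negatives -- the threshold a careful operator converges to.
snr_scene_performance <- function(seed, snr, n_nuclei = 12, peak = 1000) {
  spec <- scene_spec(
    n_nuclei = n_nuclei, rows = 3, nucleus_radius_vox = 12, nz = 10,
    margin_vox = 10, seed = seed,
    species_params = list(
      "RAD-51" = species_param(647, n_mean = 4, peak_mean = peak,
                               peak_sd = peak / 10)),
    background = c(mean = 2 * peak / snr, sd = peak / snr))
  scene <- generate_scene(spec)
  bg <- focus_free_background(scene)
  start <- calibrate_min_peak_height(scene$stack, "RAD-51", bg) + 1
  calibrated_detection(scene, "RAD-51", start)
}

calibrated_detection <- function(scene, channel, start_mph) {
  n_true <- nrow(scene$truth$foci)
  best <- NULL
  for (mph in start_mph * seq(1, 1.6, by = 0.15)) {
    tab <- find_maxima_3d(scene$stack, channel, detection_params(mph),
                          mask = scene$rois)
    m <- match_detections(scene$truth$foci, tab)
    fn <- n_true * (1 - m$recall)
    fp <- m$n_detected - n_true * m$recall
    if (is.null(best) || fp + fn < best$fp_fn) {
      best <- c(m, list(fp_fn = fp + fn, min_peak_height = mph,
                        table = tab))
    }
  }
  best
}

# Binary ImageJ .roi polygon writer (documented big-endian layout),
# used to build .roi fixtures at test time.
write_imagej_roi_fixture <- function(path, xs, ys, type = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, nchars = 4, eos = NULL)
  writeBin(227L, con, size = 2, endian = "big")        # version
  writeBin(as.integer(type), con, size = 1)            # roi type
  writeBin(0L, con, size = 1)
  top <- min(ys); left <- min(xs)
  writeBin(as.integer(c(top, left, max(ys), max(xs), length(xs))),
           con, size = 2, endian = "big")
  writeBin(raw(64L - 18L), con)                        # pad header to 64
  writeBin(as.integer(xs - left), con, size = 2, endian = "big")
  writeBin(as.integer(ys - top), con, size = 2, endian = "big")
  invisible(path)
}
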
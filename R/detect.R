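#' Detection parameters for 3D maxima finding
#'
#' Mirrors the parameterization of ImageJ-style 3D maxima finding: a
#' minimum peak height (absolute intensity), anisotropic neighborhood radii
#' in voxels, and a minimum topographic prominence ("noise"). The radii and
#' noise defaults are 1.5, 1.5 and 100, the plugin defaults used throughout
#' this kind of focus quantification; `min_peak_height` has no universal
#' default and is calibrated per image (see [calibrate_min_peak_height()]).
#'
#' @param min_peak_height Minimum intensity for a voxel to be considered a
#'   peak (`>= 0`).
#' @param radius_xy,radius_z Semi-axes of the ellipsoidal neighborhood, in
#'   voxels (not nm); fractional values define the inclusion test
#'   `(dz/radius_z)^2 + (dy/radius_xy)^2 + (dx/radius_xy)^2 <= 1`.
#' @param noise Minimum topographic prominence: a peak of height `h` is
#'   discarded when a strictly brighter voxel can be reached from it along
#'   a 26-connected path that never descends to `h - noise` or below
#'   (noise-tolerance merging; the secondary maxima that image noise
#'   sprinkles over a focus are absorbed into the focus's main peak).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_peak_height, radius_xy = 1.5,
                             radius_z = 1.5, noise = 100) {
  stopifnot(is.numeric(min_peak_height), length(min_peak_height) == 1L,
            min_peak_height >= 0,
            radius_xy > 0, radius_z > 0, noise >= 0)
  structure(list(min_peak_height = as.numeric(min_peak_height),
                 radius_xy = as.numeric(radius_xy),
                 radius_z = as.numeric(radius_z),
                 noise = as.numeric(noise)),
            class = "detection_params")
}

# Integer offsets (z, y, x) inside the ellipsoid, origin excluded.
neighborhood_offsets <- function(radius_z, radius_xy) {
  rz <- floor(radius_z); rxy <- floor(radius_xy)
  g <- expand.grid(dz = -rz:rz, dy = -rxy:rxy, dx = -rxy:rxy)
  inside <- (g$dz / radius_z)^2 + (g$dy / radius_xy)^2 +
            (g$dx / radius_xy)^2 <= 1
  g <- g[inside & !(g$dz == 0 & g$dy == 0 & g$dx == 0), , drop = FALSE]
  as.matrix(g)
}

# 26-connected component labels of the TRUE voxels of a logical volume,
# via half-shift edge extraction and graph components. Returns an integer
# array (0 outside the region).
label_components_26 <- function(region) {
  d <- dim(region)
  idx <- which(region)
  n <- length(idx)
  lab <- array(0L, dim = d)
  if (n == 0L) return(lab)
  id_of <- array(0L, dim = d)
  id_of[idx] <- seq_len(n)
  shifts <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  shifts <- shifts[shifts$dz > 0 | (shifts$dz == 0 & shifts$dy > 0) |
                   (shifts$dz == 0 & shifts$dy == 0 & shifts$dx > 0), ]
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(shifts))) {
    dz <- shifts$dz[k]; dy <- shifts$dy[k]; dx <- shifts$dx[k]
    z1 <- max(1L, 1L + dz):min(d[1L], d[1L] + dz)
    y1 <- max(1L, 1L + dy):min(d[2L], d[2L] + dy)
    x1 <- max(1L, 1L + dx):min(d[3L], d[3L] + dx)
    z0 <- z1 - dz; y0 <- y1 - dy; x0 <- x1 - dx
    both <- region[z0, y0, x0, drop = FALSE] & region[z1, y1, x1, drop = FALSE]
    if (any(both)) {
      from <- c(from, id_of[z0, y0, x0, drop = FALSE][both])
      to <- c(to, id_of[z1, y1, x1, drop = FALSE][both])
    }
  }
  if (length(from)) {
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_len(n)]
  } else {
    comp <- seq_len(n)
  }
  lab[idx] <- as.integer(comp)
  lab
}

#' Find immunofluorescence foci as 3D intensity maxima
#'
#' Calls foci in one channel of a 3D stack. A voxel `v` of intensity `h`
#' is reported iff (1) `h >= min_peak_height`; (2) it is a
#' strict-or-plateau local maximum within the anisotropic ellipsoidal
#' neighborhood of semi-axes `(radius_z, radius_xy, radius_xy)` (no
#' neighbor is brighter); (3) it stands out topographically by at least
#' `noise`: no strictly brighter voxel is reachable from `v` along a
#' 26-connected path through voxels brighter than `h - noise` (for
#' `noise = 0`, no 26-neighbor is strictly brighter); and (4) among
#' surviving candidates closer to each other than the neighborhood, only
#' the brightest is kept, ties resolved toward the smallest `(z, y, x)`
#' (so a flat plateau is reported once, at its lexicographically smallest
#' voxel). When a mask is supplied, the volume outside the mask is cleared
#' of all signal before detection and positions outside the mask are never
#' reported.
#'
#' @param stack An [image_stack()].
#' @param channel Channel label.
#' @param params A [detection_params()].
#' @param mask Optional logical region: either a `(y, x)` matrix applied to
#'   every z plane, or a full `(z, y, x)` array. A list of
#'   [nucleus_roi()] objects is also accepted and rasterised to a 2D mask.
#' @return A [detection_table()] with one row per focus, 0-based voxel
#'   indices, physical nm coordinates and `peak_height`.
#' @export
find_maxima_3d <- function(stack, channel, params, mask = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(params, "detection_params"))
  vol <- channel_volume(stack, channel)
  d <- dim(vol)
  if (!is.null(mask)) {
    if (is.list(mask) && all(vapply(mask, inherits, logical(1), "nucleus_roi"))) {
      mask <- rois_pixel_mask(mask, d[2L], d[3L])
    }
    if (is.matrix(mask)) {
      if (!identical(dim(mask), d[2:3])) {
        stop("2D mask shape ", paste(dim(mask), collapse = "x"),
             " does not match stack xy ", paste(d[2:3], collapse = "x"),
             call. = FALSE)
      }
      mask <- aperm(array(mask, dim = c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
    } else if (!identical(dim(mask), d)) {
      stop("3D mask shape does not match channel volume", call. = FALSE)
    }
    mask <- array(as.logical(mask), dim = d)
    vol[!mask] <- 0
  }
  offsets <- neighborhood_offsets(params$radius_z, params$radius_xy)
  cand <- which(vol >= params$min_peak_height, arr.ind = TRUE)
  if (!is.null(mask) && nrow(cand)) {
    cand <- cand[mask[cand], , drop = FALSE]
  }
  keep <- logical(nrow(cand))
  heights <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ctr <- cand[i, ]
    h <- vol[ctr[1L], ctr[2L], ctr[3L]]
    nbr <- sweep(offsets, 2L, ctr, `+`)
    ok <- nbr[, 1L] >= 1L & nbr[, 1L] <= d[1L] &
          nbr[, 2L] >= 1L & nbr[, 2L] <= d[2L] &
          nbr[, 3L] >= 1L & nbr[, 3L] <= d[3L]
    vals <- vol[nbr[ok, , drop = FALSE]]
    if (length(vals) && any(vals > h)) next
    keep[i] <- TRUE
    heights[i] <- h
  }
  cand <- cand[keep, , drop = FALSE]
  heights <- heights[keep]
  # topographic-prominence ("noise") merging: a candidate is dropped when a
  # strictly brighter voxel is reachable through terrain above h - noise
  if (nrow(cand)) {
    if (params$noise > 0) {
      drop <- logical(nrow(cand))
      for (h in unique(heights)) {
        at_h <- which(heights == h)
        region <- vol > h - params$noise
        lab <- label_components_26(region)
        comp_max <- tapply(vol[region], lab[region], max)
        for (i in at_h) {
          cm <- lab[cand[i, 1L], cand[i, 2L], cand[i, 3L]]
          if (cm > 0L && comp_max[[as.character(cm)]] > h) drop[i] <- TRUE
        }
      }
      cand <- cand[!drop, , drop = FALSE]
      heights <- heights[!drop]
    } else {
      # zero tolerance: only an immediately adjacent brighter voxel merges
      drop <- vapply(seq_len(nrow(cand)), function(i) {
        ctr <- cand[i, ]
        z <- max(1L, ctr[1L] - 1L):min(d[1L], ctr[1L] + 1L)
        y <- max(1L, ctr[2L] - 1L):min(d[2L], ctr[2L] + 1L)
        x <- max(1L, ctr[3L] - 1L):min(d[3L], ctr[3L] + 1L)
        any(vol[z, y, x] > heights[i])
      }, logical(1))
      cand <- cand[!drop, , drop = FALSE]
      heights <- heights[!drop]
    }
  }
  # non-maximum suppression: brightest first, ties toward smallest (z, y, x)
  ord <- order(-heights, cand[, 1L], cand[, 2L], cand[, 3L])
  cand <- cand[ord, , drop = FALSE]
  heights <- heights[ord]
  accepted <- matrix(numeric(0), ncol = 3L)
  acc_h <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (nrow(accepted)) {
      dzyx <- sweep(accepted, 2L, cand[i, ], `-`)
      near <- (dzyx[, 1L] / params$radius_z)^2 +
              (dzyx[, 2L] / params$radius_xy)^2 +
              (dzyx[, 3L] / params$radius_xy)^2 <= 1
      if (any(near)) next
    }
    accepted <- rbind(accepted, cand[i, , drop = FALSE])
    acc_h <- c(acc_h, heights[i])
  }
  # report in (z, y, x) order with 0-based indices
  if (nrow(accepted)) {
    ord <- order(accepted[, 1L], accepted[, 2L], accepted[, 3L])
    accepted <- accepted[ord, , drop = FALSE]
    acc_h <- acc_h[ord]
  }
  vox0 <- accepted - 1
  nm <- vox_to_nm(vox0, stack$spacing)
  nm <- matrix(nm, ncol = 3L)
  df <- data.frame(
    focus_id = sprintf("%s_%04d", channel, seq_len(nrow(accepted))),
    species = rep(channel, nrow(accepted)),
    z_vox = vox0[, 1L], y_vox = vox0[, 2L], x_vox = vox0[, 3L],
    z_nm = nm[, 1L], y_nm = nm[, 2L], x_nm = nm[, 3L],
    peak_height = acc_h,
    stringsAsFactors = FALSE
  )
  detection_table(df, provenance = list(
    channel = channel,
    min_peak_height = params$min_peak_height,
    radius_xy = params$radius_xy, radius_z = params$radius_z,
    noise = params$noise, masked = !is.null(mask)
  ))
}

#' Starting minimum-peak-height from background sampling
#'
#' Returns the maximum intensity over the voxels of manually sampled
#' background regions -- the starting value for the empirical calibration
#' of `min_peak_height`, which is then refined by iteratively re-running
#' detection. If a sampled region covers a real focus the returned value
#' will be at or above that focus's peak and true foci will be missed, so
#' background regions must be focus-free.
#'
#' @param stack An [image_stack()].
#' @param channel Channel label.
#' @param background_rois List of [nucleus_roi()] polygons sampling
#'   background (applied to all z planes), or a logical `(y, x)` matrix.
#' @return The maximum background intensity (a single number).
#' @export
calibrate_min_peak_height <- function(stack, channel, background_rois) {
  vol <- channel_volume(stack, channel)
  d <- dim(vol)
  if (is.matrix(background_rois) && is.logical(background_rois)) {
    mask2d <- background_rois
    if (!identical(dim(mask2d), d[2:3])) {
      stop("background mask shape does not match stack xy", call. = FALSE)
    }
  } else {
    if (!is.list(background_rois) || length(background_rois) == 0L) {
      stop("empty background ROI set", call. = FALSE)
    }
    mask2d <- rois_pixel_mask(background_rois, d[2L], d[3L])
  }
  if (!any(mask2d)) stop("background ROIs cover no pixels", call. = FALSE)
  mask3d <- aperm(array(mask2d, dim = c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  max(vol[mask3d])
}
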
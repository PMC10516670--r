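#' Build a chromosome-axis mask from an axis channel
#'
#' Thresholds the axis channel (typically HTP-3) into a binary volume
#' marking chromosome-axis signal. The threshold is either supplied
#' (`method = "fixed"`) or chosen by Otsu's criterion on the channel
#' histogram (`method = "otsu"`); the mask is `intensity >= threshold`.
#' The method and value are recorded as provenance so an alternative
#' upstream masking recipe can be slotted in.
#'
#' @param stack An [image_stack()].
#' @param axis_channel Channel label of the axis stain.
#' @param method `"fixed"` or `"otsu"`.
#' @param value Threshold intensity, required for `"fixed"`.
#' @return An object of class `axis_mask`: logical `(z, y, x)` array plus a
#'   `provenance` list (`method`, `value`, `dilated_z`).
#' @export
build_axis_mask <- function(stack, axis_channel,
                            method = c("fixed", "otsu"), value = NULL) {
  method <- match.arg(method)
  vol <- channel_volume(stack, axis_channel)
  if (method == "fixed") {
    if (is.null(value)) stop("fixed-threshold masking requires a value",
                             call. = FALSE)
    thr <- as.numeric(value)
  } else {
    hi <- max(vol)
    if (hi == 0) {
      thr <- 0
    } else {
      # Otsu on the 16-bit-normalised histogram of the whole volume
      thr <- EBImage::otsu(matrix(vol / hi, nrow = 1L), range = c(0, 1),
                           levels = 65536L) * hi
    }
  }
  axis_mask(vol >= thr, provenance = list(method = method, value = thr,
                                          dilated_z = 0L))
}

#' @rdname build_axis_mask
#' @param mask Logical `(z, y, x)` array.
#' @param provenance Named list recording how the mask was made.
#' @export
axis_mask <- function(mask, provenance = list()) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  structure(list(mask = array(as.logical(mask), dim = dim(mask)),
                 provenance = provenance),
            class = "axis_mask")
}

#' Dilate an axis mask along z
#'
#' Marks a voxel `(z, y, x)` iff the input mask is true at any
#' `(z', y, x)` with `|z - z'| <= voxels`; xy is untouched. The 1-voxel
#' default captures foci adjacent to or tethered to the axis that sit one z
#' step off the axis signal.
#'
#' @param mask An [axis_mask()].
#' @param voxels Dilation half-width in z voxels (`>= 0`); 0 is the
#'   identity.
#' @return A dilated [axis_mask()].
#' @export
dilate_z <- function(mask, voxels = 1L) {
  stopifnot(inherits(mask, "axis_mask"), voxels >= 0)
  voxels <- as.integer(voxels)
  m <- mask$mask
  if (voxels > 0L) {
    nz <- dim(m)[1L]
    out <- m
    for (dz in seq_len(voxels)) {
      if (nz > dz) {
        out[seq_len(nz - dz), , ] <- out[seq_len(nz - dz), , ] |
          m[(dz + 1L):nz, , ]
        out[(dz + 1L):nz, , ] <- out[(dz + 1L):nz, , ] | m[seq_len(nz - dz), , ]
      }
    }
    m <- out
  }
  prov <- mask$provenance
  prov$dilated_z <- (if (is.null(prov$dilated_z)) 0L else prov$dilated_z) +
    voxels
  axis_mask(m, prov)
}

#' Fraction of foci associated with the chromosome axis
#'
#' A focus is axis-associated iff the (typically z-dilated) axis mask is
#' true at the voxel of its intensity maximum. The degree of axis
#' association is `(number of axis-associated foci) / (total foci)`,
#' reported with a binomial confidence interval. Genotype comparisons on
#' these counts use a Fisher exact test (see [compare_groups()]).
#'
#' @param foci A [detection_table()] (or focus data frame) with 0-based
#'   voxel indices.
#' @param mask An [axis_mask()] whose shape matches the channel volume the
#'   foci were called in.
#' @param ci_method Passed to [proportion_ci()].
#' @return A list `(associated, total, fraction, ci_lower, ci_upper)`.
#' @export
axis_association_fraction <- function(foci, mask, ci_method = "wilson") {
  stopifnot(inherits(mask, "axis_mask"))
  f <- as.data.frame(foci)
  d <- dim(mask$mask)
  total <- nrow(f)
  if (total == 0L) {
    return(list(associated = 0L, total = 0L, fraction = NA_real_,
                ci_lower = NA_real_, ci_upper = NA_real_))
  }
  idx <- cbind(f$z_vox + 1L, f$y_vox + 1L, f$x_vox + 1L)
  if (any(idx < 1L) || any(idx[, 1L] > d[1L]) || any(idx[, 2L] > d[2L]) ||
      any(idx[, 3L] > d[3L])) {
    stop("focus position outside the mask volume", call. = FALSE)
  }
  assoc <- mask$mask[idx]
  k <- sum(assoc)
  ci <- proportion_ci(k, total, method = ci_method)
  list(associated = k, total = total, fraction = k / total,
       ci_lower = ci[["lower"]], ci_upper = ci[["upper"]])
}
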
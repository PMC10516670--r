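#' Nucleus region of interest
#'
#' A 2D polygon in voxel xy coordinates outlining one germline nucleus, as
#' drawn on a max-projected image (in practice traced around the HTP-3 axis
#' signal). Vertices are stored as an `n x 2` matrix with columns `x, y`.
#'
#' @param id Unique ROI identifier (coerced to character).
#' @param xy Numeric `n x 2` matrix (or 2-column data frame) of polygon
#'   vertices, `n >= 3`, in order around the boundary. The polygon must be
#'   simple (non-self-intersecting).
#' @param row_index Optional integer cell-row assignment (see
#'   [assign_rows()]).
#' @return An object of class `nucleus_roi` with elements `id`, `xy`,
#'   `centroid_xy` and `row_index`.
#' @export
nucleus_roi <- function(id, xy, row_index = NA_integer_) {
  xy <- as.matrix(xy)
  if (!is.numeric(xy) || ncol(xy) != 2L || nrow(xy) < 3L || anyNA(xy)) {
    stop("polygon must be a numeric n x 2 matrix with at least 3 vertices",
         call. = FALSE)
  }
  if (polygon_area(xy) == 0) {
    stop("degenerate polygon (zero area) for ROI '", id, "'", call. = FALSE)
  }
  colnames(xy) <- c("x", "y")
  structure(list(id = as.character(id), xy = xy,
                 centroid_xy = polygon_centroid(xy),
                 row_index = as.integer(row_index)),
            class = "nucleus_roi")
}

# Signed area by the shoelace formula (positive for counter-clockwise order)
polygon_signed_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(xy) abs(polygon_signed_area(xy))

# Area-weighted centroid; falls back to the vertex mean for (near-)zero area
polygon_centroid <- function(xy) {
  a <- polygon_signed_area(xy)
  if (abs(a) < .Machine$double.eps) {
    return(c(x = mean(xy[, 1L]), y = mean(xy[, 2L])))
  }
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  c(x = sum((x + xn) * cr) / (6 * a), y = sum((y + yn) * cr) / (6 * a))
}

#' @export
print.nucleus_roi <- function(x, ...) {
  cat(sprintf("<nucleus_roi> id=%s, %d vertices, centroid (%.2f, %.2f)\n",
              x$id, nrow(x$xy), x$centroid_xy["x"], x$centroid_xy["y"]))
  invisible(x)
}

roi_ids <- function(rois) vapply(rois, `[[`, character(1), "id")

roi_centroids <- function(rois) {
  m <- t(vapply(rois, `[[`, numeric(2), "centroid_xy"))
  colnames(m) <- c("x", "y")
  rownames(m) <- roi_ids(rois)
  m
}

# Boundary-inclusive point-in-polygon test for a set of points.
# x, y: point coordinates; roi: nucleus_roi.
points_in_roi <- function(x, y, roi) {
  pracma::inpolygon(x, y, roi$xy[, 1L], roi$xy[, 2L], boundary = TRUE)
}

# Logical (y, x) pixel mask of a set of ROIs on an image of size ny x nx.
# Pixel (row iy, col ix) corresponds to 0-based voxel (iy - 1, ix - 1); its
# center in the ROI coordinate frame is that 0-based index itself.
rois_pixel_mask <- function(rois, ny, nx) {
  mask <- matrix(FALSE, ny, nx)
  gx <- rep(seq_len(nx) - 1L, each = ny)
  gy <- rep(seq_len(ny) - 1L, times = nx)
  for (roi in rois) {
    bb_x <- range(roi$xy[, 1L]); bb_y <- range(roi$xy[, 2L])
    sel <- gx >= bb_x[1L] - 1 & gx <= bb_x[2L] + 1 &
           gy >= bb_y[1L] - 1 & gy <= bb_y[2L] + 1
    if (!any(sel)) next
    inside <- points_in_roi(gx[sel], gy[sel], roi)
    mask[cbind(gy[sel][inside] + 1L, gx[sel][inside] + 1L)] <- TRUE
  }
  mask
}
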
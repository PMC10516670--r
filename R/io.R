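#' Read a multi-channel z-stack from TIFF / OME-TIFF
#'
#' Planes on disk are interpreted channel-major: for `C` declared channels
#' and `P` planes the file must satisfy `P = C * Z`, planes `1..Z` being
#' channel 1, and so on. The returned stack is always indexed
#' `(channel, z, y, x)`.
#'
#' If the file carries an OME-XML ImageDescription with `PhysicalSizeX/Y/Z`
#' attributes, that spacing is used when the caller passes none; a
#' caller-supplied `spacing` always wins.
#'
#' @param path Path to a TIFF file.
#' @param channels List of [channel_meta()] (or a character vector of
#'   labels, in which case emission wavelengths default to 555 nm).
#' @param spacing Optional `(z, y, x)` voxel spacing in nm; required unless
#'   the file embeds OME physical-size metadata.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channels, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(channels)) {
    channels <- lapply(channels, channel_meta, emission_nm = 555)
  }
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  nc <- length(channels)
  np <- length(planes)
  if (np %% nc != 0L) {
    stop("channel/plane mismatch: ", np, " plane(s) cannot be split into ",
         nc, " channel(s)", call. = FALSE)
  }
  nz <- np %/% nc
  if (!all(vapply(planes, is.numeric, logical(1)))) {
    stop("non-numeric pixel data in ", path, call. = FALSE)
  }
  if (is.null(spacing)) {
    desc <- attr(planes[[1L]], "description")
    spacing <- if (!is.null(desc)) parse_ome_spacing(desc) else NULL
    if (is.null(spacing)) {
      stop("no spacing supplied and no OME physical-size metadata in ", path,
           call. = FALSE)
    }
  }
  ny <- nrow(planes[[1L]]); nx <- ncol(planes[[1L]])
  vox <- array(0, dim = c(nc, nz, ny, nx))
  for (ci in seq_len(nc)) {
    for (zi in seq_len(nz)) {
      vox[ci, zi, , ] <- planes[[(ci - 1L) * nz + zi]]
    }
  }
  image_stack(vox, spacing, channels)
}

#' Write an image stack as a 16-bit multi-plane TIFF
#'
#' Intensities are rounded to integers and must fit in 0..65535. Planes are
#' written channel-major (all z of channel 1, then channel 2, ...),
#' matching [read_stack()].
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  v <- round(stack$voxels)
  if (max(v) > 65535) {
    stop("intensities exceed the 16-bit range (max ", max(v), ")",
         call. = FALSE)
  }
  d <- dim(v)
  planes <- vector("list", d[1L] * d[2L])
  k <- 0L
  for (ci in seq_len(d[1L])) {
    for (zi in seq_len(d[2L])) {
      k <- k + 1L
      planes[[k]] <- matrix(v[ci, zi, , ], d[3L], d[4L]) / 65535
    }
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}

# Extract (z, y, x) spacing in nm from an OME-XML ImageDescription, or NULL.
# OME PhysicalSize values default to micrometers unless a *Unit attribute
# says otherwise; "nm" and "um"/micron units are handled.
parse_ome_spacing <- function(description) {
  if (!grepl("<OME", description, fixed = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(description), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  get1 <- function(attr_name, unit_name) {
    val <- xml2::xml_attr(px, attr_name)
    if (is.na(val)) return(NA_real_)
    unit <- xml2::xml_attr(px, unit_name)
    mult <- if (!is.na(unit) && unit %in% c("nm", "nanometer")) 1 else 1000
    as.numeric(val) * mult
  }
  sp <- c(z = get1("PhysicalSizeZ", "PhysicalSizeZUnit"),
          y = get1("PhysicalSizeY", "PhysicalSizeYUnit"),
          x = get1("PhysicalSizeX", "PhysicalSizeXUnit"))
  if (anyNA(sp)) NULL else sp
}

#' Read nucleus ROI polygons
#'
#' Accepts the package's canonical JSON dialect
#' (`{"rois": [{"id": ..., "xy": [[x, y], ...]}, ...]}`), a single ImageJ
#' `.roi` file, or an ImageJ `.zip` ROI archive. ImageJ ROIs must be of
#' polygon type (type codes 0 polygon, 2 freehand closed, 3 traced); any
#' other ROI type is an error. IDs are taken from the JSON records or from
#' the `.roi` entry names and are stable across re-reads.
#'
#' @param path Path to a `.json`, `.roi` or `.zip` file.
#' @return List of [nucleus_roi()] objects.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  rois <- switch(ext,
    "json" = read_rois_json(path),
    "roi"  = list(read_imagej_roi(path)),
    "zip"  = read_imagej_zip(path),
    stop("unsupported ROI file type: .", ext, call. = FALSE)
  )
  if (length(rois) == 0L) stop("empty ROI archive: ", path, call. = FALSE)
  ids <- roi_ids(rois)
  if (anyDuplicated(ids)) stop("duplicate ROI ids in ", path, call. = FALSE)
  rois
}

read_rois_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$rois)) stop("JSON ROI file lacks a 'rois' array", call. = FALSE)
  lapply(obj$rois, function(r) {
    xy <- do.call(rbind, lapply(r$xy, function(p) as.numeric(unlist(p))))
    nucleus_roi(r$id, xy)
  })
}

#' Write nucleus ROIs in the canonical JSON dialect
#'
#' @param rois List of [nucleus_roi()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  recs <- lapply(rois, function(r) {
    list(id = r$id,
         xy = lapply(seq_len(nrow(r$xy)), function(i) as.numeric(r$xy[i, ])))
  })
  jsonlite::write_json(list(rois = recs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Minimal parser for ImageJ .roi files (big-endian; header documented in the
# ImageJ source, RoiDecoder.java). Only closed polygon types are supported.
read_imagej_roi <- function(path, id = NULL) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout") {
    stop("not an ImageJ ROI file: ", path, call. = FALSE)
  }
  be_int <- function(off, size) {  # 0-based byte offset
    readBin(raw[(off + 1L):(off + size)], "integer", size = size,
            endian = "big", signed = TRUE)
  }
  type <- as.integer(raw[7L])  # byte offset 6
  if (!type %in% c(0L, 3L, 7L)) {  # polygon, freehand(closed), traced
    stop("unsupported ROI type (code ", type, "); only polygon ROIs are read",
         call. = FALSE)
  }
  top  <- be_int(8L, 2L); left <- be_int(10L, 2L)
  n    <- be_int(16L, 2L)
  if (n < 3L) stop("ROI has fewer than 3 vertices: ", path, call. = FALSE)
  xs <- vapply(seq_len(n) - 1L, function(i) be_int(64L + 2L * i, 2L), integer(1))
  ys <- vapply(seq_len(n) - 1L, function(i) be_int(64L + 2L * n + 2L * i, 2L),
               integer(1))
  if (is.null(id)) id <- sub("\\.roi$", "", basename(path))
  nucleus_roi(id, cbind(x = xs + left, y = ys + top))
}

read_imagej_zip <- function(path) {
  exdir <- tempfile("rois_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  files <- utils::unzip(path, exdir = exdir)
  files <- sort(files[grepl("\\.roi$", files)])
  if (length(files) == 0L) stop("no .roi entries in archive: ", path, call. = FALSE)
  lapply(files, function(f) read_imagej_roi(f))
}
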
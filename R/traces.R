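#' Traced chromosome
#'
#' A hand-traced chromosome represented as an ordered 3D polyline in
#' micrometers, optionally with attached crossover-site (CO) points (e.g.
#' COSA-1/MSH-5 focus positions).
#'
#' @param id Trace identifier.
#' @param points_um Numeric `n x 3` matrix of polyline vertices (x, y, z)
#'   in um, `n >= 2`, consecutive points distinct.
#' @param co_sites_um Optional `m x 3` matrix of CO-site points in um.
#' @return An object of class `chromosome_trace`.
#' @export
chromosome_trace <- function(id, points_um, co_sites_um = NULL) {
  points_um <- as.matrix(points_um)
  if (!is.numeric(points_um) || ncol(points_um) != 3L || nrow(points_um) < 2L) {
    stop("points_um must be a numeric n x 3 matrix with n >= 2", call. = FALSE)
  }
  seg <- diff(points_um)
  if (any(rowSums(seg^2) == 0)) {
    stop("consecutive polyline points must be distinct", call. = FALSE)
  }
  if (!is.null(co_sites_um)) {
    co_sites_um <- matrix(as.numeric(as.matrix(co_sites_um)), ncol = 3L)
  }
  structure(list(id = as.character(id), points_um = points_um,
                 co_sites_um = co_sites_um),
            class = "chromosome_trace")
}

#' Chromosome trace length
#'
#' Arc length of the traced polyline: the sum of consecutive-point
#' Euclidean distances, in um.
#'
#' @param trace A [chromosome_trace()].
#' @return Length in um.
#' @export
trace_length <- function(trace) {
  stopifnot(inherits(trace, "chromosome_trace"))
  sum(sqrt(rowSums(diff(trace$points_um)^2)))
}

# Project a point onto the polyline: returns the arc length at the nearest
# polyline point and the distance to it.
project_on_polyline <- function(points, p) {
  best <- list(dist = Inf, s = NA_real_)
  s0 <- 0
  for (i in seq_len(nrow(points) - 1L)) {
    a <- points[i, ]; b <- points[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- sum((p - a) * ab) / len2
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    d <- sqrt(sum((p - q)^2))
    if (d < best$dist) best <- list(dist = d, s = s0 + t * sqrt(len2))
    s0 <- s0 + sqrt(len2)
  }
  best
}

#' Relative CO position from the nearest chromosome end
#'
#' Snaps a CO-site point onto the traced chromosome, measures the arc
#' length from the snapped position to the nearer chromosome end, and
#' divides by the total trace length. The result is in `[0, 0.5]` by
#' construction (0 = chromosome end, 0.5 = midpoint) and is invariant
#' under reversing the polyline direction.
#'
#' @param trace A [chromosome_trace()].
#' @param co_point Length-3 numeric CO-site position in um.
#' @param snap_tol_um Maximum allowed distance from the CO point to the
#'   polyline; beyond it the point is considered not on this chromosome.
#' @return Relative distance from the nearest end, in `[0, 0.5]`.
#' @export
co_relative_position <- function(trace, co_point, snap_tol_um = 0.5) {
  stopifnot(inherits(trace, "chromosome_trace"))
  pr <- project_on_polyline(trace$points_um, as.numeric(co_point))
  if (pr$dist > snap_tol_um) {
    stop(sprintf("CO point is %.3f um from the trace (snap tolerance %.3f um)",
                 pr$dist, snap_tol_um), call. = FALSE)
  }
  total <- trace_length(trace)
  min(pr$s, total - pr$s) / total
}

#' Classify a trace as a fusion chromosome
#'
#' Fusion chromosomes (such as the mnT12 X;IV fusion) are distinguished
#' from normal chromosomes by traced length: a trace is a fusion iff its
#' length strictly exceeds the cutoff (default 15 um; normal chromosomes
#' trace shorter than this, fusions longer).
#'
#' @param trace A [chromosome_trace()].
#' @param cutoff_um Length cutoff in um.
#' @return `TRUE` for a fusion chromosome.
#' @export
classify_fusion <- function(trace, cutoff_um = 15) {
  trace_length(trace) > cutoff_um
}

#' Distribution of CO positions along chromosomes
#'
#' Histograms the relative CO positions (distance from the nearest end,
#' `[0, 0.5]`) separately for fusion and non-fusion chromosomes, as
#' fractions that sum to 1 within each class.
#'
#' @param traces List of [chromosome_trace()]s with CO sites attached.
#' @param bins Number of equal-width bins over `[0, 0.5]`.
#' @param cutoff_um Fusion length cutoff passed to [classify_fusion()].
#' @param snap_tol_um Passed to [co_relative_position()].
#' @return A data frame `(class, bin_lo, bin_hi, n, fraction)` with
#'   `class` in `"fusion"`/`"non_fusion"`; classes with no COs are absent.
#' @export
co_distribution_histogram <- function(traces, bins = 10L, cutoff_um = 15,
                                      snap_tol_um = 0.5) {
  stopifnot(length(traces) >= 1L)
  pos <- list(fusion = numeric(0), non_fusion = numeric(0))
  any_co <- FALSE
  for (tr in traces) {
    if (is.null(tr$co_sites_um) || nrow(tr$co_sites_um) == 0L) next
    any_co <- TRUE
    cls <- if (classify_fusion(tr, cutoff_um)) "fusion" else "non_fusion"
    rel <- apply(tr$co_sites_um, 1L, function(p)
      co_relative_position(tr, p, snap_tol_um))
    pos[[cls]] <- c(pos[[cls]], rel)
  }
  if (!any_co) stop("no CO sites on any trace", call. = FALSE)
  edges <- seq(0, 0.5, length.out = bins + 1L)
  rows <- lapply(names(pos), function(cls) {
    x <- pos[[cls]]
    if (length(x) == 0L) return(NULL)
    # right-closed bins except the first, so 0 falls in bin 1 and 0.5 in the
    # terminal bin
    b <- findInterval(x, edges, rightmost.closed = TRUE, left.open = TRUE)
    b[b == 0L] <- 1L
    n <- tabulate(b, nbins = bins)
    data.frame(class = cls, bin_lo = edges[-length(edges)],
               bin_hi = edges[-1L], n = n, fraction = n / sum(n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read chromosome traces
#'
#' Accepts the package's JSON dialect
#' (`{"traces": [{"id": ..., "points_um": [[x,y,z], ...],
#' "co_sites_um": [[x,y,z], ...]}]}`) or SWC files (one path per
#' chromosome; columns `id type x y z radius parent`, coordinates taken as
#' um, CO sites not representable in SWC).
#'
#' @param path Path to a `.json` or `.swc` file.
#' @return List of [chromosome_trace()]s.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (is.null(obj$traces)) stop("JSON trace file lacks a 'traces' array",
                                  call. = FALSE)
    lapply(obj$traces, function(tr) {
      pts <- do.call(rbind, lapply(tr$points_um, function(p)
        as.numeric(unlist(p))))
      cos <- if (!is.null(tr$co_sites_um) && length(tr$co_sites_um)) {
        do.call(rbind, lapply(tr$co_sites_um, function(p)
          as.numeric(unlist(p))))
      } else NULL
      chromosome_trace(tr$id, pts, cos)
    })
  } else if (ext == "swc") {
    df <- utils::read.table(path, comment.char = "#",
                            col.names = c("id", "type", "x", "y", "z",
                                          "radius", "parent"))
    roots <- which(df$parent == -1)
    if (length(roots) == 0L) stop("SWC file has no root node", call. = FALSE)
    bounds <- c(roots, nrow(df) + 1L)
    lapply(seq_along(roots), function(k) {
      seg <- df[bounds[k]:(bounds[k + 1L] - 1L), , drop = FALSE]
      chromosome_trace(sprintf("swc_%03d", k),
                       cbind(seg$x, seg$y, seg$z))
    })
  } else {
    stop("unsupported trace file type: .", ext, call. = FALSE)
  }
}

#' Write chromosome traces in the JSON dialect
#'
#' @param traces List of [chromosome_trace()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  recs <- lapply(traces, function(tr) {
    rec <- list(id = tr$id,
                points_um = lapply(seq_len(nrow(tr$points_um)), function(i)
                  as.numeric(tr$points_um[i, ])))
    if (!is.null(tr$co_sites_um) && nrow(tr$co_sites_um)) {
      rec$co_sites_um <- lapply(seq_len(nrow(tr$co_sites_um)), function(i)
        as.numeric(tr$co_sites_um[i, ]))
    }
    rec
  })
  jsonlite::write_json(list(traces = recs), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
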
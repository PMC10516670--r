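# Run code under a fixed seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Per-species parameters for scene generation
#'
#' @param emission_nm Emission wavelength attached to the channel.
#' @param n_mean Mean focus count per nucleus (Poisson), ignored when
#'   `n_exact` is given.
#' @param n_exact Optional fixed focus count per nucleus.
#' @param onset_row Optional 0-based cell row before which the species has
#'   no foci (for building count gradients along the gonad).
#' @param psf_sigma_vox Gaussian spot sigmas `(z, y, x)` in voxels; the
#'   defaults give a spot FWHM of about 3 voxels in xy, the scale of
#'   diffraction-limited widefield foci.
#' @param peak_mean,peak_sd Normal distribution of rendered peak heights
#'   (intensity units).
#' @return A list of class `species_param`.
#' @export
species_param <- function(emission_nm = 555, n_mean = 5, n_exact = NULL,
                          onset_row = NULL,
                          psf_sigma_vox = c(1.1, 1.3, 1.3),
                          peak_mean = 1000, peak_sd = 100) {
  structure(list(emission_nm = emission_nm, n_mean = n_mean,
                 n_exact = n_exact, onset_row = onset_row,
                 psf_sigma_vox = psf_sigma_vox,
                 peak_mean = peak_mean, peak_sd = peak_sd),
            class = "species_param")
}

#' Specification of a synthetic gonad scene
#'
#' Describes a field of germline nuclei arrayed in cell rows along the
#' gonad (x) axis, each carrying diffraction-limited foci of one or more
#' species, optionally curvilinear chromosome-axis tracks and controlled
#' colocalization / axis-association fractions, over additive Gaussian
#' background noise. The seed fixes the entire scene: identical seeds give
#' bit-identical stacks, ROIs and ground truth.
#'
#' @param n_nuclei Total nucleus count.
#' @param rows Nuclei per cell row (stacked along y); the number of cell
#'   rows along x is `ceiling(n_nuclei / rows)`.
#' @param nucleus_radius_vox Nucleus radius in xy voxels; the default of
#'   25 voxels is a 2 um radius at 80 nm pixels, the scale of a pachytene
#'   germline nucleus.
#' @param nz Number of z planes.
#' @param gonad_length_vox Image x extent; derived from the layout when
#'   `NULL`.
#' @param margin_vox Empty margin around the nucleus grid in xy voxels;
#'   enlarge it when a focus-free background region is needed for
#'   threshold calibration.
#' @param spacing Voxel spacing `(z, y, x)` in nm; defaults to 200 nm z
#'   steps and 80 nm xy pixels, typical of widefield gonad stacks on a
#'   100x/1.4 NA system.
#' @param species_params Named list of [species_param()], one per focus
#'   species; names become channel labels.
#' @param coloc_spec Optional list `(pair = c(A, B), fraction, offset_nm,
#'   exclusion_nm)`: each focus of species B is, with probability
#'   `fraction`, placed at `offset_nm` (default 100 nm, below both 242 and
#'   282 nm thresholds) from a species-A focus of its nucleus; all other B
#'   foci are kept at least `exclusion_nm` (default 564 nm, twice the
#'   larger threshold) from every A focus, so ground truth is unambiguous.
#' @param axis_spec Optional list `(channel, n_curves, intensity,
#'   assoc_fraction)`: renders `n_curves` smoothed random-walk axis tracks
#'   per nucleus into channel `channel`; `assoc_fraction` is a named vector
#'   of per-species probabilities that a focus is placed on an axis track
#'   (non-associated foci are kept at least 3 voxels away in xy).
#' @param background Named vector `(mean, sd)` of additive Gaussian noise
#'   added last (negatives clipped at zero, intensities rounded).
#' @param render If `FALSE`, skip rendering the image stack (the result's
#'   `stack` is `NULL`); ground truth and ROIs are still produced, which is
#'   all that point-pattern studies (colocalization fractions) need.
#' @param seed RNG seed fixing the scene.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(n_nuclei = 24, rows = 4, nucleus_radius_vox = 25,
                       nz = 12, gonad_length_vox = NULL, margin_vox = 3,
                       spacing = c(200, 80, 80),
                       species_params = list("RAD-51" = species_param(647)),
                       coloc_spec = NULL, axis_spec = NULL,
                       background = c(mean = 100, sd = 10), render = TRUE,
                       seed = 1) {
  stopifnot(n_nuclei >= 1, rows >= 1, nucleus_radius_vox > 0, nz >= 1,
            length(species_params) >= 1, !is.null(names(species_params)))
  if (!is.null(coloc_spec)) {
    stopifnot(all(coloc_spec$pair %in% names(species_params)),
              coloc_spec$fraction >= 0, coloc_spec$fraction <= 1)
    if (match(coloc_spec$pair[1L], names(species_params)) >
        match(coloc_spec$pair[2L], names(species_params))) {
      stop("coloc_spec$pair[1] must be listed before pair[2] in species_params",
           call. = FALSE)
    }
    if (is.null(coloc_spec$offset_nm)) coloc_spec$offset_nm <- 100
    if (is.null(coloc_spec$exclusion_nm)) coloc_spec$exclusion_nm <- 564
  }
  if (!is.null(axis_spec)) {
    if (is.null(axis_spec$channel)) axis_spec$channel <- "HTP-3"
    if (is.null(axis_spec$n_curves)) axis_spec$n_curves <- 2L
    if (is.null(axis_spec$intensity)) axis_spec$intensity <- 3000
    stopifnot(all(axis_spec$assoc_fraction >= 0),
              all(axis_spec$assoc_fraction <= 1))
  }
  structure(list(n_nuclei = n_nuclei, rows = rows,
                 nucleus_radius_vox = nucleus_radius_vox, nz = nz,
                 gonad_length_vox = gonad_length_vox,
                 margin_vox = margin_vox,
                 spacing = stats::setNames(as.numeric(spacing),
                                           c("z", "y", "x")),
                 species_params = species_params, coloc_spec = coloc_spec,
                 axis_spec = axis_spec,
                 background = background,
                 render = render, seed = seed),
            class = "scene_spec")
}

# uniform point in a disc of radius r centered at c(0, 0)
runif_disc <- function(r) {
  th <- stats::runif(1, 0, 2 * pi)
  rr <- r * sqrt(stats::runif(1))
  c(rr * cos(th), rr * sin(th))
}

# smoothed random-walk axis curve inside a disc (continuous xy points,
# 0-based voxel coordinates)
axis_curve_points <- function(center_xy, r, n_steps) {
  p <- center_xy + runif_disc(0.5 * r)
  th <- stats::runif(1, 0, 2 * pi)
  pts <- matrix(0, n_steps + 1L, 2L)
  pts[1L, ] <- p
  for (i in seq_len(n_steps)) {
    th <- th + stats::rnorm(1, 0, 0.4)
    cand <- p + c(cos(th), sin(th))
    if (sqrt(sum((cand - center_xy)^2)) > 0.85 * r) {
      # turn back toward the nucleus center when hitting the membrane
      th <- atan2(center_xy[2L] - p[2L], center_xy[1L] - p[1L]) +
        stats::rnorm(1, 0, 0.3)
      cand <- p + c(cos(th), sin(th))
    }
    p <- cand
    pts[i + 1L, ] <- p
  }
  pts
}

# stamp a truncated separable 3D Gaussian (peak h at continuous 0-based
# voxel position pos = c(z, y, x)) into vol
stamp_gaussian <- function(vol, pos, sigma, h, trunc_sd = 4) {
  d <- dim(vol)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor(pos[a] - trunc_sd * sigma[a]) + 1L)
    hi <- min(d[a], ceiling(pos[a] + trunc_sd * sigma[a]) + 1L)
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0L)) return(vol)
  gz <- exp(-0.5 * ((rng[[1L]] - 1L - pos[1L]) / sigma[1L])^2)
  gy <- exp(-0.5 * ((rng[[2L]] - 1L - pos[2L]) / sigma[2L])^2)
  gx <- exp(-0.5 * ((rng[[3L]] - 1L - pos[3L]) / sigma[3L])^2)
  patch <- h * (gz %o% gy %o% gx)
  vol[rng[[1L]], rng[[2L]], rng[[3L]]] <-
    vol[rng[[1L]], rng[[2L]], rng[[3L]]] + patch
  vol
}

#' Generate a synthetic gonad scene with ground truth
#'
#' Realises a [scene_spec()]: nuclei on a row grid along x, every true
#' focus rendered as an anisotropic Gaussian spot, colocalized partners
#' placed at the specified sub-threshold offset, axis tracks rendered as
#' bright curvilinear paths, background noise added last. The ground truth
#' records every generative choice (true positions, pairings, association
#' flags, per-nucleus rows), together with the realised colocalization /
#' association fractions next to the nominal ones.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `stack` ([image_stack()]), `rois` (list of
#'   [nucleus_roi()]), and `truth` (list: `foci` data frame, `pairs` data
#'   frame, `nuclei` data frame, `nominal` / `realized` fractions).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  r <- spec$nucleus_radius_vox
  margin <- if (is.null(spec$margin_vox)) 3 else spec$margin_vox
  pitch <- 2 * r + 4
  n_cols <- ceiling(spec$n_nuclei / spec$rows)
  nx <- if (is.null(spec$gonad_length_vox)) {
    ceiling(2 * margin + (n_cols - 1) * pitch + 2 * r)
  } else spec$gonad_length_vox
  ny <- ceiling(2 * margin + (spec$rows - 1) * pitch + 2 * r)
  nz <- spec$nz
  cz <- (nz - 1) / 2
  zc_plane <- round(cz)

  render <- !isFALSE(spec$render)
  species <- names(spec$species_params)
  axis_channel <- if (!is.null(spec$axis_spec)) spec$axis_spec$channel else NULL
  channels <- c(species, axis_channel)
  vols <- if (render) {
    stats::setNames(lapply(channels, function(ch) array(0, dim = c(nz, ny, nx))),
                    channels)
  } else NULL

  # nucleus centers: cell row j (0-based) along x, position within row along y
  centers <- t(vapply(seq_len(spec$n_nuclei) - 1L, function(i) {
    col <- i %/% spec$rows
    pos <- i %% spec$rows
    c(x = margin + r + col * pitch, y = margin + r + pos * pitch,
      row = col)
  }, numeric(3)))

  nuc_ids <- sprintf("n%03d", seq_len(spec$n_nuclei))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_nuclei)

  rois <- vector("list", spec$n_nuclei)
  foci_rows <- list()
  pair_rows <- list()
  cl <- spec$coloc_spec
  ax <- spec$axis_spec

  for (i in seq_len(spec$n_nuclei)) {
    set.seed(sub_seeds[i])
    cx <- unname(centers[i, "x"]); cy <- unname(centers[i, "y"])
    nrow_idx <- unname(centers[i, "row"])
    # circular ROI polygon (24-gon) at the nucleus boundary
    th <- seq(0, 2 * pi, length.out = 25L)[-25L]
    rois[[i]] <- nucleus_roi(nuc_ids[i],
                             cbind(cx + r * cos(th), cy + r * sin(th)),
                             row_index = nrow_idx)
    rois[[i]]$row_index <- as.integer(nrow_idx)

    # axis tracks
    curve_xy <- NULL
    if (!is.null(ax)) {
      curves <- lapply(seq_len(ax$n_curves), function(k)
        axis_curve_points(c(cx, cy), r, n_steps = round(3 * r)))
      curve_xy <- do.call(rbind, curves)
      vox <- unique(cbind(round(curve_xy[, 2L]), round(curve_xy[, 1L])))
      vox <- vox[vox[, 1L] >= 0 & vox[, 1L] < ny &
                 vox[, 2L] >= 0 & vox[, 2L] < nx, , drop = FALSE]
      if (render) {
        vols[[axis_channel]][cbind(zc_plane + 1L, vox[, 1L] + 1L,
                                   vox[, 2L] + 1L)] <- ax$intensity
      }
    }

    placed <- list()  # per species: matrix of (z, y, x) continuous positions
    for (s in species) {
      sp <- spec$species_params[[s]]
      if (!is.null(sp$onset_row) && nrow_idx < sp$onset_row) {
        placed[[s]] <- matrix(numeric(0), ncol = 3L)
        next
      }
      k <- if (!is.null(sp$n_exact)) sp$n_exact else stats::rpois(1, sp$n_mean)
      assoc_frac <- if (!is.null(ax)) ax$assoc_fraction[s] else NA_real_
      is_a_of_pair <- !is.null(cl) && identical(s, cl$pair[1L])
      is_b_of_pair <- !is.null(cl) && identical(s, cl$pair[2L])
      a_positions <- if (is_b_of_pair) placed[[cl$pair[1L]]] else NULL
      a_free <- if (is_b_of_pair) rep(TRUE, nrow(a_positions)) else logical(0)
      # the species anchoring colocalized partners needs extra same-species
      # clearance so that partner foci (placed ~1 xy voxel off their anchor)
      # remain mutually resolvable
      off_xy_vox <- if (!is.null(cl)) cl$offset_nm / min(spec$spacing) else 0
      sep_xy <- if (is_a_of_pair) 4 + 2 * off_xy_vox else 4
      sep_z <- if (is_a_of_pair) 4 else 3

      pos_mat <- matrix(numeric(0), ncol = 3L)
      flags_assoc <- logical(0)
      flags_pair <- integer(0)  # row index into a_positions, NA if none
      for (kk in seq_len(k)) {
        # the focus's character (paired / axis-associated) is drawn once,
        # so that position rejection below cannot bias the realised
        # fractions
        # each anchor focus hosts at most one partner (a colocalized pair
        # is one-to-one); when no free anchor remains the focus falls back
        # to the unpaired pool and the realised fraction records it
        want_pair <- is_b_of_pair && any(a_free) &&
          stats::runif(1) < cl$fraction
        want_assoc <- !want_pair && !is.na(assoc_frac) &&
          stats::runif(1) < assoc_frac
        attempts <- 0L
        repeat {
          attempts <- attempts + 1L
          if (attempts > 5000L) {
            stop("foci per nucleus infeasible for nucleus size (species ", s,
                 ")", call. = FALSE)
          }
          if (want_pair) {
            free_idx <- which(a_free)
            j <- free_idx[sample.int(length(free_idx), 1L)]
            u <- stats::rnorm(3)
            u <- u / sqrt(sum(u^2))
            off_vox <- cl$offset_nm * u / spec$spacing  # (z, y, x)
            p <- a_positions[j, ] + off_vox
          } else if (want_assoc && !is.null(curve_xy)) {
            cp <- curve_xy[sample.int(nrow(curve_xy), 1L), ]
            p <- c(zc_plane, cp[2L], cp[1L])
          } else {
            xy <- runif_disc(0.8 * r)
            p <- c(cz + stats::runif(1, -min(2, cz), min(2, cz)),
                   cy + xy[2L], cx + xy[1L])
          }
          # inside the volume and the nucleus?
          if (p[1L] < 0 || p[1L] > nz - 1 ||
              sqrt((p[2L] - cy)^2 + (p[3L] - cx)^2) > 0.95 * r) next
          # separation from same-species foci: spots must stay individually
          # resolvable given the anisotropic psf (semi-axes beyond the
          # Sparrow limit of 2 sigma). Paired foci inherit their spacing
          # from their anchors, which carry the enlarged clearance.
          if (!want_pair && nrow(pos_mat)) {
            dd <- sweep(pos_mat, 2L, p)
            too_close <- (dd[, 1L] / sep_z)^2 +
              (dd[, 2L]^2 + dd[, 3L]^2) / sep_xy^2 < 1
            if (any(too_close)) next
          }
          # non-paired foci of the pair's B species stay far from all A foci
          if (is_b_of_pair && !want_pair && !is.null(a_positions) &&
              nrow(a_positions) > 0L) {
            dnm <- sweep(vox_to_nm(a_positions, spec$spacing), 2L,
                         vox_to_nm(p, spec$spacing))
            if (min(sqrt(rowSums(dnm^2))) < cl$exclusion_nm) next
          }
          # non-associated foci stay >= 3 voxels from the axis in xy
          if (!is.null(curve_xy) && !is.na(assoc_frac) && !want_assoc &&
              !want_pair) {
            dxy <- sqrt((curve_xy[, 1L] - p[3L])^2 +
                        (curve_xy[, 2L] - p[2L])^2)
            if (min(dxy) < 3) next
          }
          break
        }
        pos_mat <- rbind(pos_mat, p)
        flags_assoc <- c(flags_assoc, want_assoc)
        if (want_pair) a_free[j] <- FALSE
        flags_pair <- c(flags_pair, if (want_pair) j else NA_integer_)
      }
      dimnames(pos_mat) <- NULL
      placed[[s]] <- pos_mat

      if (nrow(pos_mat)) {
        sp_ids <- sprintf("%s_%s_%02d", s, nuc_ids[i], seq_len(nrow(pos_mat)))
        peaks <- pmax(1, stats::rnorm(nrow(pos_mat), sp$peak_mean, sp$peak_sd))
        nm <- vox_to_nm(pos_mat, spec$spacing)
        nm <- matrix(nm, ncol = 3L)
        foci_rows[[length(foci_rows) + 1L]] <- data.frame(
          focus_id = sp_ids, species = s, nucleus_id = nuc_ids[i],
          row = nrow_idx,
          z_vox = pos_mat[, 1L], y_vox = pos_mat[, 2L], x_vox = pos_mat[, 3L],
          z_nm = nm[, 1L], y_nm = nm[, 2L], x_nm = nm[, 3L],
          peak_height = peaks,
          axis_associated = if (!is.null(ax) && !is.na(assoc_frac))
            flags_assoc else NA,
          stringsAsFactors = FALSE)
        if (is_b_of_pair) {
          a_ids <- sprintf("%s_%s_%02d", cl$pair[1L], nuc_ids[i],
                           seq_len(nrow(a_positions)))
          paired <- which(!is.na(flags_pair))
          if (length(paired)) {
            pair_rows[[length(pair_rows) + 1L]] <- data.frame(
              a_id = a_ids[flags_pair[paired]], b_id = sp_ids[paired],
              stringsAsFactors = FALSE)
          }
        }
        if (render) {
          for (fi in seq_len(nrow(pos_mat))) {
            vols[[s]] <- stamp_gaussian(vols[[s]], pos_mat[fi, ],
                                        sp$psf_sigma_vox, peaks[fi])
          }
        }
      }
    }
  }

  stack <- NULL
  if (render) {
    # background noise, clipping and quantisation (added last)
    bg <- spec$background
    for (ch in channels) {
      noise <- stats::rnorm(length(vols[[ch]]), bg[["mean"]], bg[["sd"]])
      vols[[ch]] <- round(pmin(pmax(vols[[ch]] + noise, 0), 65535))
    }
    stack_vox <- array(0, dim = c(length(channels), nz, ny, nx))
    metas <- vector("list", length(channels))
    for (ci in seq_along(channels)) {
      stack_vox[ci, , , ] <- vols[[channels[ci]]]
      em <- if (channels[ci] %in% species) {
        spec$species_params[[channels[ci]]]$emission_nm
      } else 488
      metas[[ci]] <- channel_meta(channels[ci], em)
    }
    stack <- image_stack(stack_vox, spec$spacing, metas)
  }

  foci <- if (length(foci_rows)) {
    do.call(rbind, c(foci_rows, make.row.names = FALSE))
  } else {
    data.frame(focus_id = character(), species = character(),
               nucleus_id = character(), row = integer(),
               z_vox = numeric(), y_vox = numeric(), x_vox = numeric(),
               z_nm = numeric(), y_nm = numeric(), x_nm = numeric(),
               peak_height = numeric(), axis_associated = logical(),
               stringsAsFactors = FALSE)
  }
  pairs <- if (length(pair_rows)) {
    do.call(rbind, c(pair_rows, make.row.names = FALSE))
  } else {
    data.frame(a_id = character(), b_id = character(),
               stringsAsFactors = FALSE)
  }

  realized <- list()
  if (!is.null(cl)) {
    n_b <- sum(foci$species == cl$pair[2L])
    realized$coloc_fraction <- if (n_b > 0) nrow(pairs) / n_b else NA_real_
    realized$coloc_pairs <- nrow(pairs)
  }
  if (!is.null(ax)) {
    realized$axis_fraction <- vapply(names(ax$assoc_fraction), function(s) {
      sel <- foci$species == s
      if (any(sel)) mean(foci$axis_associated[sel]) else NA_real_
    }, numeric(1))
  }

  truth <- list(
    foci = foci, pairs = pairs,
    nuclei = data.frame(nucleus_id = nuc_ids,
                        centroid_x = centers[, "x"],
                        centroid_y = centers[, "y"],
                        row = as.integer(centers[, "row"]),
                        stringsAsFactors = FALSE),
    nominal = list(coloc_fraction = if (!is.null(cl)) cl$fraction else NULL,
                   axis_fraction = if (!is.null(ax)) ax$assoc_fraction
                                   else NULL),
    realized = realized
  )
  list(stack = stack, rois = rois, truth = truth)
}

#' Generate synthetic chromosome traces with planted CO sites
#'
#' Draws smoothed random-walk 3D polylines whose arc lengths match the
#' drawn target lengths to well under 1% discretization error, with CO
#' sites planted at known arc-length fractions (the stored ground truth is
#' the relative distance from the nearest end, `min(u, 1 - u)`). Fusion
#' traces are drawn longer than the 15 um classification cutoff by
#' construction.
#'
#' @param n_traces Number of traces.
#' @param length_range_um Length range (uniform) for non-fusion traces;
#'   default 4-12 um, the scale of normal pachytene chromosomes.
#' @param fusion_fraction Probability a trace is a fusion chromosome.
#' @param fusion_length_range_um Length range for fusion traces; default
#'   18-30 um (above the 15 um cutoff).
#' @param co_per_trace CO sites planted per trace.
#' @param seed RNG seed.
#' @return A list `(traces, truth)`: `traces` is a list of
#'   [chromosome_trace()]s; `truth` a data frame `(trace_id, is_fusion,
#'   length_um, arc_fraction, rel_nearest_end)` with one row per CO site.
#' @export
generate_trace_set <- function(n_traces, length_range_um = c(4, 12),
                               fusion_fraction = 0,
                               fusion_length_range_um = c(18, 30),
                               co_per_trace = 1L, seed = 1) {
  stopifnot(all(length_range_um > 0), all(fusion_length_range_um > 0))
  with_seed(seed, {
    ds <- 0.02  # um per step
    traces <- vector("list", n_traces)
    truth_rows <- list()
    for (i in seq_len(n_traces)) {
      fusion <- stats::runif(1) < fusion_fraction
      rng <- if (fusion) fusion_length_range_um else length_range_um
      target <- stats::runif(1, rng[1L], rng[2L])
      n_steps <- max(2L, round(target / ds))
      # persistent random walk: unit direction jittered each step
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      pts <- matrix(0, n_steps + 1L, 3L)
      pts[1L, ] <- stats::runif(3, 0, 20)
      for (k in seq_len(n_steps)) {
        dir <- dir + stats::rnorm(3, 0, 0.08)
        dir <- dir / sqrt(sum(dir^2))
        pts[k + 1L, ] <- pts[k, ] + dir * ds
      }
      total <- n_steps * ds
      u <- stats::runif(co_per_trace)
      co <- t(vapply(u, function(uu) {
        s <- uu * total
        k <- min(n_steps, floor(s / ds))
        frac <- s / ds - k
        pts[k + 1L, ] + frac * (pts[min(k + 2L, n_steps + 1L), ] -
                                pts[k + 1L, ])
      }, numeric(3)))
      id <- sprintf("tr%03d", i)
      traces[[i]] <- chromosome_trace(id, pts, co)
      truth_rows[[i]] <- data.frame(
        trace_id = id, is_fusion = fusion, length_um = total,
        arc_fraction = u, rel_nearest_end = pmin(u, 1 - u),
        stringsAsFactors = FALSE)
    }
    list(traces = traces,
         truth = do.call(rbind, c(truth_rows, make.row.names = FALSE)))
  })
}
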
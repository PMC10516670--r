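# Independent brute-force oracles: direct evaluation of the stated
# post-conditions, written as plain nested loops so they share no code path
# with the implementation they check.

# Label the TRUE voxels of a logical volume by 26-connected component via
# plain label relaxation (each voxel repeatedly takes the minimum label in
# its neighborhood until nothing changes).
oracle_label_26 <- function(region) {
  d <- dim(region)
  lab <- array(Inf, dim = d)
  lab[region] <- which(region)
  shifted <- function(a, dz, dy, dx) {
    out <- array(Inf, dim = d)
    z1 <- max(1, 1 + dz):min(d[1], d[1] + dz)
    y1 <- max(1, 1 + dy):min(d[2], d[2] + dy)
    x1 <- max(1, 1 + dx):min(d[3], d[3] + dx)
    out[z1, y1, x1] <- a[z1 - dz, y1 - dy, x1 - dx]
    out
  }
  repeat {
    new_lab <- lab
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      new_lab <- pmin(new_lab, shifted(lab, dz, dy, dx))
    }
    new_lab[!region] <- Inf
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  lab
}

# 3D maxima post-conditions evaluated at every voxel, then iterative
# brightest-first suppression by removal.
oracle_find_maxima <- function(vol, params, mask = NULL) {
  d <- dim(vol)
  rz <- params$radius_z
  rxy <- params$radius_xy
  if (!is.null(mask)) vol[!mask] <- 0
  inside <- function(dz, dy, dx) {
    (dz / rz)^2 + (dy / rxy)^2 + (dx / rxy)^2 <= 1
  }
  cands <- list()
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (!is.null(mask) && !mask[z, y, x]) next
    h <- vol[z, y, x]
    if (h < params$min_peak_height) next
    is_max <- TRUE
    for (dz in -floor(rz):floor(rz)) {
      for (dy in -floor(rxy):floor(rxy)) {
        for (dx in -floor(rxy):floor(rxy)) {
          if (dz == 0 && dy == 0 && dx == 0) next
          if (!inside(dz, dy, dx)) next
          zz <- z + dz; yy <- y + dy; xx <- x + dx
          if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] ||
              xx < 1 || xx > d[3]) next
          if (vol[zz, yy, xx] > h) is_max <- FALSE
        }
      }
    }
    if (!is_max) next
    cands[[length(cands) + 1L]] <- c(z, y, x, h)
  }
  # topographic prominence: drop a candidate whose connected region above
  # (h - noise) holds a strictly brighter voxel
  if (length(cands)) {
    m0 <- do.call(rbind, cands)
    keep <- logical(nrow(m0))
    lab_cache <- list()
    for (i in seq_len(nrow(m0))) {
      h <- m0[i, 4]
      if (params$noise > 0) {
        key <- as.character(h)
        if (is.null(lab_cache[[key]])) {
          lab_cache[[key]] <- oracle_label_26(vol > h - params$noise)
        }
        lab <- lab_cache[[key]]
        region <- vol > h - params$noise
        cm <- lab[m0[i, 1], m0[i, 2], m0[i, 3]]
        keep[i] <- max(vol[lab == cm & region]) <= h
      } else {
        z <- max(1, m0[i, 1] - 1):min(d[1], m0[i, 1] + 1)
        y <- max(1, m0[i, 2] - 1):min(d[2], m0[i, 2] + 1)
        x <- max(1, m0[i, 3] - 1):min(d[3], m0[i, 3] + 1)
        keep[i] <- !any(vol[z, y, x] > h)
      }
    }
    cands <- lapply(which(keep), function(i) m0[i, ])
  }
  if (length(cands) == 0L) {
    return(data.frame(z_vox = numeric(), y_vox = numeric(),
                      x_vox = numeric(), peak_height = numeric()))
  }
  m <- do.call(rbind, cands)
  kept <- list()
  while (nrow(m) > 0L) {
    ord <- order(-m[, 4L], m[, 1L], m[, 2L], m[, 3L])
    m <- m[ord, , drop = FALSE]
    top <- m[1L, ]
    kept[[length(kept) + 1L]] <- top
    dd <- sweep(m[, 1:3, drop = FALSE], 2L, top[1:3])
    near <- (dd[, 1L] / rz)^2 + (dd[, 2L] / rxy)^2 + (dd[, 3L] / rxy)^2 <= 1
    m <- m[!near, , drop = FALSE]
  }
  k <- do.call(rbind, kept)
  k <- k[order(k[, 1L], k[, 2L], k[, 3L]), , drop = FALSE]
  data.frame(z_vox = k[, 1L] - 1, y_vox = k[, 2L] - 1, x_vox = k[, 3L] - 1,
             peak_height = k[, 4L])
}

# Ray-casting point-in-polygon with explicit boundary handling.
oracle_point_in_poly <- function(px, py, xy, eps = 1e-9) {
  n <- nrow(xy)
  for (i in seq_len(n)) {
    a <- xy[i, ]
    b <- xy[i %% n + 1L, ]
    ab <- b - a
    t <- sum((c(px, py) - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    if (sqrt(sum((c(px, py) - q)^2)) <= eps) return(TRUE)
  }
  crossings <- 0L
  for (i in seq_len(n)) {
    a <- xy[i, ]
    b <- xy[i %% n + 1L, ]
    if ((a[2L] > py) != (b[2L] > py)) {
      xint <- a[1L] + (py - a[2L]) * (b[1L] - a[1L]) / (b[2L] - a[2L])
      if (xint > px) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# All-pairs nearest-neighbor scan.
oracle_nearest_neighbor <- function(q_nm, r_nm, threshold_nm) {
  nq <- nrow(q_nm)
  out <- data.frame(nn_dist_nm = rep(Inf, nq), colocalized = FALSE)
  for (i in seq_len(nq)) {
    best <- Inf
    for (j in seq_len(nrow(r_nm))) {
      dist <- sqrt(sum((q_nm[i, ] - r_nm[j, ])^2))
      if (dist < best) best <- dist
    }
    out$nn_dist_nm[i] <- best
    out$colocalized[i] <- best < threshold_nm
  }
  out
}

# Exhaustive enumeration of contiguous runs of positive rows.
oracle_majority_zone <- function(flags, rows) {
  rng <- seq.int(min(rows), max(rows))
  pos <- vapply(rng, function(r) {
    sel <- rows == r
    sum(sel) > 0L && mean(flags[sel]) > 0.5
  }, logical(1))
  best <- list(len = 0L, start = NA_integer_, end = NA_integer_)
  for (i in seq_along(rng)) {
    for (j in i:length(rng)) {
      if (all(pos[i:j]) && (j - i + 1L) > best$len) {
        best <- list(len = j - i + 1L, start = rng[i], end = rng[j])
      }
    }
  }
  best
}

# Exhaustive window scan with a self-contained median.
oracle_peak_window <- function(counts, rows, width) {
  med <- function(x) {
    s <- sort(x)
    n <- length(s)
    if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
  }
  rng <- seq.int(min(rows), max(rows))
  starts <- rng[seq_len(length(rng) - width + 1L)]
  best <- list(median = -Inf, start = NA_integer_)
  for (s in starts) {
    sel <- rows >= s & rows <= s + width - 1L
    m <- if (any(sel)) med(counts[sel]) else -Inf
    if (m > best$median) best <- list(median = m, start = s)
  }
  best
}
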
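#' Zone result
#'
#' A contiguous range of cell rows selected by a zone rule. `start_row` and
#' `end_row` are inclusive 0-based row indices; an empty zone has `NA`
#' bounds and length 0.
#'
#' @param start_row,end_row Inclusive row bounds (`start_row <= end_row`),
#'   or `NA` for an empty zone.
#' @param rule Short description of the rule that produced the zone.
#' @return An object of class `zone_result` with `start_row`, `end_row`,
#'   `length_rows` and `rule`.
#' @export
zone_result <- function(start_row, end_row, rule) {
  if (is.na(start_row) || is.na(end_row)) {
    return(structure(list(start_row = NA_integer_, end_row = NA_integer_,
                          length_rows = 0L, rule = rule),
                     class = "zone_result"))
  }
  stopifnot(start_row <= end_row)
  structure(list(start_row = as.integer(start_row),
                 end_row = as.integer(end_row),
                 length_rows = as.integer(end_row - start_row + 1L),
                 rule = rule),
            class = "zone_result")
}

#' @export
print.zone_result <- function(x, ...) {
  if (is.na(x$start_row)) {
    cat(sprintf("<zone_result> empty (%s)\n", x$rule))
  } else {
    cat(sprintf("<zone_result> rows %d-%d (%d rows; %s)\n",
                x$start_row, x$end_row, x$length_rows, x$rule))
  }
  invisible(x)
}

#' Assign nuclei to cell rows by centroid-x binning
#'
#' The gonad's "cell row" (a column of nuclei perpendicular to its long
#' axis, read by eye in practice) is operationalised as equal-width bins of
#' the ROI centroid x coordinate:
#' `row_index = floor((centroid_x - min_x) / row_pitch)`. The default pitch
#' is the median nearest-neighbor spacing among distinct centroid-x values
#' (nuclei sharing a row have near-identical x, so within-row spacings are
#' excluded by the distinctness requirement).
#'
#' @param rois List of [nucleus_roi()] objects.
#' @param row_pitch Row width in voxels (> 0), or `NULL` for the default.
#' @return The ROI list with `row_index` filled in (0-based, stable order).
#' @export
assign_rows <- function(rois, row_pitch = NULL) {
  cx <- roi_centroids(rois)[, "x"]
  tol <- 1e-6  # centroid x values closer than this are the same cell row
  if (is.null(row_pitch)) {
    ux <- sort(cx)
    reps <- ux[c(TRUE, diff(ux) > tol)]
    if (length(reps) < 2L) {
      row_pitch <- 1
    } else {
      gaps <- diff(reps)
      nn <- pmin(c(gaps, Inf), c(Inf, gaps))
      row_pitch <- stats::median(nn)
    }
  }
  if (row_pitch <= 0) stop("row_pitch must be positive", call. = FALSE)
  idx <- floor((cx - min(cx) + tol) / row_pitch)
  for (i in seq_along(rois)) rois[[i]]$row_index <- as.integer(idx[i])
  rois
}

# Positive rows (> 50% of nuclei satisfy the flag) over the full integer
# row range; rows with no nuclei are negative.
row_majority <- function(flags, rows) {
  stopifnot(length(flags) == length(rows), length(flags) > 0L)
  rng <- seq.int(min(rows), max(rows))
  vapply(rng, function(r) {
    in_row <- rows == r
    sum(in_row) > 0L && mean(flags[in_row]) > 0.5
  }, logical(1))
}

#' Majority-staining zone (e.g. the CHK-2 active zone)
#'
#' A row is positive iff strictly more than 50% of its nuclei carry the
#' flag (e.g. SUN-1 pS24 staining); the zone is the longest contiguous run
#' of positive rows, ties broken toward the earliest (most distal) run.
#'
#' @param per_nucleus_flag Logical vector, one entry per nucleus.
#' @param rows Integer row index per nucleus (same length).
#' @return A [zone_result()]; empty if no row is positive.
#' @export
majority_zone <- function(per_nucleus_flag, rows) {
  if (length(per_nucleus_flag) == 0L) stop("empty input", call. = FALSE)
  pos <- row_majority(per_nucleus_flag, rows)
  rng <- seq.int(min(rows), max(rows))
  best_len <- 0L; best_start <- NA_integer_
  i <- 1L
  while (i <= length(pos)) {
    if (pos[i]) {
      j <- i
      while (j < length(pos) && pos[j + 1L]) j <- j + 1L
      if (j - i + 1L > best_len) {  # strict: earliest run wins ties
        best_len <- j - i + 1L
        best_start <- i
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.na(best_start)) {
    zone_result(NA, NA, "majority run")
  } else {
    zone_result(rng[best_start], rng[best_start + best_len - 1L],
                "majority run")
  }
}

#' Zone boundaries from per-nucleus count rules
#'
#' Finds a zone of the form "starts at the first cell row in which most
#' nuclei satisfy the start predicate; ends at the first subsequent row in
#' which most nuclei satisfy the end predicate" -- the construction behind
#' the early pachytene zone (start: most nuclei have at least one RAD-51
#' focus; end: most nuclei have 6 CO-site-associated MSH-5 or HIM-6 foci).
#' "Most" is strictly more than 50%.
#'
#' @param counts Data frame `(nucleus_id, species, n)` as produced by
#'   [count_foci_per_nucleus()] (a nucleus absent for a species counts 0).
#' @param rows Named integer vector mapping `nucleus_id` to row index.
#' @param p_start,p_end Predicates taking a named count vector (one entry
#'   per species) for one nucleus and returning `TRUE`/`FALSE`.
#' @return A [zone_result()].
#' @export
boundary_by_count_rule <- function(counts, rows, p_start, p_end) {
  stopifnot(!is.null(names(rows)))
  species <- sort(unique(counts$species))
  nuclei <- names(rows)
  count_of <- function(nid) {
    v <- stats::setNames(rep(0L, length(species)), species)
    sel <- counts$nucleus_id == nid
    if (any(sel)) v[counts$species[sel]] <- counts$n[sel]
    v
  }
  per_nuc <- lapply(nuclei, count_of)
  names(per_nuc) <- nuclei
  sat <- function(pred) vapply(per_nuc, pred, logical(1))
  rng <- seq.int(min(rows), max(rows))
  maj <- function(flags) {
    vapply(rng, function(r) {
      in_row <- rows == r
      sum(in_row) > 0L && mean(flags[in_row]) > 0.5
    }, logical(1))
  }
  start_rows <- rng[maj(sat(p_start))]
  if (length(start_rows) == 0L) stop("start rule unmet", call. = FALSE)
  start <- min(start_rows)
  end_rows <- rng[maj(sat(p_end))]
  end_rows <- end_rows[end_rows >= start]
  if (length(end_rows) == 0L) stop("end rule unmet", call. = FALSE)
  zone_result(start, min(end_rows), "count rule")
}

#' Peak-accumulation window
#'
#' The fixed-width window of cell rows maximizing the median per-nucleus
#' focus count -- the zone of peak accumulation in which focus counts are
#' compared across genotypes. Ties go to the earliest window. The default
#' width is 10 cell rows.
#'
#' @param counts Numeric focus count per nucleus.
#' @param rows Integer row index per nucleus (same length).
#' @param width_rows Window width in rows; must not exceed the row span.
#' @return A [zone_result()]; its `median_count` attribute holds the
#'   winning window's median.
#' @export
peak_window <- function(counts, rows, width_rows = 10L) {
  stopifnot(length(counts) == length(rows), length(counts) > 0L)
  rng <- seq.int(min(rows), max(rows))
  if (width_rows > length(rng)) {
    stop("width_rows (", width_rows, ") exceeds the available ",
         length(rng), " rows", call. = FALSE)
  }
  starts <- rng[seq_len(length(rng) - width_rows + 1L)]
  meds <- vapply(starts, function(s) {
    sel <- rows >= s & rows <= s + width_rows - 1L
    if (!any(sel)) -Inf else stats::median(counts[sel])
  }, numeric(1))
  best <- which.max(meds)  # which.max returns the first (earliest) maximum
  z <- zone_result(starts[best], starts[best] + width_rows - 1L,
                   "peak window")
  attr(z, "median_count") <- meds[best]
  z
}

#' Two-group statistical comparisons
#'
#' The comparisons used for focus-count and zone statistics: two-sided
#' Mann-Whitney (Wilcoxon rank-sum) for per-nucleus count distributions,
#' Welch's t test for zone lengths, and Fisher's exact test for
#' (associated, not-associated) count tables. Delegates to the standard
#' stats routines.
#'
#' @param x,y For `"mann-whitney"`/`"welch-t"`: numeric samples. For
#'   `"fisher-exact"`: length-2 count vectors `(successes, failures)` per
#'   group (together forming the 2x2 table), or `x` a 2x2 matrix with `y`
#'   omitted.
#' @param test Which test to run.
#' @return A list `(statistic, p_value, method)` (plus `estimate` for the
#'   Fisher odds ratio).
#' @export
compare_groups <- function(x, y = NULL,
                           test = c("mann-whitney", "welch-t",
                                    "fisher-exact")) {
  test <- match.arg(test)
  if (test == "fisher-exact") {
    tab <- if (is.matrix(x)) x else rbind(x, y)
    if (!all(dim(tab) == c(2L, 2L))) {
      stop("fisher-exact needs a 2x2 count table", call. = FALSE)
    }
    ft <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, p_value = ft$p.value,
                estimate = unname(ft$estimate), method = "Fisher exact test"))
  }
  if (length(x) == 0L || length(y) == 0L) stop("empty group", call. = FALSE)
  if (test == "mann-whitney") {
    ht <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "Mann-Whitney test")
  } else {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         method = "Welch's t test")
  }
}

#' Brood-viability percentages
#'
#' The progeny-viability arithmetic for single-hermaphrodite broods scored
#' at three time points: eggs + larvae at 24 h (tp1) and 48 h (tp2), and
#' adults at 72-96 h (tp3). The total eggs laid is the largest of the tp1
#' count, the tp2 count and the tp3 adult count, to guard against
#' undercounting of young larvae and larval lethality. Then
#' `% hatching = 100 * (1 - unhatched_tp2 / total)`,
#' `% reaching adulthood = 100 * adults / total`, and
#' `% males = 100 * males / adults` (NA when there are no adults).
#'
#' @param eggs_tp1,eggs_tp2 Eggs + larvae counted at time points 1 and 2.
#' @param unhatched_tp2 Unhatched eggs at time point 2.
#' @param adults_tp3 Adults at time point 3.
#' @param males_tp3 Males among those adults.
#' @return A list `(total_eggs, pct_hatching, pct_adulthood, pct_males)`.
#' @export
brood_viability <- function(eggs_tp1, eggs_tp2, unhatched_tp2, adults_tp3,
                            males_tp3) {
  counts <- c(eggs_tp1, eggs_tp2, unhatched_tp2, adults_tp3, males_tp3)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- max(eggs_tp1, eggs_tp2, adults_tp3)
  if (total == 0) stop("no eggs laid (total_eggs = 0)", call. = FALSE)
  list(total_eggs = total,
       pct_hatching = 100 * (1 - unhatched_tp2 / total),
       pct_adulthood = 100 * adults_tp3 / total,
       pct_males = if (adults_tp3 > 0) 100 * males_tp3 / adults_tp3
                   else NA_real_)
}
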
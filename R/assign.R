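#' Assign detected foci to nucleus ROIs
#'
#' A focus is assigned to a ROI iff its `(x, y)` position (taken from the
#' xy of its 3D intensity maximum, which max projection preserves) lies
#' inside the ROI polygon, with the boundary counting as inside so that no
#' focus is lost at shared edges. Foci inside no ROI keep `nucleus_id = NA`;
#' foci inside more than one ROI are flagged for resolution (see
#' [resolve_overlaps()]) and carry `NA` until resolved.
#'
#' @param foci A [detection_table()] (or data frame of focus records).
#' @param rois List of [nucleus_roi()] objects.
#' @return A [detection_table()] whose `overlaps` attribute is a data frame
#'   `(focus_id, candidate_ids)` listing every multiply-assigned focus and
#'   the comma-separated candidate ROI ids.
#' @export
assign_foci <- function(foci, rois) {
  table <- detection_table(as.data.frame(foci))
  n <- nrow(table)
  memberships <- vector("list", n)
  if (n > 0L) {
    for (roi in rois) {
      inside <- points_in_roi(table$x_vox, table$y_vox, roi)
      for (i in which(inside)) {
        memberships[[i]] <- c(memberships[[i]], roi$id)
      }
    }
  }
  n_in <- lengths(memberships)
  table$nucleus_id <- ifelse(n_in == 1L,
                             vapply(memberships, function(m)
                               if (length(m) == 1L) m else NA_character_,
                               character(1)),
                             NA_character_)
  ov <- which(n_in > 1L)
  overlaps <- data.frame(
    focus_id = table$focus_id[ov],
    candidate_ids = vapply(memberships[ov], paste, character(1),
                           collapse = ","),
    stringsAsFactors = FALSE
  )
  out <- detection_table(table, provenance = attr(foci, "provenance"))
  attr(out, "overlaps") <- overlaps
  out
}

#' Resolve multiply-assigned foci
#'
#' The manual curation step of removing ROI-overlap ambiguities is replaced
#' by a deterministic rule: each multiply-assigned focus is reassigned to
#' the candidate ROI with the nearest centroid (ties broken toward the
#' smaller ROI id), and every resolution is listed in a report for human
#' review.
#'
#' @param table Output of [assign_foci()] (carrying an `overlaps`
#'   attribute).
#' @param rois The ROI list used for assignment.
#' @return The table with all overlap foci assigned; the `resolutions`
#'   attribute is a data frame `(focus_id, assigned_to, candidates,
#'   distances)` describing every decision. A table with no overlaps is
#'   returned unchanged (with an empty report).
#' @export
resolve_overlaps <- function(table, rois) {
  overlaps <- attr(table, "overlaps")
  empty_report <- data.frame(focus_id = character(), assigned_to = character(),
                             candidates = character(), distances = character(),
                             stringsAsFactors = FALSE)
  if (is.null(overlaps) || nrow(overlaps) == 0L) {
    attr(table, "resolutions") <- empty_report
    return(table)
  }
  cents <- roi_centroids(rois)
  report <- empty_report
  for (k in seq_len(nrow(overlaps))) {
    fid <- overlaps$focus_id[k]
    cand_ids <- strsplit(overlaps$candidate_ids[k], ",", fixed = TRUE)[[1L]]
    i <- match(fid, table$focus_id)
    p <- c(table$x_vox[i], table$y_vox[i])
    dists <- sqrt((cents[cand_ids, "x"] - p[1L])^2 +
                  (cents[cand_ids, "y"] - p[2L])^2)
    ord <- order(dists, cand_ids)  # nearest centroid, ties by smaller id
    winner <- cand_ids[ord[1L]]
    table$nucleus_id[i] <- winner
    report <- rbind(report, data.frame(
      focus_id = fid, assigned_to = winner,
      candidates = paste(cand_ids, collapse = ","),
      distances = paste(sprintf("%.3f", dists), collapse = ","),
      stringsAsFactors = FALSE))
  }
  attr(table, "overlaps") <- overlaps[0, , drop = FALSE]
  attr(table, "resolutions") <- report
  table
}

#' Relative position of each nucleus along the quantified region
#'
#' Expresses each nucleus's position as a percentage of the length between
#' the start of the quantified region (0%, e.g. the distal tip) and its end
#' (100%, e.g. the end of the pachytene zone), using the ROI centroid x as
#' the nucleus position. The percentage is attached to every focus assigned
#' to that nucleus; unassigned foci keep `NA`. Centroids outside the region
#' are clamped to 0/100 with a warning.
#'
#' @param table A [detection_table()] with resolved assignments.
#' @param rois The ROI list (source of centroids).
#' @param region_x_start,region_x_end Region bounds in voxel x coordinates,
#'   `region_x_end > region_x_start`.
#' @return The table with `rel_position_pct` filled in.
#' @export
relative_positions <- function(table, rois, region_x_start, region_x_end) {
  if (region_x_end <= region_x_start) {
    stop("region_x_end must exceed region_x_start", call. = FALSE)
  }
  cents <- roi_centroids(rois)
  pct <- 100 * (cents[, "x"] - region_x_start) /
         (region_x_end - region_x_start)
  if (any(pct < 0 | pct > 100)) {
    warning("ROI centroid(s) outside the quantified region; clamped to [0, 100]")
    pct <- pmin(pmax(pct, 0), 100)
  }
  idx <- match(table$nucleus_id, rownames(cents))
  table$rel_position_pct <- ifelse(is.na(idx), NA_real_, pct[idx])
  table
}

#' Per-nucleus focus counts by species
#'
#' Tallies assigned foci per nucleus and species. Unassigned foci are
#' excluded from the counts and reported through the `unassigned`
#' attribute, so that counts plus unassigned always equal the table total.
#'
#' @param table A [detection_table()] with resolved assignments.
#' @return A data frame `(nucleus_id, species, n)`; attribute `unassigned`
#'   holds the number of excluded foci.
#' @export
count_foci_per_nucleus <- function(table) {
  assigned <- !is.na(table$nucleus_id)
  if (!any(assigned)) {
    out <- data.frame(nucleus_id = character(), species = character(),
                      n = integer(), stringsAsFactors = FALSE)
  } else {
    tab <- base::table(nucleus_id = table$nucleus_id[assigned],
                       species = table$species[assigned])
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(out) <- c("nucleus_id", "species", "n")
    out <- out[order(out$nucleus_id, out$species), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "unassigned") <- sum(!assigned)
  out
}
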
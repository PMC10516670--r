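#' Load and validate a pipeline configuration
#'
#' The configuration is a single JSON file (or an equivalent R list)
#' naming the inputs and every stage parameter, so that a run is fully
#' reproducible from the config alone:
#' \describe{
#'   \item{image, rois}{input stack (TIFF) and ROI file.}
#'   \item{spacing}{voxel spacing `(z, y, x)` nm.}
#'   \item{channels}{array of `{name, emission_nm}`.}
#'   \item{detection}{per-channel detection parameters
#'     (`min_peak_height`, optional `radius_xy`, `radius_z`, `noise`).}
#'   \item{numerical_aperture}{objective NA for thresholds (default 1.4).}
#'   \item{region}{optional `[x_start, x_end]` of the quantified region for
#'     relative positions.}
#'   \item{coloc_pairs}{optional array of `[query, reference]` species
#'     pairs; each pair's threshold is the resolution limit of the
#'     longer-wavelength channel.}
#'   \item{axis}{optional `{channel, method, value, dilate_z,
#'     foci_channel}` for axis-association scoring.}
#'   \item{zones}{optional `{peak_species, peak_width}` for the
#'     peak-accumulation window.}
#' }
#'
#' @param config Path to a JSON config or a named list.
#' @return The validated config list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  stopifnot(is.list(config))
  for (f in c("image", "rois", "spacing", "channels", "detection")) {
    if (is.null(config[[f]])) stop("config lacks '", f, "'", call. = FALSE)
  }
  config$spacing <- as.numeric(unlist(config$spacing))
  if (length(config$spacing) != 3L || any(config$spacing <= 0)) {
    stop("config spacing must be three positive values", call. = FALSE)
  }
  if (is.null(config$numerical_aperture)) config$numerical_aperture <- 1.4
  if (config$numerical_aperture <= 0) {
    stop("numerical_aperture must be positive", call. = FALSE)
  }
  ch_names <- vapply(config$channels, function(ch) ch$name, character(1))
  referenced <- names(config$detection)
  if (!is.null(config$coloc_pairs)) {
    referenced <- c(referenced,
                    unlist(lapply(config$coloc_pairs, unlist)))
  }
  if (!is.null(config$axis)) {
    referenced <- c(referenced, config$axis$channel, config$axis$foci_channel)
  }
  missing <- setdiff(referenced, ch_names)
  if (length(missing)) {
    stop("config references unknown channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  class(config) <- c("pipeline_config", "list")
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full quantification pipeline
#'
#' Executes detection, nucleus assignment, relative positioning, per-pair
#' colocalization, axis-association scoring and zone detection as
#' configured, writing every stage's output plus a provenance record
#' (parameters, package version, input hashes) into `out_dir`. Identical
#' config and inputs give byte-identical outputs. One structured log line
#' is emitted per stage; any stage failure aborts with the stage name and
#' cause.
#'
#' @param config A [pipeline_config()] (or path / list accepted by it).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf(...))
  results <- list()

  metas <- lapply(config$channels, function(ch)
    channel_meta(ch$name, ch$emission_nm))
  stk <- stage("read_inputs", {
    read_stack(config$image, channels = metas, spacing = config$spacing)
  })
  rois <- stage("read_inputs", read_rois(config$rois))
  log_stage("stage=read_inputs channels=%d nuclei=%d",
            length(metas), length(rois))

  tables <- list()
  for (ch in names(config$detection)) {
    p <- config$detection[[ch]]
    params <- detection_params(
      min_peak_height = p$min_peak_height,
      radius_xy = if (is.null(p$radius_xy)) 1.5 else p$radius_xy,
      radius_z = if (is.null(p$radius_z)) 1.5 else p$radius_z,
      noise = if (is.null(p$noise)) 100 else p$noise)
    tab <- stage("detect", find_maxima_3d(stk, ch, params, mask = rois))
    tab <- stage("assign", resolve_overlaps(assign_foci(tab, rois), rois))
    if (!is.null(config$region)) {
      region <- as.numeric(unlist(config$region))
      tab <- stage("assign",
                   relative_positions(tab, rois, region[1L], region[2L]))
    }
    tables[[ch]] <- tab
    write_detection_table(tab, file.path(out_dir,
                                         paste0("foci_", ch, ".tsv")))
    log_stage("stage=detect channel=%s min_peak=%g foci=%d",
              ch, params$min_peak_height, nrow(tab))
  }
  results$tables <- tables

  combined <- detection_table(do.call(rbind, lapply(tables, as.data.frame)))
  write_detection_table(combined, file.path(out_dir, "table.tsv"))
  counts <- count_foci_per_nucleus(combined)
  utils::write.table(counts, file.path(out_dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  results$counts <- counts
  log_stage("stage=count foci=%d unassigned=%d", nrow(combined),
            attr(counts, "unassigned"))

  if (!is.null(config$coloc_pairs)) {
    emission <- stats::setNames(
      vapply(config$channels, function(ch) as.numeric(ch$emission_nm),
             numeric(1)),
      vapply(config$channels, function(ch) ch$name, character(1)))
    summaries <- list()
    for (pair in config$coloc_pairs) {
      pair <- unlist(pair)
      thr <- resolution_threshold(max(emission[pair]),
                                  config$numerical_aperture)
      recs <- stage("coloc", nearest_neighbor_classify(
        tables[[pair[1L]]], tables[[pair[2L]]], thr))
      rep1 <- coloc_report(recs)
      rep1 <- cbind(data.frame(query = pair[1L], reference = pair[2L],
                               threshold_nm = thr), rep1)
      summaries[[paste(pair, collapse = "_vs_")]] <- rep1
      utils::write.table(
        recs, file.path(out_dir,
                        sprintf("coloc_%s_vs_%s.tsv", pair[1L], pair[2L])),
        sep = "\t", quote = FALSE, row.names = FALSE)
      log_stage("stage=coloc %s_vs_%s threshold=%.1fnm coloc=%d/%d",
                pair[1L], pair[2L], thr, rep1$n_coloc, rep1$n_total)
    }
    summary_df <- do.call(rbind, c(summaries, make.row.names = FALSE))
    utils::write.table(summary_df, file.path(out_dir, "coloc_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$coloc <- summary_df
  }

  if (!is.null(config$axis)) {
    axc <- config$axis
    mask <- stage("axis", build_axis_mask(
      stk, axc$channel,
      method = if (is.null(axc$method)) "otsu" else axc$method,
      value = axc$value))
    dz <- if (is.null(axc$dilate_z)) 1L else axc$dilate_z
    mask <- dilate_z(mask, dz)
    assoc <- stage("axis", axis_association_fraction(
      tables[[axc$foci_channel]], mask))
    assoc$provenance <- mask$provenance
    jsonlite::write_json(assoc, file.path(out_dir, "axis_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$axis <- assoc
    log_stage("stage=axis channel=%s associated=%d/%d",
              axc$channel, assoc$associated, assoc$total)
  }

  if (!is.null(config$zones)) {
    zc <- config$zones
    rois_rowed <- stage("zones", assign_rows(rois))
    rows <- stats::setNames(
      vapply(rois_rowed, `[[`, integer(1), "row_index"), roi_ids(rois_rowed))
    sp <- zc$peak_species
    per_nuc <- stats::setNames(rep(0, length(rows)), names(rows))
    sel <- counts$species == sp
    per_nuc[counts$nucleus_id[sel]] <- counts$n[sel]
    width <- if (is.null(zc$peak_width)) 10L else zc$peak_width
    zone <- stage("zones", peak_window(per_nuc, rows[names(per_nuc)],
                                       width_rows = width))
    zone_out <- list(start_row = zone$start_row, end_row = zone$end_row,
                     length_rows = zone$length_rows, rule = zone$rule,
                     median_count = attr(zone, "median_count"))
    jsonlite::write_json(zone_out, file.path(out_dir, "zones.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$zones <- zone
    log_stage("stage=zones rule=peak rows=%d-%d median=%g",
              zone$start_row, zone$end_row, attr(zone, "median_count"))
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("gonadfoci")),
    config = unclass(config),
    input_md5 = list(image = unname(tools::md5sum(config$image)),
                     rois = unname(tools::md5sum(config$rois))))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("stage=done out_dir=%s", out_dir)
  invisible(results)
}

#' Write a simulated scene to disk
#'
#' Convenience wrapper around [generate_scene()] that writes the rendered
#' stack (`image.tif`), the ROI set (`rois.json`) and the ground-truth
#' focus list (`truth.tsv`) into a directory, the on-disk starting point
#' for a pipeline run on synthetic data.
#'
#' @param spec A [scene_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, the [generate_scene()] result.
#' @export
simulate_to_dir <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scene <- generate_scene(spec)
  write_stack(scene$stack, file.path(out_dir, "image.tif"))
  write_rois(scene$rois, file.path(out_dir, "rois.json"))
  utils::write.table(scene$truth$foci, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(scene)
}
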
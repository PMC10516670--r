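DETECTION_COLUMNS <- c("focus_id", "species", "z_vox", "y_vox", "x_vox",
                       "z_nm", "y_nm", "x_nm", "peak_height", "nucleus_id",
                       "rel_position_pct")

#' Detection table of called foci
#'
#' A data frame of focus records with one row per called focus and the
#' fixed column set `focus_id, species, z_vox, y_vox, x_vox, z_nm, y_nm,
#' x_nm, peak_height, nucleus_id, rel_position_pct`. Voxel indices are
#' 0-based; physical coordinates are nm under the voxel-center convention.
#' `nucleus_id` and `rel_position_pct` are `NA` until assignment. A
#' `provenance` attribute (named list) records the source image and
#' detection parameters.
#'
#' @param df Data frame holding at least `focus_id`, `species`, the voxel
#'   coordinates and `peak_height`; missing optional columns are added as
#'   `NA`.
#' @param provenance Named list of provenance fields.
#' @return A `detection_table` (a data frame).
#' @export
detection_table <- function(df = NULL, provenance = list()) {
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(focus_id = character(), species = character(),
                     z_vox = numeric(), y_vox = numeric(), x_vox = numeric(),
                     z_nm = numeric(), y_nm = numeric(), x_nm = numeric(),
                     peak_height = numeric(), nucleus_id = character(),
                     rel_position_pct = numeric(),
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    for (col in c("nucleus_id", "rel_position_pct")) {
      if (is.null(df[[col]])) {
        df[[col]] <- if (col == "nucleus_id") NA_character_ else NA_real_
      }
    }
    missing <- setdiff(DETECTION_COLUMNS, names(df))
    if (length(missing)) {
      stop("detection table lacks column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    df <- df[DETECTION_COLUMNS]
    df$focus_id <- as.character(df$focus_id)
    df$nucleus_id <- as.character(df$nucleus_id)
  }
  if (anyDuplicated(df$focus_id)) {
    stop("duplicate focus ids in detection table", call. = FALSE)
  }
  structure(df, class = c("detection_table", "data.frame"),
            provenance = provenance)
}

#' Write / read a detection table as TSV
#'
#' Tab-delimited UTF-8 text with one header row, `.` as decimal separator
#' and the fixed column order of [detection_table()]. Numeric fields are
#' written with 17 significant digits so the round trip is lossless at full
#' double precision; `NA` fields are written as empty strings.
#'
#' @param table A [detection_table()].
#' @param path File path.
#' @return `write_detection_table()` returns `path` invisibly;
#'   `read_detection_table()` returns a [detection_table()].
#' @export
write_detection_table <- function(table, path) {
  df <- as.data.frame(table)
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(df[[col]]), "",
                           sprintf("%.17g", df[[col]]))
    } else {
      out[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_detection_table
#' @export
read_detection_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c(focus_id = "character",
                                         species = "character",
                                         z_vox = "numeric", y_vox = "numeric",
                                         x_vox = "numeric", z_nm = "numeric",
                                         y_nm = "numeric", x_nm = "numeric",
                                         peak_height = "numeric",
                                         nucleus_id = "character",
                                         rel_position_pct = "numeric"),
                          na.strings = "", encoding = "UTF-8")
  if (!identical(names(df), DETECTION_COLUMNS)) {
    stop("malformed detection TSV (unexpected columns): ", path, call. = FALSE)
  }
  detection_table(df)
}
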
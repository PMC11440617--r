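#' Read and write soma-field CSV files
#'
#' The on-disk format is a plain CSV with header columns `id`, `x_um`,
#' `y_um`, and optional `diameter_um` (default 10) and `labels`
#' (semicolon-joined tags). Coordinates are micrometres. `save_soma_csv`
#' followed by `load_soma_csv` reproduces the field exactly.
#'
#' @param path File path.
#' @param window A [field_window()] the points are validated against.
#' @return `load_soma_csv`: a [soma_field()]. `save_soma_csv`: `path`,
#'   invisibly.
#' @export
load_soma_csv <- function(path, window) {
  stopifnot(inherits(window, "field_window"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  need <- c("id", "x_um", "y_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("x_um", "y_um")) {
    v <- df[[col]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-numeric %s at data row %s", path, col,
                   paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
    df[[col]] <- as.numeric(v)
  }
  bad <- which(!in_window(df$x_um, df$y_um, window))
  if (length(bad) > 0) {
    stop(sprintf("%s: points outside window at data row %s", path,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  soma_field(df$x_um, df$y_um, window,
             diameter_um = if ("diameter_um" %in% names(df))
               as.numeric(df$diameter_um) else 10,
             id = df$id,
             labels = if ("labels" %in% names(df)) {
               ifelse(is.na(df$labels), "", as.character(df$labels))
             } else "")
}

#' @rdname load_soma_csv
#' @param field A [soma_field()] to write.
#' @export
save_soma_csv <- function(field, path) {
  stopifnot(inherits(field, "soma_field"))
  utils::write.csv(field$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse a soma's label tags
#'
#' @param labels Character vector of semicolon-joined tag strings.
#' @return List of character vectors (tag sets).
#' @export
parse_labels <- function(labels) {
  lapply(strsplit(labels, ";", fixed = TRUE),
         function(s) s[nzchar(s)])
}

#' Read and write arbor polygons as JSON
#'
#' JSON array of objects `{"reference_id": ..., "source_field_id": ...,
#' "vertices_um": [[x, y], ...]}`. Polygons are validated on load (simple,
#' >= 3 vertices, positive area); a self-intersecting polygon is rejected
#' with an error naming its reference id.
#'
#' @param path File path.
#' @return `load_polygons_json`: list of [arbor_territory()].
#' @export
load_polygons_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  lapply(raw, function(rec) {
    v <- do.call(rbind, lapply(rec$vertices_um, as.numeric))
    tryCatch(
      arbor_territory(rec$reference_id, v,
                      source_field_id = rec$source_field_id %||% NA),
      error = function(e) {
        stop(sprintf("invalid polygon for reference_id '%s': %s",
                     rec$reference_id, conditionMessage(e)), call. = FALSE)
      })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_polygons_json
#' @param arbors List of [arbor_territory()] to write.
#' @export
save_polygons_json <- function(arbors, path) {
  recs <- lapply(arbors, function(a) {
    list(reference_id = a$reference_id,
         source_field_id = if (is.na(a$source_field_id)) NULL else
           a$source_field_id,
         vertices_um = apply(a$vertices, 1, as.numeric, simplify = FALSE))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a DRP result as a tidy per-bin TSV
#'
#' Columns: `bin_mid_um`, `count`, `corrected_area_um2`,
#' `density_cells_per_mm2`.
#'
#' @param drp A `drp_result`.
#' @param path Output path.
#' @export
save_drp_tsv <- function(drp, path) {
  stopifnot(inherits(drp, "drp_result"))
  df <- data.frame(bin_mid_um = drp$bin_mid_um, count = drp$counts,
                   corrected_area_um2 = drp$corrected_area_um2,
                   density_cells_per_mm2 = drp$density_mm2)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
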
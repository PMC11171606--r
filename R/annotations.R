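#' Cell point annotations
#'
#' An annotation set is a plain `data.frame` with one row per cell and
#' columns `x_um`, `y_um` (coordinates in microns, origin at the tile's
#' top-left corner, x rightward, y downward) and `label`, one of `"t"`
#' (tumor), `"n"` (non-tumor) or `"i"` (indistinguishable). The pixel at
#' row r, column c (1-based) has its center at
#' `((c - 0.5) * mpp, (r - 0.5) * mpp)`.
#'
#' @param x_um,y_um Numeric coordinates in microns.
#' @param label Character vector of cell class codes (`"t"`, `"n"`, `"i"`).
#' @return A `data.frame` with columns `x_um`, `y_um`, `label`.
#' @export
annotation_set <- function(x_um = numeric(), y_um = numeric(),
                           label = character()) {
  stopifnot(length(x_um) == length(y_um), length(label) == length(x_um))
  if (length(x_um) && (!all(is.finite(x_um)) || !all(is.finite(y_um))))
    stop("annotation coordinates must be finite")
  label <- as.character(label)
  bad <- setdiff(unique(label), c("t", "n", "i"))
  if (length(bad))
    stop("unknown cell labels: ", paste(bad, collapse = ", "))
  data.frame(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
             label = label, stringsAsFactors = FALSE)
}

#' Read / write annotation CSV files
#'
#' The on-disk format is a CSV with columns `x_um,y_um,label`
#' (label in t/n/i). Gold-standard files add a column `n_annotators`.
#'
#' @param path File path.
#' @return `read_annotations()` returns an annotation `data.frame`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("x_um", "y_um", "label")
  if (!all(req %in% names(df)))
    stop("annotation CSV must have columns x_um,y_um,label: ", path)
  out <- annotation_set(df$x_um, df$y_um, df$label)
  if ("n_annotators" %in% names(df)) out$n_annotators <- df$n_annotators
  out
}

#' @param ann Annotation `data.frame`.
#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(ann, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export annotations as GeoJSON points
#'
#' Each cell becomes a GeoJSON `Point` feature (coordinates in microns)
#' with a `label` property.
#'
#' @param ann Annotation `data.frame`.
#' @param path Optional output path; if `NULL` the GeoJSON string is
#'   returned instead.
#' @export
annotations_to_geojson <- function(ann, path = NULL) {
  features <- lapply(seq_len(nrow(ann)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(ann$x_um[i], ann$y_um[i])),
         properties = list(label = ann$label[i]))
  })
  gj <- list(type = "FeatureCollection", features = features)
  txt <- jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
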
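#' Tissue-class raster with physical pixel size
#'
#' A `tissue_map` is the spatial substrate of the analysis: a single-channel
#' integer raster in which every pixel carries a tissue class label, plus the
#' physical side length of a pixel in micrometers. The label vocabulary is
#' fixed: 0 = background (glass, necrosis, artifacts), 1 = tumor epithelium,
#' 2 = stroma, 3 = lymphoid follicle.
#'
#' The coordinate convention used throughout the package: origin at the
#' raster top-left corner, x increases rightward (columns), y increases
#' downward (rows), all geometry in micrometers. The center of pixel
#' `(row i, col j)` sits at `x = (j - 0.5) * pixel_size_um`,
#' `y = (i - 0.5) * pixel_size_um`.
#'
#' @param labels integer matrix of tissue class labels, values in 0:3.
#' @param pixel_size_um positive scalar, micrometers per pixel side.
#' @return An object of class `tissue_map`: a list with elements `labels`
#'   (integer matrix) and `pixel_size_um`.
#' @examples
#' tm <- tissue_map(matrix(c(1, 1, 2, 2), 2, 2), pixel_size_um = 10)
#' tissue_areas_mm2(tm)
#' @export
tissue_map <- function(labels, pixel_size_um) {
  if (!is.matrix(labels) || length(labels) == 0L)
    stop("`labels` must be a non-empty matrix", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive scalar", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L | labels > 3L))
    stop("tissue labels must all be in {0, 1, 2, 3}", call. = FALSE)
  structure(list(labels = labels, pixel_size_um = as.numeric(pixel_size_um)),
            class = "tissue_map")
}

#' @export
print.tissue_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<tissue_map> %d x %d px @ %.3g um/px (%.3g x %.3g mm)\n",
              d[1], d[2], x$pixel_size_um,
              d[2] * x$pixel_size_um / 1000, d[1] * x$pixel_size_um / 1000))
  a <- tissue_areas_mm2(x)
  cat(sprintf("  areas (mm^2): background %.3f | tumor %.3f | stroma %.3f | follicle %.3f\n",
              a[["background"]], a[["tumor"]], a[["stroma"]], a[["follicle"]]))
  invisible(x)
}

#' Per-class tissue areas of a raster
#'
#' @param tm a [tissue_map()].
#' @return Named numeric vector of class areas in mm^2
#'   (`background`, `tumor`, `stroma`, `follicle`).
#' @export
tissue_areas_mm2 <- function(tm) {
  stopifnot(inherits(tm, "tissue_map"))
  px_mm2 <- (tm$pixel_size_um / 1000)^2
  counts <- tabulate(tm$labels + 1L, nbins = 4L)
  stats::setNames(counts * px_mm2,
                  c("background", "tumor", "stroma", "follicle"))
}

.TISSUE_CLASSES <- c(background = 0L, tumor = 1L, stroma = 2L, follicle = 3L)
.MARKERS <- c("CD8", "CD20", "CD68")

#' Read a tissue map from a label image plus JSON sidecar
#'
#' Reads a single-channel 8-bit PNG (or TIFF, if the `tiff` package is
#' available) whose pixel values are tissue class labels, together with a
#' JSON sidecar of the form
#' `{"pixel_size_um": 2.0, "label_map": {"background": 0, "tumor": 1, "stroma": 2, "follicle": 3}}`.
#' Label values in the image are remapped through `label_map` onto the
#' package's fixed vocabulary.
#'
#' @param image_path path to the PNG/TIFF label image.
#' @param sidecar_path path to the JSON sidecar; defaults to
#'   `<image_path>.json`.
#' @return A [tissue_map()].
#' @export
read_tissue_map <- function(image_path, sidecar_path = paste0(image_path, ".json")) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_um))
    stop("sidecar is missing `pixel_size_um`", call. = FALSE)
  ext <- tolower(tools::file_ext(image_path))
  raw <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the `tiff` package", call. = FALSE)
    tiff::readTIFF(image_path)
  } else {
    png::readPNG(image_path)
  }
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  labels <- matrix(as.integer(round(raw * 255)), nrow(raw), ncol(raw))
  if (!is.null(meta$label_map)) {
    lm <- unlist(meta$label_map)
    remap <- labels
    for (nm in names(lm)) {
      target <- .TISSUE_CLASSES[[tolower(nm)]]
      if (is.null(target)) stop("unknown tissue class in label_map: ", nm, call. = FALSE)
      remap[labels == lm[[nm]]] <- target
    }
    labels <- remap
  }
  tissue_map(labels, meta$pixel_size_um)
}

#' Write a tissue map to a PNG label image plus JSON sidecar
#'
#' @param tm a [tissue_map()].
#' @param image_path output PNG path.
#' @param sidecar_path output JSON path; defaults to `<image_path>.json`.
#' @return `image_path`, invisibly.
#' @export
write_tissue_map <- function(tm, image_path, sidecar_path = paste0(image_path, ".json")) {
  stopifnot(inherits(tm, "tissue_map"))
  png::writePNG(tm$labels / 255, image_path)
  jsonlite::write_json(
    list(pixel_size_um = tm$pixel_size_um,
         label_map = as.list(.TISSUE_CLASSES)),
    sidecar_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(image_path)
}

#' Construct or read a marker-cell coordinate table
#'
#' A cell table holds one row per detected immune cell: the marker (one of
#' CD8, CD20, CD68) and the cell centroid in micrometers, in the same
#' coordinate frame as the tissue raster. Coordinates may fall outside the
#' raster; such cells are dropped (with a recorded count) when assigned to a
#' hexagon grid.
#'
#' @param marker character vector of marker names (case-insensitive).
#' @param x_um,y_um numeric coordinates in micrometers.
#' @return A `data.frame` with columns `marker`, `x_um`, `y_um` and class
#'   `cell_table`.
#' @export
cell_table <- function(marker, x_um, y_um) {
  marker <- toupper(as.character(marker))
  bad <- which(!marker %in% .MARKERS)
  if (length(bad))
    stop(sprintf("unknown marker(s) %s at row(s) %s; expected one of %s",
                 paste(unique(marker[bad]), collapse = ", "),
                 paste(utils::head(bad, 10L), collapse = ", "),
                 paste(.MARKERS, collapse = ", ")), call. = FALSE)
  x_um <- as.numeric(x_um); y_um <- as.numeric(y_um)
  if (length(x_um) != length(marker) || length(y_um) != length(marker))
    stop("marker, x_um and y_um must have equal length", call. = FALSE)
  if (length(x_um) && (!all(is.finite(x_um)) || !all(is.finite(y_um))))
    stop("cell coordinates must be finite", call. = FALSE)
  structure(data.frame(marker = marker, x_um = x_um, y_um = y_um),
            class = c("cell_table", "data.frame"))
}

#' Read a cell table from CSV
#'
#' Expects the header `case_id,marker,x_um,y_um` (the `case_id` column is
#' optional and ignored for single-case use).
#'
#' @param path CSV path.
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("cell table CSV must have columns marker, x_um, y_um", call. = FALSE)
  cell_table(df$marker, df$x_um, df$y_um)
}
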
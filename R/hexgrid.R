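#' Build a hexagonal sampling grid over a tissue raster
#'
#' Tiles the raster with a regular hexagon lattice and records one row per
#' hexagon that covers at least one pixel center. Pixel membership follows
#' the pixel-center rule: a pixel belongs to the hexagon containing its
#' center, so the hexagons partition the raster exactly and per-class areas
#' are conserved in pixel units.
#'
#' @param tm a [tissue_map()].
#' @param hex_side_um hexagon side length (circumradius) in micrometers;
#'   must be at least `2 * pixel_size_um`. Default 65.
#' @param orientation `"pointy"` (default) or `"flat"` hexagon orientation.
#' @param compute_areas fill per-class areas immediately (default `TRUE`);
#'   with `FALSE` the area columns are `NA` until
#'   [compute_area_fractions()] is called.
#' @return A `hex_grid`: a `data.frame` with one row per hexagon and columns
#'   `q, r, center_x_um, center_y_um, area_tumor_mm2, area_stroma_mm2,
#'   area_follicle_mm2, area_background_mm2, n_cd8, n_cd20, n_cd68` (cell
#'   counts are zero until [assign_cells()]), plus per-marker counts of
#'   cells on tumor-class pixels used for intratumoral densities. The
#'   source raster and the per-pixel hexagon index are kept in attributes.
#' @seealso [compute_area_fractions()], [assign_cells()], [classify_hexagons()]
#' @export
build_hex_grid <- function(tm, hex_side_um = 65,
                           orientation = c("pointy", "flat"),
                           compute_areas = TRUE) {
  stopifnot(inherits(tm, "tissue_map"))
  orientation <- match.arg(orientation)
  if (length(tm$labels) == 0L)
    stop("empty raster: cannot build a hexagon grid", call. = FALSE)
  if (hex_side_um < 2 * tm$pixel_size_um)
    stop(sprintf(paste0("invalid resolution: hex_side_um (%.3g) must be >= ",
                        "2 * pixel_size_um (%.3g)"),
                 hex_side_um, 2 * tm$pixel_size_um), call. = FALSE)

  px <- tm$pixel_size_um
  nr <- nrow(tm$labels); nc <- ncol(tm$labels)
  # pixel centers, column-major to match matrix storage order
  xs <- (seq_len(nc) - 0.5) * px
  ys <- (seq_len(nr) - 0.5) * px
  pix_x <- rep(xs, each = nr)
  pix_y <- rep(ys, times = nc)
  ax <- hex_xy_to_axial(pix_x, pix_y, hex_side_um, orientation)

  key <- .hex_key(ax$q, ax$r)
  ukey <- unique(key)
  hex_index <- match(key, ukey)            # per-pixel hexagon row index
  first <- match(ukey, key)
  q <- ax$q[first]; r <- ax$r[first]
  ord <- order(r, q)
  q <- q[ord]; r <- r[ord]
  # re-map per-pixel indices to the sorted row order
  hex_index <- order(ord)[hex_index]

  cen <- hex_axial_to_xy(q, r, hex_side_um, orientation)
  n <- length(q)
  grid <- data.frame(
    q = q, r = r, center_x_um = cen$x, center_y_um = cen$y,
    area_tumor_mm2 = NA_real_, area_stroma_mm2 = NA_real_,
    area_follicle_mm2 = NA_real_, area_background_mm2 = NA_real_,
    n_cd8 = 0L, n_cd20 = 0L, n_cd68 = 0L,
    n_cd8_tumor = 0L, n_cd20_tumor = 0L, n_cd68_tumor = 0L)
  attr(grid, "hex_side_um") <- hex_side_um
  attr(grid, "orientation") <- orientation
  attr(grid, "tissue_map") <- tm
  attr(grid, "pixel_hex_index") <- hex_index
  attr(grid, "cells_assigned") <- FALSE
  class(grid) <- c("hex_grid", "data.frame")
  if (compute_areas) grid <- compute_area_fractions(grid, tm) else grid
}

#' Fill per-hexagon tissue-class areas by pixel counting
#'
#' For every hexagon, sums the area of its member pixels per tissue class.
#' Because each pixel belongs to exactly one hexagon, the per-class totals
#' over all hexagons equal the raster class areas exactly (in pixel units).
#' The analyzed-tissue area of a hexagon is its tumor + stroma area;
#' follicle and background are tracked but excluded from density
#' denominators.
#'
#' @param grid a `hex_grid` built over `tm` by [build_hex_grid()].
#' @param tm the same [tissue_map()] the grid was built over.
#' @return The grid with the four `area_*_mm2` columns filled.
#' @export
compute_area_fractions <- function(grid, tm) {
  stopifnot(inherits(grid, "hex_grid"), inherits(tm, "tissue_map"))
  src <- attr(grid, "tissue_map")
  if (!identical(dim(src$labels), dim(tm$labels)) ||
      src$pixel_size_um != tm$pixel_size_um)
    stop("geometry error: grid was built over a different raster", call. = FALSE)
  hex_index <- attr(grid, "pixel_hex_index")
  px_mm2 <- (tm$pixel_size_um / 1000)^2
  lab <- as.integer(tm$labels)
  n <- nrow(grid)
  cnt <- function(class_id)
    tabulate(hex_index[lab == class_id], nbins = n) * px_mm2
  grid$area_background_mm2 <- cnt(0L)
  grid$area_tumor_mm2 <- cnt(1L)
  grid$area_stroma_mm2 <- cnt(2L)
  grid$area_follicle_mm2 <- cnt(3L)
  grid
}

#' Assign marker cells to hexagons
#'
#' Each in-bounds cell is assigned to exactly one hexagon (the hexagon
#' containing its coordinates; boundary ties broken by nearest center, then
#' lowest `(q, r)`). Out-of-raster cells are dropped with a recorded count.
#' Cells lying on lymphoid-follicle pixels are excluded by default, since
#' follicles are segmented as a separate class precisely to keep lymphoid
#' aggregates out of microenvironment density estimates.
#'
#' @param grid a `hex_grid` with areas computed.
#' @param cells a [cell_table()].
#' @param exclude_follicle drop cells on follicle-class pixels
#'   (default `TRUE`).
#' @return The grid with per-marker counts filled (`n_cd8`, `n_cd20`,
#'   `n_cd68`, and the tumor-pixel-restricted `n_*_tumor` used for
#'   intratumoral densities). Dropped-cell counts are recorded in the
#'   attributes `n_dropped_out_of_bounds` and `n_dropped_follicle`.
#' @export
assign_cells <- function(grid, cells, exclude_follicle = TRUE) {
  stopifnot(inherits(grid, "hex_grid"))
  if (!inherits(cells, "cell_table"))
    cells <- cell_table(cells$marker, cells$x_um, cells$y_um)
  tm <- attr(grid, "tissue_map")
  px <- tm$pixel_size_um
  w <- ncol(tm$labels) * px
  h <- nrow(tm$labels) * px

  inb <- cells$x_um >= 0 & cells$x_um < w & cells$y_um >= 0 & cells$y_um < h
  n_oob <- sum(!inb)
  if (n_oob > 0)
    message(sprintf("assign_cells: dropped %d cell(s) outside the raster", n_oob))
  cells <- cells[inb, , drop = FALSE]

  # tissue class of the pixel under each cell
  ci <- pmin(pmax(floor(cells$y_um / px) + 1, 1), nrow(tm$labels))
  cj <- pmin(pmax(floor(cells$x_um / px) + 1, 1), ncol(tm$labels))
  cell_lab <- tm$labels[cbind(ci, cj)]
  n_fol <- 0L
  if (exclude_follicle) {
    fol <- cell_lab == 3L
    n_fol <- sum(fol)
    cells <- cells[!fol, , drop = FALSE]
    cell_lab <- cell_lab[!fol]
    ci <- ci[!fol]; cj <- cj[!fol]
  }

  side <- attr(grid, "hex_side_um")
  ax <- hex_xy_to_axial(cells$x_um, cells$y_um, side, attr(grid, "orientation"))
  row <- match(.hex_key(ax$q, ax$r), .hex_key(grid$q, grid$r))
  # a cell can land in a boundary hexagon sliver holding no pixel centers;
  # fall back to the hexagon of the cell's own pixel, which is always in
  # the grid
  miss <- is.na(row)
  if (any(miss)) {
    hex_index <- attr(grid, "pixel_hex_index")
    nrm <- nrow(tm$labels)
    row[miss] <- hex_index[(cj[miss] - 1L) * nrm + ci[miss]]
  }

  n <- nrow(grid)
  for (m in .MARKERS) {
    sel <- cells$marker == m
    col <- paste0("n_", tolower(m))
    grid[[col]] <- tabulate(row[sel], nbins = n)
    grid[[paste0(col, "_tumor")]] <- tabulate(row[sel & cell_lab == 1L], nbins = n)
  }
  stopifnot(sum(grid$n_cd8, grid$n_cd20, grid$n_cd68) == nrow(cells))
  attr(grid, "n_dropped_out_of_bounds") <- n_oob
  attr(grid, "n_dropped_follicle") <- n_fol
  attr(grid, "cells_assigned") <- TRUE
  grid
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> %d hexagons, side %.3g um (%s-top)\n",
              nrow(x), attr(x, "hex_side_um"), attr(x, "orientation")))
  if (!anyNA(x$area_tumor_mm2))
    cat(sprintf("  tumor %.3f mm^2 | stroma %.3f mm^2 | cells: CD8 %d, CD20 %d, CD68 %d\n",
                sum(x$area_tumor_mm2), sum(x$area_stroma_mm2),
                sum(x$n_cd8), sum(x$n_cd20), sum(x$n_cd68)))
  if (!is.null(x$rank))
    cat(sprintf("  ranked: TE hexagons %d, rank range [%d, %d]\n",
                sum(x$is_te), min(x$rank, na.rm = TRUE), max(x$rank, na.rm = TRUE)))
  invisible(x)
}

#' Export a hexagon grid to CSV
#'
#' Writes the documented grid dialect: `q,r,center_x_um,center_y_um,
#' area_tumor_mm2,area_stroma_mm2,area_follicle_mm2,area_background_mm2,
#' n_cd8,n_cd20,n_cd68`, extended with `base_class,rank,is_te,aspect`
#' when the grid has been ranked.
#'
#' @param grid a `hex_grid`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hex_grid <- function(grid, path) {
  cols <- c("q", "r", "center_x_um", "center_y_um",
            "area_tumor_mm2", "area_stroma_mm2", "area_follicle_mm2",
            "area_background_mm2", "n_cd8", "n_cd20", "n_cd68")
  extra <- intersect(c("base_class", "rank", "is_te", "aspect"), names(grid))
  utils::write.csv(as.data.frame(grid)[, c(cols, extra)], path, row.names = FALSE)
  invisible(path)
}
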
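#' Fit the Immunogradient indicators for one case
#'
#' The main per-case entry point. Builds the hexagonal sampling grid over
#' the tissue raster, aggregates per-class areas and marker cell counts,
#' applies tissue-area quality control, detects the tumor edge, assigns
#' signed ranks, extracts the interface zone, and computes the full
#' indicator set: per marker, the Center of Mass of the density gradient
#' across the interface zone, the mean densities in the stroma (S), tumor
#' edge (TE) and tumor (T) aspects, and the intratumoral density.
#'
#' @param tm a [tissue_map()] (or a path readable by [read_tissue_map()]).
#' @param cells a [cell_table()] (or a CSV path for [read_cell_table()]).
#' @param hex_side_um hexagon side length in micrometers (default 65).
#' @param orientation hexagon orientation, `"pointy"` or `"flat"`.
#' @param iz_width interface-zone width in ranks (odd; default 3, the IZ3).
#' @param theta mixed-content threshold for edge-candidate hexagons.
#' @param background_threshold analyzed-tissue fraction below which a
#'   hexagon is background.
#' @param exclude_follicle drop cells on lymphoid-follicle pixels.
#' @param min_area_mm2 per-hexagon analyzed-tissue area filter for density
#'   estimates.
#' @param min_tumor_area_mm2 QC threshold on total tumor area (default 4.5).
#' @param stat rank statistic: `"mean"` of per-hexagon densities (default)
#'   or `"pooled"` count-over-area.
#' @return An object of class `immunogradient` with components
#'   `grid` (the ranked hexagon grid), `iz` (the interface zone, or `NULL`
#'   when the case has no tumor-stroma interface), `profiles` (per-marker
#'   [gradient_profile()]s), `indicators` (one-row data frame of the 15
#'   indicators plus flags), `qc` (see [qc_case()]) and `params`.
#' @examples
#' sim <- simulate_tissue_map(width_px = 160, height_px = 160,
#'                            pixel_size_um = 4, seed = 1)
#' cells <- simulate_cells(sim, seed = 2)
#' fit <- immunogradient(sim$tissue_map, cells$cells, hex_side_um = 40)
#' coef(fit)["CD8_CM"]
#' @export
immunogradient <- function(tm, cells = NULL,
                           hex_side_um = 65,
                           orientation = c("pointy", "flat"),
                           iz_width = 3L,
                           theta = 0.1,
                           background_threshold = 0.05,
                           exclude_follicle = TRUE,
                           min_area_mm2 = 1e-3,
                           min_tumor_area_mm2 = 4.5,
                           stat = c("mean", "pooled")) {
  orientation <- match.arg(orientation)
  stat <- match.arg(stat)
  if (is.character(tm)) tm <- read_tissue_map(tm)
  if (is.character(cells)) cells <- read_cell_table(cells)
  if (is.null(cells)) cells <- cell_table(character(0), numeric(0), numeric(0))

  grid <- build_hex_grid(tm, hex_side_um = hex_side_um, orientation = orientation)
  grid <- assign_cells(grid, cells, exclude_follicle = exclude_follicle)
  qc <- qc_case(grid, min_tumor_area_mm2 = min_tumor_area_mm2)

  flags <- character(0)
  iz <- NULL
  profiles <- list()
  ranked <- tryCatch({
    g <- classify_hexagons(grid, theta = theta,
                           background_threshold = background_threshold)
    g <- detect_tumor_edge(g)
    rank_hexagons(g)
  }, no_interface_error = function(e) {
    flags <<- c(flags, paste0("no-interface: ", conditionMessage(e)))
    NULL
  })
  if (!is.null(ranked)) {
    grid <- ranked
    iz <- extract_interface_zone(ranked, iz_width)
    for (m in .MARKERS)
      profiles[[m]] <- gradient_profile(iz, m, min_area_mm2 = min_area_mm2,
                                        stat = stat)
  }
  indicators <- compute_indicator_set(grid, iz_width = iz_width, theta = theta,
                                      background_threshold = background_threshold,
                                      min_area_mm2 = min_area_mm2, stat = stat)
  if (length(flags))
    indicators$flags <- paste(unique(c(flags,
      Filter(nzchar, indicators$flags))), collapse = "; ")

  structure(list(grid = grid, iz = iz, profiles = profiles,
                 indicators = indicators, qc = qc,
                 params = list(hex_side_um = hex_side_um,
                               orientation = orientation,
                               iz_width = as.integer(iz_width),
                               theta = theta,
                               background_threshold = background_threshold,
                               exclude_follicle = exclude_follicle,
                               min_area_mm2 = min_area_mm2,
                               min_tumor_area_mm2 = min_tumor_area_mm2,
                               stat = stat),
                 call = match.call()),
            class = "immunogradient")
}

#' @export
print.immunogradient <- function(x, ...) {
  cat("Immunogradient case fit\n")
  cat(sprintf("  grid: %d hexagons (side %.3g um), tumor %.2f mm^2, QC %s\n",
              nrow(x$grid), x$params$hex_side_um,
              x$qc$tumor_area_mm2, if (x$qc$pass) "pass" else "FAIL"))
  if (is.null(x$iz)) {
    cat("  no tumor-stroma interface detected\n")
  } else {
    cat(sprintf("  IZ width %d: %d hexagons (S %d | TE %d | T %d)\n",
                attr(x$iz, "width"), nrow(x$iz),
                sum(x$iz$aspect == "S"), sum(x$iz$aspect == "TE"),
                sum(x$iz$aspect == "T")))
  }
  cm <- coef(x)[paste0(.MARKERS, "_CM")]
  cat("  Center of Mass: ",
      paste(sprintf("%s %.3f", .MARKERS, cm), collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.immunogradient <- function(object, ...) {
  ind <- object$indicators
  stats::setNames(as.numeric(ind[1, setdiff(names(ind), "flags")]),
                  setdiff(names(ind), "flags"))
}

#' @export
summary.immunogradient <- function(object, ...) {
  structure(list(fit = object), class = "summary.immunogradient")
}

#' @export
print.summary.immunogradient <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nIndicators (cells/mm^2 unless CM, dimensionless):\n")
  ind <- fit$indicators
  for (m in .MARKERS) {
    cat(sprintf("  %-5s CM %7.3f | d_S %8.2f | d_TE %8.2f | d_T %8.2f | INT %8.2f\n",
                m, ind[[paste0(m, "_CM")]], ind[[paste0(m, "_d_S")]],
                ind[[paste0(m, "_d_TE")]], ind[[paste0(m, "_d_T")]],
                ind[[paste0("INT_", m)]]))
  }
  if (nzchar(ind$flags)) cat("  flags:", ind$flags, "\n")
  invisible(x)
}

#' Plot an Immunogradient case fit
#'
#' `which = "map"` draws the hexagon grid with the interface-zone aspect
#' coloring used throughout the package (tumor edge yellow, tumor aspect
#' red, stroma aspect green, remaining tumor/stroma muted). `which =
#' "profile"` plots the per-rank density profile of one marker across the
#' interface zone.
#'
#' @param x an `immunogradient` fit.
#' @param which `"map"` or `"profile"`.
#' @param marker marker for the profile plot.
#' @param ... passed to the underlying plot.
#' @return `x`, invisibly.
#' @export
plot.immunogradient <- function(x, which = c("map", "profile"),
                                marker = "CD8", ...) {
  which <- match.arg(which)
  if (which == "profile") {
    prof <- x$profiles[[toupper(marker)]]
    if (is.null(prof)) {
      warning("no interface zone: nothing to plot")
      return(invisible(x))
    }
    graphics::plot(prof$rank, prof$q, type = "b", pch = 19,
                   xlab = "rank (stroma < 0 < tumor)",
                   ylab = sprintf("%s density (cells/mm^2)", toupper(marker)),
                   main = sprintf("%s gradient across IZ", toupper(marker)), ...)
    graphics::abline(v = 0, lty = 3)
    return(invisible(x))
  }
  g <- x$grid
  side <- attr(g, "hex_side_um")
  orientation <- attr(g, "orientation")
  col <- rep("grey90", nrow(g))
  if (!is.null(g$base_class)) {
    col[g$base_class == "tumor"] <- "rosybrown2"
    col[g$base_class == "stroma"] <- "darkseagreen1"
  }
  if (!is.null(g$rank)) {
    col[!is.na(g$rank) & g$rank == 1] <- "red"
    col[!is.na(g$rank) & g$rank == -1] <- "green3"
    col[g$is_te] <- "yellow"
  }
  graphics::plot(NA, xlim = range(g$center_x_um) + c(-side, side),
                 ylim = rev(range(g$center_y_um) + c(-side, side)),
                 asp = 1, xlab = "x (um)", ylab = "y (um)",
                 main = "Interface zone (TE yellow, T red, S green)", ...)
  for (i in seq_len(nrow(g))) {
    v <- hex_vertices(g$q[i], g$r[i], side, orientation)
    graphics::polygon(v[, "x"], v[, "y"], col = col[i], border = "grey50",
                      lwd = 0.3)
  }
  invisible(x)
}
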
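#' Classify hexagons as tumor, stroma, edge candidate or background
#'
#' Classification is by area fractions inside each hexagon. A hexagon whose
#' analyzed-tissue (tumor + stroma) fraction of its covered area falls below
#' `background_threshold` is background. Otherwise, if both the tumor and
#' the stroma fraction of the analyzed tissue reach the mixed-content
#' threshold `theta`, the hexagon is an edge candidate; else it takes the
#' majority class of its analyzed tissue.
#'
#' @param grid a `hex_grid` with areas computed.
#' @param theta mixed-content threshold on the tumor and stroma fractions of
#'   analyzed tissue, `0 < theta <= 0.5`. Default 0.1.
#' @param background_threshold minimum analyzed-tissue fraction of the
#'   hexagon's covered area for a hexagon to count as tissue. Default 0.05.
#' @return The grid with a `base_class` column
#'   (`"tumor"`, `"stroma"`, `"edge"`, `"background"`).
#' @export
classify_hexagons <- function(grid, theta = 0.1, background_threshold = 0.05) {
  stopifnot(inherits(grid, "hex_grid"))
  if (anyNA(grid$area_tumor_mm2))
    stop("area fractions must be computed before classification", call. = FALSE)
  if (!(theta > 0 && theta <= 0.5))
    stop("`theta` must be in (0, 0.5]", call. = FALSE)
  total <- grid$area_tumor_mm2 + grid$area_stroma_mm2 +
    grid$area_follicle_mm2 + grid$area_background_mm2
  tissue <- grid$area_tumor_mm2 + grid$area_stroma_mm2
  ft <- ifelse(tissue > 0, grid$area_tumor_mm2 / tissue, 0)
  fs <- ifelse(tissue > 0, grid$area_stroma_mm2 / tissue, 0)
  cls <- ifelse(tissue / total < background_threshold, "background",
         ifelse(ft >= theta & fs >= theta, "edge",
         ifelse(ft > fs, "tumor", "stroma")))
  grid$base_class <- cls
  attr(grid, "theta") <- theta
  attr(grid, "background_threshold") <- background_threshold
  grid
}

# row indices of the six lattice neighbors of every hexagon (NA when the
# neighbor is not in the grid)
.hex_neighbor_matrix <- function(grid) {
  keys <- .hex_key(grid$q, grid$r)
  out <- matrix(NA_integer_, nrow(grid), 6L)
  for (k in 1:6) {
    out[, k] <- match(.hex_key(grid$q + .HEX_NEIGHBORS[k, "q"],
                               grid$r + .HEX_NEIGHBORS[k, "r"]), keys)
  }
  out
}

.no_interface_error <- function(msg) {
  stop(structure(class = c("no_interface_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Detect the tumor edge (TE)
#'
#' The tumor edge is the set of hexagons sitting on the tumor-stroma
#' transition: every mixed-content (edge-candidate) hexagon, augmented by
#' tumor hexagons with at least one stroma neighbor in the 6-neighborhood,
#' so that a sharp boundary falling exactly between hexagons still yields a
#' continuous TE band. The TE may consist of several connected components.
#'
#' @param grid a classified `hex_grid` (see [classify_hexagons()]).
#' @param augment_adjacent also mark tumor hexagons adjacent to stroma
#'   (default `TRUE`).
#' @return The grid with a logical `is_te` column.
#' @section Errors: signals a condition of class `no_interface_error` when
#'   the grid has no tumor-stroma interface (e.g. an all-tumor or all-stroma
#'   raster); callers flag the case rather than crash.
#' @export
detect_tumor_edge <- function(grid, augment_adjacent = TRUE) {
  stopifnot(inherits(grid, "hex_grid"))
  if (is.null(grid$base_class))
    stop("classify_hexagons() must run before detect_tumor_edge()", call. = FALSE)
  has_tumor <- any(grid$base_class %in% c("tumor", "edge"))
  has_stroma <- any(grid$base_class %in% c("stroma", "edge"))
  if (!has_tumor) .no_interface_error("no tumor hexagons: no interface to extract")
  if (!has_stroma) .no_interface_error("no stroma hexagons: no interface to extract")

  is_te <- grid$base_class == "edge"
  if (augment_adjacent) {
    nb <- .hex_neighbor_matrix(grid)
    cls <- grid$base_class
    tum <- which(cls == "tumor")
    for (i in tum) {
      nbi <- nb[i, ]
      nbi <- nbi[!is.na(nbi)]
      if (any(cls[nbi] == "stroma")) is_te[i] <- TRUE
    }
  }
  if (!any(is_te))
    .no_interface_error("tumor and stroma are present but never adjacent: no interface")
  grid$is_te <- is_te
  grid
}

#' Assign signed ranks relative to the tumor edge
#'
#' Rank 0 is the tumor edge. Every other tissue hexagon gets `|rank|` equal
#' to its hexagon-lattice graph distance (multi-source breadth-first search
#' over the 6-neighborhood) to the nearest TE hexagon, with positive sign on
#' the tumor side and negative sign on the stromal side. Background hexagons
#' carry no rank and, by default, block traversal so that glass or necrosis
#' cannot connect distant tissue regions.
#'
#' @param grid a `hex_grid` with `base_class` and `is_te` set.
#' @param background_traversable allow BFS to step through background
#'   hexagons (default `FALSE`).
#' @return A `ranked_grid`: the grid with integer `rank` (NA for background
#'   and for tissue unreachable from the TE) and `is_te`.
#' @export
rank_hexagons <- function(grid, background_traversable = FALSE) {
  stopifnot(inherits(grid, "hex_grid"))
  if (is.null(grid$is_te))
    stop("detect_tumor_edge() must run before rank_hexagons()", call. = FALSE)
  if (!any(grid$is_te)) .no_interface_error("empty tumor edge")

  nb <- .hex_neighbor_matrix(grid)
  n <- nrow(grid)
  traversable <- grid$base_class != "background" | background_traversable
  dist <- rep(NA_integer_, n)
  frontier <- which(grid$is_te)
  dist[frontier] <- 0L
  d <- 0L
  while (length(frontier)) {
    nxt <- unique(as.vector(nb[frontier, , drop = FALSE]))
    nxt <- nxt[!is.na(nxt)]
    nxt <- nxt[is.na(dist[nxt]) & traversable[nxt]]
    d <- d + 1L
    dist[nxt] <- d
    frontier <- nxt
  }
  sign <- ifelse(grid$base_class == "tumor", 1L,
          ifelse(grid$base_class == "stroma", -1L, 1L))
  rank <- ifelse(grid$is_te, 0L, sign * dist)
  rank[grid$base_class == "background"] <- NA_integer_
  grid$rank <- as.integer(rank)
  if (!inherits(grid, "ranked_grid"))
    class(grid) <- c("ranked_grid", class(grid))
  grid
}

#' Extract an interface zone (IZ) of a given width
#'
#' An IZ of odd width `w` consists of the hexagons with rank in
#' `[-(w-1)/2, (w-1)/2]`; e.g. width 9 covers ranks -4..4 and width 3
#' (the IZ3 used for the Immunogradient indicators) covers ranks -1, 0, +1.
#' Member hexagons carry an aspect label: `"S"` (stroma side, rank < 0),
#' `"TE"` (rank 0) and `"T"` (tumor side, rank > 0).
#'
#' @param grid a `ranked_grid`.
#' @param width odd positive integer IZ width in hexagon ranks. Default 3.
#' @return An `interface_zone`: the member subset of the grid with an
#'   `aspect` column and a `width` attribute.
#' @export
extract_interface_zone <- function(grid, width = 3L) {
  stopifnot(inherits(grid, "ranked_grid"))
  if (length(width) != 1L || width < 1L || width %% 2L == 0L)
    stop("`width` must be an odd positive integer", call. = FALSE)
  half <- (width - 1L) %/% 2L
  iz <- grid[!is.na(grid$rank) & abs(grid$rank) <= half, , drop = FALSE]
  iz$aspect <- ifelse(iz$rank < 0L, "S", ifelse(iz$rank == 0L, "TE", "T"))
  attr(iz, "width") <- as.integer(width)
  class(iz) <- c("interface_zone", class(grid))
  iz
}

#' Case-level tissue-area quality control
#'
#' A case fails QC when its total tumor-class area falls below the minimum
#' analyzable tumor area. The boundary is inclusive: an area exactly at the
#' threshold passes.
#'
#' @param grid a `hex_grid` with areas computed (or a [tissue_map()]).
#' @param min_tumor_area_mm2 minimum tumor area in mm^2. Default 4.5.
#' @return A list with `pass` (logical), `tumor_area_mm2` and `reason`
#'   (`NA` when passing).
#' @export
qc_case <- function(grid, min_tumor_area_mm2 = 4.5) {
  area <- if (inherits(grid, "tissue_map")) {
    tissue_areas_mm2(grid)[["tumor"]]
  } else {
    stopifnot(inherits(grid, "hex_grid"))
    sum(grid$area_tumor_mm2)
  }
  pass <- area >= min_tumor_area_mm2
  list(pass = pass, tumor_area_mm2 = area,
       reason = if (pass) NA_character_ else
         sprintf("tumor area %.3f mm^2 below minimum %.3f mm^2",
                 area, min_tumor_area_mm2))
}
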
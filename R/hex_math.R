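# Axial-coordinate hexagon lattice geometry.
#
# Hexagons are addressed by axial coordinates (q, r). `side` is the
# circumradius (= the hexagon side length). Two orientations:
#   pointy-top: x = side * sqrt(3) * (q + r/2),  y = side * 3/2 * r
#   flat-top:   x = side * 3/2 * q,              y = side * sqrt(3) * (r + q/2)
# The hexagon of a point is the Voronoi cell of the lattice centers, so
# point-to-hexagon assignment is nearest-center assignment.

#' Convert axial hexagon coordinates to Cartesian centers
#'
#' Closed-form center positions for the hexagon lattice; the inverse of
#' [hex_xy_to_axial()] at lattice points.
#'
#' @param q,r integer axial coordinates (vectorized).
#' @param side hexagon side length (circumradius), micrometers.
#' @param orientation `"pointy"` (pointy-top) or `"flat"` (flat-top).
#' @return A list with numeric vectors `x` and `y` (micrometers).
#' @export
hex_axial_to_xy <- function(q, r, side, orientation = c("pointy", "flat")) {
  orientation <- match.arg(orientation)
  if (orientation == "pointy")
    list(x = side * sqrt(3) * (q + r / 2), y = side * 1.5 * r)
  else
    list(x = side * 1.5 * q, y = side * sqrt(3) * (r + q / 2))
}

# Fractional axial coordinates of Cartesian points (before rounding).
.hex_xy_to_frac <- function(x, y, side, orientation) {
  if (orientation == "pointy") {
    r <- y / (1.5 * side)
    q <- x / (sqrt(3) * side) - r / 2
  } else {
    q <- x / (1.5 * side)
    r <- y / (sqrt(3) * side) - q / 2
  }
  list(q = q, r = r)
}

# Cube-coordinate rounding of fractional axial coordinates to the nearest
# lattice point (standard hex-grid rounding).
.hex_round <- function(qf, rf) {
  xf <- qf; zf <- rf; yf <- -xf - zf
  xr <- round(xf); yr <- round(yf); zr <- round(zf)
  dx <- abs(xr - xf); dy <- abs(yr - yf); dz <- abs(zr - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  xr[fix_x] <- -yr[fix_x] - zr[fix_x]
  zr[fix_z] <- -xr[fix_z] - yr[fix_z]
  list(q = as.integer(xr), r = as.integer(zr))
}

# Axial offsets of the six lattice neighbors (same for both orientations).
.HEX_NEIGHBORS <- cbind(q = c(1L, 1L, 0L, -1L, -1L, 0L),
                        r = c(0L, -1L, -1L, 0L, 1L, 1L))

#' Assign Cartesian points to hexagons
#'
#' Maps each point to the hexagon containing it (equivalently, the nearest
#' lattice center). Points exactly equidistant from several centers are
#' broken deterministically: nearest center first, then lowest `q`, then
#' lowest `r`.
#'
#' @inheritParams hex_axial_to_xy
#' @param x,y point coordinates in micrometers.
#' @return A list with integer vectors `q` and `r`.
#' @export
hex_xy_to_axial <- function(x, y, side, orientation = c("pointy", "flat")) {
  orientation <- match.arg(orientation)
  fr <- .hex_xy_to_frac(x, y, side, orientation)
  cand <- .hex_round(fr$q, fr$r)
  # Refine over the candidate and its six neighbors so the tie-break
  # contract holds even for points on hexagon boundaries/vertices.
  bq <- cand$q; br <- cand$r
  cen <- hex_axial_to_xy(bq, br, side, orientation)
  bd <- (x - cen$x)^2 + (y - cen$y)^2
  eps <- (1e-9 * side)^2
  for (k in seq_len(nrow(.HEX_NEIGHBORS))) {
    nq <- cand$q + .HEX_NEIGHBORS[k, "q"]
    nr <- cand$r + .HEX_NEIGHBORS[k, "r"]
    nc <- hex_axial_to_xy(nq, nr, side, orientation)
    nd <- (x - nc$x)^2 + (y - nc$y)^2
    closer <- nd < bd - eps
    tie <- abs(nd - bd) <= eps & (nq < bq | (nq == bq & nr < br))
    take <- closer | tie
    if (any(take)) {
      bq[take] <- nq[take]; br[take] <- nr[take]; bd[take] <- nd[take]
    }
  }
  list(q = bq, r = br)
}

#' Vertex polygon of hexagons
#'
#' @inheritParams hex_axial_to_xy
#' @return For scalar `(q, r)`, a 6 x 2 matrix of vertex coordinates
#'   (micrometers), counter-clockwise.
#' @export
hex_vertices <- function(q, r, side, orientation = c("pointy", "flat")) {
  orientation <- match.arg(orientation)
  cen <- hex_axial_to_xy(q, r, side, orientation)
  ang0 <- if (orientation == "pointy") pi / 6 else 0
  ang <- ang0 + (0:5) * pi / 3
  cbind(x = cen$x + side * cos(ang), y = cen$y + side * sin(ang))
}

# Area of one full hexagon, mm^2.
.hex_area_mm2 <- function(side_um) 3 * sqrt(3) / 2 * (side_um / 1000)^2

# Integer key for (q, r) pairs, used for O(1) lattice lookups.
.hex_key <- function(q, r) paste(q, r, sep = ",")
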
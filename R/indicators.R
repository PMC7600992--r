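#' Marker density profile across interface-zone ranks
#'
#' For each rank level `r` of the interface zone, the rank statistic `q(r)`
#' is the arithmetic mean of per-hexagon cell densities (marker count
#' divided by the hexagon's analyzed-tissue area, in cells/mm^2) over the
#' usable hexagons of that rank. Hexagons whose analyzed-tissue area falls
#' below `min_area_mm2` are excluded; rank levels with no usable hexagon are
#' omitted and flagged. A pooled variant (`stat = "pooled"`: total count
#' over total area per rank) is available for sensitivity analysis.
#'
#' @param iz an `interface_zone` (or any ranked grid subset with counts).
#' @param marker `"CD8"`, `"CD20"` or `"CD68"`.
#' @param min_area_mm2 minimum analyzed-tissue area per hexagon. Default 1e-3.
#' @param stat `"mean"` (default) or `"pooled"` rank statistic.
#' @return A `gradient_profile`: `data.frame(rank, q, n_hex)` with ranks
#'   strictly increasing; attributes `marker` and `omitted_ranks`.
#' @export
gradient_profile <- function(iz, marker = .MARKERS, min_area_mm2 = 1e-3,
                             stat = c("mean", "pooled")) {
  marker <- match.arg(toupper(marker[1]), .MARKERS)
  stat <- match.arg(stat)
  if (is.null(iz$rank)) stop("ranks must be assigned first", call. = FALSE)
  tissue <- iz$area_tumor_mm2 + iz$area_stroma_mm2
  count <- iz[[paste0("n_", tolower(marker))]]
  usable <- !is.na(iz$rank) & tissue >= min_area_mm2
  all_ranks <- sort(unique(iz$rank[!is.na(iz$rank)]))
  rk <- iz$rank[usable]
  dens <- count[usable] / tissue[usable]
  lev <- sort(unique(rk))
  if (stat == "mean") {
    q <- as.numeric(tapply(dens, factor(rk, levels = lev), mean))
  } else {
    q <- as.numeric(tapply(count[usable], factor(rk, levels = lev), sum)) /
      as.numeric(tapply(tissue[usable], factor(rk, levels = lev), sum))
  }
  out <- data.frame(rank = lev, q = q,
                    n_hex = as.integer(table(factor(rk, levels = lev))))
  attr(out, "marker") <- marker
  attr(out, "omitted_ranks") <- setdiff(all_ranks, lev)
  class(out) <- c("gradient_profile", "data.frame")
  out
}

#' Center of Mass of a density profile
#'
#' The Immunogradient Center of Mass statistic,
#' \deqn{CM(q) = \frac{\sum_i r_i\, q(r_i)}{\sum_i q(r_i)},}
#' where `r_i` are the interface-zone ranks and `q(r_i)` the rank
#' statistics (mean cell density per rank). CM lies within the rank range;
#' larger values mean the cell density gravitates toward the tumor aspect.
#' When all `q(r_i)` are zero the statistic is undefined and returned as
#' `NA` with a flag attribute (zero is a meaningful interior value, so the
#' undefined case must not collapse onto it).
#'
#' @param profile a [gradient_profile()], or a numeric vector of rank
#'   statistics with ranks supplied via `ranks`.
#' @param ranks ranks matching `profile` when it is a plain vector.
#' @return Scalar CM, or `NA` (with `attr(, "flag") = "undefined"`).
#' @examples
#' center_of_mass(c(1, 1, 1), ranks = c(-1, 0, 1))   # 0 by symmetry
#' center_of_mass(c(0, 0, 5), ranks = c(-1, 0, 1))   # +1, all mass in tumor
#' @export
center_of_mass <- function(profile, ranks = NULL) {
  if (inherits(profile, "gradient_profile")) {
    ranks <- profile$rank
    q <- profile$q
  } else {
    q <- as.numeric(profile)
    if (is.null(ranks) || length(ranks) != length(q))
      stop("`ranks` must accompany a plain numeric profile", call. = FALSE)
  }
  if (length(q) == 0L || sum(q) == 0)
    return(structure(NA_real_, flag = "undefined"))
  sum(ranks * q) / sum(q)
}

#' Mean cell densities in the S, TE and T aspects of an interface zone
#'
#' Means of per-hexagon densities over the stroma aspect (rank < 0), the
#' tumor edge (rank 0) and the tumor aspect (rank > 0), using the same
#' hexagon filter as [gradient_profile()]. For the IZ3 these equal
#' `q(-1)`, `q(0)` and `q(+1)`. Empty aspects are `NA` with a flag.
#'
#' @inheritParams gradient_profile
#' @return Named numeric vector `c(d_S, d_TE, d_T)` (cells/mm^2), with an
#'   attribute `flag` naming empty aspects if any.
#' @export
aspect_densities <- function(iz, marker = .MARKERS, min_area_mm2 = 1e-3) {
  marker <- match.arg(toupper(marker[1]), .MARKERS)
  tissue <- iz$area_tumor_mm2 + iz$area_stroma_mm2
  count <- iz[[paste0("n_", tolower(marker))]]
  usable <- !is.na(iz$rank) & tissue >= min_area_mm2
  dens <- count / tissue
  pick <- function(sel) if (any(sel & usable)) mean(dens[sel & usable]) else NA_real_
  out <- c(d_S = pick(iz$rank < 0), d_TE = pick(iz$rank == 0),
           d_T = pick(iz$rank > 0))
  empty <- names(out)[is.na(out)]
  if (length(empty)) attr(out, "flag") <- paste("empty aspect:", paste(empty, collapse = ", "))
  out
}

#' Intratumoral marker cell density
#'
#' Pooled density over all tumor tissue of the slide: the number of marker
#' cells lying on tumor-class pixels divided by the total tumor-class area,
#' in cells/mm^2. A hexagon-mean variant (`pooled = FALSE`) averages
#' per-hexagon tumor densities instead.
#'
#' @param grid a `hex_grid` with cells assigned.
#' @param marker `"CD8"`, `"CD20"` or `"CD68"`.
#' @param pooled pooled count-over-area statistic (default) or mean of
#'   per-hexagon densities.
#' @param min_area_mm2 hexagon tumor-area filter for the hexagon-mean
#'   variant.
#' @return Scalar density (cells/mm^2); `NA` with a flag when the slide has
#'   no tumor area.
#' @export
intratumoral_density <- function(grid, marker = .MARKERS, pooled = TRUE,
                                 min_area_mm2 = 1e-3) {
  marker <- match.arg(toupper(marker[1]), .MARKERS)
  stopifnot(inherits(grid, "hex_grid"))
  count <- grid[[paste0("n_", tolower(marker), "_tumor")]]
  area <- grid$area_tumor_mm2
  if (sum(area) == 0)
    return(structure(NA_real_, flag = "no tumor area"))
  if (pooled) {
    sum(count) / sum(area)
  } else {
    ok <- area >= min_area_mm2
    mean(count[ok] / area[ok])
  }
}

#' Compute the full per-case indicator set
#'
#' Orchestrates classification, tumor-edge detection, ranking, IZ
#' extraction and the indicator computations to produce the 15 per-case
#' indicators: for each marker, the Center of Mass (`*_CM`), the aspect
#' densities (`*_d_S`, `*_d_TE`, `*_d_T`) and the intratumoral density
#' (`INT_*`). Cases without a tumor-stroma interface keep their
#' intratumoral densities and carry flags on the interface-dependent
#' indicators; no case is silently dropped.
#'
#' @param grid a `hex_grid` with areas and cell counts.
#' @param iz_width interface-zone width (odd; default 3).
#' @param theta,background_threshold see [classify_hexagons()].
#' @param min_area_mm2 hexagon tissue-area filter for densities.
#' @param stat rank statistic variant, see [gradient_profile()].
#' @return One-row `data.frame` with the 15 indicator columns
#'   (`CD8_CM, CD8_d_S, ..., INT_CD68`) plus a `flags` column
#'   (empty string when clean).
#' @export
compute_indicator_set <- function(grid, iz_width = 3L, theta = 0.1,
                                  background_threshold = 0.05,
                                  min_area_mm2 = 1e-3,
                                  stat = c("mean", "pooled")) {
  stopifnot(inherits(grid, "hex_grid"))
  stat <- match.arg(stat)
  flags <- character(0)
  iz <- NULL
  ranked <- tryCatch({
    g <- classify_hexagons(grid, theta = theta,
                           background_threshold = background_threshold)
    g <- detect_tumor_edge(g)
    rank_hexagons(g)
  }, no_interface_error = function(e) {
    flags <<- c(flags, paste0("no-interface: ", conditionMessage(e)))
    NULL
  })
  if (!is.null(ranked)) iz <- extract_interface_zone(ranked, iz_width)

  row <- list()
  for (m in .MARKERS) {
    if (!is.null(iz)) {
      prof <- gradient_profile(iz, m, min_area_mm2 = min_area_mm2, stat = stat)
      cm <- center_of_mass(prof)
      if (!is.null(attr(cm, "flag")))
        flags <- c(flags, paste0(m, "_CM ", attr(cm, "flag")))
      d <- aspect_densities(iz, m, min_area_mm2 = min_area_mm2)
      if (!is.null(attr(d, "flag")))
        flags <- c(flags, paste0(m, " ", attr(d, "flag")))
    } else {
      cm <- NA_real_
      d <- c(d_S = NA_real_, d_TE = NA_real_, d_T = NA_real_)
    }
    int <- intratumoral_density(grid, m)
    if (!is.null(attr(int, "flag")))
      flags <- c(flags, paste0("INT_", m, " ", attr(int, "flag")))
    row[[paste0(m, "_CM")]] <- as.numeric(cm)
    row[[paste0(m, "_d_S")]] <- as.numeric(d[["d_S"]])
    row[[paste0(m, "_d_TE")]] <- as.numeric(d[["d_TE"]])
    row[[paste0(m, "_d_T")]] <- as.numeric(d[["d_T"]])
    row[[paste0("INT_", m)]] <- as.numeric(int)
  }
  out <- as.data.frame(row)
  out$flags <- paste(flags, collapse = "; ")
  out
}
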
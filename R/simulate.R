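#' Simulate a tissue-class raster with a single tumor blob
#'
#' Generates a labeled raster containing one tumor blob in a stroma field,
#' with an optional background border and lymphoid follicles. The blob
#' boundary is a radial-perturbation polygon
#' `r(theta) = R * (1 + amp * (0.7 sin(f theta + phi1) + 0.3 sin((f+3) theta + phi2)))`
#' with random phases: `roughness_amp = 0` gives a circle, emulating a
#' smooth "pushing" tumor margin, while large amplitude and frequency give
#' a fingered, "infiltrative"-like margin. The exact ground-truth boundary
#' polygon is returned so downstream checks never depend on the hexagon
#' pipeline.
#'
#' @param width_px,height_px raster size in pixels.
#' @param pixel_size_um micrometers per pixel side.
#' @param center_um blob center `c(x, y)` in micrometers; default raster
#'   center.
#' @param radius_um mean blob radius; default 30% of the smaller raster
#'   extent.
#' @param roughness_amp relative boundary perturbation amplitude in
#'   `[0, 1)`. Default 0.
#' @param roughness_freq principal angular frequency of the perturbation.
#' @param background_border_um width of a background (glass) border along
#'   the raster edge. Default 0.
#' @param n_follicles number of circular lymphoid follicles placed in the
#'   stroma. Default 0.
#' @param follicle_radius_um follicle radius. Default 60.
#' @param seed RNG seed (recorded in the output).
#' @return A `sim_tissue` list: `tissue_map` (a [tissue_map()]),
#'   `boundary` (data frame `theta, r_um, x_um, y_um`; the closed
#'   ground-truth polygon), `center_um`, and `params`.
#' @export
simulate_tissue_map <- function(width_px = 512, height_px = 512,
                                pixel_size_um = 2,
                                center_um = NULL, radius_um = NULL,
                                roughness_amp = 0, roughness_freq = 6,
                                background_border_um = 0,
                                n_follicles = 0, follicle_radius_um = 60,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (roughness_amp < 0 || roughness_amp >= 1)
    stop("`roughness_amp` must be in [0, 1)", call. = FALSE)
  w_um <- width_px * pixel_size_um
  h_um <- height_px * pixel_size_um
  if (is.null(center_um)) center_um <- c(w_um, h_um) / 2
  if (is.null(radius_um)) radius_um <- 0.3 * min(w_um, h_um)
  phases <- stats::runif(2, 0, 2 * pi)
  r_fun <- function(theta) {
    radius_um * (1 + roughness_amp *
                   (0.7 * sin(roughness_freq * theta + phases[1]) +
                    0.3 * sin((roughness_freq + 3) * theta + phases[2])))
  }
  rmax <- radius_um * (1 + roughness_amp)
  if (center_um[1] - rmax < background_border_um ||
      center_um[2] - rmax < background_border_um ||
      center_um[1] + rmax > w_um - background_border_um ||
      center_um[2] + rmax > h_um - background_border_um)
    stop("tumor blob does not fit inside the raster", call. = FALSE)

  px <- pixel_size_um
  xs <- (seq_len(width_px) - 0.5) * px
  ys <- (seq_len(height_px) - 0.5) * px
  X <- matrix(rep(xs, each = height_px), height_px, width_px)
  Y <- matrix(rep(ys, times = width_px), height_px, width_px)
  dx <- X - center_um[1]; dy <- Y - center_um[2]
  theta <- atan2(dy, dx)
  rho <- sqrt(dx^2 + dy^2)
  labels <- matrix(2L, height_px, width_px)           # stroma
  labels[rho < r_fun(theta)] <- 1L                    # tumor
  if (background_border_um > 0) {
    border <- X < background_border_um | X > w_um - background_border_um |
      Y < background_border_um | Y > h_um - background_border_um
    labels[border] <- 0L
  }
  if (n_follicles > 0) {
    stroma_idx <- which(labels == 2L)
    for (k in seq_len(n_follicles)) {
      # keep follicles clear of the tumor boundary
      ok <- stroma_idx[rho[stroma_idx] > rmax + 2 * follicle_radius_um]
      if (!length(ok)) break
      c_idx <- sample(ok, 1L)
      fx <- X[c_idx]; fy <- Y[c_idx]
      inside <- (X - fx)^2 + (Y - fy)^2 < follicle_radius_um^2
      labels[inside & labels == 2L] <- 3L
    }
  }
  th <- seq(0, 2 * pi, length.out = 1441L)[-1441L]
  boundary <- data.frame(theta = th, r_um = r_fun(th),
                         x_um = center_um[1] + r_fun(th) * cos(th),
                         y_um = center_um[2] + r_fun(th) * sin(th))
  structure(list(tissue_map = tissue_map(labels, pixel_size_um),
                 boundary = boundary, center_um = center_um,
                 params = list(width_px = width_px, height_px = height_px,
                               pixel_size_um = pixel_size_um,
                               radius_um = radius_um,
                               roughness_amp = roughness_amp,
                               roughness_freq = roughness_freq,
                               background_border_um = background_border_um,
                               n_follicles = n_follicles,
                               follicle_radius_um = follicle_radius_um,
                               seed = seed)),
            class = "sim_tissue")
}

#' Shoelace area of the ground-truth boundary polygon
#'
#' @param sim a `sim_tissue`.
#' @return Polygon area in mm^2.
#' @export
boundary_polygon_area_mm2 <- function(sim) {
  x <- sim$boundary$x_um; y <- sim$boundary$y_um
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2 / 1e6
}

#' Signed distance to the ground-truth tumor boundary
#'
#' Distance in micrometers from points to the simulated tumor boundary
#' polygon, positive inside the tumor and negative in the stroma. Computed
#' against the densely sampled ground-truth polygon, independently of any
#' hexagon-grid machinery.
#'
#' @param sim a `sim_tissue`.
#' @param x,y point coordinates in micrometers.
#' @return Numeric vector of signed distances.
#' @export
signed_boundary_distance <- function(sim, x, y) {
  bx <- sim$boundary$x_um; by <- sim$boundary$y_um
  n <- length(x)
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / length(bx)))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- outer(x[idx], bx, "-")^2 + outer(y[idx], by, "-")^2
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  dx <- x - sim$center_um[1]; dy <- y - sim$center_um[2]
  th <- atan2(dy, dx)
  rfun <- stats::approxfun(c(sim$boundary$theta - 2 * pi, sim$boundary$theta,
                             sim$boundary$theta + 2 * pi),
                           rep(sim$boundary$r_um, 3L))
  inside <- sqrt(dx^2 + dy^2) < rfun(th)
  out * ifelse(inside, 1, -1)
}

# default exponential distance-intensity parameters, cells/mm^2 at the
# boundary (a) and per-um slope (b); negative b = density declines toward
# the tumor interior, the pattern dominating CRC cohorts
.DEFAULT_INTENSITY <- list(
  CD8 = c(a = 200, b = -0.004),
  CD20 = c(a = 50, b = -0.012),
  CD68 = c(a = 170, b = -0.0035))

#' Simulate marker cells as an inhomogeneous Poisson process
#'
#' Draws cell point patterns per marker by thinning: candidate points are
#' generated as a homogeneous Poisson process at the intensity bound over
#' the tissue (tumor + stroma pixels; cells are never placed on background
#' or follicles) and accepted with probability `lambda(d) / lambda_max`,
#' where `d` is the signed distance (micrometers, positive inside tumor)
#' of the candidate's pixel center to the ground-truth boundary. The
#' default intensity family is exponential, `lambda(d) = a * exp(b * d)`
#' cells/mm^2; `b > 0` makes the density gravitate toward the tumor
#' (positive Center of Mass), `b < 0` toward the stroma. Any function of
#' `d` can be supplied instead (e.g. piecewise-constant per rank, for
#' exact Center-of-Mass oracles).
#'
#' @param sim a `sim_tissue`.
#' @param intensity named list over markers; each element either
#'   `c(a = , b = )` for the exponential family or a vectorized function
#'   `lambda(d_um)` returning cells/mm^2.
#' @param lambda_max optional explicit thinning bound (cells/mm^2); it is
#'   an error for the realized intensity to exceed it.
#' @param seed RNG seed.
#' @return List: `cells` (a [cell_table()]), `n_expected` (expected count
#'   per marker, `sum(lambda) * pixel area`), `intensity`.
#' @export
simulate_cells <- function(sim, intensity = .DEFAULT_INTENSITY,
                           lambda_max = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tm <- sim$tissue_map
  px <- tm$pixel_size_um
  px_mm2 <- (px / 1000)^2
  tissue_idx <- which(tm$labels == 1L | tm$labels == 2L)
  nr <- nrow(tm$labels)
  pj <- (tissue_idx - 1L) %/% nr + 1L
  pi_ <- (tissue_idx - 1L) %% nr + 1L
  cx <- (pj - 0.5) * px
  cy <- (pi_ - 0.5) * px
  d <- signed_boundary_distance(sim, cx, cy)

  out_marker <- character(0); out_x <- numeric(0); out_y <- numeric(0)
  n_expected <- stats::setNames(numeric(length(intensity)), names(intensity))
  for (m in names(intensity)) {
    spec <- intensity[[m]]
    lam <- if (is.function(spec)) spec(d) else spec[["a"]] * exp(spec[["b"]] * d)
    if (any(lam < 0)) stop("negative intensity for marker ", m, call. = FALSE)
    bound <- if (is.null(lambda_max)) max(lam) else lambda_max
    if (max(lam) > bound)
      stop("intensity exceeds the thinning bound for marker ", m, call. = FALSE)
    n_expected[[m]] <- sum(lam) * px_mm2
    if (bound <= 0) next
    n_cand <- stats::rpois(1L, bound * length(tissue_idx) * px_mm2)
    if (n_cand == 0L) next
    pick <- sample.int(length(tissue_idx), n_cand, replace = TRUE)
    keep <- stats::runif(n_cand) < lam[pick] / bound
    if (!any(keep)) next
    pick <- pick[keep]
    out_marker <- c(out_marker, rep(m, length(pick)))
    out_x <- c(out_x, cx[pick] + stats::runif(length(pick), -px / 2, px / 2))
    out_y <- c(out_y, cy[pick] + stats::runif(length(pick), -px / 2, px / 2))
  }
  list(cells = cell_table(out_marker, out_x, out_y),
       n_expected = n_expected, intensity = intensity)
}

# Model#1-anchored default effects: log hazard ratios carried by the
# unfavorable stratum of each factor (low CD8 CM, low CD20 CM,
# infiltrative growth)
.DEFAULT_LNHR <- c(cd8_low = log(1 / 0.31), cd20_low = log(1 / 0.33),
                   growth_infiltrative = log(2.90))

#' Simulate a patient cohort under proportional hazards
#'
#' Draws, per patient, the true binary strata (high CD8 CM, high CD20 CM,
#' pushing growth pattern) from the configured prevalences; survival times
#' are exponential with hazard
#' `h0 * exp(sum(lnHR * (1 - bin)))`, so each unfavorable stratum
#' multiplies the hazard by its configured hazard ratio. Censoring is
#' independent uniform on `(0, m)` with `m` solved numerically so the
#' expected censoring fraction matches `censoring_rate`. Continuous
#' Center-of-Mass indicator values consistent with the true bins are
#' emitted (two Gaussian clusters per indicator, located at cohort-typical
#' values) so cutoff learning can be exercised, along with the ground
#' truth for parameter-recovery tests.
#'
#' @param n cohort size (default 87).
#' @param prevalence named probabilities of the favorable strata:
#'   `cd8_high`, `cd20_high`, `growth_pushing`.
#' @param lnHR named log hazard ratios of the unfavorable strata (defaults
#'   anchored at the multivariate model of the source cohort: HRs 1/0.31,
#'   1/0.33 and 2.90).
#' @param baseline_hazard hazard per month of the all-favorable stratum
#'   (default 0.001, about 94% 5-year survival).
#' @param censoring_rate target expected fraction censored, in `[0, 1)`.
#' @param seed RNG seed.
#' @return Data frame with `case_id`, `OS_months`, `event`, the true bins
#'   (`true_cd8_bin`, `true_cd20_bin`, `true_growth_bin`), continuous
#'   `CD8_CM` / `CD20_CM`, `growth_pattern`, `MSI`, `sex`, `age_group`.
#'   The censoring horizon and seed are stored as attributes.
#' @export
simulate_cohort <- function(n = 87,
                            prevalence = c(cd8_high = 0.5, cd20_high = 0.5,
                                           growth_pushing = 0.56),
                            lnHR = .DEFAULT_LNHR,
                            baseline_hazard = 0.001,
                            censoring_rate = 0.67,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 2) stop("`n` must be at least 2", call. = FALSE)
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("`censoring_rate` must be in [0, 1)", call. = FALSE)

  cd8 <- stats::rbinom(n, 1L, prevalence[["cd8_high"]])
  cd20 <- stats::rbinom(n, 1L, prevalence[["cd20_high"]])
  growth <- stats::rbinom(n, 1L, prevalence[["growth_pushing"]])
  loghr <- lnHR[["cd8_low"]] * (1 - cd8) + lnHR[["cd20_low"]] * (1 - cd20) +
    lnHR[["growth_infiltrative"]] * (1 - growth)
  rate <- baseline_hazard * exp(loghr)
  t_true <- stats::rexp(n, rate)

  if (censoring_rate > 0) {
    # expected censoring fraction under C ~ U(0, m) for the bin mixture
    p8 <- prevalence[["cd8_high"]]; p20 <- prevalence[["cd20_high"]]
    pg <- prevalence[["growth_pushing"]]
    combos <- expand.grid(c8 = 0:1, c20 = 0:1, g = 0:1)
    wts <- (p8^combos$c8 * (1 - p8)^(1 - combos$c8)) *
      (p20^combos$c20 * (1 - p20)^(1 - combos$c20)) *
      (pg^combos$g * (1 - pg)^(1 - combos$g))
    rates <- baseline_hazard * exp(lnHR[["cd8_low"]] * (1 - combos$c8) +
                                   lnHR[["cd20_low"]] * (1 - combos$c20) +
                                   lnHR[["growth_infiltrative"]] * (1 - combos$g))
    cens_frac <- function(m) sum(wts * (1 - exp(-rates * m)) / (rates * m))
    m <- stats::uniroot(function(m) cens_frac(m) - censoring_rate,
                        lower = 1e-3, upper = 1e7, tol = 1e-8)$root
    c_time <- stats::runif(n, 0, m)
  } else {
    m <- Inf
    c_time <- rep(Inf, n)
  }
  event <- as.integer(t_true <= c_time)
  os <- pmin(t_true, c_time)

  cm8 <- ifelse(cd8 == 1L, stats::rnorm(n, -0.18, 0.10),
                stats::rnorm(n, -0.45, 0.10))
  cm20 <- ifelse(cd20 == 1L, stats::rnorm(n, -0.40, 0.12),
                 stats::rnorm(n, -0.65, 0.12))
  out <- data.frame(
    case_id = sprintf("case_%03d", seq_len(n)),
    OS_months = os, event = event,
    true_cd8_bin = cd8, true_cd20_bin = cd20, true_growth_bin = growth,
    CD8_CM = cm8, CD20_CM = cm20,
    growth_pattern = ifelse(growth == 1L, "pushing", "infiltrative"),
    MSI = ifelse(stats::rbinom(n, 1L, 39 / 87) == 1L, "MSI", "MSS"),
    sex = ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "female", "male"),
    age_group = ifelse(stats::rbinom(n, 1L, 0.5) == 1L, ">71", "<=71"),
    stringsAsFactors = FALSE)
  attr(out, "censor_horizon_months") <- m
  attr(out, "seed") <- seed
  out
}
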
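# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no stored data.

# Fabricate a hex_grid object directly from per-hexagon values, bypassing
# the raster pipeline, for unit tests of classification/ranking/indicators.
fab_grid <- function(q, r, area_tumor = 0, area_stroma = 0,
                     area_follicle = 0, area_background = 0,
                     n_cd8 = 0L, n_cd20 = 0L, n_cd68 = 0L,
                     side = 50, orientation = "pointy") {
  n <- length(q)
  rl <- function(x) rep_len(x, n)
  cen <- hex_axial_to_xy(q, r, side, orientation)
  g <- data.frame(
    q = as.integer(q), r = as.integer(r),
    center_x_um = cen$x, center_y_um = cen$y,
    area_tumor_mm2 = rl(area_tumor), area_stroma_mm2 = rl(area_stroma),
    area_follicle_mm2 = rl(area_follicle),
    area_background_mm2 = rl(area_background),
    n_cd8 = as.integer(rl(n_cd8)), n_cd20 = as.integer(rl(n_cd20)),
    n_cd68 = as.integer(rl(n_cd68)),
    n_cd8_tumor = 0L, n_cd20_tumor = 0L, n_cd68_tumor = 0L)
  attr(g, "hex_side_um") <- side
  attr(g, "orientation") <- orientation
  attr(g, "tissue_map") <- tissue_map(matrix(1L, 2, 2), 1)
  class(g) <- c("hex_grid", "data.frame")
  g
}

# axial-coordinate rhombus patch
axial_patch <- function(qs, rs) {
  e <- expand.grid(q = qs, r = rs)
  list(q = e$q, r = e$r)
}

# Independent rank oracle: all-pairs shortest paths on the explicit lattice
# adjacency graph via igraph, signed by base class.
rank_oracle <- function(g) {
  n <- nrow(g)
  keys <- paste(g$q, g$r)
  offs <- rbind(c(1, 0), c(1, -1), c(0, -1), c(-1, 0), c(-1, 1), c(0, 1))
  trav <- g$base_class != "background"
  edges <- integer(0)
  for (i in seq_len(n)) {
    for (k in 1:6) {
      j <- match(paste(g$q[i] + offs[k, 1], g$r[i] + offs[k, 2]), keys)
      if (!is.na(j) && i < j && trav[i] && trav[j]) edges <- c(edges, i, j)
    }
  }
  gr <- igraph::make_graph(edges, n = n, directed = FALSE)
  D <- igraph::distances(gr)
  te <- which(g$is_te)
  d <- apply(D[, te, drop = FALSE], 1, min)
  sgn <- ifelse(g$base_class == "tumor", 1, ifelse(g$base_class == "stroma", -1, 1))
  rank <- ifelse(g$is_te, 0, sgn * d)
  rank[!trav | is.infinite(d)] <- NA
  rank[g$is_te] <- 0
  as.integer(rank)
}

# classified + ranked grid from a small random simulated blob slide
random_blob_grid <- function(seed, width_px = 100, height_px = 100,
                             pixel_size_um = 5, hex_side_um = 25,
                             roughness_amp = NULL) {
  set.seed(seed)
  if (is.null(roughness_amp)) roughness_amp <- runif(1, 0, 0.45)
  sim <- simulate_tissue_map(width_px = width_px, height_px = height_px,
                             pixel_size_um = pixel_size_um,
                             radius_um = runif(1, 0.18, 0.3) * width_px * pixel_size_um,
                             roughness_amp = roughness_amp,
                             roughness_freq = sample(3:8, 1),
                             seed = seed)
  g <- build_hex_grid(sim$tissue_map, hex_side_um = hex_side_um)
  g <- classify_hexagons(g)
  detect_tumor_edge(g)
}

# Exact two-sided Fisher p by complete enumeration of tables with the
# observed margins (hypergeometric), independent of stats::fisher.test.
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
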
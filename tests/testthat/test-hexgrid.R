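# Hexagon lattice construction, area aggregation and cell assignment.

test_that("axial <-> Cartesian center conversion round-trips in both orientations", {
  set.seed(42)
  for (orient in c("pointy", "flat")) {
    q <- sample(-50:50, 200, replace = TRUE)
    r <- sample(-50:50, 200, replace = TRUE)
    cen <- hex_axial_to_xy(q, r, side = 37.3, orientation = orient)
    back <- hex_xy_to_axial(cen$x, cen$y, side = 37.3, orientation = orient)
    expect_identical(back$q, as.integer(q))
    expect_identical(back$r, as.integer(r))
  }
})

test_that("grid membership matches a brute-force nearest-center enumeration", {
  # 1000 x 1000 um raster, side 65, pointy-top
  tm <- tissue_map(matrix(1L, 250, 250), pixel_size_um = 4)
  side <- 65
  g <- build_hex_grid(tm, hex_side_um = side, orientation = "pointy")

  # oracle: enumerate a generous candidate lattice, assign every pixel
  # center to its nearest candidate center by exhaustive distance search
  rs <- -3:12; qs <- -10:12
  cand <- expand.grid(q = qs, r = rs)
  cc <- hex_axial_to_xy(cand$q, cand$r, side, "pointy")
  px <- 4
  xs <- (1:250 - 0.5) * px
  pts <- expand.grid(x = xs, y = xs)
  nearest <- integer(nrow(pts))
  for (s in seq(1, nrow(pts), by = 5000)) {
    idx <- s:min(s + 4999, nrow(pts))
    d2 <- outer(pts$x[idx], cc$x, "-")^2 + outer(pts$y[idx], cc$y, "-")^2
    nearest[idx] <- apply(d2, 1, which.min)
  }
  oracle_keys <- sort(unique(paste(cand$q[nearest], cand$r[nearest])))
  got_keys <- sort(paste(g$q, g$r))
  expect_identical(got_keys, oracle_keys)
})

test_that("a raster smaller than one hexagon still yields the overlapping hexagons", {
  tm <- tissue_map(matrix(1L, 8, 8), pixel_size_um = 2)  # 16 um square
  g <- build_hex_grid(tm, hex_side_um = 65)
  expect_gte(nrow(g), 1)
  expect_equal(sum(g$area_tumor_mm2), 16 * 16 / 1e6)
})

test_that("resolution and empty-input preconditions are enforced", {
  tm <- tissue_map(matrix(1L, 10, 10), pixel_size_um = 10)
  expect_error(build_hex_grid(tm, hex_side_um = 15), "invalid resolution")
  expect_error(tissue_map(matrix(integer(0), 0, 0), 1), "non-empty")
  expect_error(tissue_map(matrix(5L, 2, 2), 1), "labels")
})

test_that("per-class areas are conserved exactly and building is deterministic", {
  set.seed(7)
  lab <- matrix(sample(0:3, 120 * 90, replace = TRUE), 90, 120)
  tm <- tissue_map(lab, pixel_size_um = 3)
  g1 <- build_hex_grid(tm, hex_side_um = 20)
  g2 <- build_hex_grid(tm, hex_side_um = 20)
  expect_identical(g1, g2)
  truth <- tissue_areas_mm2(tm)
  expect_equal(sum(g1$area_tumor_mm2), truth[["tumor"]], tolerance = 1e-12)
  expect_equal(sum(g1$area_stroma_mm2), truth[["stroma"]], tolerance = 1e-12)
  expect_equal(sum(g1$area_follicle_mm2), truth[["follicle"]], tolerance = 1e-12)
  expect_equal(sum(g1$area_background_mm2), truth[["background"]], tolerance = 1e-12)
  # total equals raster area
  tot <- sum(g1$area_tumor_mm2 + g1$area_stroma_mm2 +
               g1$area_follicle_mm2 + g1$area_background_mm2)
  expect_equal(tot, 120 * 90 * 9 / 1e6, tolerance = 1e-12)
})

test_that("a hexagon straddling a class boundary through its center splits 50/50", {
  # flat-top centers sit at x = 1.5 * side * q, so with side 40 the hexagon
  # column q = 2 is centered exactly on x = 120 um, a pixel boundary at
  # 2 um/px; pixels mirror around the cut, so the split is exact up to the
  # tie-break of boundary pixels
  px <- 2
  lab <- matrix(2L, 100, 120)
  xs <- (seq_len(120) - 0.5) * px
  lab[, xs < 120] <- 1L
  tm <- tissue_map(lab, pixel_size_um = px)
  g <- build_hex_grid(tm, hex_side_um = 40, orientation = "flat")
  hx <- g[g$q == 2 & g$r %in% 0:1, ]
  expect_gt(nrow(hx), 0)
  frac <- hx$area_tumor_mm2 / (hx$area_tumor_mm2 + hx$area_stroma_mm2)
  quantum <- 5 * (px / 1000)^2 / (hx$area_tumor_mm2 + hx$area_stroma_mm2)
  expect_true(all(abs(frac - 0.5) <= quantum))
})

test_that("every in-bounds cell is assigned once; totals are conserved per marker", {
  tm <- tissue_map(matrix(1L, 100, 100), pixel_size_um = 4)
  g <- build_hex_grid(tm, hex_side_um = 30)
  set.seed(11)
  cells <- cell_table(rep("CD8", 100), runif(100, 0, 400), runif(100, 0, 400))
  g <- assign_cells(g, cells)
  expect_equal(sum(g$n_cd8), 100L)
  expect_equal(sum(g$n_cd20), 0L)
  # out-of-bounds cells are dropped with a recorded count
  cells2 <- cell_table(c("CD8", "CD20"), c(150, -5), c(150, 20))
  expect_message(g2 <- assign_cells(build_hex_grid(tm, hex_side_um = 30), cells2),
                 "dropped 1 cell")
  expect_equal(attr(g2, "n_dropped_out_of_bounds"), 1L)
  expect_equal(sum(g2$n_cd8), 1L)
  expect_equal(sum(g2$n_cd20), 0L)
})

test_that("cell assignment equals a brute-force nearest-center oracle", {
  tm <- tissue_map(matrix(1L, 80, 80), pixel_size_um = 5)
  g0 <- build_hex_grid(tm, hex_side_um = 28)
  set.seed(23)
  n <- 500
  cells <- cell_table(sample(c("CD8", "CD20", "CD68"), n, replace = TRUE),
                      runif(n, 0, 400), runif(n, 0, 400))
  g <- assign_cells(g0, cells)

  # oracle: candidate centers = grid hexagons plus their full 1-ring;
  # nearest center wins, ties to lowest (q, r); winners outside the grid
  # fall back to the hexagon of the cell's pixel (the documented contract)
  offs <- rbind(c(0, 0), c(1, 0), c(1, -1), c(0, -1), c(-1, 0), c(-1, 1), c(0, 1))
  cq <- as.vector(outer(g0$q, offs[, 1], "+"))
  cr <- as.vector(outer(g0$r, offs[, 2], "+"))
  keep <- !duplicated(paste(cq, cr))
  cq <- cq[keep]; cr <- cr[keep]
  ord <- order(cq, cr)
  cq <- cq[ord]; cr <- cr[ord]
  cc <- hex_axial_to_xy(cq, cr, 28, "pointy")
  counts <- matrix(0L, nrow(g0), 3,
                   dimnames = list(NULL, c("CD8", "CD20", "CD68")))
  gkey <- paste(g0$q, g0$r)
  for (i in seq_len(n)) {
    d2 <- (cells$x_um[i] - cc$x)^2 + (cells$y_um[i] - cc$y)^2
    best <- which(d2 <= min(d2) + 1e-9)[1]   # candidates sorted by (q, r)
    row <- match(paste(cq[best], cr[best]), gkey)
    if (is.na(row)) {
      pc_x <- (floor(cells$x_um[i] / 5) + 0.5) * 5
      pc_y <- (floor(cells$y_um[i] / 5) + 0.5) * 5
      d2p <- (pc_x - cc$x)^2 + (pc_y - cc$y)^2
      bp <- which(d2p <= min(d2p) + 1e-9)[1]
      row <- match(paste(cq[bp], cr[bp]), gkey)
    }
    counts[row, cells$marker[i]] <- counts[row, cells$marker[i]] + 1L
  }
  expect_equal(g$n_cd8, unname(counts[, "CD8"]))
  expect_equal(g$n_cd20, unname(counts[, "CD20"]))
  expect_equal(g$n_cd68, unname(counts[, "CD68"]))
})

test_that("boundary cells are assigned deterministically across reruns", {
  tm <- tissue_map(matrix(1L, 60, 60), pixel_size_um = 5)
  g0 <- build_hex_grid(tm, hex_side_um = 25)
  # place cells exactly at hexagon vertices (shared by three hexagons)
  v <- hex_vertices(2, 2, 25, "pointy")
  cells <- cell_table(rep("CD8", 6), v[, "x"], v[, "y"])
  a <- assign_cells(g0, cells)
  b <- assign_cells(g0, cells)
  expect_identical(a$n_cd8, b$n_cd8)
  expect_equal(sum(a$n_cd8), 6L)
})

test_that("cells on follicle pixels are excluded when the flag is on", {
  lab <- matrix(2L, 50, 50)
  lab[21:30, 21:30] <- 3L
  tm <- tissue_map(lab, pixel_size_um = 4)
  g0 <- build_hex_grid(tm, hex_side_um = 20)
  cells <- cell_table(rep("CD20", 2), c(100, 10), c(100, 10))  # one in follicle
  g <- assign_cells(g0, cells)
  expect_equal(sum(g$n_cd20), 1L)
  expect_equal(attr(g, "n_dropped_follicle"), 1L)
  g_keep <- assign_cells(g0, cells, exclude_follicle = FALSE)
  expect_equal(sum(g_keep$n_cd20), 2L)
})

test_that("unknown marker names raise a vocabulary error naming the rows", {
  expect_error(cell_table(c("CD8", "CD4"), c(1, 2), c(1, 2)), "CD4.*row")
})

test_that("points at hexagon centers map to their own hexagon", {
  cen <- hex_axial_to_xy(c(0, 3, -2), c(0, -1, 4), 65, "pointy")
  ax <- hex_xy_to_axial(cen$x, cen$y, 65, "pointy")
  expect_identical(ax$q, c(0L, 3L, -2L))
  expect_identical(ax$r, c(0L, -1L, 4L))
})
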
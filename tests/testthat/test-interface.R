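# Hexagon classification, tumor-edge detection, signed ranking, IZ
# extraction and case QC.

test_that("classification follows the area-fraction rules", {
  p <- axial_patch(0:3, 0)
  g <- fab_grid(p$q, p$r,
                area_tumor = c(1, 0.5, 0.05, 0.001),
                area_stroma = c(0, 0.5, 0.95, 0.002),
                area_background = c(0, 0, 0, 0.997))
  cls <- classify_hexagons(g, theta = 0.1, background_threshold = 0.05)
  expect_equal(cls$base_class, c("tumor", "edge", "stroma", "background"))
})

test_that("classification equals an independent row-by-row rule application", {
  set.seed(31)
  n <- 300
  p <- axial_patch(1:20, 1:15)
  idx <- sample(length(p$q), n)
  g <- fab_grid(p$q[idx], p$r[idx],
                area_tumor = runif(n), area_stroma = runif(n),
                area_follicle = runif(n, 0, 0.2),
                area_background = runif(n, 0, 0.5))
  theta <- 0.2; bg <- 0.1
  cls <- classify_hexagons(g, theta = theta, background_threshold = bg)$base_class
  oracle <- character(n)
  for (i in seq_len(n)) {
    tot <- g$area_tumor_mm2[i] + g$area_stroma_mm2[i] +
      g$area_follicle_mm2[i] + g$area_background_mm2[i]
    tis <- g$area_tumor_mm2[i] + g$area_stroma_mm2[i]
    oracle[i] <- if (tis / tot < bg) "background"
      else if (g$area_tumor_mm2[i] / tis >= theta &&
               g$area_stroma_mm2[i] / tis >= theta) "edge"
      else if (g$area_tumor_mm2[i] > g$area_stroma_mm2[i]) "tumor" else "stroma"
  }
  expect_identical(cls, oracle)
})

test_that("two half-planes meeting on a line give a one-hexagon-thick TE band", {
  p <- axial_patch(-6:14, 0:9)
  cx <- hex_axial_to_xy(p$q, p$r, 50, "pointy")$x
  cut <- 300
  g <- fab_grid(p$q, p$r,
                area_tumor = ifelse(cx < cut, 1, 0),
                area_stroma = ifelse(cx < cut, 0, 1))
  g <- detect_tumor_edge(classify_hexagons(g))
  # TE = tumor hexagons adjacent to stroma: exactly the last tumor column
  expect_true(all(g$base_class[g$is_te] == "tumor"))
  r_lv <- sort(unique(g$r))
  per_row <- table(g$r[g$is_te])
  expect_true(all(per_row == 1))               # one TE hexagon per lattice row
  expect_equal(sort(as.integer(names(per_row))), r_lv)
  ranked <- rank_hexagons(g)
  # rank +1 hexagons are the tumor neighbors of the band, -1 the stroma side
  expect_true(all(ranked$rank[ranked$base_class == "stroma"] <= -1))
  expect_true(all(ranked$rank[ranked$base_class == "tumor" & !ranked$is_te] >= 1))
})

test_that("an all-tumor grid flags a missing interface instead of crashing", {
  p <- axial_patch(0:4, 0:4)
  g <- classify_hexagons(fab_grid(p$q, p$r, area_tumor = 1))
  expect_error(detect_tumor_edge(g), class = "no_interface_error")
})

test_that("TE hexagons have rank 0 and adjacent tumor hexagons rank +1", {
  p <- axial_patch(0:6, 0:4)
  cx <- hex_axial_to_xy(p$q, p$r, 50, "pointy")$x
  g <- fab_grid(p$q, p$r,
                area_tumor = ifelse(cx < 250, 1, 0),
                area_stroma = ifelse(cx < 250, 0, 1))
  ranked <- rank_hexagons(detect_tumor_edge(classify_hexagons(g)))
  expect_true(all(ranked$rank[ranked$is_te] == 0))
  nb <- rbind(c(1, 0), c(1, -1), c(0, -1), c(-1, 0), c(-1, 1), c(0, 1))
  keys <- paste(ranked$q, ranked$r)
  for (i in which(ranked$base_class == "tumor" & !ranked$is_te)) {
    adj_te <- any(vapply(1:6, function(k) {
      j <- match(paste(ranked$q[i] + nb[k, 1], ranked$r[i] + nb[k, 2]), keys)
      !is.na(j) && ranked$is_te[j]
    }, logical(1)))
    if (adj_te) expect_equal(ranked$rank[i], 1L)
  }
})

test_that("ranks equal brute-force shortest-path distances on random blobs", {
  for (seed in c(101, 202, 303)) {
    g <- random_blob_grid(seed)
    expect_lte(nrow(g), 220)
    ranked <- rank_hexagons(g)
    expect_identical(ranked$rank, rank_oracle(g))
  }
})

test_that("interface zones cover exactly the requested rank band and nest monotonically", {
  g <- random_blob_grid(404, width_px = 120, height_px = 120)
  ranked <- rank_hexagons(g)
  iz3 <- extract_interface_zone(ranked, 3)
  expect_true(all(iz3$rank %in% -1:1))
  expect_setequal(unique(iz3$aspect[iz3$rank == -1]), "S")
  expect_setequal(unique(iz3$aspect[iz3$rank == 0]), "TE")
  expect_setequal(unique(iz3$aspect[iz3$rank == 1]), "T")
  iz9 <- extract_interface_zone(ranked, 9)
  expect_true(all(abs(iz9$rank) <= 4))
  iz1 <- extract_interface_zone(ranked, 1)
  expect_identical(sort(paste(iz1$q, iz1$r)),
                   sort(paste(ranked$q[ranked$is_te], ranked$r[ranked$is_te])))
  # monotone nesting over available widths
  prev <- character(0)
  for (w in c(1, 3, 5, 7, 9)) {
    izw <- extract_interface_zone(ranked, w)
    cur <- paste(izw$q, izw$r)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_error(extract_interface_zone(ranked, 4), "odd")
})

test_that("no hexagon's rank sign contradicts its base class", {
  for (seed in c(11, 12, 13, 14)) {
    ranked <- rank_hexagons(random_blob_grid(seed))
    expect_true(all(ranked$rank[ranked$base_class == "stroma" & !ranked$is_te] < 0,
                    na.rm = TRUE))
    expect_true(all(ranked$rank[ranked$base_class == "tumor" & !ranked$is_te] > 0,
                    na.rm = TRUE))
    expect_true(all(is.na(ranked$rank[ranked$base_class == "background"])))
  }
})

test_that("shifting the raster by a lattice vector shifts TE and ranks identically", {
  # (0, 3 * side) is the lattice vector (dq, dr) = (-1, 2) for pointy-top;
  # with side 40 and 4 um pixels that is a 30-pixel vertical shift
  set.seed(55)
  lab <- matrix(2L, 130, 100)
  blob_r <- 28; ci <- 45; cj <- 50
  for (i in 1:130) for (j in 1:100)
    if ((i - ci)^2 + (j - cj)^2 < blob_r^2) lab[i, j] <- 1L
  lab_shift <- rbind(matrix(2L, 30, 100), lab[1:100, ])
  tm1 <- tissue_map(lab[1:100, ], 4)
  tm2 <- tissue_map(lab_shift[1:130, ], 4)
  r1 <- rank_hexagons(detect_tumor_edge(classify_hexagons(
    build_hex_grid(tm1, hex_side_um = 40))))
  r2 <- rank_hexagons(detect_tumor_edge(classify_hexagons(
    build_hex_grid(tm2, hex_side_um = 40))))
  k1 <- paste(r1$q, r1$r)
  k2 <- paste(r2$q + 1, r2$r - 2)   # undo the (dq, dr) = (-1, 2) lattice shift
  common <- intersect(k1, k2)
  # interior hexagons must agree; only raster-border hexagons may differ
  m1 <- r1$rank[match(common, k1)]
  m2 <- r2$rank[match(common, k2)]
  interior <- r1$center_y_um[match(common, k1)] > 60 &
    r1$center_y_um[match(common, k1)] < 340
  expect_identical(m1[interior], m2[interior])
})

test_that("tissue-area QC applies an inclusive boundary", {
  p <- axial_patch(0:9, 0:9)
  g44 <- fab_grid(p$q, p$r, area_tumor = 0.044)   # 4.4 mm^2 total
  g45 <- fab_grid(p$q, p$r, area_tumor = 0.045)   # 4.5 mm^2 total
  expect_false(qc_case(g44)$pass)
  expect_match(qc_case(g44)$reason, "below minimum")
  expect_true(qc_case(g45)$pass)
  expect_true(is.na(qc_case(g45)$reason))
})

test_that("QC tumor area matches a hand-computed painted area", {
  lab <- matrix(2L, 60, 60)
  lab[11:40, 11:50] <- 1L                      # 30 x 40 px painted tumor
  tm <- tissue_map(lab, pixel_size_um = 10)
  g <- build_hex_grid(tm, hex_side_um = 25)
  expected <- 30 * 40 * (10 / 1000)^2          # 0.12 mm^2
  expect_equal(qc_case(g)$tumor_area_mm2, expected, tolerance = 1e-12)
  expect_true(qc_case(g, min_tumor_area_mm2 = 0.12)$pass)
  expect_false(qc_case(g, min_tumor_area_mm2 = 0.1201)$pass)
})
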
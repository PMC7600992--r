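# immunogradient

Spatial analytics for immune-cell infiltration at the tumor–stroma
interface of segmented whole-slide images, with the downstream survival
statistics that turn the spatial indicators into prognostic scores for
colorectal cancer cohorts.

## The problem and the method

Digital image analysis of immunohistochemistry slides yields a
tissue-class raster (tumor / stroma / lymphoid follicle / background) and
the coordinates of CD8+ (cytotoxic T), CD20+ (B) and CD68+ (macrophage)
cells. Absolute cell densities ignore *where* the cells sit relative to
the invasive margin. This package quantifies the **direction** of immune
infiltration across the tumor–stroma interface:

1. The raster is subsampled by a regular hexagonal grid; each hexagon
   records its per-class tissue areas and per-marker cell counts.
2. Hexagons are classified by area fractions; the **tumor edge (TE)** is
   the set of mixed tumor/stroma hexagons plus tumor hexagons adjacent to
   stroma. Every tissue hexagon gets a signed **rank**: its hexagon-lattice
   distance to the nearest TE hexagon, positive on the tumor side,
   negative on the stromal side (TE = 0).
3. An **interface zone** of width *w* is the band of ranks
   [−(w−1)/2, (w−1)/2]; the default IZ₃ covers the stroma aspect (S,
   rank −1), the TE (rank 0) and the tumor aspect (T, rank +1).
4. With q(r) the mean per-hexagon cell density (cells/mm²) at rank r, the
   **Center of Mass** of marker density across the IZ is

   CM(q) = Σᵢ rᵢ q(rᵢ) / Σᵢ q(rᵢ),

   a dimensionless statistic in [min rank, max rank]: CM > 0 means the
   density gravitates toward the tumor. Per-aspect means (d_S, d_TE, d_T)
   and the pooled intratumoral density (INT, cells per mm² of all tumor
   tissue) complete the 15 per-case indicators.
5. Cohort statistics: optimal log-rank cutoffs dichotomize CD8 CM and
   CD20 CM; the **CD8-CD20 Immunogradient score** (0–2) sums the two
   favorable strata, and the **immuno-interface score (IIS)** (0–3) adds
   the binary growth-pattern term (pushing margin favorable, infiltrative
   unfavorable). Kaplan–Meier estimates, stepwise likelihood-ratio Cox
   models and leave-one-out cross-validation quantify the prognostic
   value.

A synthetic-data module simulates label rasters (tumor blobs with smooth
"pushing" or fingered "infiltrative" margins), inhomogeneous Poisson cell
patterns with configurable density gradients across the margin, and
proportional-hazards patient cohorts, so the full pipeline is testable
without patient data.

## Worked example

```r
library(immunogradient)

sim   <- simulate_tissue_map(width_px = 256, height_px = 256,
                             pixel_size_um = 4, seed = 1)
cells <- simulate_cells(sim, seed = 2)
fit   <- immunogradient(sim$tissue_map, cells$cells,
                        hex_side_um = 40, min_tumor_area_mm2 = 0.1)
fit
#> Immunogradient case fit
#>   grid: 279 hexagons (side 40 um), tumor 0.30 mm^2, QC pass
#>   IZ width 3: 92 hexagons (S 37 | TE 31 | T 24)
#>   Center of Mass: CD8 -0.168 | CD20 -0.325 | CD68 -0.272
```

The default simulated slide has all three marker densities declining from
stroma into tumor (the pattern dominating real CRC cohorts), so all three
CM values are negative; CD20 declines fastest, hence its CM is the most
negative. `coef(fit)` returns the 15 indicators;
`plot(fit, which = "map")` draws the interface zone (TE yellow, tumor
aspect red, stroma aspect green) and `plot(fit, which = "profile")` the
per-rank density profile.

Cohort level:

```r
coh <- simulate_cohort(n = 87, seed = 8)         # study-scale cohort
res <- run_cohort(coh)
res$cox
#> Cox model (Efron ties): LR = 24.88 on 3 df, p = 1.632e-05
#>   growth_bin                   HR  0.261 (0.112-0.608), p = 0.001859
#>   ...
```

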
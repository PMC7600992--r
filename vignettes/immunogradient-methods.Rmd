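---
title: "Immunogradient analytics: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immunogradient analytics: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunogradient)
```

This vignette is the package's own account of the method it implements:
what is being estimated, which tunable parameters matter and why they
default where they do, what the synthetic-data generator does and does not
emulate, and where the design was genuinely open.

## The spatial model

The inputs are a tissue-class raster (an integer label per pixel: 0
background, 1 tumor, 2 stroma, 3 lymphoid follicle, with a known
micrometer pixel size) and a table of immune-cell centroids
(CD8+/CD20+/CD68+, coordinates in micrometers in the raster frame). Both
are outputs of upstream image-analysis software; the package deliberately
starts *after* segmentation and cell detection.

**Hexagonal subsampling.** A regular hexagon lattice (pointy-top by
default, side = circumradius `hex_side_um`) is laid over the raster.
A pixel belongs to the hexagon containing its center, which makes the
hexagons an exact partition of the raster: per-class areas summed over
hexagons equal the raster class areas in pixel units, with no polygon
clipping and resolution-convergent accuracy. Cells are assigned by
point-in-hexagon (equivalently nearest lattice center, since hexagons are
the Voronoi cells of the lattice); boundary ties break deterministically
by nearest center, then lowest `(q, r)` axial coordinates.

**Tumor edge and ranks.** Hexagons are classified by area fractions:
background when the analyzed-tissue (tumor + stroma) share of the covered
area falls below `background_threshold` (default 0.05); an edge candidate
when both the tumor and stroma fractions of analyzed tissue reach `theta`
(default 0.1); otherwise the majority class. The tumor edge (TE) is the
edge-candidate set augmented with tumor hexagons that touch stroma in the
6-neighborhood — the augmentation matters because a perfectly sharp
boundary that falls between hexagons would otherwise produce no
mixed-content hexagons and hence no TE. Every tissue hexagon then gets a
signed rank by multi-source breadth-first search from the TE over the
lattice adjacency: |rank| is the hexagon-step distance to the nearest TE
hexagon, positive on the tumor side, negative on the stromal side.
Lattice-graph distance, not Euclidean distance, is the right metric here
because the interface zone is defined in whole hexagon layers.
Background hexagons are non-traversable by default so that glass or
necrosis cannot connect distant tissue regions; a flag restores
traversal. Ties between several TE components resolve to the minimum
distance automatically.

**Indicators.** With an interface zone of width 3 (ranks −1, 0, +1), the
rank statistic q(r) is the arithmetic mean over rank-r hexagons of the
per-hexagon density: marker count divided by the hexagon's analyzed-tissue
area. The Center of Mass

$$\mathrm{CM}(q) = \frac{\sum_i r_i\, q(r_i)}{\sum_i q(r_i)}$$

summarizes which side of the interface the density gravitates toward. It
is scale-invariant, bounded by the rank range, and for the IZ₃ reduces to
$(q(1) - q(-1)) / (q(-1) + q(0) + q(1))$. When every q(r) is zero the CM
is undefined and reported as missing — zero is a meaningful interior
value (a balanced gradient), so the undefined case must not collapse onto
it. Aspect densities d_S, d_TE, d_T are q(−1), q(0), q(+1); the
intratumoral density INT is the pooled count of marker cells on
tumor-class pixels divided by total tumor area.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `hex_side_um` | 65 | µm | The upstream literature does not fix the grid scale. 65 µm gives hexagons of ≈0.011 mm² (tens to hundreds of cells at realistic densities) and an IZ₃ roughly 340 µm wide — a few cell layers on each side of the margin. Overridable everywhere. |
| `orientation` | pointy | – | No physical meaning; fixed per run for reproducibility. |
| `theta` | 0.1 | fraction | Mixed-content threshold for edge candidates; 0.1 flags hexagons with a non-trivial share of both classes without swallowing nearly-pure ones. |
| `background_threshold` | 0.05 | fraction | Hexagons under 5% analyzed tissue are glass/necrosis for practical purposes. |
| `iz_width` | 3 | ranks | The IZ₃ is the established operating point for colorectal material. |
| `min_area_mm2` | 1e-3 | mm² | Hexagons with less analyzed tissue than ~10% of a hexagon yield unstable density ratios and are excluded from q(r). |
| `min_tumor_area_mm2` | 4.5 | mm² | Case-level QC floor on analyzable tumor area; the boundary is inclusive (exactly 4.5 passes; "below the minimum" fails). |
| `exclude_follicle` | TRUE | – | Follicles are segmented as a separate class precisely to keep lymphoid aggregates out of microenvironment densities; cells on follicle pixels are dropped from counts, and follicle area never enters density denominators. Both choices are flags because the upstream convention is not documented. |
| `stat` | "mean" | – | q(r) as the mean of per-hexagon densities matches the indicator definitions; a pooled count-over-area variant is available for sensitivity analysis. The same open question exists for INT, where the pooled form is the default. |

## Cohort statistics

Density indicators are right-skewed, so group comparisons log-transform
as ln(x+1) before ANOVA / Welch tests; the +1 offset keeps zero densities
finite and is configurable. Pairwise tests use Bonferroni's
multiply-by-k adjustment. Prognostic cutoffs come from an exhaustive
log-rank scan over midpoints between consecutive distinct indicator
values, restricted to splits that leave at least 10% of patients per
group; the returned p-value is the raw scan minimum — no multiple-testing
correction — and every cutoff result carries an `exploratory` flag so the
optimism stays visible. Five-year overall survival is read from the
right-continuous Kaplan–Meier step at exactly 60 months. Cox models use
Efron tie handling; stepwise selection runs forward steps (add the
best-LR-p term while p < 0.05) with backward checks (drop any term whose
LR p rises above 0.05) until stable, since the selection direction was an
open choice. Cutoffs may also be supplied externally, because in-sample
cutoff learning followed by in-sample survival curves is optimistically
biased; the mode used is recorded in the result.

Leave-one-out validation refits the model n times and reports two
statistics. The cross-validated partial log-likelihood follows
Verweij–van Houwelingen. The cross-validated concordance scores each
comparable pair under the two leave-one-out models that each exclude one
pair member (half weight each), with tied predicted risks excluded.
Scoring pairs inside a single model's risk ordering — rather than pooling
linear predictors across all n models — avoids a known anti-conservative
bias of pooled-LOO concordance under null models, where each patient's
own leave-out influence couples to their outcome; excluding ties lets a
perfectly separating binary factor reach concordance 1.

**Scores.** The binary strata use a strictly-greater convention (value
above the cutoff = high stratum; a value exactly at the cutoff is low),
fixed and documented because the convention is otherwise arbitrary.
A pushing growth margin maps to 1 (favorable), infiltrative to 0. The
CD8-CD20 Immunogradient score is the sum of the two favorable CM strata
(support exactly {0,1,2}); the IIS adds the growth term (support exactly
{0,1,2,3}). Missing components propagate to missing scores rather than
silently dropping cases.

## The synthetic-data generator

The generator exists so that every stage of the pipeline has a testable
ground truth; its defaults are chosen once to emulate the structure of a
colorectal cohort at desk scale.

* **Tissue**: one tumor blob per slide, built as a radial-perturbation
  polygon r(θ) = R(1 + a(0.7 sin(fθ+φ₁) + 0.3 sin((f+3)θ+φ₂))). Zero
  amplitude gives a circle (a "pushing"-like margin); larger amplitude
  and frequency give fingered, "infiltrative"-like margins. The exact
  boundary polygon is returned so area and distance oracles never depend
  on the hexagon pipeline.
* **Cells**: an inhomogeneous Poisson process per marker, drawn by
  thinning against λ(d), where d is the signed micrometer distance of a
  candidate's pixel center to the ground-truth polygon (positive inside
  tumor), computed against the densely sampled boundary (1440 vertices,
  sub-2-µm vertex error). The default family is exponential,
  λ(d) = a·e^{bd}; b > 0 pulls density toward the tumor (CM > 0). Any
  function of d can be substituted, e.g. piecewise-constant per rank for
  exact CM oracles. Intensities are evaluated at pixel centers, so the
  sampler is exact for the piecewise-constant-per-pixel intensity. The
  defaults (CD8 a = 200, b = −0.004; CD20 a = 50, b = −0.012; CD68
  a = 170, b = −0.0035 per µm) reproduce the qualitative cohort pattern:
  all three densities decline from stroma into tumor, CD20 most sharply
  and least abundantly.
* **Cohorts**: true binary strata drawn from configurable prevalences
  (favorable CM strata at 0.5, pushing margin at 0.56); exponential
  survival with hazard h₀·exp(Σ lnHR·(1−bin)), the default log hazard
  ratios anchored at the multivariate-model effects the score is built
  from (1/0.31, 1/0.33, 2.90) and h₀ = 0.001/month (≈94% five-year
  survival in the all-favorable stratum); independent uniform censoring
  with the horizon solved numerically for a 67% expected censoring
  fraction, matching the cohort's event yield. Continuous CM values
  consistent with the true bins (two Gaussian clusters per indicator,
  centered at cohort-typical values) are emitted so cutoff learning can
  be exercised against ground truth.

What the generator does **not** emulate: histological texture, multi-blob
or metastatic topologies, cell clustering beyond the Poisson assumption
(real infiltrates are overdispersed), correlated indicator noise, and
informative censoring. Passing tests therefore demonstrate that the
estimators recover known structure under the stated model — not that the
biological effect sizes would replicate in new patient material.

## Numerical choices and degenerate inputs

* Pixel-center membership makes all area bookkeeping exact in pixel
  units; hexagon membership at boundaries resolves by the documented
  nearest-center/lowest-(q,r) tie-break, so reruns are bit-identical.
* Cases without any tumor–stroma interface (all-tumor or all-stroma
  rasters, or tumor and stroma never adjacent) signal a typed
  `no_interface_error`; orchestration converts it to per-case flags —
  interface indicators go missing, intratumoral densities survive, and
  the case is never silently dropped.
* Unreachable tissue (isolated behind background) keeps an undefined rank
  and is excluded downstream rather than being assigned a misleading
  distance.
* The cutoff scan breaks p-value ties toward the smaller cutoff; the
  group-size floor (10%) prevents the log-rank statistic from being
  driven by extreme small splits.
* Zero-variance covariates are excluded from Cox fits with a warning; an
  event count under five per candidate term triggers a warning, and
  suspected monotone likelihood (a diverging coefficient) is flagged.

## Problem sizes used in the checks

The test-suite simulations are sized for a single CPU: slide fixtures of
100–256 px per side at 4–5 µm pixels (0.2–1 mm² of tissue, hexagon sides
22–40 µm), rank-oracle fixtures capped at 200 hexagons, cohort
simulations of n = 87–400 with up to 200 replicates for calibration
checks and 30–100 replicates for recovery means, and 50 slide replicates
for gradient sign recovery. These sizes keep Monte Carlo error well
inside the asserted tolerances while the full suite runs in minutes.

## Known limitations

* The tumor edge is defined per hexagon layer; sub-hexagon (vector
  contour) interface geometry is out of scope, so indicator values depend
  mildly on `hex_side_um` and the lattice phase relative to the tissue.
* The TE rule treats the edge as one global set; per-region interfaces of
  multifocal tumors are not separated.
* In-sample cutoff learning inflates the univariate stratification
  p-values; the package marks them exploratory and supports external
  cutoffs, but does not itself correct the scan optimism.
* The LOO concordance definition excludes predictor-tied pairs; with
  heavily discretized predictors it therefore summarizes only the
  informative comparisons.
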
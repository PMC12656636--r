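---
title: "Methods: small-sample coastal SDM and decision mapping with coastcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-sample coastal SDM and decision mapping with coastcore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(coastcore)
```

## The problem

Near-shore island endemics are hard subjects for species distribution
modelling: records are few (tens, not thousands), spatially clustered along
a narrow coastal ecotone, collected across irregular survey campaigns, and
often too sensitive to publish. Managers nevertheless need a defensible,
regulation-ready map: where is habitat, how sure are we, and where should
the next survey go. `coastcore` implements a complete blueprint for this
setting -- terrain-based predictors from a fine DEM, a presence--background
maximum-entropy model with conservative complexity control, cluster-aware
spatial validation, high-specificity binarization with ecological
post-filters, and explicit sensitivity "bands" instead of single numbers --
and couples it to a synthetic-island generator so every stage is testable
without touching real coordinates.

## The model

The core model is a maximum-entropy (Gibbs) distribution over landscape
cells. With expanded features $f_j(x)$ and coefficients $\lambda_j$, the
relative occurrence rate is

$$\mathrm{raw}(x) = \frac{e^{\sum_j \lambda_j f_j(x)}}{Z}, \qquad
Z = \sum_{x \in \text{background}} e^{\sum_j \lambda_j f_j(x)},$$

fitted by minimising the convex penalised objective

$$-\frac{1}{m}\sum_{i \in \text{presence}} \sum_j \lambda_j f_j(x_i)
 + \log Z + \sum_j \beta_j |\lambda_j|.$$

Features are min--max scaled variables (`l`), their squares (`q`) and
optionally forward/reverse hinge bases (`h`). Penalties follow the familiar
per-class default schedule, interpolated in the presence count and scaled
by the feature's background standard deviation, $\sqrt{m}$, and a single
regularization multiplier RM. The optimizer is a monotone FISTA (proximal
gradient with soft thresholding, momentum restarts and backtracking); the
objective tolerance is $10^{-7}$ with a $10^4$ iteration cap, and a
degenerate separable fit (unbounded objective) is reported as an error
rather than a huge coefficient. Predictions are reported on the cloglog
scale $1 - \exp(-e^{H}\,\mathrm{raw})$, where $H$ is the entropy of the
fitted raw distribution over the training background; this is a monotone
transform of the linear predictor, so ranking metrics are unaffected by it.

Model complexity is chosen on a feature-class x RM grid by seeded k-fold
cross-validation, maximising the robustness score (mean AUC $-$ 0.5 SD),
with AICc (on presence log-likelihood, counting nonzero coefficients)
reported for comparability, and ties resolved toward simpler classes and
stronger regularization.

## Predictors

Twelve layers are derived from the DEM and shoreline at the native grid:
elevation, Horn slope and aspect components (eastness/northness), TRI (RMS
of the eight neighbour differences), TPI (elevation minus the circular
window mean, 90 m radius), Euclidean distance to shore (exact distance
transform, cell centre to land/sea interface), a McCune--Keon heat-load
index (aspect folded about the southwest axis), a wetness proxy
($-$[scaled window relief] $-$ [scaled slope]; the min--max rescale that
makes the two terms commensurate is this package's declared convention,
deliberately not the flow-accumulation form), and three coastal-exposure
metrics whose exact published definitions are not available and are
therefore declared conventions here: wave exposure (exponential distance
decay times the fraction of 16 compass rays reaching sea within the decay
length, default 200 m), edge slope (mean slope of shore-adjacent cells
within the decay length), and cliff proximity (distance transform to cells
at or above 40 degrees, with a finite sentinel when no cliff exists).
All window statistics use land cells only; NoData is never imputed.

Fitting happens on a block-mean aggregated stack; prediction reuses the
same coefficients on the native stack. Collinearity is reduced before
fitting by greedy Spearman pruning ($|\rho| > 0.7$; within a pair the
variable with the larger mean absolute correlation is dropped) followed by
iterative VIF pruning (ceiling 5), protecting ecologically prioritized
variables -- by default distance to coast, elevation and the wetness proxy.
When protected variables are themselves collinear they are kept, with a
warning; only perfect collinearity is an error.

## Validation

Spatial validation is leave-one-cluster-out (LOCO): presences are grouped
into clusters by the epsilon-graph components at 250 m (the minPts = 1
DBSCAN case, identical to the 30 m rule used to consolidate raw records
into unique sites), and each cluster is held out whole. The evaluation
background for a fold is the fixed training background minus any cell
holding a held-out presence. Metrics are rank-based AUC (ties counted one
half), a standardized partial AUC restricted to specificity at or above
0.90 (trapezoidal area with boundary interpolation, rescaled so chance is
0.5 and perfection 1.0), and a relative RMSE: RMSE of cloglog scores
against 0/1 labels, normalised by the fold's score range. The published
wording for that denominator is ambiguous (observed scores could mean
labels, whose range is always one); this package normalises by the range
of the predictions and flags a zero-range fold as undefined. Random k-fold
results, used only for model selection and sensitivity sweeps, are
labelled `random-CV` and must never be compared with LOCO numbers.

## Decision layer

Continuous cloglog suitability becomes a regulation-ready product in three
steps, all inclusive at thresholds:

1. **Threshold.** The default rule is Spec0.980, the 0.98 quantile of the
   training-background predictions, which guarantees at least 98%
   background specificity. Quantiles use the type-7 (linear interpolation)
   convention; because an interpolated quantile can leave the strict-below
   fraction marginally under 0.98, the threshold steps up to the next
   unique background score whenever needed so the guarantee holds exactly.
   The menu also provides TP10, a coverage-target rule, apparent and
   cross-validated Youden thresholds and maximum balanced accuracy, with
   Youden argmax ties resolved to the midpoint below the smallest
   maximizer (strictly between perfectly separated classes).
2. **Ecological filters.** A coastal belt at the 0.90 quantile of recent
   presences' coastal distances (about 90 m; explicit 60/90/120 m
   overrides supported), then a minimum mapping unit of 3 cells under
   8-neighbour connectivity.
3. **Accounting.** Area is the CORE cell count times the cell area;
   coverage is the fraction of recent presence sites whose cell is CORE;
   leakage is thresholded area outside the belt, reported before belt
   clipping and asserted to be exactly zero afterwards (a property of the
   construction, not an ecological statement).

Two sweeps quantify robustness: refitting across accessible-mask widths
(300/450/600 m) and background ratios (10:1 to 30:1), recomputing the
Spec0.980 threshold from each run's own training background (so thresholds
legitimately differ across runs), and recomputing CORE across belt widths
and MMU sizes. The min--max range of post-processed CORE areas is the
*area band* carried forward as explicit planning uncertainty. Coastline
segments (100 m, rolling median over 3 segments) are ranked against the
threshold and reported as quantile priority bands, never as absolute
discovery probabilities; optional effort and safety priors enter as
multiplicative weights in $[0,1]$ and default to 1.

## The synthetic island

Because real coordinates for such species are justifiably withheld, the
package ships a generator that emulates the statistical structure the
analysis assumes, and the packaged study scenario is built entirely from
it.

**Landscape.** A 256 x 256 grid of 20 m cells: a cone (peak 400 m, island
radius 80% of the grid half-width) with an inverted-Gaussian caldera,
radial ridge-and-valley modulation (amplitude 0.25, six ridges, tapered at
the summit) and smoothed Gaussian roughness (sd 8 m). Sea is NoData;
interior depressions are filled so the island is one landmass with a
single shoreline. The 20 m cell -- rather than the 5 m of the archetypal
survey DEM -- is a deliberate choice: it makes the island about 4 km
across with a 16 km coastline, so the method's absolute distances (30 m
consolidation, the ~90 m belt, 250 m holdout clustering, the 300 m
accessible mask) keep realistic proportions to the coastline while the
grid stays desk-sized. The ridges matter statistically as well as
visually: they break the near-perfect collinearity between elevation and
coastal distance that a smooth cone imposes, which is what lets an
L1-penalised model attribute negative effects to both variables rather
than arbitrarily zeroing one.

**Truth surface.** Suitability is a logistic function of distance to coast
(negative), elevation (negative), patch-scale slope (negative; smoothed
over 60 m so habitat pockets are larger than GPS error), patch-scale
northness (positive -- a wind-exposed-sector preference producing a
continuous northern core with lee-side satellites), a unimodal wetness
preference (negative quadratic in the wetness proxy, which a
linear-quadratic model can represent exactly), plus a small smooth random
field (amplitude 1 on the link scale) standing for microhabitat variation
the predictors cannot see. Coefficients were calibrated once, jointly,
against the emulation targets -- the 0.90 quantile of presence coastal
distances near 90 m, on the order of 25 unique presence sites, several
spatially separated presence clusters, and enough signal that honest
cluster-holdout AUC above 0.9 is attainable -- and then frozen; they are
the study conditions, not tuning knobs.

**Surveys.** Sites are drawn without replacement over land cells with
probability proportional to truth; each site is visited in four periods
(2008, 2014--2016, 2020--2022, 2023--2024) with per-visit detection
probability 0.7 (mirroring the stable 0.65--0.75 detection-rate band the
monitoring design expects), a fifth of sites silently vanish in the final
period to exercise the loss/persistence/gain classification, coordinates
carry within-cell placement plus 10 m Gaussian GPS jitter, and 30% of
detections emit a near-duplicate record 20--30 m away to exercise
consolidation.

**What passing tests do and do not show.** The generator produces the
right kind of data: clustered, near-shore, noisy, multi-period, with a
partially explainable niche. It does not simulate vegetation dynamics,
tides, observer heterogeneity or demographic decline, so a green suite
demonstrates the machinery is correct and the workflow behaves as designed
under its stated assumptions -- not that any particular real species obeys
them.

## Numerical choices and degenerate inputs

Quantiles are type 7 throughout. Thresholding is inclusive (score at or
above theta). Areas are cell counts times cell area in a projected-metre
grid. Aspect is undefined on flat cells and excluded from aspect-derived
layers rather than imputed (heat load uses a neutral fold there, where its
aspect terms vanish anyway). The wetness proxy of a perfectly flat island
is 0 everywhere (its maximum). The cliff-proximity layer uses a finite
sentinel (10x the grid extent) when no cliff exists so downstream code
never meets infinities. Zero-variance variables are excluded from feature
expansion with a warning; prediction rows are clamped to [-0.1, 1.1] after
scaling. A fold whose fit fails is flagged and excluded from summaries
with a warning; a zero score range makes RelRMSE NaN rather than a number.

## Problem sizes

The packaged demo fits about 25 presence sites against roughly 600
background cells on a 60 m fitting grid (the native mapping grid is
256 x 256 at 20 m), runs a six-point RM grid under 5-fold CV, a LOCO
evaluation over 4--8 clusters, a 15-run mask/ratio sweep and a 24-cell
belt/MMU grid; a complete blueprint run takes on the order of ten seconds
on one CPU, and the full test suite a few minutes.

## Known limitations

The MaxEnt implementation covers linear, quadratic and hinge features
only (no product or threshold features, no sampling-bias grids), and aims
for statistical agreement with the published algorithm rather than
bit-for-bit replication of any reference binary. DBSCAN consolidation
implements the minPts = 1 case only, which is the only case the workflow
uses. The wetness proxy is not a hydrological TWI. Coastal-exposure
formulas are declared conventions, parameterized so alternates can be
swapped in. Detection probability is not modelled (no occupancy-detection
layer); detection rates with bootstrap CIs are descriptive. The area band
brackets mask-driven uncertainty only -- it says nothing about model
misspecification beyond what the sweeps vary.
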
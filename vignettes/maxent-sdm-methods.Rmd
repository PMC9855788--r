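---
title: "Methods: presence-only maximum-entropy distribution modelling in maxentsdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only maximum-entropy distribution modelling in maxentsdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`maxentsdm` implements the standard presence-only habitat-suitability
workflow for a species whose records come from heterogeneous sources
(herbaria, citizen science, survey plots): spatial rarefaction, predictor
pruning, a maximum-entropy niche model, threshold-based binary mapping,
and zonal change accounting across climate scenarios. This vignette is the
package's account of the statistical machinery, the defaults, and the
choices made where the method leaves room.

## The estimation problem

Presence-only data tell us where a species *was recorded*, not where it is
absent. The maximum-entropy approach models the distribution of presences
over the cells of the study region relative to an availability sample (the
"background"): among all distributions consistent with the presences'
feature means, it picks the one closest to uniform. Equivalently, it is
the Gibbs model

$$q_\lambda(x) \propto \exp(\lambda \cdot f(x))$$

over background cells, fitted by minimising the L1-penalised negative
log-likelihood

$$J(\lambda) = -\overline{\lambda\cdot f}_{\text{pres}}
  + \log \textstyle\sum_{\text{bg}} e^{\lambda\cdot f(x)}
  - \log n_{\text{bg}} + \sum_j \beta_j\,|\lambda_j|.$$

$J$ is convex; $J(0) = 0$ defines the zero of the "gain" scale
(gain $= -J$ without the penalty), so a fitted model always has
non-negative penalised gain. Key assumptions worth keeping in mind:

* background cells are an unbiased availability sample of the region
  (`sample_background()` draws uniformly from the valid mask; no
  target-group bias correction is implemented);
* sampling effort is homogeneous after rarefaction — one record per grid
  cell at most, which removes within-cell duplication but not broader
  geographic reporting bias;
* the niche is stationary in environmental space (the same $\lambda$
  applies when projecting to future layers).

## Features and regularisation

Features map each environmental variable into $[0,1]$ using the training
background's range: linear (min–max scaled), quadratic (the square,
min–max scaled), pairwise products, forward/reverse hinges with knots at
background quantiles (default 10 interior knots per variable), and step
thresholds at the same knots. The default feature classes grow with
presence count — fewer than 10 presences use linear only, 10–79 add
quadratic and hinge, 80+ add product and threshold — mirroring common
MaxEnt practice of restraining model complexity when data are scarce.

Each feature $j$ carries penalty
$\beta_j = m \cdot \beta_{\text{class}} \cdot \mathrm{sd}_j(\text{bg}) / \sqrt{n_{\text{pres}}}$
with class constants 1.0 for linear/quadratic/product/threshold and 0.5
for hinge, all held at 1.0 below 10 presences, and $m$ the user's
`reg_multiplier` (default 1; the virtual-species analyses in this package
use 0.5, i.e. deliberately weak regularisation, because structure recovery
— not parsimony — is their goal). A tiny floor ($10^{-8}$) keeps every
coordinate strictly penalised so the optimum is unique even for separable
toys.

When a fitted model is projected onto new layers (e.g. a future scenario),
raw inputs are clamped to the training background's per-variable range and
features are clipped to $[0,1]$ — the usual guard against uncontrolled
extrapolation. Constant variables cannot be scaled and their features are
dropped with a warning.

## Optimisation

The fitter is cyclic coordinate descent with, per coordinate, a
soft-thresholded Newton step (gradient $-\bar f_j + E_q[f_j]$, curvature
$\mathrm{Var}_q[f_j]$) and exact-objective backtracking, so $J$ is
non-increasing by construction. Convergence is declared when a full sweep
changes $J$ by less than `tol` (default $10^{-6}$, relative); the sweep
cap is `max_iter = 5000`, and hitting it returns the model with
`converged = FALSE` plus a warning rather than an error. This optimiser
was chosen over off-the-shelf penalised-GLM solvers because the
per-update bookkeeping is exactly what `percent_contribution()` needs:
every accepted update's decrease in $J$ is credited to the updated
feature, rolled up to variables (products split equally), floored at zero
and normalised to 100.

The test suite pins the fitter to an independent brute-force oracle — a
dense grid search over $\lambda$ on one- and two-feature toys — to within
$2\times10^{-3}$, and checks the closed-form limits (uniform model under
heavy regularisation; $\sum_x q(x) = 1$ after every fit).

## Outputs: raw and cloglog

The *raw* output is $q_\lambda$ itself, defined only over the training
background (asking for it elsewhere is an error, since the normaliser is
background-specific). Maps use the *cloglog* transform

$$c(x) = 1 - \exp(-e^{H}\,\tilde q(x)),$$

where $H$ is the entropy of the fitted raw distribution and $\tilde q$ the
density evaluated with clamping. It is a strictly monotone rescaling of
the linear predictor into $[0,1]$ whose uniform-model value is
$1 - e^{-1} \approx 0.632$ — both properties are asserted in the tests.

## Validation and thresholding

Discrimination is summarised by the ROC AUC of presence versus background
scores, computed by the rank (Mann–Whitney) formulation, which equals the
exhaustive pairwise probability with ties counted half. Because
threshold-free AUC alone is a blunt instrument in presence-only settings,
the package also reports TSS (sensitivity + specificity − 1) and Cohen's
kappa at a concrete threshold. That threshold is the MTSS rule: scan the
distinct observed scores (plus 0) and keep the candidate maximising
sensitivity + specificity, ties resolved toward the smallest threshold
(the most inclusive map among equals). TSS and kappa are reported at the
MTSS threshold computed on the same score sets, since no other threshold
is canonically defined for this workflow. Background cells stand in for
absences in all confusion counts — the only option presence-only data
allow, and the convention of the field.

Replicated evaluation uses seeded 75/25 re-splits of the rarefied records
(`round(0.75 n)` to calibration), with replicate $r$ seeded `seed + r`.
Re-splitting was chosen over bootstrap or $k$-fold because it is the
simplest scheme consistent with "replicate the model $n$ times with a
fixed calibration fraction"; the ensemble map is the cellwise *mean* of
the replicate cloglog grids, and thresholding is applied *after*
averaging, using the MTSS threshold of a single full-calibration fit (all
rarefied points), so that one threshold is shared by all scenario maps.

## Variable selection

Candidate layers are compared by Spearman rank correlation by default
(robust to the skewed, nonlinearly related distributions typical of
bioclimatic variables); Pearson is available and every report records
which method was used. Computation happens on the background sample —
correlations should describe the available environment, not the occupied
subset. Pruning is greedy: while any retained pair has $|r|$ at or above
the threshold (default 0.75; retention is strict, $|r| < 0.75$), drop the
lower-priority member of the worst pair. Priority defaults to the
univariate model gain (a one-variable linear+quadratic fit per layer), the
standard "keep the ecologically more informative twin" rule; ties break by
larger mean $|r|$ against the rest, then later input order, making the
selection deterministic. The tests verify idempotence, threshold
monotonicity, and agreement with a brute-force search over feasible
subsets on small cases.

## Habitat accounting

Binary maps mark cells with suitability $\ge t$ suitable. Area uses the
constant 4.5 km² per 2.5-arcmin cell convention; a cosine-of-latitude
corrected mode exists (`latitude_correction = TRUE`) but is off by
default, because the constant convention is what the field's area tables
use and what the packaged reference tables assume. Percent change is
$100(\text{future}-\text{current})/\text{current}$, undefined (NA, with a
`new_colonization` flag) when the current area is zero. Zonal mean
suitability averages over *all* valid zone cells, not just suitable ones,
so a zone with no suitable habitat still has a defined mean and category.
Categories read the conventional printed bounds (≤0.25 / 0.26–0.50 /
0.51–0.75 / ≥0.76) as half-open continuous intervals with cut points at
0.25, 0.50, 0.75 — the printed 0.26 and 0.76 are two-decimal roundings,
so e.g. 0.505 is "high" and 0.25 exactly is "low".

## The virtual-species generator

Because real occurrence and climate downloads are out of scope, the
package ships a generator that emulates their statistical structure:

* **Layers** are Gaussian random fields (white noise convolved with a
  separable Gaussian kernel, edge-renormalised), standardised and mixed
  through the Cholesky factor of a target correlation matrix, then given
  temperature-like or precipitation-like units. This reproduces the two
  properties the pipeline is sensitive to — spatial smoothness and
  inter-layer collinearity — with a dial for each.
* **The niche** is a Gibbs model linear in the min–max-scaled layers, with
  known weights; its cloglog transform is the ground-truth suitability.
  Using the same functional family as the fitted model makes parameter
  and rank recovery well defined.
* **Presences** are drawn cell-wise proportional to the true raw density,
  placed uniformly within their cell, and a chosen fraction is forced
  into already-occupied cells to create the within-cell duplication that
  rarefaction is designed to remove.
* **Scenarios** are affine per-layer perturbations (shift/scale), and
  **zones** are seeded Voronoi partitions of the valid mask.

What the generator does *not* emulate: geographic sampling bias beyond
duplication, non-climatic covariates, dispersal limitation, and the
spatial autocorrelation of real residuals. Passing recovery tests
therefore demonstrates the *pipeline's* correctness, not that any given
real-data analysis will be as clean.

The recovery analyses (tests and the acceptance script) use fixed study
conditions chosen once: a 200×200 landscape, six layers with an engineered
$r = 0.9$ collinear pair, true weights (Bio1 = 12, Bio3 = −10) — a
habitat specialist occupying a small percentage of the landscape, the
regime where presence-only modelling is most informative and a patchy
invader plausibly sits — 500 presences with 20% duplication, and 10,000
background cells. Desk-scale smoke tests use 25–80-cell grids and 2–5
replicates; these sizes were picked so the whole suite stays fast enough
to run habitually.

## Numerical and degenerate-input conventions

* Points map to cells under half-open intervals $[w, e) \times (s, n]$,
  so boundary points are never double-counted; rarefaction keeps the
  *first* record in input order within a cell (deterministic, and no
  better criterion is defined).
* ESRI ASCII is the raster interchange format (corner- and
  centre-registered headers accepted; values written with 6 significant
  digits by default); nodata cells are `NA` in memory and the sentinel on
  disk. Multi-band and projected formats are out of scope, as is any
  reprojection — all layers must share one grid.
* Empty rarefaction input returns an empty result (not an error); fewer
  than 2 records cannot be split; fewer than 3 sample cells cannot be
  correlated; a background request larger than the valid mask returns
  every valid cell.
* Constant layers: correlation against them is defined as 0 and flagged;
  their features are dropped with a warning.
* log-sum-exp is max-shifted everywhere; raw probabilities renormalise to
  1 after every fit by construction.

## Limitations

The model is a from-scratch implementation of the published
maximum-entropy method, not a bit-compatible port of any particular
MaxEnt release; defaults (knot counts, beta table, class schedule) are
declared here rather than inherited. Evaluation treats background as
pseudo-absence, so reported TSS/kappa depend on background size and
prevalence in the usual way. Area accounting ignores latitude distortion
by default. Zones must already be rasterised on the analysis grid;
polygon zonal statistics are not provided.
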
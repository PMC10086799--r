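---
title: "Measuring wing fluctuating asymmetry from museum landmark data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring wing fluctuating asymmetry from museum landmark data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingfa)
```

## The problem

Fluctuating asymmetry (FA) — small, random deviations from perfect
bilateral symmetry — is a widely used morphological proxy of developmental
stress: the two sides of a bilateral trait are built by the same genome, so
departures from symmetry reflect the organism's failure to buffer
development against adverse conditions. Museum insect collections make it
possible to track FA across a century, but the specimens are pinned, fragile
and unevenly sampled in space and time, so an FA pipeline for such material
must deal with digitisation error, mounting artifacts (tilted wings) and
heavily skewed collection intensity before any trend can be trusted.

`wingfa` implements that pipeline for paired 13-landmark insect forewing
configurations: TPS input, matching-symmetry Procrustes alignment,
Procrustes-distance FA, measurement-error ANOVA, quality filters,
stratified rarefaction, climate joins and penalised-spline trend models.
Because the original collections cannot be redistributed, the package ships
a synthetic-data generator with full ground truth; every stage of the
pipeline is tested against data whose asymmetry structure is known by
construction.

## Shape analysis

### Alignment

Each wing is a configuration of 13 homologous vein-junction landmarks in
image coordinates. Translation is removed by centring on the centroid, size
by dividing by centroid size $CS = \sqrt{\sum_k \lVert x_k - \bar x
\rVert^2}$, and orientation by generalised Procrustes alignment (GPA):
configurations are iteratively rotated onto an evolving consensus (the
landmark-wise mean shape, re-normalised each round) until the root mean
square movement of the consensus falls below `tol` (default `1e-8`).
Rotations are the closed-form two-dimensional Kabsch solution restricted to
proper rotations (determinant $+1$); reflections must never be absorbed
into the fit, because left–right differences are exactly what we are
measuring. This is *partial* Procrustes alignment: sizes stay fixed at 1
during rotation, with no per-iteration rescaling by $\cos\rho$.

Matching symmetry is handled by mirroring all left wings (negating $x$)
before a single joint GPA of all wings of all specimens and replicates. The
consensus is initialised from the first configuration after a deterministic
sort by (specimen, side, replicate), so results are independent of input
order. The alignment is insensitive to this initialisation for realistic
data; the test suite verifies agreement with an independently implemented
pairwise-iterative GPA with random initialisation to within $10^{-6}$.

### The FA measure

A specimen's FA is the Procrustes distance $\sqrt{\sum_k \lVert L_k - R_k
\rVert^2}$ between its aligned mirrored-left and right wing shapes. The two
digitisation replicates of each wing are averaged into one shape per side
before the distance is taken (`mean_shape` policy); averaging shapes rather
than distances shrinks digitisation noise, and the alternative
(`mean_distance`) is available and tested. Directional asymmetry — the
consistent side-to-side mean difference — is estimated by the Procrustes
ANOVA but deliberately *not* subtracted from the per-specimen FA values:
FA here is the raw left–right distance.

### Measurement error

Because every wing is digitised twice, measurement error is estimable by a
Side × Individual Procrustes ANOVA: sums of squares are pooled over all
landmarks and both coordinates, and conventional two-way degrees of freedom
are multiplied by the shape-space dimension $2k - 4 = 22$. The
side × individual mean square is the FA component and the residual mean
square is digitisation error; their ratio is the standard check that FA
exceeds noise. The decomposition is exact (components sum to the total SS),
verified against a direct-summation oracle at $10^{-10}$. Landmarker
consistency between data collectors is checked by modelling each
digitisation's distance to its image's mean shape with collector as a fixed
effect and image as a random intercept (`nlme::lme`).

## Quality filters and rarefaction

Three filters run in a fixed order, each with a type-7 (linear
interpolation) quantile convention so thresholds are bit-for-bit
reproducible:

1. **Shape outliers.** Every wing's distance to the consensus is pooled
   across sides; a specimen is removed when either wing lies strictly above
   the upper quartile of that pooled distribution.
2. **Wing-angle differential.** The angle of the base→tip landmark vector
   (landmarks 1 and 13 by default, configurable) is computed from *raw*
   coordinates, left wings mirrored first; specimens whose left–right
   differential exceeds Q3 + IQR are removed. Tilted mounting shows up as a
   large differential and inflates apparent FA, which the synthetic tilt
   artifact reproduces (see below).
3. **Rarefaction.** Stage 1 keeps one random record per species × month ×
   year × region × caste group; stage 2 caps each year at 20 records.
   Random choices use a dedicated RNG stream keyed by (seed, group), so
   adding one group never reshuffles the others, and per-year kept counts
   are seed-invariant.

## Climate

Specimens are assigned to one of the nine UK climate reporting regions by
point-in-polygon test; the packaged geometry is a deliberately simplified
synthetic partition of Britain into labelled boxes (adequate for the
synthetic data and for testing; users with real data should supply a
faithful GeoJSON of the Met Office regions). Annual mean temperature and
total precipitation are left-joined on (region, year); the series starts in
1910, and earlier specimens keep missing climate so they remain available
to the purely temporal models. A Pearson correlation screen of annual
against seasonal variables documents why annual exposures suffice.

## Trend models

All models use natural-log FA as the response (log transformation makes
the residuals approximately normal) and are penalised-spline models fitted
by REML through `mgcv`:

* **Species baseline** — species + caste intercepts, a thin-plate smooth of
  (latitude, longitude), and year-as-factor random intercepts
  (`bs = "re"`). Reference levels: *B. hortorum*, worker.
* **Century half** — caste + a first/second-half contrast + the spatial
  smooth; the contrast is reported as $100(e^\beta - 1)$ percent change in
  FA. A descriptive per-species percent change (computed per species on raw
  FA, then averaged with an SE across species) is reported alongside.
* **Year smooth** — caste + one global smooth of year − 1899 (basis
  dimension 10) + the spatial smooth; the smooth's effective degrees of
  freedom (EDF) distinguish linear from nonlinear trends, and predictions
  at a reference profile (worker, mean coordinates, ±2 SE band) give the
  trend curve.
* **Climate surface** — caste + a tensor-product smooth of temperature ×
  precipitation (5 × 5 marginal bases) + the spatial smooth + year random
  intercepts, fitted on the climate-complete subset. Predictions are masked
  outside the convex hull of the observed climate values, where the tensor
  smooth would extrapolate.

Nested models are compared by referring the change in residual sum of
squares per model degree of freedom (summed EDF) to the F distribution —
the classical model-variance comparison — with the AIC difference reported
alongside. Default basis dimensions (year 10, space 30, tensor 5 × 5) are
arguments, not constants; the simulation studies below use a spatial basis
of 10 to keep hundreds of refits fast without changing the models'
structure.

## The synthetic-data generator

`simulate_dataset()` makes the generative assumptions of the analysis
explicit. Per specimen: a true shape (template + isotropic individual
variation, normalised); a right wing displaced by half the directional
asymmetry vector plus half an individual FA displacement; a left wing
displaced oppositely, then mirrored; and per replicate, raw image
coordinates built by adding digitisation noise and applying tilt, scale and
translation. Tilt contributes both an in-plane rotation (which GPA removes)
and an out-of-plane foreshortening factor $\cos(\text{tilt})$ on one axis
(which GPA cannot remove) — this is what makes the angle filter's value
measurable: tilted specimens show both a large angle differential and
inflated FA.

The FA displacement's total Procrustes length is drawn $|N(0,
\sigma_{FA})|$, with $\sigma_{FA}$ the product of a baseline (0.056, chosen
so mean FA ≈ 0.045, the magnitude typical of bumblebee forewings) and
species, year and climate multipliers. The displacement direction is
projected into the tangent space orthogonal to translation, scale and
rotation of the individual's shape and its length corrected by
$1/\sqrt{1 - m^2/4}$; this makes the matched-pair Procrustes distance of
the normalised wings equal the drawn magnitude *exactly*, so the pipeline's
FA can be checked against ground truth at $10^{-6}$ rather than only in
distribution. Collector "bias" in the repeatability generator is an extra
per-digitisation tangent displacement of the stated length: a fixed offset
would shift the image mean with it and be invisible to the
distance-to-mean response.

`century_scale_scenario()` fixes the study conditions: 590 specimens of four
species, species baseline multipliers matching mean FA of ≈ 0.041 / 0.047 /
0.041 / 0.046, two replicates per wing, 5° tilt SD, months March–November,
a few heavily collected years to exercise the rarefaction cap, an FA ramp
that is flat until 1925 and reaches +8.8 % by 1998, and a climate bump —
higher FA above 9 °C with intermediate (750–1250 mm) rainfall. The bump's
log-scale amplitude (0.30) was calibrated so the fitted tensor smooth's
significance in simulated datasets matches the strength of the reported
climate signal at this sample size (median p ≈ 0.008); a weaker bump
produces data in which the climate effect is usually undetectable, i.e. a
scenario inconsistent with the conditions being emulated.

### Model-level simulations

Parameter-recovery and error-rate studies of the trend models use a direct
model-level generator (`simulate_model_data()`): log FA = baseline +
species + caste + year effect + climate effect + Gaussian residual. The
residual SD default of 0.26 is anchored to the uncertainty such collections
display: an SE of about ±2.3 percentage points on a century-half FA change
at n = 590 implies a log-scale residual SD of roughly
$2.3 / (109\sqrt{4/590}) \approx 0.26$. The landmark-level folded-normal
magnitude draw is *not* used for these studies: $\log|N(0,1)|$ has SD
≈ 1.11, an order more dispersion than real log-FA data show, under which no
century-half contrast of realistic size is recoverable at n = 590. The two
generators serve different purposes — the landmark generator validates the
geometry and filters; the model-level generator validates the statistical
layer at realistic dispersion.

### What the synthetic data do not emulate

Real digitisation error is heteroscedastic across landmarks; real wing
damage is not isotropic noise; locality coordinates come from geocoded
label text with tiered precision; and the true Met Office region boundaries
are not boxes. Passing tests therefore demonstrate correctness of the
algorithms under the stated generative model, not that the biological
conclusions would survive every artifact of real collections.

## Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere; "above" thresholds are strict.
* GPA convergence: RMS consensus movement < `1e-8`, cap 100 iterations,
  explicit `converged` flag and warning on failure.
* Zero centroid size (all landmarks coincident) and coincident angle
  landmarks are hard errors; FA exactly 0 (identical digitisations) yields
  `NA` log-FA with a warning rather than `-Inf`.
* Factors with a single observed level are dropped from model formulas
  with a warning, so the pipeline still runs on small or degenerate
  subsets; a single observed year drops the random intercept.
* Climate with fewer than five distinct (temperature, precipitation) cells
  is rejected; near-collinear climate (r > 0.99) warns.
* Simulation problem sizes in the test suite: 50 reseeded runs at n = 590
  for recovery checks and 500 replicates for null error rates, with the
  spatial basis at k = 10.

## Known limitations

Object symmetry (midline landmarks), sliding semilandmarks, 3D
configurations, antisymmetry diagnostics, allometric FA-size corrections
and spatial autocorrelation structures beyond the coordinate smooth are out
of scope. The region geometry shipped with the package is synthetic; the
per-year rarefaction cap is applied overall (not per species), and which
landmarks define the "wing angle" is a declared convention (1 → 13), both
points on which reasonable implementations could differ.
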
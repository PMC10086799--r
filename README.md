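# wingfa

Fluctuating asymmetry (FA) of paired insect wings from 2D landmark data —
a tested pipeline for the kind of century-scale museum-collection study in
which left/right forewing shape differences serve as a morphological proxy
of developmental stress in bumblebees (*Bombus*).

Small random deviations from bilateral symmetry arise when development
fails to buffer environmental stress, so trends in FA across a century of
pinned specimens can indicate when wild populations experienced stress.
Getting there from pinned, twice-digitised, unevenly collected specimens
requires a chain of careful steps, all implemented and tested here:

* **TPS landmark I/O** (tpsDig dialect, 13 forewing landmarks, two wings ×
  two digitisation replicates per specimen) and metadata handling,
  including exclusion of likely overwintered queens collected before
  species-specific Julian days (150/164/164/159).
* **Matching-symmetry Procrustes alignment**: left wings mirrored, one
  joint generalised Procrustes alignment of all wings; FA is the
  Procrustes distance between a specimen's aligned left and right shapes,

  `FA = sqrt( sum_k || L_k - R_k ||^2 )`.
* **Side × Individual Procrustes ANOVA** quantifying digitisation error
  against the FA component, plus a mixed-model landmarker-repeatability
  check between data collectors.
* **Quality filters** in fixed order: shape outliers (pooled wing distance
  above Q3), wing-angle differentials (above Q3 + IQR; tilted mounting
  inflates FA), and two-stage rarefaction (one specimen per species ×
  month × year × climate-region × caste group, then ≤ 20 per year).
* **Climate join**: assignment to the nine UK climate reporting regions
  and a left join of annual mean temperature and total precipitation
  (series from 1910).
* **Trend models** (penalised regression splines via `mgcv`, REML): a
  species-baseline GAMM with year random intercepts, a century-half GAM
  (reported as `100·(exp(β) − 1)` percent FA change), a nonlinear
  year-smooth GAM, and a temperature × precipitation tensor-product GAMM,
  with nested-model F comparisons on model variances.
* **A synthetic-data generator** with exact ground truth (injected FA
  magnitudes, directional asymmetry, digitisation noise, tilt artifacts,
  temporal and climate effects), so every stage is verifiable without the
  original collections.

## Worked example

The `analysis/` scripts run the whole study on the packaged century-scale
scenario (590 synthetic specimens, 1900–2000):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_align_asymmetry.R
Rscript analysis/03_quality_filters.R
Rscript analysis/04_climate_join.R
Rscript analysis/05_trend_models.R
```

Step 2 prints, for example:

```
Queen exclusion removed 55 early-season queens; 535 specimens remain
Generalised Procrustes alignment
  configurations: 2140
  iterations:     3 (converged)
FA over 535 specimens: mean 0.0572 | median 0.0456
Side x Individual MS is 53.5 times the measurement-error MS: digitisation noise is negligible
Collector repeatability: F = 0.36 , p = 0.549 -> no systematic collector difference
```

meaning 535 specimens survive the date screen, the joint alignment of all
2140 wing digitisations converged, and replicate digitisations disagree
far less than left and right wings do — FA is measurable above noise.
Step 3 then removes shape outliers (here 189 specimens above the pooled
Q3 of 0.109) and tilted specimens (23 above a 13.8° angle differential)
and rarefies to 321 records; step 5 fits the four model families, e.g.

```
== 2. Century half ==
Second vs first half:  15.8 % change in FA (F = 4.71 , p = 0.0385 )
== 3. Year smooth ==
Predicted FA 0.0313 (1925) -> 0.0364 (1998): 16.3 % increase
```

an FA increase between the century halves recovered from a generator that
injected a ramp rising after 1925. Equivalent calls in R: see
`?run_fa_pipeline`, which chains every stage on in-memory objects.

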
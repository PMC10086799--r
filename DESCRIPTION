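Package: wingfa
Title: Fluctuating Asymmetry of Insect Wings from Landmark Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating fluctuating asymmetry (FA) of paired
    bilateral structures from two-dimensional landmark data, built around
    the matching-symmetry protocol for insect forewings digitised from
    museum specimens. Provides TPS landmark input/output, generalised
    Procrustes alignment with reflection of one side, Procrustes-distance
    FA measures, Side x Individual Procrustes ANOVA for measurement error,
    landmarker repeatability checks, quality filters (shape outliers,
    wing-angle differentials) and stratified rarefaction for uneven museum
    sampling, climate-region assignment and annual climate joins, and
    penalised-spline trend models (GAM/GAMM) for species baselines,
    century-half contrasts, nonlinear year trends and temperature x
    precipitation surfaces. A synthetic-data module generates landmark
    datasets with known asymmetry structure so every pipeline stage is
    verifiable without access to the original collections.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    nlme,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
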
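test_that("model_data derives scaled year, century half and reference levels", {
  d <- data.frame(specimen_id = c("a", "b"), species = c("pascuorum", "hortorum"),
                  caste = c("queen", "worker"), year = c(1900L, 1950L),
                  latitude = c(52, 55), longitude = c(0, -2),
                  fa = c(0.04, 0.05))
  md <- model_data(d)
  expect_equal(md$year_scaled, c(1L, 51L))
  expect_equal(as.character(md$century_half), c("first", "second"))
  expect_equal(levels(md$species)[1], "hortorum")
  expect_equal(levels(md$caste)[1], "worker")
  expect_equal(md$log_fa, log(d$fa))
  expect_error(model_data(d[, setdiff(names(d), "fa")]), "fa")
})

test_that("species baseline GAMM recovers injected species offsets", {
  d <- simulate_model_data(
    n = 600, seed = 60,
    species_offsets = c(hortorum = 0, lapidarius = 0.12,
                        muscorum = 0, pascuorum = 0.12))
  fit <- fit_species_baseline(d, k_space = 10)
  pt <- fit$parametric
  expect_gt(pt["specieslapidarius", "Estimate"], 0)
  expect_gt(pt["speciespascuorum", "Estimate"], 0)
  expect_lt(pt["specieslapidarius", "Pr(>|t|)"], 0.05)
  expect_lt(pt["speciespascuorum", "Pr(>|t|)"], 0.05)
  expect_equal(fit$parametric["specieslapidarius", "Estimate"], 0.12,
               tolerance = 0.1)
  # model df at least the parametric count; EDF of smooths >= ~1
  expect_gte(fit$model_df, nrow(pt))
})

test_that("spatially flat data shrink the spatial smooth towards its null space", {
  d <- simulate_model_data(n = 500, seed = 61)
  fit <- fit_species_baseline(d, k_space = 20)
  sp_row <- grep("latitude", rownames(fit$smooths))
  expect_lt(fit$smooths[sp_row, "edf"], 5)
})

test_that("century-half contrast recovers a multiplicative shift and centres on zero without one", {
  shift <- function(year) ifelse(year >= 1950, log(1.09), 0)
  d <- simulate_model_data(n = 590, seed = 62, year_effect = shift)
  fit <- fit_century_half(d, k_space = 10)
  expect_equal(fit$percent_change, 9, tolerance = 0.6)  # within ~5 points
  # null: contrast within 3 SE of zero for most seeds; check one
  d0 <- simulate_model_data(n = 590, seed = 63)
  fit0 <- fit_century_half(d0, k_space = 10)
  expect_lt(abs(fit0$half_coef), 3 * fit0$half_se)
})

test_that("year smooth is near-linear for linear truth and flat for flat truth", {
  d_flat <- simulate_model_data(n = 500, seed = 64)
  f_flat <- fit_year_smooth(d_flat, k_space = 10)
  expect_lt(f_flat$year_edf, 2.5)

  d_lin <- simulate_model_data(n = 500, seed = 65,
                               year_effect = function(y) 0.002 * (y - 1900))
  f_lin <- fit_year_smooth(d_lin, k_space = 10)
  pr <- predict_reference(f_lin, over = "year_scaled")
  line <- lm(fit_log ~ year_scaled, data = pr)
  expect_lt(max(abs(residuals(line))), 0.1 * diff(range(pr$fit_log)))
})

test_that("a post-1925 ramp is recovered as a rising year smooth", {
  ramp <- function(y) log(1.0881) * pmax(0, y - 1925) / 73
  d <- simulate_model_data(n = 590, seed = 66, year_effect = ramp)
  fit <- fit_year_smooth(d, k_space = 10)
  pr <- predict_reference(fit, over = "year_scaled", grid = c(26, 99))
  expect_gt(pr$fit_log[2], pr$fit_log[1])
  expect_gt(fit$year_edf, 1)
})

test_that("climate surface localises an injected warm-wet FA bump", {
  bump <- function(t, p) 0.2 * plogis((t - 9) / 0.25) * exp(-((p - 1000) / 250)^2 / 2)
  d <- simulate_model_data(n = 590, seed = 67, climate_effect = bump)
  fit <- fit_climate_surface(d, k_space = 10)
  expect_gt(fit$climate_edf, 1)
  surf <- predict_climate_surface(fit, n_grid = 25)
  top <- surf[which.max(surf$fa), ]
  expect_gt(top$mean_annual_temp, 8.5)
  expect_true(top$annual_precip > 600 && top$annual_precip < 1400)
  # hull masking: corners of the grid outside observed climate are NA
  expect_true(anyNA(surf$fa))
})

test_that("degenerate climate structure is rejected", {
  d <- simulate_model_data(n = 100, seed = 68)
  d$mean_annual_temp <- 9
  d$annual_precip <- 1000
  expect_error(fit_climate_surface(d), "degenerate climate")
})

test_that("nested model comparison behaves like an F-test on model variances", {
  d <- simulate_model_data(
    n = 600, seed = 69,
    species_offsets = c(hortorum = 0, lapidarius = 0.3,
                        muscorum = 0, pascuorum = 0.3))
  full <- fit_species_baseline(d, k_space = 10)
  reduced <- fit_species_baseline(d, k_space = 10, include_species = FALSE)
  cmp <- compare_models(full, reduced)
  expect_gte(cmp$df_full, cmp$df_reduced)
  expect_lt(cmp$p, 0.01)
  expect_lt(cmp$delta_aic, 0)  # full model preferred

  same <- compare_models(full, full)
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  half <- fit_century_half(d, k_space = 10)
  expect_error(compare_models(full, half), "not nested")
})

test_that("reference predictions match fitted values and widen where data are sparse", {
  d <- simulate_model_data(n = 400, seed = 70)
  fit <- fit_year_smooth(d, k_space = 10)
  # the reference-profile prediction equals an independently built newdata
  pr <- predict_reference(fit, over = "year_scaled", grid = 50)
  manual_nd <- data.frame(year_scaled = 50,
                          caste = factor("worker", levels = levels(d$caste)),
                          latitude = mean(d$latitude),
                          longitude = mean(d$longitude))
  expect_equal(pr$fit_log, unname(predict(fit$model, newdata = manual_nd)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # prediction at an observed data point's covariates equals its fitted value
  expect_equal(as.vector(predict(fit$model, newdata = fit$data[57, ])),
               unname(fitted(fit$model)[57]), tolerance = 1e-8)
  # bands are fit +/- 2 SE; FA columns are the exp back-transform
  curve <- predict_reference(fit, over = "year_scaled")
  expect_equal(curve$upper - curve$fit_log, 2 * curve$se)
  expect_equal(curve$fa, exp(curve$fit_log))
  # SE grows towards the sparse extremes of the year range
  expect_gt(curve$se[1], curve$se[50])
  expect_error(predict_reference(fit, caste = "soldier"), "unknown caste")
})

test_that("per-species percent change matches its arithmetic definition", {
  d <- data.frame(
    specimen_id = 1:8,
    species = rep(c("hortorum", "pascuorum"), each = 4),
    caste = "worker", latitude = 52, longitude = 0,
    year = rep(c(1920L, 1920L, 1960L, 1960L), 2),
    fa = c(0.04, 0.06, 0.055, 0.055, 0.03, 0.05, 0.044, 0.044))
  res <- percent_change_by_species(model_data(d))
  # hortorum: mean 0.05 -> 0.055 (+10%); pascuorum: 0.04 -> 0.044 (+10%)
  expect_equal(res$per_species$pct_change, c(10, 10), tolerance = 1e-10)
  expect_equal(res$mean, 10, tolerance = 1e-10)
})
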
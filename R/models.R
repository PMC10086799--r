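#' Assemble a model-ready data frame
#'
#' Builds the analysis table used by all trend models: natural-log FA
#' response, species and caste factors (reference levels *B. hortorum* and
#' worker), scaled year (`year - 1899`, so the intercept is the level at
#' the start of the century), century half (1900-1949 vs 1950-2000), a
#' year factor for random intercepts, coordinates and annual climate.
#'
#' @param records data frame with columns `specimen_id`, `fa` (or
#'   `log_fa`), `species`, `caste`, `year`, `latitude`, `longitude` and
#'   optionally `mean_annual_temp`, `annual_precip`.
#' @return data frame of class `wingfa_model_data`.
#' @export
model_data <- function(records) {
  d <- as.data.frame(records)
  if (is.null(d$log_fa)) {
    if (is.null(d$fa)) stop("records need an fa or log_fa column")
    if (any(d$fa <= 0, na.rm = TRUE)) stop("fa must be positive to log")
    d$log_fa <- log(d$fa)
  }
  for (col in c("species", "caste", "year", "latitude", "longitude")) {
    if (is.null(d[[col]])) stop("records need a ", col, " column")
  }
  sp_levels <- c("hortorum", "lapidarius", "muscorum", "pascuorum")
  d$species <- factor(as.character(d$species),
                      levels = union(sp_levels, unique(as.character(d$species))))
  d$species <- droplevels(d$species)
  caste_levels <- c("worker", "queen", "drone")
  d$caste <- factor(as.character(d$caste),
                    levels = union(caste_levels, unique(as.character(d$caste))))
  d$caste <- droplevels(d$caste)
  d$year <- as.integer(d$year)
  if (any(d$year < 1900 | d$year > 2000, na.rm = TRUE)) {
    warning("years outside 1900-2000 present")
  }
  d$year_scaled <- d$year - 1899L
  d$century_half <- factor(ifelse(d$year <= 1949, "first", "second"),
                           levels = c("first", "second"))
  d$year_f <- factor(d$year)
  if (is.null(d$mean_annual_temp)) d$mean_annual_temp <- NA_real_
  if (is.null(d$annual_precip)) d$annual_precip <- NA_real_
  class(d) <- c("wingfa_model_data", "data.frame")
  d
}

# Wrap an mgcv fit with the summaries the pipeline reports.
new_wingfa_fit <- function(model, family, data) {
  sm <- summary(model)
  structure(list(
    model = model, family = family,
    n = nrow(model$model),
    model_df = sum(model$edf),
    adj_r2 = sm$r.sq,
    parametric = as.data.frame(sm$p.table),
    smooths = if (length(sm$s.table)) as.data.frame(sm$s.table) else NULL,
    data = data
  ), class = "wingfa_fit")
}

#' @export
print.wingfa_fit <- function(x, ...) {
  cat("wingfa trend model:", x$family, "\n")
  cat("  n =", x$n, " model df =", round(x$model_df, 2),
      " adj R2 =", round(x$adj_r2, 3), "\n")
  cat("Parametric terms:\n")
  print(round(x$parametric, 4))
  if (!is.null(x$smooths)) {
    cat("Smooth terms:\n")
    print(round(x$smooths, 4))
  }
  invisible(x)
}

# Keep only usable factor terms: a factor with < 2 observed levels is
# dropped with a warning so the pipeline still runs on degenerate subsets.
usable_factor <- function(d, col) {
  ok <- nlevels(droplevels(d[[col]])) >= 2L
  if (!ok) warning("term '", col, "' dropped: fewer than 2 levels present")
  ok
}

#' Species-baseline GAMM
#'
#' Models log FA with species and caste intercepts, a global bivariate
#' smooth of latitude and longitude (penalised thin-plate spline), and
#' year-as-factor as a random intercept (ridge-penalised `bs = "re"`
#' term), smoothness selected by REML. Species contrasts are reported
#' against the reference species (*B. hortorum*).
#'
#' @param data a `wingfa_model_data` data frame.
#' @param k_space basis dimension of the spatial smooth (default 30).
#' @param include_species set `FALSE` to fit the nested model without
#'   species intercepts (for the species comparison F-test).
#' @return a `wingfa_fit`.
#' @export
fit_species_baseline <- function(data, k_space = 30, include_species = TRUE) {
  d <- droplevels(as.data.frame(data))
  terms <- character(0)
  if (include_species && usable_factor(d, "species")) terms <- c(terms, "species")
  if (usable_factor(d, "caste")) terms <- c(terms, "caste")
  terms <- c(terms, sprintf("s(latitude, longitude, k = %d)", k_space))
  if (nlevels(droplevels(d$year_f)) >= 2L) {
    terms <- c(terms, 's(year_f, bs = "re")')
  } else {
    warning("single year present: year random effect dropped")
  }
  f <- as.formula(paste("log_fa ~", paste(terms, collapse = " + ")))
  m <- mgcv::gam(f, data = d, method = "REML")
  new_wingfa_fit(m, "species_baseline", d)
}

#' Century-half GAM
#'
#' Models log FA with caste, a first-half vs second-half century contrast
#' and a global spatial smooth. The exponentiated contrast gives the
#' multiplicative change in FA between 1900-1949 and 1950-2000, reported
#' as `percent_change` = 100 (exp(beta) - 1).
#'
#' @inheritParams fit_species_baseline
#' @param include_half set `FALSE` for the nested model without the
#'   century-half term.
#' @return a `wingfa_fit` with extra elements `half_coef`, `half_se` and
#'   `percent_change`.
#' @export
fit_century_half <- function(data, k_space = 30, include_half = TRUE) {
  d <- droplevels(as.data.frame(data))
  terms <- character(0)
  if (usable_factor(d, "caste")) terms <- c(terms, "caste")
  if (include_half && usable_factor(d, "century_half")) {
    terms <- c(terms, "century_half")
  }
  terms <- c(terms, sprintf("s(latitude, longitude, k = %d)", k_space))
  f <- as.formula(paste("log_fa ~", paste(terms, collapse = " + ")))
  m <- mgcv::gam(f, data = d, method = "REML")
  fit <- new_wingfa_fit(m, "century_half", d)
  if ("century_halfsecond" %in% rownames(fit$parametric)) {
    beta <- fit$parametric["century_halfsecond", "Estimate"]
    fit$half_coef <- beta
    fit$half_se <- fit$parametric["century_halfsecond", "Std. Error"]
    fit$percent_change <- 100 * (exp(beta) - 1)
  }
  fit
}

#' Nonlinear year-trend GAM
#'
#' Models log FA with caste, one global penalised smooth of scaled year
#' and a global spatial smooth, exposing the smooth's effective degrees of
#' freedom, F and p. Use [predict_reference()] to obtain the fitted trend
#' (with 2 SE band) for a worker at mean coordinates.
#'
#' @inheritParams fit_species_baseline
#' @param k_year basis dimension of the year smooth (default 10; shrunk
#'   with a warning when fewer unique years are available).
#' @return a `wingfa_fit` with extra elements `year_edf`, `year_F`,
#'   `year_p`.
#' @export
fit_year_smooth <- function(data, k_year = 10, k_space = 30) {
  d <- droplevels(as.data.frame(data))
  n_years <- length(unique(d$year_scaled))
  if (n_years < 10L) stop("year smooth needs >= 10 distinct years")
  if (k_year > n_years - 1L) {
    warning("year basis shrunk to ", n_years - 1L, " (few unique years)")
    k_year <- n_years - 1L
  }
  terms <- character(0)
  if (usable_factor(d, "caste")) terms <- c(terms, "caste")
  terms <- c(terms, sprintf("s(year_scaled, k = %d)", k_year),
             sprintf("s(latitude, longitude, k = %d)", k_space))
  f <- as.formula(paste("log_fa ~", paste(terms, collapse = " + ")))
  m <- mgcv::gam(f, data = d, method = "REML")
  fit <- new_wingfa_fit(m, "year_smooth", d)
  srow <- grep("year_scaled", rownames(fit$smooths))
  fit$year_edf <- fit$smooths[srow, "edf"]
  fit$year_F <- fit$smooths[srow, "F"]
  fit$year_p <- fit$smooths[srow, "p-value"]
  fit
}

#' Temperature x precipitation surface GAMM
#'
#' Models log FA with caste, a 2D tensor-product smooth of mean annual
#' temperature and total annual precipitation (cubic marginal bases), a
#' global spatial smooth, and year-as-factor random intercepts. Fitted on
#' the subset of records with climate data (series start 1910).
#'
#' @inheritParams fit_species_baseline
#' @param k_climate marginal basis dimensions of the tensor smooth
#'   (default c(5, 5)).
#' @param include_climate set `FALSE` for the nested model without the
#'   tensor smooth.
#' @return a `wingfa_fit` with extra elements `climate_edf`, `climate_F`,
#'   `climate_p`.
#' @export
fit_climate_surface <- function(data, k_climate = c(5, 5), k_space = 30,
                                include_climate = TRUE) {
  d <- as.data.frame(data)
  d <- d[complete.cases(d$mean_annual_temp, d$annual_precip), , drop = FALSE]
  d <- droplevels(d)
  if (nrow(d) < 30L) stop("too few records with climate data")
  if (length(unique(paste(d$mean_annual_temp, d$annual_precip))) < 5L) {
    stop("degenerate climate: too few distinct (temperature, precipitation) cells")
  }
  if (abs(cor(d$mean_annual_temp, d$annual_precip)) > 0.99) {
    warning("temperature and precipitation are near-collinear")
  }
  terms <- character(0)
  if (usable_factor(d, "caste")) terms <- c(terms, "caste")
  if (include_climate) {
    terms <- c(terms, sprintf(
      "te(mean_annual_temp, annual_precip, k = c(%d, %d))",
      k_climate[1], k_climate[2]))
  }
  terms <- c(terms, sprintf("s(latitude, longitude, k = %d)", k_space))
  if (nlevels(droplevels(d$year_f)) >= 2L) {
    terms <- c(terms, 's(year_f, bs = "re")')
  }
  f <- as.formula(paste("log_fa ~", paste(terms, collapse = " + ")))
  m <- mgcv::gam(f, data = d, method = "REML")
  fit <- new_wingfa_fit(m, "climate_surface", d)
  srow <- grep("te\\(", rownames(fit$smooths))
  if (length(srow) == 1L) {
    fit$climate_edf <- fit$smooths[srow, "edf"]
    fit$climate_F <- fit$smooths[srow, "F"]
    fit$climate_p <- fit$smooths[srow, "p-value"]
  }
  fit
}

#' Compare nested trend models with an F-test
#'
#' Compares a full and a nested reduced model by referring the change in
#' residual sum of squares per model degree of freedom to the F
#' distribution, the classical variance-ratio comparison for (penalised)
#' regression models; model degrees of freedom are the summed effective
#' degrees of freedom of all terms. The AIC difference (full - reduced)
#' is reported alongside.
#'
#' @param full,reduced `wingfa_fit` objects on the same data rows, reduced
#'   nested in full.
#' @return list with `df_full`, `df_reduced`, `F`, `p`, `delta_aic`.
#' @export
compare_models <- function(full, reduced) {
  stopifnot(inherits(full, "wingfa_fit"), inherits(reduced, "wingfa_fit"))
  if (full$n != reduced$n) stop("models fitted to different data")
  tf <- attr(terms(formula(full$model)), "term.labels")
  tr <- attr(terms(formula(reduced$model)), "term.labels")
  if (!all(tr %in% tf)) {
    stop("models are not nested: reduced has terms absent from full")
  }
  rss_f <- sum(residuals(full$model)^2)
  rss_r <- sum(residuals(reduced$model)^2)
  df_f <- full$model_df
  df_r <- reduced$model_df
  ddf <- df_f - df_r
  if (ddf <= .Machine$double.eps^0.5) {
    return(list(df_full = df_f, df_reduced = df_r, F = 0, p = 1,
                delta_aic = AIC(full$model) - AIC(reduced$model)))
  }
  n <- full$n
  f_stat <- ((rss_r - rss_f) / ddf) / (rss_f / (n - df_f))
  f_stat <- max(f_stat, 0)
  list(df_full = df_f, df_reduced = df_r, F = f_stat,
       p = pf(f_stat, ddf, n - df_f, lower.tail = FALSE),
       delta_aic = AIC(full$model) - AIC(reduced$model))
}

#' Predictions at a reference covariate profile
#'
#' Deterministic predictions from a fitted trend model over a grid of one
#' covariate, holding the rest at a reference profile: caste worker (by
#' default), latitude and longitude at their data means, species at the
#' reference level, and year random effects excluded. The band is the fit
#' +/- 2 standard errors; `fa` columns hold the exponential
#' back-transform to the FA scale.
#'
#' @param fit a `wingfa_fit`.
#' @param over name of the covariate to vary.
#' @param grid values of `over` (default: 100 points across the observed
#'   range; extrapolation requires passing an explicit grid and
#'   `extrapolate = TRUE`).
#' @param caste caste level for the profile (default "worker").
#' @param extrapolate allow grid values outside the observed range.
#' @return data frame with the grid, `fit_log`, `se`, `lower`, `upper`
#'   (log scale) and `fa`, `fa_lower`, `fa_upper` (FA scale).
#' @export
predict_reference <- function(fit, over = "year_scaled", grid = NULL,
                              caste = "worker", extrapolate = FALSE) {
  stopifnot(inherits(fit, "wingfa_fit"))
  d <- fit$data
  if (!caste %in% levels(d$caste)) stop("unknown caste level: ", caste)
  obs <- d[[over]]
  if (is.null(grid)) {
    grid <- seq(min(obs), max(obs), length.out = 100)
  } else if (!extrapolate && (min(grid) < min(obs) || max(grid) > max(obs))) {
    stop("grid extends outside the observed range of ", over,
         " (set extrapolate = TRUE to allow)")
  }
  nd <- data.frame(grid)
  names(nd) <- over
  nd$caste <- factor(caste, levels = levels(d$caste))
  if (!is.null(d$species) && is.factor(d$species) && !(over == "species")) {
    nd$species <- factor(levels(d$species)[1], levels = levels(d$species))
  }
  for (v in c("latitude", "longitude", "year_scaled",
              "mean_annual_temp", "annual_precip")) {
    if (!(v %in% names(nd)) && v %in% names(d)) nd[[v]] <- mean(d[[v]], na.rm = TRUE)
  }
  if (!is.null(d$century_half) && !("century_half" %in% names(nd))) {
    nd$century_half <- factor(levels(d$century_half)[1],
                              levels = levels(d$century_half))
  }
  excl <- NULL
  if (!is.null(d$year_f) && !("year_f" %in% names(nd))) {
    nd$year_f <- factor(levels(d$year_f)[1], levels = levels(d$year_f))
    if (any(grepl("year_f", rownames(fit$smooths %||% data.frame())))) {
      excl <- "s(year_f)"
    }
  }
  pr <- predict(fit$model, newdata = nd, se.fit = TRUE, exclude = excl,
                newdata.guaranteed = TRUE)
  out <- nd
  out$fit_log <- as.vector(pr$fit)
  out$se <- as.vector(pr$se.fit)
  out$lower <- out$fit_log - 2 * out$se
  out$upper <- out$fit_log + 2 * out$se
  out$fa <- exp(out$fit_log)
  out$fa_lower <- exp(out$lower)
  out$fa_upper <- exp(out$upper)
  out
}

#' Predicted FA surface over the climate plane
#'
#' Evaluates a climate-surface fit on a temperature x precipitation grid
#' at the reference profile, masking grid cells outside the convex hull of
#' the observed climate values (where the tensor smooth would
#' extrapolate).
#'
#' @param fit a `wingfa_fit` from [fit_climate_surface()].
#' @param n_grid grid resolution per axis (default 30).
#' @param caste caste level for the profile.
#' @return data frame with `mean_annual_temp`, `annual_precip`, predicted
#'   `fa` and log-scale `fit_log`, `se`; `inside_hull` flags supported
#'   cells (predictions outside are NA).
#' @export
predict_climate_surface <- function(fit, n_grid = 30, caste = "worker") {
  d <- fit$data
  tg <- seq(min(d$mean_annual_temp), max(d$mean_annual_temp),
            length.out = n_grid)
  pg <- seq(min(d$annual_precip), max(d$annual_precip), length.out = n_grid)
  grid <- expand.grid(mean_annual_temp = tg, annual_precip = pg)
  hull_idx <- chull(d$mean_annual_temp, d$annual_precip)
  hull <- cbind(d$mean_annual_temp[hull_idx], d$annual_precip[hull_idx])
  inside <- vapply(seq_len(nrow(grid)), function(i)
    point_in_polygon(grid$mean_annual_temp[i], grid$annual_precip[i], hull),
    TRUE)
  nd <- grid
  nd$caste <- factor(caste, levels = levels(d$caste))
  nd$latitude <- mean(d$latitude)
  nd$longitude <- mean(d$longitude)
  nd$year_f <- factor(levels(d$year_f)[1], levels = levels(d$year_f))
  excl <- if (any(grepl("year_f", rownames(fit$smooths %||% data.frame()))))
    "s(year_f)" else NULL
  pr <- predict(fit$model, newdata = nd, se.fit = TRUE, exclude = excl,
                newdata.guaranteed = TRUE)
  grid$fit_log <- ifelse(inside, as.vector(pr$fit), NA_real_)
  grid$se <- ifelse(inside, as.vector(pr$se.fit), NA_real_)
  grid$fa <- exp(grid$fit_log)
  grid$inside_hull <- inside
  grid
}

#' Descriptive per-species percent change in FA between century halves
#'
#' Computes 100 (mean second-half FA - mean first-half FA) / mean
#' first-half FA on the raw FA scale per species, then averages across
#' species (mean +/- SE across the per-species changes).
#'
#' @param data a `wingfa_model_data` data frame with `fa`.
#' @return list with `per_species` data frame, `mean` and `se`.
#' @export
percent_change_by_species <- function(data) {
  d <- as.data.frame(data)
  if (is.null(d$fa)) d$fa <- exp(d$log_fa)
  per <- lapply(split(d, droplevels(d$species)), function(s) {
    m1 <- mean(s$fa[s$century_half == "first"])
    m2 <- mean(s$fa[s$century_half == "second"])
    data.frame(species = s$species[1], pct_change = 100 * (m2 - m1) / m1)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  ok <- is.finite(per$pct_change)
  list(per_species = per, mean = mean(per$pct_change[ok]),
       se = sd(per$pct_change[ok]) / sqrt(sum(ok)))
}
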
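#' The 13-landmark forewing template
#'
#' Fixed wing-like template of the 13 homologous vein-junction landmarks,
#' stored as a packaged plain-text fixture. Landmark 1 is the most
#' proximal (wing base), landmark 13 the most distal (wing tip), matching
#' the wing-angle convention of the quality filters.
#'
#' @return 13 x 2 numeric matrix of (x, y) coordinates in arbitrary units.
#' @export
wing_template <- function() {
  path <- system.file("extdata", "wing_template_13.csv", package = "wingfa")
  tmpl <- as.matrix(utils::read.csv(path)[, c("x", "y")])
  dimnames(tmpl) <- NULL
  tmpl
}

# Synthetic-region bounding boxes and climate normals shared by the
# generator and the packaged synthetic geometry.
region_info <- function() {
  data.frame(
    region = climate_regions(),
    lat_min = c(52.2, 53.5, 53.5, 49.8, 52.2, 49.8, 55.5, 57.0, 55.5),
    lat_max = c(53.5, 55.5, 55.5, 52.2, 53.5, 52.2, 57.0, 58.8, 58.8),
    lon_min = c(-0.5, -2.2, -6.5, -1.5, -6.5, -6.5, -4.0, -4.0, -6.5),
    lon_max = c(1.8, 1.8, -2.2, 1.8, -0.5, -1.5, 1.8, 1.8, -4.0),
    base_temp = c(9.7, 8.8, 8.9, 10.0, 9.2, 10.2, 7.9, 7.0, 7.9),
    base_precip = c(610, 840, 1180, 780, 760, 1150, 850, 1290, 1550),
    stringsAsFactors = FALSE
  )
}

#' Simulation parameters for the landmark-level generator
#'
#' Bundles the generative assumptions of the asymmetry analysis: a
#' symmetric mean wing, isotropic individual shape variation, a consistent
#' directional-asymmetry displacement, per-individual fluctuating
#' asymmetry whose magnitude (drawn |N(0, sigma)| in Procrustes units) can
#' be modulated by species, year and climate, digitisation error per
#' replicate, and image-level nuisance transforms (tilt with out-of-plane
#' foreshortening, scale, translation).
#'
#' @param n_specimens number of specimens.
#' @param mean_wing 13 x 2 template matrix.
#' @param species_probs,caste_probs,region_probs,month_probs,year_weights
#'   named sampling weights for the metadata marginals.
#' @param sigma_individual SD of isotropic landmark noise for individual
#'   shape variation (Procrustes units per coordinate).
#' @param da_length directional-asymmetry displacement length (Procrustes
#'   units; a fixed tangent direction shared by all specimens).
#' @param sigma_fa_base baseline SD of the fluctuating-asymmetry magnitude
#'   (Procrustes units).
#' @param fa_species_effect named multipliers of `sigma_fa_base` per
#'   species.
#' @param fa_year_effect function(year) -> multiplier.
#' @param fa_climate_effect function(temp, precip) -> multiplier.
#' @param sigma_measurement SD of digitisation noise per coordinate per
#'   replicate (Procrustes units).
#' @param tilt_sd SD of wing tilt in degrees (drives both the in-plane
#'   angle and the out-of-plane cos(tilt) foreshortening artifact).
#' @param replicates_per_side digitisation replicates per wing.
#' @param years candidate collection years.
#' @param fa_fixed optional fixed FA magnitude (Procrustes units) given to
#'   every specimen instead of the |N(0, sigma)| draw; used for exact
#'   construction checks.
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `wingfa_sim_params`.
#' @export
sim_params <- function(
    n_specimens = 200L,
    mean_wing = wing_template(),
    species_probs = c(hortorum = 0.196, lapidarius = 0.245,
                      muscorum = 0.153, pascuorum = 0.406),
    caste_probs = c(worker = 0.5, queen = 0.3, drone = 0.2),
    region_probs = setNames(rep(1 / 9, 9), climate_regions()),
    month_probs = setNames(c(1, 2, 4, 6, 7, 6, 4, 2, 1) / 33, 3:11),
    year_weights = NULL,
    sigma_individual = 0.02,
    da_length = 0.01,
    sigma_fa_base = 0.056,
    fa_species_effect = c(hortorum = 1, lapidarius = 1, muscorum = 1,
                          pascuorum = 1),
    fa_year_effect = function(year) rep(1, length(year)),
    fa_climate_effect = function(temp, precip) rep(1, length(temp)),
    sigma_measurement = 0.002,
    tilt_sd = 5,
    replicates_per_side = 2L,
    years = 1900:2000,
    fa_fixed = NULL,
    seed = 1L) {
  if (is.null(year_weights)) year_weights <- setNames(rep(1, length(years)), years)
  stopifnot(sigma_individual >= 0, sigma_fa_base >= 0,
            sigma_measurement >= 0, tilt_sd >= 0, da_length >= 0,
            replicates_per_side >= 1L)
  if (sum(year_weights) <= 0) stop("year weights sum to zero")
  structure(list(
    n_specimens = as.integer(n_specimens), mean_wing = mean_wing,
    species_probs = species_probs, caste_probs = caste_probs,
    region_probs = region_probs, month_probs = month_probs,
    year_weights = year_weights, sigma_individual = sigma_individual,
    da_length = da_length, sigma_fa_base = sigma_fa_base,
    fa_species_effect = fa_species_effect,
    fa_year_effect = fa_year_effect,
    fa_climate_effect = fa_climate_effect,
    sigma_measurement = sigma_measurement, tilt_sd = tilt_sd,
    replicates_per_side = as.integer(replicates_per_side),
    years = years, fa_fixed = fa_fixed, seed = as.integer(seed)
  ), class = "wingfa_sim_params")
}

# Orthonormal tangent basis killing translation (v1, v2), scale (shape) and
# rotation (90-degree rotated shape) directions at a unit-size centred shape.
tangent_project <- function(vec, shape) {
  k <- nrow(shape)
  basis <- cbind(
    c(rep(1 / sqrt(k), k), rep(0, k)),
    c(rep(0, k), rep(1 / sqrt(k), k)),
    as.vector(shape),
    as.vector(cbind(-shape[, 2], shape[, 1]))
  )
  v <- as.vector(vec)
  for (j in seq_len(ncol(basis))) {
    b <- basis[, j] / sqrt(sum(basis[, j]^2))
    v <- v - sum(v * b) * b
  }
  matrix(v, k, 2)
}

# Unit tangent direction from N(0,1) draws.
random_tangent <- function(shape) {
  u <- tangent_project(matrix(rnorm(2 * nrow(shape)), ncol = 2), shape)
  u / sqrt(sum(u^2))
}

#' Synthetic annual regional climate table
#'
#' Generates mean annual temperature and total annual precipitation per
#' climate region and year around region normals, with a gentle
#' century-scale warming trend and interannual noise.
#'
#' @param years years to cover (series starts 1910 as in the real series).
#' @param seed integer seed.
#' @return data frame with `region`, `year`, `mean_annual_temp`,
#'   `annual_precip`.
#' @export
simulate_climate_table <- function(years = 1910:2000, seed = 1L) {
  years <- years[years >= 1910]
  info <- region_info()
  with_local_seed(group_seed(seed, "climate"), {
    grid <- expand.grid(region = info$region, year = years,
                        stringsAsFactors = FALSE)
    idx <- match(grid$region, info$region)
    grid$mean_annual_temp <- info$base_temp[idx] +
      0.006 * (grid$year - 1955) + rnorm(nrow(grid), 0, 0.45)
    grid$annual_precip <- info$base_precip[idx] *
      exp(rnorm(nrow(grid), 0, 0.08))
    grid[order(grid$region, grid$year), ]
  })
}

#' Simulate a landmark dataset with known ground truth
#'
#' Generates, per specimen: a true shape (template plus isotropic
#' individual variation, normalised to unit centroid size); a right wing
#' displaced by half the directional-asymmetry vector plus half the
#' individual FA displacement; a left wing displaced oppositely and then
#' mirrored; and, per digitisation replicate, raw image coordinates
#' produced by adding digitisation noise and applying wing tilt
#' (out-of-plane foreshortening cos(tilt) on one axis plus an in-plane
#' rotation by the tilt angle), random scale and translation.
#'
#' The FA displacement is drawn with total Procrustes length |N(0,
#' sigma_fa_i)| where sigma_fa_i = sigma_fa_base x species x year x
#' climate multipliers; its direction is an isotropic draw projected into
#' the tangent space orthogonal to translation, scale and rotation of the
#' individual's shape, with the length corrected so that the matched-pair
#' Procrustes distance between the normalised mirrored-left and right
#' shapes equals the drawn magnitude exactly (see the methods vignette).
#'
#' @param params a `wingfa_sim_params` object.
#' @return list with `configs` (TPS-ready raw configurations), `metadata`
#'   (specimen table), `climate` (annual regional table), `truth`
#'   (per-specimen ground truth: injected FA magnitude, tilts, group
#'   assignments) and `params`.
#' @export
simulate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "wingfa_sim_params"))
  info <- region_info()
  climate <- simulate_climate_table(seed = params$seed)
  with_local_seed(group_seed(params$seed, "dataset"), {
    n <- params$n_specimens
    template <- center_and_scale(params$mean_wing)$coords
    k <- nrow(template)
    u_da <- random_tangent(template)

    species <- sample(names(params$species_probs), n, replace = TRUE,
                      prob = params$species_probs)
    caste <- sample(names(params$caste_probs), n, replace = TRUE,
                    prob = params$caste_probs)
    region <- sample(names(params$region_probs), n, replace = TRUE,
                     prob = params$region_probs)
    month <- as.integer(sample(names(params$month_probs), n, replace = TRUE,
                               prob = params$month_probs))
    year <- as.integer(sample(names(params$year_weights), n, replace = TRUE,
                              prob = params$year_weights))
    day <- sample.int(28L, n, replace = TRUE)
    ridx <- match(region, info$region)
    lat <- runif(n, info$lat_min[ridx] + 0.1, info$lat_max[ridx] - 0.1)
    lon <- runif(n, info$lon_min[ridx] + 0.1, info$lon_max[ridx] - 0.1)
    clim_hit <- match(paste(region, year), paste(climate$region, climate$year))
    temp <- climate$mean_annual_temp[clim_hit]
    precip <- climate$annual_precip[clim_hit]

    sp_mult <- params$fa_species_effect[species]
    if (anyNA(sp_mult)) stop("fa_species_effect missing a species multiplier")
    yr_mult <- params$fa_year_effect(year)
    cl_mult <- ifelse(is.na(temp), 1, params$fa_climate_effect(
      ifelse(is.na(temp), 0, temp), ifelse(is.na(precip), 0, precip)))
    sigma_fa <- params$sigma_fa_base * sp_mult * yr_mult * cl_mult

    ids <- sprintf("sp%04d", seq_len(n))
    configs <- list()
    fa_true <- numeric(n)
    tilt_l <- tilt_r <- numeric(n)
    for (i in seq_len(n)) {
      true_shape <- template +
        matrix(rnorm(2 * k, 0, params$sigma_individual), k, 2)
      true_shape <- center_and_scale(true_shape)$coords
      m <- if (!is.null(params$fa_fixed)) params$fa_fixed else
        abs(rnorm(1, 0, sigma_fa[i]))
      m <- min(m, 1.5)  # keep the half-angle correction defined
      u <- random_tangent(true_shape)
      delta <- u * (m / 2) / sqrt(1 - m^2 / 4)
      da <- if (params$da_length > 0)
        tangent_project(u_da, true_shape) * (params$da_length / 2) else 0
      right_shape <- true_shape + delta + da
      left_shape <- reflect_coords(true_shape - delta - da)
      fa_true[i] <- m
      tilt_l[i] <- rnorm(1, 0, params$tilt_sd)
      tilt_r[i] <- rnorm(1, 0, params$tilt_sd)
      for (side in c("left", "right")) {
        shape <- if (side == "left") left_shape else right_shape
        tilt <- if (side == "left") tilt_l[i] else tilt_r[i]
        theta <- tilt * pi / 180
        fore <- diag(c(1, cos(theta)))
        rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
        s <- runif(1, 80, 120)
        b <- runif(2, 100, 900)
        for (rep_ in seq_len(params$replicates_per_side)) {
          noisy <- shape + matrix(rnorm(2 * k, 0, params$sigma_measurement), k, 2)
          raw <- s * (noisy %*% t(fore) %*% t(rot))
          raw <- sweep(raw, 2, b, `+`)
          configs[[length(configs) + 1L]] <- list(
            specimen_id = ids[i], side = side, replicate = rep_,
            coords = raw, scale = 1 / s,
            image = sprintf("%s_%s_%d.jpg", ids[i],
                            toupper(substr(side, 1, 1)), rep_),
            id = sprintf("%s_%s_%d", ids[i],
                         toupper(substr(side, 1, 1)), rep_)
          )
        }
      }
    }
    metadata <- data.frame(
      specimen_id = ids, species = species, caste = caste,
      date = sprintf("%04d-%02d-%02d", year, month, day),
      latitude = lat, longitude = lon,
      museum = sample(c("NHM London", "NMS Edinburgh", "OUMNH Oxford",
                        "Tullie House", "World Museum"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      specimen_id = ids, species = species, caste = caste, year = year,
      month = month, climate_region = region,
      fa_true = fa_true, sigma_fa = sigma_fa,
      tilt_left = tilt_l, tilt_right = tilt_r,
      mean_annual_temp = temp, annual_precip = precip,
      stringsAsFactors = FALSE
    )
    list(configs = configs, metadata = metadata, climate = climate,
         truth = truth, params = params)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the exact dialects the ingest stage reads: a TPS file of all
#' digitisations, a tab-delimited metadata table and a CSV climate table.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tps(sim$configs, file.path(dir, "landmarks.tps"))
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(sim$climate, file.path(dir, "climate.csv"), row.names = FALSE)
  write.csv(sim$truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Century-scale study scenario
#'
#' Canned parameterisation emulating the museum study conditions: 590
#' specimens of four species with species-specific baseline FA (higher in
#' the two range-expanding species), an FA ramp beginning in 1925 and
#' reaching about +9 percent by the late century, an FA bump under warm
#' (> 9 degrees C) years with intermediate rainfall (750-1250 mm), wing
#' tilt artifacts, two digitisation replicates per wing, and a few
#' heavily collected years to exercise the rarefaction cap.
#'
#' @param seed integer seed.
#' @return a `wingfa_sim_params` object.
#' @export
century_scale_scenario <- function(seed = 1L) {
  years <- 1900:2000
  yw <- setNames(rep(1, length(years)), years)
  yw[as.character(c(1912, 1938, 1960, 1985))] <- 8  # heavy collection years
  sim_params(
    n_specimens = 590L,
    year_weights = yw,
    fa_species_effect = c(hortorum = 1.000, lapidarius = 1.131,
                          muscorum = 0.993, pascuorum = 1.124),
    fa_year_effect = function(year)
      exp(log(1.0881) * pmax(0, year - 1925) / (1998 - 1925)),
    fa_climate_effect = function(temp, precip)
      exp(0.30 * stats::plogis((temp - 9) / 0.25) *
            exp(-((precip - 1000) / 250)^2 / 2)),
    tilt_sd = 5,
    seed = seed
  )
}

#' Simulate model-ready FA data with known effects
#'
#' Generates the analysis table directly on the log-FA scale (lognormal
#' FA), bypassing the landmark level, for studying the trend models'
#' parameter recovery and error rates: log FA = baseline + species +
#' caste + year effect + climate effect + Gaussian residual. The residual
#' SD default (0.26) matches the dispersion implied by the reported
#' uncertainty of century-half FA changes in collections of this size.
#'
#' @param n number of specimens (default 590).
#' @param seed integer seed.
#' @param baseline_log_fa intercept: log FA of the reference species.
#' @param species_offsets named log-scale offsets per species.
#' @param caste_offsets named log-scale offsets per caste.
#' @param year_effect function(year) -> log-scale additive effect.
#' @param climate_effect function(temp, precip) -> log-scale additive
#'   effect.
#' @param sigma_log residual SD on the log scale.
#' @param years candidate years.
#' @return a `wingfa_model_data` data frame with `fa_expected` (the
#'   noise-free log FA) kept as ground truth.
#' @export
simulate_model_data <- function(
    n = 590L, seed = 1L,
    baseline_log_fa = log(0.0411),
    species_offsets = c(hortorum = 0, lapidarius = 0.123,
                        muscorum = -0.007, pascuorum = 0.118),
    caste_offsets = c(worker = 0, queen = 0.03, drone = -0.03),
    year_effect = function(year) rep(0, length(year)),
    climate_effect = function(temp, precip) rep(0, length(temp)),
    sigma_log = 0.26,
    years = 1900:2000) {
  info <- region_info()
  climate <- simulate_climate_table(years = years, seed = seed)
  with_local_seed(group_seed(seed, "model_data"), {
    species <- sample(names(species_offsets), n, replace = TRUE,
                      prob = c(0.196, 0.245, 0.153, 0.406)[
                        seq_along(species_offsets)])
    caste <- sample(names(caste_offsets), n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2)[seq_along(caste_offsets)])
    region <- sample(info$region, n, replace = TRUE)
    year <- sample(years, n, replace = TRUE)
    month <- sample(3:11, n, replace = TRUE)
    ridx <- match(region, info$region)
    lat <- runif(n, info$lat_min[ridx] + 0.1, info$lat_max[ridx] - 0.1)
    lon <- runif(n, info$lon_min[ridx] + 0.1, info$lon_max[ridx] - 0.1)
    hit <- match(paste(region, year), paste(climate$region, climate$year))
    temp <- climate$mean_annual_temp[hit]
    precip <- climate$annual_precip[hit]
    mu <- baseline_log_fa + species_offsets[species] +
      caste_offsets[caste] + year_effect(year) +
      ifelse(is.na(temp), 0, climate_effect(
        ifelse(is.na(temp), 0, temp), ifelse(is.na(precip), 0, precip)))
    log_fa <- mu + rnorm(n, 0, sigma_log)
    d <- data.frame(
      specimen_id = sprintf("sp%04d", seq_len(n)),
      species = species, caste = caste, year = year, month = month,
      climate_region = region, latitude = lat, longitude = lon,
      mean_annual_temp = temp, annual_precip = precip,
      fa = exp(log_fa), fa_expected = unname(mu),
      stringsAsFactors = FALSE
    )
    model_data(d)
  })
}

#' Simulate a landmarker-repeatability study
#'
#' Repeated digitisations of the same images by multiple collectors over
#' sessions, with optional collector bias: each digitisation by the biased
#' collector is displaced by a tangent vector of the given Procrustes
#' length (fresh direction per digitisation), on top of shared
#' digitisation noise, raising that collector's expected distance to the
#' image mean shape by about the bias length.
#'
#' @param n_images number of images (default 20).
#' @param n_sessions sessions per collector (default 4).
#' @param collectors collector labels.
#' @param bias Procrustes-length displacement applied to the second
#'   collector's digitisations (default 0).
#' @param sigma_measurement digitisation noise SD per coordinate.
#' @param seed integer seed.
#' @return list of configurations suitable for
#'   [landmarker_repeatability()].
#' @export
simulate_repeatability <- function(n_images = 20L, n_sessions = 4L,
                                   collectors = c("A", "B"), bias = 0,
                                   sigma_measurement = 0.002, seed = 1L) {
  template <- center_and_scale(wing_template())$coords
  k <- nrow(template)
  with_local_seed(group_seed(seed, "repeatability"), {
    configs <- list()
    for (img in seq_len(n_images)) {
      shape <- center_and_scale(
        template + matrix(rnorm(2 * k, 0, 0.02), k, 2))$coords
      for (coll in collectors) {
        for (ses in seq_len(n_sessions)) {
          xy <- shape + matrix(rnorm(2 * k, 0, sigma_measurement), k, 2)
          if (coll == collectors[2] && bias > 0) {
            xy <- xy + random_tangent(shape) * bias
          }
          configs[[length(configs) + 1L]] <- list(
            specimen_id = sprintf("img%03d", img), side = "right",
            replicate = ses, collector = coll, session = ses,
            coords = xy, scale = NA_real_,
            image = sprintf("img%03d.jpg", img),
            id = sprintf("img%03d_R_%d_%s", img, ses, coll)
          )
        }
      }
    }
    configs
  })
}
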
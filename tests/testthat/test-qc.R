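test_that("shape outlier filter removes specimens with a wing above the pooled Q3", {
  # 20 specimens, one constructed far from the consensus on one wing
  p <- sim_params(n_specimens = 20, sigma_individual = 0.01,
                  sigma_measurement = 0, tilt_sd = 0, seed = 40)
  sim <- simulate_dataset(p)
  # corrupt one left wing of one specimen
  for (i in seq_along(sim$configs)) {
    if (sim$configs[[i]]$specimen_id == "sp0001" &&
        sim$configs[[i]]$side == "left") {
      sim$configs[[i]]$coords <- sim$configs[[i]]$coords +
        matrix(rnorm(26, 0, 30), 13, 2)
    }
  }
  al <- gpa(sim$configs, reflect_side = "left")
  res <- shape_outlier_filter(al)
  expect_false("sp0001" %in% res$kept)
  # threshold is the type-7 upper quartile of the pooled wing distances
  expect_equal(res$report$threshold,
               quantile(res$distances$distance, 0.75, type = 7, names = FALSE))
  removed <- unique(res$distances$specimen_id[
    res$distances$distance > res$report$threshold])
  expect_setequal(setdiff(unique(al$info$specimen_id), res$kept), removed)
  expect_equal(res$report$n_in - res$report$n_removed, length(res$kept))
})

test_that("equidistant wings yield no strict outliers", {
  # an orbit of one shape: every wing at (numerically) zero distance
  tmpl <- wing_template()
  configs <- list()
  for (i in 1:4) for (s in c("left", "right")) {
    xy <- if (s == "left") reflect_coords(tmpl) else tmpl
    configs[[length(configs) + 1L]] <- list(
      specimen_id = sprintf("s%d", i), side = s, replicate = 1L, coords = xy)
  }
  al <- gpa(configs, reflect_side = "left")
  res <- shape_outlier_filter(al)
  expect_length(res$kept, 4L)
})

test_that("wing angles follow the base-to-tip vector with left wings mirrored", {
  coords <- matrix(0, 13, 2)
  coords[13, ] <- c(1, 0)
  expect_equal(wing_angle(list(coords = coords, side = "right",
                               specimen_id = "x")), 0)
  coords[13, ] <- c(0, 1)
  expect_equal(wing_angle(list(coords = coords, side = "right",
                               specimen_id = "x")), 90)
  # a left wing is mirrored before the angle is taken
  left <- list(coords = reflect_coords(coords), side = "left",
               specimen_id = "x")
  expect_equal(wing_angle(left), 90)
  expect_error(wing_angle(list(coords = matrix(0, 13, 2), side = "right",
                               specimen_id = "x")), "coincide")
})

test_that("a constructed 7-degree tilt shows up as a 7-degree differential", {
  tmpl <- wing_template()
  rot7 <- matrix(c(cos(7 * pi / 180), sin(7 * pi / 180),
                   -sin(7 * pi / 180), cos(7 * pi / 180)), 2, 2)
  base <- tmpl[1, ]
  left_raw <- reflect_coords(sweep(sweep(tmpl, 2, base) %*% t(rot7), 2, base, `+`))
  pairs <- list(spA = list(
    left = list(list(coords = left_raw, side = "left", specimen_id = "spA")),
    right = list(list(coords = tmpl, side = "right", specimen_id = "spA"))))
  tab <- wing_angle_table(pairs)
  expect_equal(tab$differential, 7, tolerance = 1e-6)
})

test_that("angle differential filter applies the Q3 + IQR rule strictly", {
  angles <- data.frame(specimen_id = paste0("s", 1:5),
                       angle_left = 0, angle_right = 0,
                       differential = c(1, 2, 3, 4, 100))
  res <- angle_differential_filter(angles)
  expect_equal(res$report$threshold, 6)  # Q3 = 4, IQR = 2 (type 7)
  expect_setequal(res$kept, paste0("s", 1:4))

  same <- data.frame(specimen_id = paste0("s", 1:6),
                     angle_left = 0, angle_right = 0, differential = 5)
  expect_length(angle_differential_filter(same)$kept, 6L)
  expect_error(angle_differential_filter(angles[1:3, ]), "at least 4")
})

test_that("injected tilt inflates FA, correlates with the differential, and the filter helps", {
  p <- sim_params(n_specimens = 80, tilt_sd = 8, sigma_measurement = 0.001,
                  sigma_fa_base = 0.03, seed = 41)
  sim <- simulate_dataset(p)
  paired <- pair_wings(sim$configs, sim$metadata)
  al <- gpa(sim$configs, reflect_side = "left")
  fa <- compute_fa(al)
  angles <- wing_angle_table(paired$pairs)
  m <- merge(fa, angles, by = "specimen_id")
  expect_gt(cor(m$fa, m$differential), 0)
  res <- angle_differential_filter(angles)
  expect_lt(mean(m$fa[m$specimen_id %in% res$kept]), mean(m$fa))
})

make_rarefy_records <- function() {
  # one heavy year (35 distinct groups), plus a 3-record group in 1930
  heavy <- expand.grid(species = c("hortorum", "lapidarius", "muscorum",
                                   "pascuorum"),
                       month = 3:11, stringsAsFactors = FALSE)[1:35, ]
  heavy$year <- 1950L
  heavy$climate_region <- "East Anglia"
  heavy$caste <- "worker"
  trio <- data.frame(species = "hortorum", month = 6L, year = 1930L,
                     climate_region = "Midlands", caste = "queen")
  rec <- rbind(heavy, trio[rep(1, 3), ])
  rec$specimen_id <- sprintf("r%03d", seq_len(nrow(rec)))
  rec
}

test_that("rarefaction keeps one record per group then caps each year", {
  rec <- make_rarefy_records()
  res <- rarefy(rec, per_year_cap = 20L, seed = 99L)
  kept <- res$kept
  expect_equal(sum(kept$year == 1930), 1L)   # 3 records, one 5-way group
  expect_equal(sum(kept$year == 1950), 20L)  # 35 groups capped at 20
  expect_equal(nrow(kept), 21L)
})

test_that("rarefaction is seed-reproducible with seed-invariant counts", {
  rec <- make_rarefy_records()
  a <- rarefy(rec, per_year_cap = 20L, seed = 7L)
  b <- rarefy(rec, per_year_cap = 20L, seed = 7L)
  c0 <- rarefy(rec, per_year_cap = 20L, seed = 8L)
  expect_identical(a$kept$specimen_id, b$kept$specimen_id)
  expect_identical(table(a$kept$year), table(c0$kept$year))
  expect_false(identical(a$kept$specimen_id, c0$kept$specimen_id))
})

test_that("adding a new group never reshuffles the choice within other groups", {
  rec <- make_rarefy_records()
  trio2 <- data.frame(species = "muscorum", month = 7L, year = 1931L,
                      climate_region = "Midlands", caste = "drone",
                      specimen_id = c("x1", "x2", "x3"))
  grown <- rbind(rec, trio2)
  a <- rarefy(rec, per_year_cap = 100L, seed = 7L)   # no year cap in play
  b <- rarefy(grown, per_year_cap = 100L, seed = 7L)
  expect_true(all(a$kept$specimen_id %in% b$kept$specimen_id))
})

test_that("rarefaction errors on records with missing grouping fields", {
  rec <- make_rarefy_records()
  rec$climate_region[3] <- NA
  expect_error(rarefy(rec, seed = 1L), rec$specimen_id[3])
})

test_that("filter reports chain: counts reconcile across the whole pipeline", {
  p <- century_scale_scenario(seed = 5)
  p$n_specimens <- 60L
  sim <- simulate_dataset(p)
  out <- run_fa_pipeline(sim$configs, sim$metadata, sim$climate, seed = 2)
  rep_ <- out$reports
  expect_true(all(rep_$n_in - rep_$n_removed == rep_$n_out))
  # each step's input is the previous step's output
  expect_equal(rep_$n_in[3], rep_$n_out[2])
  expect_equal(rep_$n_in[4], rep_$n_out[3])
  expect_equal(rep_$n_in[5], rep_$n_out[4])
  expect_equal(nrow(out$records), rep_$n_out[5])
})
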
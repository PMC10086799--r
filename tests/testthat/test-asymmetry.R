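# Build an alignment from explicit per-wing shapes around the template:
# each entry of `dev` is a 13x2 displacement added to the (unit) template.
make_alignment <- function(dev, sides, ids, reps) {
  tmpl <- center_and_scale(wing_template())$coords
  configs <- lapply(seq_along(dev), function(i) {
    list(specimen_id = ids[i], side = sides[i], replicate = reps[i],
         coords = tmpl + dev[[i]])
  })
  gpa(configs, reflect_side = "none")
}

test_that("compute_fa recovers the injected pair distance and is replicate-exchangeable", {
  p <- sim_params(n_specimens = 25, sigma_individual = 0,
                  sigma_measurement = 0, tilt_sd = 0, da_length = 0,
                  fa_fixed = 0.05, seed = 21)
  sim <- simulate_dataset(p)
  al <- gpa(sim$configs, reflect_side = "left")
  fa <- compute_fa(al)
  expect_equal(fa$fa, rep(0.05, 25), tolerance = 1e-6)

  # swapping replicate labels changes nothing
  swapped <- lapply(sim$configs, function(cfg) {
    cfg$replicate <- 3L - cfg$replicate
    cfg
  })
  fa2 <- compute_fa(gpa(swapped, reflect_side = "left"))
  expect_equal(fa2$fa, fa$fa, tolerance = 1e-10)
})

test_that("a perfectly symmetric specimen has zero FA and is flagged on log transform", {
  p <- sim_params(n_specimens = 10, sigma_individual = 0.02,
                  sigma_measurement = 0, tilt_sd = 0, da_length = 0,
                  sigma_fa_base = 0, replicates_per_side = 1L, seed = 22)
  sim <- simulate_dataset(p)
  al <- gpa(sim$configs, reflect_side = "left")
  fa <- suppressWarnings(compute_fa(al))
  expect_lt(max(fa$fa), 1e-8)
  if (any(fa$fa == 0)) {
    expect_warning(compute_fa(al), "flagged")
    expect_true(anyNA(fa$log_fa))
  }
})

test_that("averaging replicate shapes shrinks noise relative to averaging distances", {
  set.seed(23)
  p <- sim_params(n_specimens = 40, sigma_individual = 0.02,
                  sigma_measurement = 0.01, tilt_sd = 0, da_length = 0,
                  sigma_fa_base = 0, seed = 24)
  sim <- simulate_dataset(p)
  al <- gpa(sim$configs, reflect_side = "left")
  fa_shape <- compute_fa(al, "mean_shape")
  fa_dist <- compute_fa(al, "mean_distance")
  expect_lt(mean(fa_shape$fa), mean(fa_dist$fa))
})

test_that("Procrustes ANOVA SS components always sum to the total", {
  p <- sim_params(n_specimens = 12, sigma_measurement = 0.004, seed = 25)
  sim <- simulate_dataset(p)
  al <- gpa(sim$configs, reflect_side = "left")
  tab <- procrustes_anova(al)
  total <- tab$SS[tab$effect == "total"]
  expect_equal(sum(tab$SS[tab$effect != "total"]), total,
               tolerance = 1e-6 * total)
  expect_true(all(tab$SS >= 0))
  expect_equal(tab$df[tab$effect == "side"], 22)
})

test_that("Procrustes ANOVA equals a direct-summation oracle on a small fixture", {
  # 3 individuals x 2 sides x 2 replicates, deterministic displacements
  ids <- rep(sprintf("i%d", 1:3), each = 4)
  sides <- rep(rep(c("left", "right"), each = 2), 3)
  reps <- rep(1:2, 6)
  set.seed(26)
  dev <- lapply(1:12, function(i) matrix(rnorm(26, 0, 0.03), 13, 2))
  al <- make_alignment(dev, sides, ids, reps)
  tab <- procrustes_anova(al)
  orc <- oracle_procrustes_anova(al$coords, al$info$specimen_id, al$info$side)
  expect_equal(tab$SS[tab$effect == "individual"], orc$ss_ind, tolerance = 1e-10)
  expect_equal(tab$SS[tab$effect == "side"], orc$ss_side, tolerance = 1e-10)
  expect_equal(tab$SS[tab$effect == "side_x_individual"], orc$ss_int,
               tolerance = 1e-10)
  expect_equal(tab$SS[tab$effect == "measurement_error"], orc$ss_err,
               tolerance = 1e-10)
  expect_equal(tab$SS[tab$effect == "total"], orc$ss_tot, tolerance = 1e-10)
})

test_that("identical replicates give zero measurement-error SS; <2 replicates error", {
  ids <- rep(c("a", "b"), each = 4)
  sides <- rep(rep(c("left", "right"), each = 2), 2)
  reps <- rep(1:2, 4)
  set.seed(27)
  dev_half <- lapply(1:4, function(i) matrix(rnorm(26, 0, 0.02), 13, 2))
  dev <- dev_half[c(1, 1, 2, 2, 3, 3, 4, 4)]  # replicate pairs identical
  al <- make_alignment(dev, sides, ids, reps)
  tab <- procrustes_anova(al)
  expect_lt(tab$SS[tab$effect == "measurement_error"], 1e-20)

  one_rep <- make_alignment(dev_half, rep(c("left", "right"), 2),
                            rep(c("a", "b"), each = 2), rep(1L, 4))
  expect_error(procrustes_anova(one_rep), "not estimable")
})

test_that("FA mean square dominates error mean square when digitisation noise is small", {
  p <- sim_params(n_specimens = 30, sigma_fa_base = 0.05,
                  sigma_measurement = 0.001, tilt_sd = 0, seed = 28)
  sim <- simulate_dataset(p)
  tab <- procrustes_anova(gpa(sim$configs, reflect_side = "left"))
  ms <- setNames(tab$MS, tab$effect)
  expect_gt(ms["side_x_individual"] / ms["measurement_error"], 10)
})

test_that("collector repeatability: zero effect for identical digitisations, bias detected", {
  cfg <- simulate_repeatability(n_images = 6, n_sessions = 2,
                                sigma_measurement = 0, bias = 0, seed = 30)
  res <- landmarker_repeatability(cfg)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # systematic collector bias of 0.02 Procrustes units is detectable
  set.seed(31)
  hits <- vapply(1:20, function(i) {
    cfg <- simulate_repeatability(n_images = 20, n_sessions = 4,
                                  bias = 0.02, sigma_measurement = 0.002,
                                  seed = 3000 + i)
    landmarker_repeatability(cfg)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  expect_error(landmarker_repeatability(
    simulate_repeatability(collectors = c("A", "A"), seed = 1)),
    "two collectors")
})

test_that("collector test holds its nominal size without injected bias", {
  set.seed(32)
  pvals <- vapply(1:120, function(i) {
    cfg <- simulate_repeatability(n_images = 12, n_sessions = 2,
                                  bias = 0, sigma_measurement = 0.003,
                                  seed = 5000 + i)
    landmarker_repeatability(cfg)$p_value
  }, 0)
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.005)
  expect_lte(rate, 0.12)
})
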
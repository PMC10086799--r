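# Independent oracles used to cross-check the package's core geometry.
# These are deliberately separate implementations: plain loops, their own
# normalisation, random consensus initialisation.

# Normalise a configuration: centre at origin, unit centroid size.
oracle_normalise <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

# Best proper rotation of x onto y by scanning a fine angle grid around the
# closed-form optimum is too slow for an inner loop, so the oracle GPA uses
# the analytic two-dimensional solution written directly from the
# cross-terms (no SVD): theta* = atan2(sum(x X y), sum(x . y)).
oracle_rotate_onto <- function(x, y) {
  num <- sum(x[, 1] * y[, 2] - x[, 2] * y[, 1])
  den <- sum(x[, 1] * y[, 1] + x[, 2] * y[, 2])
  theta <- atan2(num, den)
  r <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  x %*% r
}

# Pairwise-iterative generalised Procrustes oracle: random consensus
# initialisation, iterate rotate-all/re-mean to a very tight tolerance.
oracle_gpa <- function(mats, tol = 1e-12, max_iter = 500) {
  mats <- lapply(mats, oracle_normalise)
  consensus <- mats[[sample.int(length(mats), 1)]]
  for (it in seq_len(max_iter)) {
    mats <- lapply(mats, oracle_rotate_onto, y = consensus)
    new_cons <- oracle_normalise(Reduce(`+`, mats) / length(mats))
    if (sqrt(mean((new_cons - consensus)^2)) < tol) {
      consensus <- new_cons
      break
    }
    consensus <- new_cons
  }
  list(aligned = mats, consensus = consensus)
}

# Brute-force rotation search on an angle grid (the slow, sure check).
grid_best_distance <- function(moving, target, step = 0.001) {
  thetas <- seq(-pi, pi, by = step)
  best <- Inf
  for (theta in thetas) {
    r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    d <- sum((moving %*% r - target)^2)
    if (d < best) best <- d
  }
  sqrt(best)
}

# Direct-summation Side x Individual ANOVA oracle: explicit loops over
# individuals i, sides j, replicates k and coordinates, no matrix algebra.
oracle_procrustes_anova <- function(arr, ind, side) {
  n_conf <- dim(arr)[3]
  flat <- matrix(NA_real_, n_conf, dim(arr)[1] * 2)
  for (c0 in seq_len(n_conf)) flat[c0, ] <- as.vector(arr[, , c0])
  inds <- unique(ind)
  sides <- unique(side)
  r <- sum(ind == inds[1] & side == sides[1])
  grand <- colMeans(flat)
  ss_ind <- 0; ss_side <- 0; ss_int <- 0; ss_err <- 0; ss_tot <- 0
  ind_mean <- list(); side_mean <- list(); cell_mean <- list()
  for (i in inds) ind_mean[[i]] <- colMeans(flat[ind == i, , drop = FALSE])
  for (j in sides) side_mean[[j]] <- colMeans(flat[side == j, , drop = FALSE])
  for (i in inds) for (j in sides) {
    cell_mean[[paste(i, j)]] <-
      colMeans(flat[ind == i & side == j, , drop = FALSE])
  }
  for (i in inds) ss_ind <- ss_ind +
    length(sides) * r * sum((ind_mean[[i]] - grand)^2)
  for (j in sides) ss_side <- ss_side +
    length(inds) * r * sum((side_mean[[j]] - grand)^2)
  for (i in inds) for (j in sides) {
    dev <- cell_mean[[paste(i, j)]] - ind_mean[[i]] - side_mean[[j]] + grand
    ss_int <- ss_int + r * sum(dev^2)
  }
  for (c0 in seq_len(n_conf)) {
    ss_err <- ss_err + sum((flat[c0, ] - cell_mean[[paste(ind[c0], side[c0])]])^2)
    ss_tot <- ss_tot + sum((flat[c0, ] - grand)^2)
  }
  list(ss_ind = ss_ind, ss_side = ss_side, ss_int = ss_int,
       ss_err = ss_err, ss_tot = ss_tot)
}

# Small perturbed wing set used by several geometry tests.
make_wing_configs <- function(n, sigma = 0.03, seed = 1, sides = "right") {
  set.seed(seed)
  tmpl <- wingfa::wing_template()
  configs <- list()
  for (i in seq_len(n)) {
    for (s in sides) {
      xy <- tmpl + matrix(rnorm(26, 0, sigma), 13, 2)
      theta <- runif(1, -pi, pi)
      r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      xy <- sweep(xy %*% r * runif(1, 0.5, 2), 2, runif(2, -5, 5), `+`)
      configs[[length(configs) + 1L]] <- list(
        specimen_id = sprintf("w%03d", i), side = s, replicate = 1L,
        coords = xy, scale = NA_real_, image = NA_character_,
        id = sprintf("w%03d_%s_1", i, toupper(substr(s, 1, 1))))
    }
  }
  configs
}
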
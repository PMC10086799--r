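#' Per-specimen fluctuating asymmetry from a joint alignment
#'
#' Computes the FA measure of each specimen as the Procrustes distance
#' between its (mirrored) left and right aligned wing shapes. With the
#' default `mean_shape` policy the digitisation replicates of each side are
#' averaged into one shape per side before the distance is taken, shrinking
#' measurement noise; with `mean_distance` the distance is computed for
#' every left x right replicate pairing and then averaged.
#'
#' @param alignment a `wingfa_gpa` object from [gpa()] run jointly on all
#'   wings (left wings reflected).
#' @param replicate_policy `"mean_shape"` (default) or `"mean_distance"`.
#' @return data frame with `specimen_id`, `fa` and `log_fa` (natural log;
#'   `NA` with a warning when `fa` is exactly zero) plus `n_left`/`n_right`
#'   replicate counts.
#' @export
compute_fa <- function(alignment,
                       replicate_policy = c("mean_shape", "mean_distance")) {
  replicate_policy <- match.arg(replicate_policy)
  stopifnot(inherits(alignment, "wingfa_gpa"))
  info <- alignment$info
  ids <- unique(info$specimen_id)
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    li <- which(info$specimen_id == ids[i] & info$side == "left")
    ri <- which(info$specimen_id == ids[i] & info$side == "right")
    if (length(li) == 0L || length(ri) == 0L) next
    if (replicate_policy == "mean_shape") {
      lm_left <- mean_shape(alignment$coords, li)
      lm_right <- mean_shape(alignment$coords, ri)
      fa <- procrustes_distance(lm_left, lm_right)
    } else {
      grid <- expand.grid(l = li, r = ri)
      fa <- mean(mapply(function(l, r)
        procrustes_distance(alignment$coords[, , l], alignment$coords[, , r]),
        grid$l, grid$r))
    }
    res[[i]] <- data.frame(specimen_id = ids[i], fa = fa,
                           n_left = length(li), n_right = length(ri))
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no specimen has both a left and a right wing")
  zero <- out$fa == 0
  if (any(zero)) {
    warning(sum(zero), " specimen(s) with FA exactly 0 (identical ",
            "digitisations?); log_fa set to NA, flagged for review")
  }
  out$log_fa <- ifelse(zero, NA_real_, log(out$fa))
  rownames(out) <- NULL
  out
}

mean_shape <- function(arr, idx) {
  if (length(idx) == 1L) return(arr[, , idx])
  apply(arr[, , idx, drop = FALSE], c(1, 2), mean)
}

#' Side x Individual Procrustes ANOVA
#'
#' Goodall-style decomposition of shape variation over all landmark
#' coordinates into individual, side (directional asymmetry),
#' side x individual (fluctuating asymmetry) and measurement-error
#' components, for a balanced design of n individuals x 2 sides x r >= 2
#' digitisation replicates. Sums of squares are summed squared deviations
#' over all landmarks and both dimensions; degrees of freedom are the
#' conventional two-way-with-replication counts multiplied by the shape
#' space dimension 2k - 4 (22 for 13 two-dimensional landmarks, after
#' removing translation, size and rotation).
#'
#' The side x individual mean square is the FA component; the residual mean
#' square estimates digitisation (measurement) error. F ratios are
#' MS(side)/MS(side x individual) and MS(side x individual)/MS(error).
#'
#' @param alignment a `wingfa_gpa` object with both sides and at least two
#'   replicates per wing for every specimen included.
#' @return object of class `wingfa_procrustes_anova`: a data frame with
#'   rows individual, side, side_x_individual, measurement_error, total and
#'   columns SS, df, MS, F.
#' @export
procrustes_anova <- function(alignment) {
  stopifnot(inherits(alignment, "wingfa_gpa"))
  info <- alignment$info
  ids <- unique(info$specimen_id)
  counts <- table(info$specimen_id, info$side)
  if (!all(c("left", "right") %in% colnames(counts)) ||
      any(counts == 0L)) {
    stop("every specimen needs wings on both sides")
  }
  r <- unique(as.vector(counts))
  if (length(r) != 1L) {
    stop("unbalanced replicate structure; equal replicate counts required")
  }
  if (r < 2L) stop("measurement error not estimable: < 2 replicates per wing")
  n <- length(ids)
  k <- dim(alignment$coords)[1]
  p <- 2L
  shape_dim <- p * k - 4L

  flat <- t(apply(alignment$coords, 3, as.vector))  # configs x (k*p)
  ind <- factor(info$specimen_id, levels = ids)
  side <- factor(info$side, levels = c("left", "right"))

  grand <- colMeans(flat)
  ind_means <- rowsum(flat, as.integer(ind)) / (2 * r)   # rows ordered 1..n
  side_means <- rowsum(flat, as.integer(side)) / (n * r) # rows left, right
  cell_key <- sprintf("%06d_%d", as.integer(ind), as.integer(side))
  cell_means <- rowsum(flat, cell_key) / r
  cell_i <- as.integer(sub("_.*$", "", rownames(cell_means)))
  cell_j <- as.integer(sub("^.*_", "", rownames(cell_means)))

  ss_ind <- 2 * r * sum(sweep(ind_means, 2, grand)^2)
  ss_side <- n * r * sum(sweep(side_means, 2, grand)^2)
  cell_dev <- cell_means - ind_means[cell_i, , drop = FALSE] -
    side_means[cell_j, , drop = FALSE]
  cell_dev <- sweep(cell_dev, 2, grand, `+`)
  ss_int <- r * sum(cell_dev^2)
  resid <- flat - cell_means[match(cell_key, rownames(cell_means)), , drop = FALSE]
  ss_err <- sum(resid^2)
  ss_total <- sum(sweep(flat, 2, grand)^2)

  df <- c(individual = (n - 1) * shape_dim,
          side = 1 * shape_dim,
          side_x_individual = (n - 1) * shape_dim,
          measurement_error = 2 * n * (r - 1) * shape_dim)
  ss <- c(ss_ind, ss_side, ss_int, ss_err)
  ms <- ss / df
  f <- c(NA, ms["side"] / ms["side_x_individual"],
         ms["side_x_individual"] / ms["measurement_error"], NA)
  tab <- data.frame(
    effect = c(names(df), "total"),
    SS = c(ss, ss_total), df = c(df, sum(df)),
    MS = c(ms, NA), F = c(f, NA),
    row.names = NULL
  )
  structure(tab, class = c("wingfa_procrustes_anova", "data.frame"))
}

#' Landmarker repeatability across collectors
#'
#' Quantifies whether repeated digitisations of the same images by
#' different data collectors differ systematically. Each digitisation's
#' Procrustes distance to its image's mean aligned shape is modelled with
#' collector as a fixed effect and image identity as a random intercept
#' (linear mixed-effects model); the returned F statistic and p-value test
#' the collector effect.
#'
#' @param configs list of wing configurations of the repeated images, each
#'   carrying extra fields `collector` and `session`; `specimen_id`
#'   identifies the image.
#' @return list with `statistic` (F), `p_value`, `n_images`,
#'   `n_digitisations` and the per-digitisation `distances` data frame.
#' @export
landmarker_repeatability <- function(configs) {
  collectors <- vapply(configs, function(x)
    as.character(x$collector %||% NA_character_), "")
  if (anyNA(collectors)) stop("every configuration needs a collector field")
  if (length(unique(collectors)) < 2L) {
    stop("repeatability needs at least two collectors")
  }
  # replicate slot may collide across sessions; re-key uniquely for the GPA
  for (i in seq_along(configs)) configs[[i]]$replicate <- i
  al <- gpa(configs, reflect_side = "none")
  info <- al$info
  dists <- numeric(nrow(info))
  for (img in unique(info$specimen_id)) {
    idx <- which(info$specimen_id == img)
    centre <- mean_shape(al$coords, idx)
    for (i in idx) dists[i] <- procrustes_distance(al$coords[, , i], centre)
  }
  ord <- vapply(configs, function(x) x$replicate, 0L)
  dat <- data.frame(
    image = info$specimen_id,
    collector = collectors[match(info$replicate, ord)],
    distance = dists, stringsAsFactors = FALSE
  )
  if (sd(dat$distance) < .Machine$double.eps^0.5) {
    # identical digitisations: no variation to attribute to collectors
    return(list(statistic = 0, p_value = 1,
                n_images = length(unique(dat$image)),
                n_digitisations = nrow(dat), distances = dat))
  }
  fit <- nlme::lme(distance ~ collector, random = ~ 1 | image, data = dat,
                   method = "REML")
  an <- anova(fit)
  list(statistic = unname(an["collector", "F-value"]),
       p_value = unname(an["collector", "p-value"]),
       n_images = length(unique(dat$image)),
       n_digitisations = nrow(dat), distances = dat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
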
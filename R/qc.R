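#' Remove specimens with outlying wing shapes
#'
#' Pools the Procrustes distances of every wing (both sides,
#' replicate-averaged) to the consensus shape, computes the upper quartile
#' (Q3) of that pooled distribution, and removes a specimen when either of
#' its wings lies strictly above Q3. Quantiles use linear interpolation
#' between order statistics (type 7), the convention fixed throughout the
#' package so thresholds are reproducible bit for bit.
#'
#' @param alignment a `wingfa_gpa` object.
#' @return list with `kept` (character vector of specimen ids), `report`
#'   (a filter report row) and `distances` (per-wing distance table).
#' @export
shape_outlier_filter <- function(alignment) {
  stopifnot(inherits(alignment, "wingfa_gpa"))
  info <- alignment$info
  wings <- unique(info[, c("specimen_id", "side")])
  if (nrow(wings) < 4L) stop("quartile undefined on fewer than 4 wings")
  wings$distance <- NA_real_
  for (w in seq_len(nrow(wings))) {
    idx <- which(info$specimen_id == wings$specimen_id[w] &
                   info$side == wings$side[w])
    wings$distance[w] <- procrustes_distance(
      mean_shape(alignment$coords, idx), alignment$consensus)
  }
  q3 <- quantile(wings$distance, 0.75, type = 7, names = FALSE)
  bad <- unique(wings$specimen_id[wings$distance > q3])
  ids <- unique(info$specimen_id)
  kept <- setdiff(ids, bad)
  list(kept = kept,
       report = filter_report("shape_outlier", threshold = q3,
                              n_in = length(ids), removed = bad),
       distances = wings)
}

#' Wing angle of a raw (pre-alignment) configuration
#'
#' Angle, in degrees relative to the image x axis, of the vector from the
#' wing-base landmark to the wing-tip landmark of the raw coordinates.
#' Left wings are mirrored first so left and right angles are directly
#' comparable; specimens pinned with tilted or rotated wings show a large
#' left-right angle differential.
#'
#' @param config a wing configuration with raw `coords` and `side`.
#' @param base,tip landmark indices of the most proximal and most distal
#'   landmarks (defaults 1 and 13).
#' @return angle in degrees in (-180, 180].
#' @export
wing_angle <- function(config, base = 1L, tip = 13L) {
  coords <- as_coord_matrix(config$coords)
  if (identical(config$side, "left")) coords <- reflect_coords(coords)
  v <- coords[tip, ] - coords[base, ]
  if (sqrt(sum(v^2)) < .Machine$double.eps^0.5) {
    stop("wing-angle landmarks coincide for ", config$specimen_id)
  }
  ang <- atan2(v[2], v[1]) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Left-right wing-angle differentials for paired specimens
#'
#' Computes, per specimen, the replicate-averaged left and right wing
#' angles from raw coordinates and their minimal circular difference.
#'
#' @param pairs paired specimens from [pair_wings()] (`$pairs`).
#' @param base,tip landmark indices passed to [wing_angle()].
#' @return data frame with `specimen_id`, `angle_left`, `angle_right` and
#'   `differential` (degrees in [0, 180]).
#' @export
wing_angle_table <- function(pairs, base = 1L, tip = 13L) {
  mean_angle <- function(cfgs) {
    # circular mean of replicate angles
    a <- vapply(cfgs, wing_angle, 0, base = base, tip = tip) * pi / 180
    atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
  }
  out <- data.frame(
    specimen_id = names(pairs),
    angle_left = vapply(pairs, function(p) mean_angle(p$left), 0),
    angle_right = vapply(pairs, function(p) mean_angle(p$right), 0),
    stringsAsFactors = FALSE
  )
  d <- abs(out$angle_left - out$angle_right) %% 360
  out$differential <- pmin(d, 360 - d)
  rownames(out) <- NULL
  out
}

#' Remove specimens with large wing-angle differentials
#'
#' Threshold is the upper quartile plus the interquartile range (both type
#' 7) of the differential distribution; specimens strictly above it are
#' removed. A large angle differential indicates tilted or displaced wing
#' mounting, which inflates apparent asymmetry.
#'
#' @param angles data frame from [wing_angle_table()].
#' @return list with `kept` ids and `report`.
#' @export
angle_differential_filter <- function(angles) {
  if (nrow(angles) < 4L) stop("angle filter needs at least 4 specimens")
  q <- quantile(angles$differential, c(0.25, 0.75), type = 7, names = FALSE)
  threshold <- q[2] + (q[2] - q[1])
  bad <- angles$specimen_id[angles$differential > threshold]
  list(kept = setdiff(angles$specimen_id, bad),
       report = filter_report("angle_differential", threshold = threshold,
                              n_in = nrow(angles), removed = bad))
}

#' Two-stage rarefaction of museum records
#'
#' Equalises sampling intensity across the century. Stage 1 keeps exactly
#' one uniformly random record per non-empty species x month x year x
#' climate-region x caste group; stage 2 caps each year at
#' `per_year_cap` randomly chosen records. Stage-1 draws use a dedicated
#' RNG stream keyed by (seed, group key), so adding one group never
#' reshuffles the choices in others, and the per-year kept counts equal
#' min(cap, groups in year) independent of the seed.
#'
#' @param records data frame with `specimen_id`, `species`, `month`,
#'   `year`, `climate_region`, `caste` columns.
#' @param per_year_cap maximum records retained per year (default 20).
#' @param seed integer seed controlling all random choices.
#' @return list with `kept` (data frame of retained records) and `report`.
#' @export
rarefy <- function(records, per_year_cap = 20L, seed) {
  needed <- c("specimen_id", "species", "month", "year",
              "climate_region", "caste")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0L) stop("rarefy() needs columns: ",
                              paste(miss, collapse = ", "))
  bad <- !complete.cases(records[, needed])
  if (any(bad)) {
    stop("records with missing grouping fields: ",
         paste(head(records$specimen_id[bad], 10L), collapse = ", "))
  }
  key <- paste(records$species, records$month, records$year,
               records$climate_region, records$caste, sep = "|")
  stage1 <- unlist(lapply(split(seq_len(nrow(records)), key), function(idx) {
    if (length(idx) == 1L) idx else
      idx[seeded_sample_one(seed, key[idx[1]], length(idx))]
  }), use.names = FALSE)
  s1 <- records[sort(stage1), , drop = FALSE]

  stage2 <- unlist(lapply(split(seq_len(nrow(s1)), s1$year), function(idx) {
    yr <- s1$year[idx[1]]
    if (length(idx) <= per_year_cap) idx else
      idx[seeded_sample(seed, paste0("year|", yr), length(idx), per_year_cap)]
  }), use.names = FALSE)
  kept <- s1[sort(stage2), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       report = rbind(
         filter_report("rarefy_stage1_one_per_group", threshold = NA,
                       n_in = nrow(records),
                       removed = setdiff(records$specimen_id, s1$specimen_id)),
         filter_report("rarefy_stage2_year_cap", threshold = per_year_cap,
                       n_in = nrow(s1),
                       removed = setdiff(s1$specimen_id, kept$specimen_id))
       ))
}

# Deterministic per-group RNG stream: a rolling string hash of the group key
# mixed with the user seed feeds a local set.seed; the global RNG state is
# left untouched.
group_seed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

seeded_sample_one <- function(seed, key, n) {
  with_local_seed(group_seed(seed, key), sample.int(n, 1L))
}

seeded_sample <- function(seed, key, n, size) {
  with_local_seed(group_seed(seed, key), sample.int(n, size))
}

filter_report <- function(step, threshold, n_in, removed) {
  data.frame(step = step, threshold = as.numeric(threshold[1]),
             n_in = n_in, n_removed = length(removed),
             n_out = n_in - length(removed),
             removed_ids = paste(removed, collapse = ";"),
             stringsAsFactors = FALSE)
}
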
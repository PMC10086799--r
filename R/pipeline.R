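#' Run the full asymmetry pipeline
#'
#' Chains every stage on in-memory inputs: date-based queen exclusion,
#' wing pairing, joint generalised Procrustes alignment (left wings
#' reflected), per-specimen FA, the three quality filters in their fixed
#' order (shape outlier, wing-angle differential, two-stage rarefaction),
#' climate-region assignment and the annual climate join, ending in a
#' model-ready table.
#'
#' @param configs list of raw wing configurations (e.g. from [read_tps()]
#'   or [simulate_dataset()]).
#' @param metadata specimen metadata data frame; a `date` column is
#'   expanded into `year`, `month` and `julian_day` when absent.
#' @param climate annual regional climate table (`region`, `year`,
#'   `mean_annual_temp`, `annual_precip`).
#' @param geometry region geometry (default: packaged synthetic fixture).
#' @param seed integer seed for the rarefaction draws.
#' @param per_year_cap rarefaction stage-2 cap (default 20).
#' @param thresholds queen Julian-day cutoffs.
#' @param replicate_policy FA replicate policy, see [compute_fa()].
#' @return list with `alignment`, `fa`, `angles`, `reports` (stacked
#'   filter reports), `records` (retained specimen records with region and
#'   climate) and `model_data`.
#' @export
run_fa_pipeline <- function(configs, metadata, climate,
                            geometry = read_region_geometry(),
                            seed = 1L, per_year_cap = 20L,
                            thresholds = queen_day_thresholds(),
                            replicate_policy = "mean_shape") {
  meta <- as.data.frame(metadata)
  if (is.null(meta$year) || is.null(meta$julian_day) || is.null(meta$month)) {
    meta$date <- as.Date(meta$date)
    meta$year <- as.integer(format(meta$date, "%Y"))
    meta$month <- as.integer(format(meta$date, "%m"))
    meta$julian_day <- julian_day(meta$date)
  }
  meta <- exclude_overwintered_queens(meta, thresholds)
  queen_report <- filter_report("overwintered_queens", threshold = NA,
                                n_in = nrow(meta) + attr(meta, "n_removed"),
                                removed = character(attr(meta, "n_removed")))
  queen_report$n_removed <- attr(meta, "n_removed")
  queen_report$n_out <- nrow(meta)

  paired <- pair_wings(configs, meta)
  paired_ids <- names(paired$pairs)
  configs_paired <- configs[vapply(configs, function(x)
    x$specimen_id %in% paired_ids, TRUE)]

  alignment <- gpa(configs_paired, reflect_side = "left")
  fa <- compute_fa(alignment, replicate_policy = replicate_policy)

  step1 <- shape_outlier_filter(alignment)
  angles <- wing_angle_table(paired$pairs[step1$kept])
  step2 <- angle_differential_filter(angles)

  records <- meta[match(step2$kept, meta$specimen_id), , drop = FALSE]
  reg <- assign_region(records$latitude, records$longitude, geometry)
  records$climate_region <- reg$region

  step3 <- rarefy(records, per_year_cap = per_year_cap, seed = seed)
  kept <- join_climate(step3$kept, climate)
  kept <- merge(kept, fa[, c("specimen_id", "fa", "log_fa")],
                by = "specimen_id", sort = TRUE)

  reports <- rbind(queen_report, step1$report, step2$report, step3$report)
  list(alignment = alignment, fa = fa, angles = angles,
       reports = reports, records = kept,
       model_data = model_data(kept))
}
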
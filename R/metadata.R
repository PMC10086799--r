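#' Default Julian-day cutoffs for overwintered queens
#'
#' Species-specific day-of-year thresholds below which collected queens are
#' likely to have developed in the year preceding collection (overwintered
#' gynes) and are excluded from year-resolved analyses.
#'
#' @return named integer vector over the four study species.
#' @export
queen_day_thresholds <- function() {
  c(hortorum = 150L, lapidarius = 164L, muscorum = 164L, pascuorum = 159L)
}

#' Day-of-year of a calendar date
#'
#' January 1 maps to 1; leap years follow the calendar, so March 1 of a
#' leap year is day 61.
#'
#' @param date a `Date` (or string coercible via `as.Date`).
#' @return integer day-of-year in 1..366.
#' @export
julian_day <- function(date) {
  date <- as.Date(date)
  as.POSIXlt(date)$yday + 1L
}

#' Read a specimen metadata table
#'
#' Reads a delimited text file with one row per specimen and at least the
#' columns `specimen_id`, `species`, `caste`, `date` (ISO-8601),
#' `latitude`, `longitude`. Adds derived `year` and `julian_day` columns.
#'
#' @param path path to a delimited text file with a header row.
#' @param sep field separator (default tab; "," for CSV).
#' @return data frame of specimen records.
#' @export
read_specimen_metadata <- function(path, sep = "\t") {
  rec <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("specimen_id", "species", "caste", "date",
                "latitude", "longitude")
  missing_cols <- setdiff(required, names(rec))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  rec$date <- as.Date(rec$date)
  if (anyNA(rec$date)) stop("unparseable (non ISO-8601) dates in metadata")
  rec$year <- as.integer(format(rec$date, "%Y"))
  rec$month <- as.integer(format(rec$date, "%m"))
  rec$julian_day <- julian_day(rec$date)
  rec
}

#' Exclude likely overwintered queens
#'
#' Removes records with caste "queen" collected strictly before the
#' species-specific Julian-day threshold; such early-season queens
#' developed in the year before collection, so their wing asymmetry cannot
#' be attributed to the collection year's conditions. Workers and drones
#' are never removed.
#'
#' @param records specimen metadata data frame with `species`, `caste` and
#'   `julian_day` columns.
#' @param thresholds named vector mapping species to a Julian-day cutoff;
#'   defaults to [queen_day_thresholds()].
#' @return filtered data frame (attribute `n_removed` records the count).
#' @export
exclude_overwintered_queens <- function(records,
                                        thresholds = queen_day_thresholds()) {
  present <- unique(as.character(records$species))
  missing_sp <- setdiff(present, names(thresholds))
  if (length(missing_sp) > 0L) {
    stop("no queen-day threshold for species: ",
         paste(missing_sp, collapse = ", "))
  }
  is_queen <- as.character(records$caste) == "queen"
  cutoff <- thresholds[as.character(records$species)]
  drop <- is_queen & records$julian_day < cutoff
  out <- records[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  out
}
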
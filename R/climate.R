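#' The nine UK climate reporting regions
#'
#' Region labels used by the UK and Regional Series of annual climate
#' values, in the fixed order used throughout the package.
#'
#' @return character vector of nine region labels.
#' @export
climate_regions <- function() {
  c("East Anglia", "East & NE England", "NW England & N Wales",
    "SE & Central England", "Midlands", "S Wales & SW England",
    "East Scotland", "North Scotland", "West Scotland")
}

#' Read region geometry from GeoJSON
#'
#' Reads a FeatureCollection of (multi)polygons in decimal-degree
#' coordinates whose feature property `region` names the climate region.
#' The packaged fixture `uk_climate_regions_synthetic.geojson` is a
#' deliberately simplified synthetic partition of Britain into the nine
#' reporting regions, adequate for region assignment of specimen
#' coordinates but not a cartographic product.
#'
#' @param path path to a GeoJSON file; default is the packaged synthetic
#'   geometry.
#' @return named list mapping region label to a list of polygons, each an
#'   n x 2 matrix of (longitude, latitude) vertices.
#' @export
read_region_geometry <- function(path = system.file(
  "extdata", "uk_climate_regions_synthetic.geojson", package = "wingfa")) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  geometry <- list()
  for (feat in gj$features) {
    region <- feat$properties$region
    geom <- feat$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, `[[`, 1L),
      stop("unsupported geometry type: ", geom$type))
    polys <- lapply(rings, function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    })
    geometry[[region]] <- c(geometry[[region]], polys)
  }
  geometry
}

# Even-odd ray-casting point-in-polygon test; boundary points count inside.
point_in_polygon <- function(lon, lat, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-edge check
    if (point_segment_distance(lon, lat, xi, yi, xj, yj) < 1e-12) return(TRUE)
    if ((yi > lat) != (yj > lat)) {
      xint <- xi + (lat - yi) * (xj - xi) / (yj - yi)
      if (lon < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  t <- if (len2 == 0) 0 else max(0, min(1, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Assign a coordinate to a climate region
#'
#' Returns the region whose polygon contains the point. Points on shared
#' boundaries, or within `tolerance` (decimal degrees) outside all
#' polygons, are assigned to the nearest region and flagged; points
#' farther away are an error.
#'
#' @param latitude,longitude decimal-degree coordinates (vectorised).
#' @param geometry region geometry from [read_region_geometry()].
#' @param tolerance snap distance in decimal degrees (default 0.5).
#' @return data frame with `region` and logical `snapped`.
#' @export
assign_region <- function(latitude, longitude, geometry, tolerance = 0.5) {
  stopifnot(length(latitude) == length(longitude))
  region <- character(length(latitude))
  snapped <- logical(length(latitude))
  for (i in seq_along(latitude)) {
    hit <- NA_character_
    for (nm in names(geometry)) {
      if (any(vapply(geometry[[nm]], function(p)
        point_in_polygon(longitude[i], latitude[i], p), TRUE))) {
        hit <- nm
        break
      }
    }
    if (is.na(hit)) {
      dists <- vapply(names(geometry), function(nm) {
        min(vapply(geometry[[nm]], function(p) {
          n <- nrow(p)
          min(vapply(seq_len(n), function(k) {
            k2 <- if (k == n) 1L else k + 1L
            point_segment_distance(longitude[i], latitude[i],
                                   p[k, 1], p[k, 2], p[k2, 1], p[k2, 2])
          }, 0))
        }, 0))
      }, 0)
      if (min(dists) > tolerance) {
        stop("coordinate (", latitude[i], ", ", longitude[i],
             ") lies far outside the region geometry")
      }
      hit <- names(geometry)[which.min(dists)]
      snapped[i] <- TRUE
    }
    region[i] <- hit
  }
  data.frame(region = region, snapped = snapped, stringsAsFactors = FALSE)
}

#' Join annual regional climate onto specimen records
#'
#' Left join on (climate_region, year). Records before the first year of
#' the climate series keep missing climate values: they remain available
#' to the temporal models and are excluded only from climate models.
#'
#' @param records data frame with `climate_region` and `year` columns.
#' @param climate data frame with `region`, `year`, `mean_annual_temp`,
#'   `annual_precip`; one row per (region, year).
#' @return `records` with `mean_annual_temp` and `annual_precip` attached.
#' @export
join_climate <- function(records, climate) {
  key <- paste(climate$region, climate$year, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate climate rows for: ", key[duplicated(key)][1])
  }
  hit <- match(paste(records$climate_region, records$year, sep = "|"), key)
  records$mean_annual_temp <- climate$mean_annual_temp[hit]
  records$annual_precip <- climate$annual_precip[hit]
  n_missing <- sum(is.na(hit))
  if (n_missing > 0L) {
    message(n_missing, " record(s) without climate data (pre-series years ",
            "or unmatched region); retained with missing climate")
  }
  records
}

#' Correlation screen of an annual climate variable against alternatives
#'
#' Pairwise Pearson correlations (with two-sided p-values) between one
#' annual variable and a set of seasonal or derived variables, used to
#' justify collapsing the climate exposure to annual values. Zero-variance
#' columns yield missing correlations, which are reported.
#'
#' @param climate data frame of climate series.
#' @param annual_var name of the annual variable column.
#' @param other_vars character vector of comparison columns.
#' @return data frame with `variable`, `r`, `p`, `n`; attribute `min_r`
#'   holds the minimum correlation across comparisons.
#' @export
correlation_screen <- function(climate, annual_var, other_vars) {
  out <- lapply(other_vars, function(v) {
    ok <- complete.cases(climate[[annual_var]], climate[[v]])
    x <- climate[[annual_var]][ok]
    y <- climate[[v]][ok]
    if (sum(ok) < 3L || sd(x) == 0 || sd(y) == 0) {
      return(data.frame(variable = v, r = NA_real_, p = NA_real_,
                        n = sum(ok)))
    }
    ct <- cor.test(x, y, method = "pearson")
    data.frame(variable = v, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok))
  })
  res <- do.call(rbind, out)
  attr(res, "min_r") <- suppressWarnings(min(res$r, na.rm = TRUE))
  res
}
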
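#' Read landmark configurations from a TPS file
#'
#' Parses the tpsDig dialect: records start with `LM=<n>`, followed by n
#' lines of `<x> <y>`, optionally followed by `IMAGE=`, `ID=` and `SCALE=`
#' lines. Specimen identity, side and digitisation replicate are recovered
#' from the ID field under the convention `<specimen>_<L|R>_<replicate>`;
#' an explicit mapping can be supplied instead for collections that do not
#' follow it.
#'
#' Records whose landmark count differs from `n_landmarks` are reported and
#' skipped. A record with no ID line is keyed by its ordinal index in the
#' file, with a warning.
#'
#' @param path path to a TPS file.
#' @param n_landmarks required landmark count per configuration (default 13,
#'   the homologous forewing vein junctions).
#' @param id_map optional data frame with columns `id`, `specimen_id`,
#'   `side`, `replicate` overriding the ID naming convention (`id` is
#'   matched against the TPS ID field, or IMAGE field when ID is absent).
#' @return list of wing configurations; each a list with `specimen_id`,
#'   `side` ("left"/"right"), `replicate` (integer), `coords` (matrix),
#'   `scale` (numeric or NA) and `image` (character or NA).
#' @export
read_tps <- function(path, n_landmarks = 13L, id_map = NULL) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  starts <- grep("^LM=", lines)
  if (length(starts) == 0L) stop("no LM= records in ", path)
  bounds <- c(starts, length(lines) + 1L)
  configs <- list()
  skipped <- 0L
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:(bounds[r + 1L] - 1L)]
    n <- suppressWarnings(as.integer(sub("^LM=", "", block[1L])))
    if (is.na(n)) stop("malformed LM= header at line ", starts[r], " of ", path)
    coord_lines <- block[seq_len(n) + 1L]
    coords <- matrix(NA_real_, n, 2L)
    for (j in seq_len(n)) {
      parts <- suppressWarnings(as.numeric(strsplit(coord_lines[j], "[[:space:]]+")[[1]]))
      if (length(parts) != 2L || anyNA(parts)) {
        stop("malformed coordinate line ", starts[r] + j, " of ", path,
             ": '", coord_lines[j], "'")
      }
      coords[j, ] <- parts
    }
    keyed <- block[-seq_len(n + 1L)]
    get_key <- function(key) {
      hit <- grep(paste0("^", key, "="), keyed, value = TRUE)
      if (length(hit) == 0L) NA_character_ else sub(paste0("^", key, "="), "", hit[1L])
    }
    id <- get_key("ID")
    image <- get_key("IMAGE")
    scale <- suppressWarnings(as.numeric(get_key("SCALE")))
    if (n != n_landmarks) {
      warning("record ", r, " (ID=", if (is.na(id)) "<none>" else id,
              ") has ", n, " landmarks, expected ", n_landmarks, "; skipped")
      skipped <- skipped + 1L
      next
    }
    if (is.na(id)) {
      warning("record ", r, " has no ID; keyed by ordinal index")
      id <- sprintf("record%04d", r)
    }
    parsed <- parse_tps_id(id, id_map = id_map, image = image)
    configs[[length(configs) + 1L]] <- list(
      specimen_id = parsed$specimen_id, side = parsed$side,
      replicate = parsed$replicate, coords = coords,
      scale = scale, image = image, id = id
    )
  }
  configs
}

# Resolve a TPS ID (or image name) to specimen/side/replicate, either via an
# explicit mapping table or the "<specimen>_<L|R>_<rep>" convention.
parse_tps_id <- function(id, id_map = NULL, image = NA_character_) {
  if (!is.null(id_map)) {
    hit <- match(id, id_map$id)
    if (is.na(hit) && !is.na(image)) hit <- match(image, id_map$id)
    if (!is.na(hit)) {
      return(list(specimen_id = as.character(id_map$specimen_id[hit]),
                  side = normalise_side(id_map$side[hit]),
                  replicate = as.integer(id_map$replicate[hit])))
    }
  }
  m <- regmatches(id, regexec("^(.*)_([LlRr])_([0-9]+)$", id))[[1]]
  if (length(m) == 4L) {
    return(list(specimen_id = m[2L], side = normalise_side(m[3L]),
                replicate = as.integer(m[4L])))
  }
  list(specimen_id = id, side = NA_character_, replicate = 1L)
}

normalise_side <- function(side) {
  side <- tolower(as.character(side))
  if (side %in% c("l", "left")) return("left")
  if (side %in% c("r", "right")) return("right")
  stop("unrecognised side label: ", side)
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: writes `LM=`, coordinate lines at full double
#' precision, and `IMAGE=`, `ID=`, `SCALE=` keys when present, so that a
#' write/read round trip reproduces the stored coordinates exactly.
#'
#' @param configs list of wing configurations.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  out <- character(0)
  for (cfg in configs) {
    coords <- as_coord_matrix(cfg$coords)
    out <- c(out, paste0("LM=", nrow(coords)),
             sprintf("%.17g %.17g", coords[, 1], coords[, 2]))
    if (!is.null(cfg$image) && !is.na(cfg$image)) {
      out <- c(out, paste0("IMAGE=", cfg$image))
    }
    id <- if (!is.null(cfg$id) && !is.na(cfg$id)) cfg$id else
      paste(cfg$specimen_id, toupper(substr(cfg$side, 1, 1)), cfg$replicate,
            sep = "_")
    out <- c(out, paste0("ID=", id))
    if (!is.null(cfg$scale) && !is.na(cfg$scale)) {
      out <- c(out, sprintf("SCALE=%.17g", cfg$scale))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Pair left and right wing configurations into specimens
#'
#' Matches configurations to metadata rows by specimen id and keeps only
#' specimens that have at least one left and one right configuration and a
#' metadata row. Unpaired wings and orphan metadata are counted in the
#' report. Duplicate (specimen, side, replicate) triples indicate ambiguous
#' digitisation and are a hard error.
#'
#' @param configs list of wing configurations.
#' @param records specimen metadata data frame with a `specimen_id` column.
#' @return list with `pairs` (named list per specimen: `left`, `right`
#'   config lists and `record` row) and `report` (counts of paired
#'   specimens, unpaired wings, orphan metadata rows).
#' @export
pair_wings <- function(configs, records) {
  if (length(configs) > 0L) {
    key <- vapply(configs, function(x)
      paste(x$specimen_id, x$side, x$replicate, sep = "\r"), "")
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1]
      stop("duplicate (specimen, side, replicate) digitisation: ",
           gsub("\r", "/", dup))
    }
  }
  ids <- vapply(configs, `[[`, "", "specimen_id")
  sides <- vapply(configs, `[[`, "", "side")
  meta_ids <- as.character(records$specimen_id)
  pairs <- list()
  unpaired <- 0L
  for (sid in unique(ids)) {
    lefts <- configs[ids == sid & sides == "left"]
    rights <- configs[ids == sid & sides == "right"]
    row <- match(sid, meta_ids)
    if (length(lefts) >= 1L && length(rights) >= 1L && !is.na(row)) {
      pairs[[sid]] <- list(left = lefts, right = rights,
                           record = records[row, , drop = FALSE])
    } else {
      unpaired <- unpaired + length(lefts) + length(rights)
    }
  }
  orphan_meta <- sum(!(meta_ids %in% names(pairs)))
  list(pairs = pairs,
       report = data.frame(n_paired = length(pairs),
                           n_unpaired_wings = unpaired,
                           n_orphan_metadata = orphan_meta))
}
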
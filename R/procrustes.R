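#' Centre a landmark configuration and scale it to unit centroid size
#'
#' Translates a configuration so its centroid sits at the origin and divides
#' by centroid size, the square root of the summed squared distances of the
#' landmarks from their centroid. This is the size measure removed before
#' rotation during generalised Procrustes alignment.
#'
#' @param coords numeric matrix, one landmark per row, two columns (x, y).
#' @return list with `coords` (centred, unit-size matrix) and
#'   `centroid_size` (the pre-scaling size).
#' @examples
#' sq <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
#' center_and_scale(sq)$centroid_size  # sqrt(8)
#' @export
center_and_scale <- function(coords) {
  coords <- as_coord_matrix(coords)
  centroid <- colMeans(coords)
  centred <- sweep(coords, 2, centroid)
  cs <- sqrt(sum(centred^2))
  if (cs < .Machine$double.eps^0.5) {
    stop("degenerate configuration: all landmarks coincide (zero centroid size)")
  }
  list(coords = centred / cs, centroid_size = cs)
}

#' Optimal proper rotation between two centred configurations
#'
#' Returns the 2x2 rotation matrix (determinant +1, reflections excluded)
#' that minimises the summed squared distances between `moving %*% R` and
#' `target`, computed from the singular value decomposition of the
#' cross-covariance of the two configurations.
#'
#' @param moving,target centred landmark matrices with matching dimensions.
#' @return 2x2 rotation matrix with determinant +1.
#' @export
optimal_rotation <- function(moving, target) {
  moving <- as_coord_matrix(moving, n_landmarks = nrow(target))
  m <- crossprod(moving, target)
  sv <- svd(m)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

#' Mirror a configuration about the y axis
#'
#' Negates the x coordinates, preserving landmark order, so that left-side
#' structures become directly comparable with right-side ones (matching
#' symmetry: each landmark k remains landmark k).
#'
#' @param coords landmark matrix.
#' @return mirrored landmark matrix.
#' @export
reflect_coords <- function(coords) {
  coords <- as_coord_matrix(coords)
  coords[, 1] <- -coords[, 1]
  coords
}

#' Generalised Procrustes alignment of wing configurations
#'
#' Superimposes a set of landmark configurations by removing translation
#' (centroids to the origin), size (unit centroid size) and orientation
#' (iterative rotation to an evolving consensus, the landmark-wise mean
#' shape). Left-side configurations can be mirrored before alignment so
#' left and right wings of all specimens and replicates enter one joint
#' alignment, the standard matching-symmetry treatment.
#'
#' Configurations are sorted deterministically by (specimen, side,
#' replicate) and the consensus is initialised from the first configuration
#' after that sort, so results do not depend on input order.
#'
#' @param configs list of wing configurations (as from [read_tps()]), each
#'   with `specimen_id`, `side`, `replicate` and a 13x2 `coords` matrix.
#' @param reflect_side which side to mirror before alignment
#'   (`"left"`, `"right"` or `"none"`).
#' @param tol convergence tolerance: root-mean-square movement of consensus
#'   landmarks between iterations.
#' @param max_iter maximum number of alignment iterations.
#' @return object of class `wingfa_gpa`: list with `coords` (landmark x
#'   dimension x configuration array of aligned shapes), `info` (data frame
#'   of specimen_id, side, replicate, centroid_size), `consensus`
#'   (unit-size mean shape), `iterations` and `converged`.
#' @export
gpa <- function(configs, reflect_side = c("left", "right", "none"),
                tol = 1e-8, max_iter = 100L) {
  reflect_side <- match.arg(reflect_side)
  if (length(configs) < 2L) stop("gpa() needs at least two configurations")
  info <- data.frame(
    specimen_id = vapply(configs, `[[`, "", "specimen_id"),
    side = vapply(configs, `[[`, "", "side"),
    replicate = vapply(configs, function(x) as.integer(x$replicate), 0L),
    stringsAsFactors = FALSE
  )
  ord <- order(info$specimen_id, info$side, info$replicate)
  configs <- configs[ord]
  info <- info[ord, , drop = FALSE]
  rownames(info) <- NULL

  k <- nrow(as_coord_matrix(configs[[1]]$coords))
  arr <- array(NA_real_, c(k, 2L, length(configs)))
  cs <- numeric(length(configs))
  for (i in seq_along(configs)) {
    xy <- as_coord_matrix(configs[[i]]$coords, n_landmarks = k)
    if (reflect_side != "none" && identical(configs[[i]]$side, reflect_side)) {
      xy <- reflect_coords(xy)
    }
    norm <- center_and_scale(xy)
    arr[, , i] <- norm$coords
    cs[i] <- norm$centroid_size
  }
  info$centroid_size <- cs

  consensus <- arr[, , 1L]
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    for (i in seq_len(dim(arr)[3])) {
      arr[, , i] <- arr[, , i] %*% optimal_rotation(arr[, , i], consensus)
    }
    new_consensus <- apply(arr, c(1, 2), mean)
    new_consensus <- center_and_scale(new_consensus)$coords
    movement <- sqrt(mean((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (movement < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("gpa() did not converge in ", max_iter, " iterations")
  }
  structure(
    list(coords = arr, info = info, consensus = consensus,
         iterations = iterations, converged = converged),
    class = "wingfa_gpa"
  )
}

#' @export
print.wingfa_gpa <- function(x, ...) {
  cat("Generalised Procrustes alignment\n")
  cat("  configurations:", dim(x$coords)[3], "\n")
  cat("  landmarks:     ", dim(x$coords)[1], "\n")
  cat("  iterations:    ", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Procrustes distance between two aligned shapes
#'
#' Square root of the summed squared distances between corresponding
#' landmarks of two superimposed configurations; the FA measure when
#' applied to a specimen's mirrored left and right wings.
#'
#' @param a,b landmark matrices with identical dimensions, already
#'   superimposed (same alignment).
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- as_coord_matrix(a)
  b <- as_coord_matrix(b, n_landmarks = nrow(a))
  sqrt(sum((a - b)^2))
}

# Coerce to a numeric n x 2 matrix, checking landmark count when requested.
as_coord_matrix <- function(coords, n_landmarks = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L) stop("landmark coordinates must have two columns")
  if (!all(is.finite(coords))) stop("landmark coordinates must be finite")
  if (!is.null(n_landmarks) && nrow(coords) != n_landmarks) {
    stop("mismatched landmark counts: ", nrow(coords), " vs ", n_landmarks)
  }
  storage.mode(coords) <- "double"
  coords
}
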
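#' Construct a 3D polyline
#'
#' A polyline is an ordered dense digitization of one anterior-crest curve,
#' stored as an n x 3 matrix of (x, y, z) coordinates in millimetres.
#'
#' @param points Matrix-like object with three columns (x, y, z), one row per
#'   digitized point, in the order they were recorded.
#' @param source_id Provenance string (file path or specimen id).
#' @return A `polyline3d` object: a numeric matrix with columns x, y, z and a
#'   `source_id` attribute.
#' @export
polyline3d <- function(points, source_id = NA_character_) {
  pts <- as.matrix(points)
  if (ncol(pts) != 3L)
    stop("a polyline needs exactly 3 coordinate columns, got ", ncol(pts))
  if (nrow(pts) < 2L)
    stop("a polyline needs at least 2 points, got ", nrow(pts))
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts)))
    stop("polyline contains non-finite coordinates")
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  structure(pts, class = c("polyline3d", "matrix", "array"),
            source_id = source_id)
}

#' @export
print.polyline3d <- function(x, ...) {
  cat(sprintf("<polyline3d> %d points, arc length %.2f mm (source: %s)\n",
              nrow(x), arc_length(x), attr(x, "source_id")))
  invisible(x)
}

#' Construct a semilandmark curve
#'
#' An ordered configuration of k semilandmarks (default workflow: k = 20)
#' subdividing one digitized crest curve equidistantly by arc length. The
#' first and last semilandmarks are the anatomically anchored curve endpoints.
#'
#' @param coords k x 3 matrix of semilandmark coordinates (mm).
#' @param length_mm Arc length of the source polyline (mm); the size variable
#'   used for allometry.
#' @param specimen_id Specimen identifier.
#' @return A `semilandmark_curve` object.
#' @export
semilandmark_curve <- function(coords, length_mm = NA_real_,
                               specimen_id = NA_character_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("semilandmark coords need 3 columns")
  if (nrow(coords) < 3L) stop("need at least 3 semilandmarks")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) stop("non-finite semilandmark coordinates")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(coords = coords, k = nrow(coords), length_mm = length_mm,
                 specimen_id = specimen_id),
            class = "semilandmark_curve")
}

#' @export
print.semilandmark_curve <- function(x, ...) {
  cat(sprintf("<semilandmark_curve> k = %d, curve length %.2f mm (%s)\n",
              x$k, x$length_mm, x$specimen_id))
  invisible(x)
}

# Coerce a list of semilandmark curves to a k x 3 x n array with ids.
curves_to_array <- function(curves) {
  stopifnot(length(curves) >= 1L)
  ks <- vapply(curves, function(cv) cv$k, 1L)
  if (length(unique(ks)) != 1L)
    stop("all curves must share the same semilandmark count")
  k <- ks[[1L]]
  arr <- array(NA_real_, c(k, 3L, length(curves)),
               dimnames = list(NULL, c("x", "y", "z"),
                               vapply(curves, function(cv)
                                 as.character(cv$specimen_id), "")))
  for (i in seq_along(curves)) arr[, , i] <- curves[[i]]$coords
  arr
}
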
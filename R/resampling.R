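#' Arc length of a polyline
#'
#' Sum of consecutive Euclidean segment lengths (mm). Duplicate consecutive
#' points contribute zero. This is the "curve length" size variable used for
#' allometry, kept distinct from centroid size.
#'
#' @param polyline A [polyline3d()] or plain n x 3 matrix.
#' @return Arc length in mm.
#' @export
arc_length <- function(polyline) {
  pts <- unclass(as.matrix(polyline))
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Drop consecutive duplicate points (zero-length segments) ahead of
# arc-length parameterization.
collapse_duplicates <- function(pts) {
  seg <- sqrt(rowSums(diff(pts)^2))
  keep <- c(TRUE, seg > 0)
  pts[keep, , drop = FALSE]
}

#' Resample a polyline equidistantly by arc length
#'
#' Subdivides the digitized curve into `k` semilandmarks so that
#' semilandmark j (j = 0..k-1) lies on the polyline at arc-length fraction
#' j/(k-1), by linear interpolation within segments. The curve endpoints
#' (the two anatomically anchored type III landmarks) are preserved exactly.
#' With dense digitizations (about 1,800-2,000 points per curve) the
#' piecewise-linear parameterization introduces negligible chordal error and
#' keeps the operator exactly idempotent on its own output.
#'
#' @param polyline A [polyline3d()].
#' @param k Semilandmark count (default 20, the workflow standard).
#' @param specimen_id Identifier for the result (defaults to the polyline's
#'   `source_id`).
#' @return A [semilandmark_curve()] whose `length_mm` is the source
#'   polyline's arc length.
#' @export
resample_equidistant <- function(polyline, k = 20L, specimen_id = NULL) {
  stopifnot(k >= 3L)
  pts <- collapse_duplicates(unclass(as.matrix(polyline)))
  n <- nrow(pts)
  if (n < 2L) stop("degenerate polyline: zero arc length")
  if (n < 2L * k)
    warning(sprintf("polyline has only %d points for k = %d semilandmarks",
                    n, k))
  cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- cum[n]
  if (total <= 0) stop("degenerate polyline: zero arc length")
  targets <- total * seq(0, 1, length.out = k)
  coords <- vapply(1:3, function(j)
    stats::approx(cum, pts[, j], xout = targets, ties = "ordered")$y,
    numeric(k))
  coords[1L, ] <- pts[1L, ]
  coords[k, ] <- pts[n, ]
  semilandmark_curve(coords, length_mm = total,
                     specimen_id = specimen_id %||%
                       attr(polyline, "source_id"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximal caliper (book) distance of a point cloud
#'
#' The diameter of the vertex set: the maximum Euclidean distance between
#' any two points, computed exactly by blocked pairwise search. For an
#' elongated bone-like cloud this coincides with the osteometric-board
#' maximal length.
#'
#' @param cloud m x 3 matrix of vertices (e.g. from [read_obj_vertices()]).
#' @return Maximal pairwise distance (mm).
#' @export
max_caliper_length <- function(cloud) {
  pts <- unclass(as.matrix(cloud))
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 vertices")
  if (!all(is.finite(pts))) stop("non-finite vertex coordinates")
  sq <- rowSums(pts^2)
  block <- 2048L
  best <- 0
  for (i0 in seq(1L, n, by = block)) {
    i1 <- min(i0 + block - 1L, n)
    g <- tcrossprod(pts[i0:i1, , drop = FALSE], pts)
    d2 <- outer(sq[i0:i1], sq, `+`) - 2 * g
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}
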
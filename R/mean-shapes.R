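#' Mean shape of a group of aligned specimens
#'
#' @param sample An `aligned_sample`.
#' @param members Index vector (integer, logical, or specimen ids) selecting
#'   the group; must be non-empty.
#' @return k x 3 coordinate-wise mean shape.
#' @export
group_mean <- function(sample, members) {
  stopifnot(inherits(sample, "aligned_sample"))
  if (is.character(members))
    members <- match(members, sample$specimen_ids)
  if (is.logical(members)) members <- which(members)
  if (length(members) == 0L || anyNA(members))
    stop("empty or unmatched member set")
  apply(sample$shapes[, , members, drop = FALSE], c(1L, 2L), mean)
}

#' Anatomical reference frame of a crest curve
#'
#' Builds a deterministic right-handed orthonormal triad from a mean curve:
#' the proximo-distal axis runs from the first to the last semilandmark
#' (the chord); the anterior-posterior axis is the unit component,
#' orthogonal to the chord, of the displacement of the curve's arc-length
#' midpoint from the chord midpoint (the bow direction defines "anterior");
#' the medio-lateral axis completes the right-handed triad
#' (`ml = pd x ap`). The "medial view" is the (ap, pd) plane and exposes
#' A-P bowing; the "anterior view" is the (ml, pd) plane and exposes the
#' M-L sigmoid.
#'
#' @param mean_shape k x 3 mean curve (aligned shape or mm coordinates).
#' @return An `anatomical_frame`: list with unit vectors `pd_axis`,
#'   `ap_axis`, `ml_axis` and `origin` (the first semilandmark).
#' @export
anatomical_frame <- function(mean_shape) {
  x <- as_config(mean_shape)
  k <- nrow(x)
  chord <- x[k, ] - x[1L, ]
  nc <- sqrt(sum(chord^2))
  if (nc <= 0) stop("degenerate curve: coincident endpoints")
  pd <- chord / nc
  # arc-length midpoint of the curve
  cum <- c(0, cumsum(sqrt(rowSums(diff(x)^2))))
  half <- cum[k] / 2
  j <- findInterval(half, cum, rightmost.closed = TRUE)
  t <- (half - cum[j]) / max(cum[j + 1L] - cum[j], 1e-300)
  mid_arc <- (1 - t) * x[j, ] + t * x[j + 1L, ]
  w <- mid_arc - (x[1L, ] + x[k, ]) / 2
  w <- w - sum(w * pd) * pd
  nw <- sqrt(sum(w^2))
  if (nw < 1e-9 * nc)
    stop("curve has no detectable bow: supply an explicit frame")
  ap <- w / nw
  ml <- c(pd[2L] * ap[3L] - pd[3L] * ap[2L],
          pd[3L] * ap[1L] - pd[1L] * ap[3L],
          pd[1L] * ap[2L] - pd[2L] * ap[1L])
  structure(list(pd_axis = pd, ap_axis = ap, ml_axis = ml,
                 origin = x[1L, ]),
            class = "anatomical_frame")
}

#' Difference field between two mean shapes
#'
#' Per-semilandmark displacement vectors from a reference mean shape to a
#' target mean shape (the arrows of a vector plot; the norms are the sphere
#' diameters), with projections into the anatomical A-P ("medial view",
#' ap x pd) and M-L ("anterior view", ml x pd) planes. Antisymmetric under
#' swapping reference and target.
#'
#' @param mean_a Reference mean shape (k x 3).
#' @param mean_b Target mean shape (k x 3, same k).
#' @param frame An [anatomical_frame()]; in the analysis pipeline this is
#'   computed once from the pooled consensus so all group fields share axes.
#' @param reference_label,target_label Labels stored with the field.
#' @return A `difference_field`: `vectors` (k x 3), `magnitudes` (k),
#'   `ap_projection` and `ml_projection` (k x 2, columns = in-plane lateral
#'   and proximo-distal components), `frame`, and the two labels.
#' @export
difference_field <- function(mean_a, mean_b, frame,
                             reference_label = "reference",
                             target_label = "target") {
  A <- as_config(mean_a); B <- as_config(mean_b)
  if (!all(dim(A) == dim(B))) stop("mean shapes must have equal k")
  stopifnot(inherits(frame, "anatomical_frame"))
  v <- B - A
  mag <- sqrt(rowSums(v^2))
  ap <- cbind(drop(v %*% frame$ap_axis), drop(v %*% frame$pd_axis))
  ml <- cbind(drop(v %*% frame$ml_axis), drop(v %*% frame$pd_axis))
  colnames(ap) <- colnames(ml) <- c("lateral", "pd")
  structure(list(reference_label = reference_label,
                 target_label = target_label, vectors = v,
                 magnitudes = mag, frame = frame,
                 ap_projection = ap, ml_projection = ml),
            class = "difference_field")
}

#' @export
print.difference_field <- function(x, ...) {
  cat(sprintf(
    "<difference_field> %s -> %s: mean |v| = %.4g, max |v| = %.4g\n",
    x$reference_label, x$target_label, mean(x$magnitudes),
    max(x$magnitudes)))
  invisible(x)
}

#' Confidence ellipse of a 2D score cloud
#'
#' Ellipse of the group's score covariance scaled by the chi-square(2)
#' quantile at the given coverage level; under bivariate normality it
#' contains the stated fraction of the distribution. The workflow default
#' level for PC1-PC2 group ellipses is 0.70.
#'
#' @param scores_2d n x 2 matrix of scores (n >= 3).
#' @param level Coverage probability in (0, 1); default 0.70.
#' @return An `ellipse_spec`: `center` (2), `semi_axes` (2, major first),
#'   `orientation` (radians of the major axis), `level`, `covariance`.
#' @export
confidence_ellipse <- function(scores_2d, level = 0.70) {
  sc <- as.matrix(scores_2d)
  stopifnot(ncol(sc) == 2L, nrow(sc) >= 3L, level > 0, level < 1)
  ctr <- colMeans(sc)
  S <- stats::cov(sc)
  e <- eigen(S, symmetric = TRUE)
  if (e$values[2L] <= e$values[1L] * 1e-12)
    warning("degenerate score covariance: ellipse collapses to a segment")
  r2 <- stats::qchisq(level, df = 2L)
  structure(list(center = ctr,
                 semi_axes = sqrt(pmax(e$values, 0) * r2),
                 orientation = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
                 level = level, covariance = S),
            class = "ellipse_spec")
}

#' @export
print.ellipse_spec <- function(x, ...) {
  cat(sprintf(
    "<ellipse_spec> %.0f%% ellipse at (%.3g, %.3g), semi-axes %.3g x %.3g\n",
    100 * x$level, x$center[1L], x$center[2L], x$semi_axes[1L],
    x$semi_axes[2L]))
  invisible(x)
}

#' Export a difference field as a flat table
#'
#' @param field A [difference_field()].
#' @return Data frame: semilandmark index, vector xyz, magnitude, A-P plane
#'   (u, v) and M-L plane (u, v) projected components.
#' @export
field_table <- function(field) {
  stopifnot(inherits(field, "difference_field"))
  data.frame(semilandmark = seq_along(field$magnitudes),
             dx = field$vectors[, 1L], dy = field$vectors[, 2L],
             dz = field$vectors[, 3L], magnitude = field$magnitudes,
             ap_u = field$ap_projection[, 1L],
             ap_v = field$ap_projection[, 2L],
             ml_u = field$ml_projection[, 1L],
             ml_v = field$ml_projection[, 2L])
}
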
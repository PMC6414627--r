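# --- low-level rigid/similarity machinery -----------------------------------

center_config <- function(x) sweep(x, 2L, colMeans(x))

centroid_size <- function(x) sqrt(sum(center_config(x)^2))

# Optimal proper rotation R (det +1, no reflection: all configurations are
# left-side elements) minimizing ||x %*% R - ref||^2 for centered x, ref.
optimal_rotation <- function(x, ref) {
  m <- crossprod(x, ref)
  sv <- svd(m)
  d <- det(sv$u %*% t(sv$v))
  sv$u %*% diag(c(1, 1, sign(d))) %*% t(sv$v)
}

as_config <- function(a) {
  if (inherits(a, "semilandmark_curve")) a$coords else unclass(as.matrix(a))
}

#' Full Procrustes alignment of one configuration onto another
#'
#' Finds the similarity transform (translation, proper rotation, positive
#' scale; reflections excluded) minimizing the summed squared distances of
#' `b`'s semilandmarks from `a`'s, and reports the partial Procrustes
#' distance between the two shapes (root summed squared differences of the
#' centered, unit-centroid-size configurations after optimal rotation).
#'
#' @param a,b [semilandmark_curve()] objects or k x 3 matrices with equal k.
#' @return List with `rotation` (3 x 3), `scale`, `translation` (so that
#'   `b` maps to `scale * (b - centroid_b) %*% rotation + translation`),
#'   `distance` (Procrustes distance on unit-size shapes), and `b_aligned`.
#' @export
procrustes_align_pair <- function(a, b) {
  A <- as_config(a); B <- as_config(b)
  if (!all(dim(A) == dim(B))) stop("configurations must have equal k")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- center_config(A); Bc <- center_config(B)
  sa <- sqrt(sum(Ac^2)); sb <- sqrt(sum(Bc^2))
  if (sa <= 0 || sb <= 0) stop("degenerate configuration: zero centroid size")
  r <- optimal_rotation(Bc, Ac)
  beta <- sum((Bc %*% r) * Ac) / sum(Bc^2)
  dist <- sqrt(sum((Ac / sa - (Bc / sb) %*% r)^2))
  list(rotation = r, scale = beta, translation = ca,
       distance = dist,
       b_aligned = beta * Bc %*% r + matrix(ca, nrow(A), 3L, byrow = TRUE))
}

#' Procrustes distance between two pre-standardized shapes
#'
#' Root summed squared coordinate differences after optimal proper rotation.
#' Inputs must already be centered and scaled to unit centroid size (this is
#' a contract, not a convenience: violating it silently changes the metric).
#'
#' @param a,b Centered, unit-centroid-size k x 3 shapes.
#' @param tol Tolerance for the centering/size contract check.
#' @return Non-negative Procrustes distance; zero iff the shapes are
#'   identical up to rotation.
#' @export
procrustes_distance <- function(a, b, tol = 1e-6) {
  A <- as_config(a); B <- as_config(b)
  if (!all(dim(A) == dim(B))) stop("shapes must have equal k")
  for (x in list(A, B)) {
    if (max(abs(colMeans(x))) > tol)
      stop("shape is not centered (contract violation)")
    if (abs(sqrt(sum(x^2)) - 1) > tol)
      stop("shape does not have unit centroid size (contract violation)")
  }
  r <- optimal_rotation(B, A)
  sqrt(sum((A - B %*% r)^2))
}

# Deterministic canonical orientation from the consensus principal axes.
# Removes the global rotational ambiguity of GPA so that the aligned sample
# is invariant (up to numerics) to arbitrary similarity transforms of the
# inputs. Sign convention: each of the first two axes is flipped so that the
# consensus point with the largest-magnitude projection onto it projects
# positively (projections are rotation-invariant, axis components are not);
# the third axis completes a right-handed triad.
canonical_rotation <- function(consensus) {
  cc <- center_config(consensus)
  v <- eigen(crossprod(cc), symmetric = TRUE)$vectors
  for (j in 1:2) {
    proj <- cc %*% v[, j]
    i <- which.max(abs(proj))
    if (proj[i] < 0) v[, j] <- -v[, j]
  }
  v[, 3L] <- c(v[2L, 1L] * v[3L, 2L] - v[3L, 1L] * v[2L, 2L],
               v[3L, 1L] * v[1L, 2L] - v[1L, 1L] * v[3L, 2L],
               v[1L, 1L] * v[2L, 2L] - v[2L, 1L] * v[1L, 2L])
  v
}

# Core GPA iteration on a k x 3 x n array of centered unit-size shapes.
# Rotates each shape to the evolving unit-size consensus until the relative
# change of the total Procrustes sum of squares drops below `tol`.
gpa_core <- function(shapes, tol = 1e-10, max_iter = 100L) {
  n <- dim(shapes)[3L]
  cons <- apply(shapes, c(1L, 2L), mean)
  cons <- cons / sqrt(sum(center_config(cons)^2))
  ss_prev <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n))
      shapes[, , i] <- shapes[, , i] %*% optimal_rotation(shapes[, , i], cons)
    cons <- apply(shapes, c(1L, 2L), mean)
    cons <- center_config(cons) / sqrt(sum(center_config(cons)^2))
    ss <- sum(sweep(shapes, c(1L, 2L), cons)^2)
    trace <- c(trace, ss)
    if (is.finite(ss_prev) && abs(ss_prev - ss) <= tol * max(ss_prev, 1e-12))
      break
    ss_prev <- ss
  }
  if (it == max_iter && length(trace) >= 2L &&
      abs(trace[it - 1L] - trace[it]) > tol * max(trace[it - 1L], 1e-12))
    warning("GPA did not converge in ", max_iter, " iterations")
  # canonical orientation (consensus principal axes)
  rc <- canonical_rotation(cons)
  for (i in seq_len(n)) shapes[, , i] <- shapes[, , i] %*% rc
  cons <- cons %*% rc
  list(shapes = shapes, consensus = cons, ss = ss, trace = trace,
       iterations = it)
}

#' Generalized Procrustes analysis of semilandmark curves
#'
#' Removes position, orientation, and scale: every configuration is
#' centered, scaled to unit centroid size, and iteratively rotated to the
#' evolving sample consensus until the total Procrustes sum of squares
#' stabilizes (relative change below `tol`). Reflections are never used.
#' The converged sample is put in a deterministic canonical orientation
#' (consensus principal axes), which makes the result invariant to
#' arbitrary similarity transforms applied to the inputs.
#'
#' @param curves List of [semilandmark_curve()] objects (n >= 2, common k),
#'   or a k x 3 x n array.
#' @param tol Relative convergence tolerance on the total Procrustes SS.
#' @param max_iter Iteration cap.
#' @return An `aligned_sample`: list with `shapes` (k x 3 x n aligned
#'   coordinates), `consensus` (k x 3 unit-size mean shape),
#'   `centroid_sizes` (mm), `curve_lengths` (mm, from the resampling stage;
#'   NA if unknown), `specimen_ids`, and `iterations` (stage/pass/SS log).
#' @export
gpa <- function(curves, tol = 1e-10, max_iter = 100L) {
  if (is.array(curves) && length(dim(curves)) == 3L) {
    arr <- curves
    ids <- dimnames(arr)[[3L]] %||% as.character(seq_len(dim(arr)[3L]))
    lens <- rep(NA_real_, dim(arr)[3L])
  } else {
    arr <- curves_to_array(curves)
    ids <- dimnames(arr)[[3L]]
    lens <- vapply(curves, function(cv) cv$length_mm, 0)
  }
  n <- dim(arr)[3L]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    x <- center_config(arr[, , i])
    sizes[i] <- sqrt(sum(x^2))
    if (sizes[i] <= 0) stop("degenerate configuration: zero centroid size")
    arr[, , i] <- x / sizes[i]
  }
  fit <- gpa_core(arr, tol = tol, max_iter = max_iter)
  dimnames(fit$shapes) <- list(NULL, c("x", "y", "z"), ids)
  dimnames(fit$consensus) <- list(NULL, c("x", "y", "z"))
  structure(list(shapes = fit$shapes, consensus = fit$consensus,
                 centroid_sizes = sizes, curve_lengths = lens,
                 specimen_ids = ids,
                 iterations = data.frame(stage = "gpa",
                                         pass = seq_along(fit$trace),
                                         ss = fit$trace)),
            class = "aligned_sample")
}

#' @export
print.aligned_sample <- function(x, ...) {
  cat(sprintf(
    "<aligned_sample> n = %d, k = %d, total Procrustes SS = %.6g (%s)\n",
    dim(x$shapes)[3L], dim(x$shapes)[1L], total_procrustes_ss(x),
    if (any(x$iterations$stage == "slide")) "slid" else "not slid"))
  invisible(x)
}

#' Total Procrustes sum of squares of an aligned sample
#'
#' @param sample An `aligned_sample`.
#' @return Sum over specimens of the squared deviation from the consensus.
#' @export
total_procrustes_ss <- function(sample) {
  sum(sweep(sample$shapes, c(1L, 2L), sample$consensus)^2)
}

# One sliding pass against a fixed consensus. Each interior semilandmark i
# moves only along its tangent t_i = unit(p[i+1] - p[i-1]) by the projection
# of (consensus_i - p_i) onto t_i -- the exact 1D minimizer of that point's
# squared distance to the consensus along the tangent line. Endpoints
# (the anatomically anchored first and last semilandmarks) never move.
# Coincident neighbours (zero tangent) skip the pass; their count is
# returned.
slide_pass <- function(shapes, consensus) {
  k <- dim(shapes)[1L]
  n <- dim(shapes)[3L]
  skipped <- 0L
  int <- 2:(k - 1L)
  for (i in seq_len(n)) {
    p <- shapes[, , i]
    tang <- p[3:k, , drop = FALSE] - p[1:(k - 2L), , drop = FALSE]
    nt <- sqrt(rowSums(tang^2))
    ok <- nt > 1e-12
    skipped <- skipped + sum(!ok)
    tang[ok, ] <- tang[ok, , drop = FALSE] / nt[ok]
    lam <- rowSums((consensus[int, , drop = FALSE] -
                      p[int, , drop = FALSE]) * tang)
    lam[!ok] <- 0
    shapes[int, , i] <- p[int, , drop = FALSE] + lam * tang
  }
  list(shapes = shapes, skipped = skipped)
}

#' Slide interior semilandmarks by Procrustes-distance minimization
#'
#' Alternates (1) sliding every interior semilandmark of every specimen
#' along its local tangent direction — given by the adjacent pair of
#' semilandmarks — to minimize its distance to the sample consensus, and
#' (2) re-superimposition by [gpa()] with an updated consensus. The first
#' and last semilandmarks are anatomical landmarks and are never slid.
#' Passes stop when the relative change of the total Procrustes SS falls
#' below `tol` or after `max_passes` passes; the SS is non-increasing
#' across passes (logged in `iterations`).
#'
#' @param sample An `aligned_sample` from [gpa()] with k >= 3.
#' @param tol Relative convergence tolerance on total Procrustes SS.
#' @param max_passes Cap on slide + re-superimposition passes.
#' @return The slid, re-aligned `aligned_sample`; `iterations` gains one
#'   `"slide"` row per pass.
#' @export
slide_semilandmarks <- function(sample, tol = 1e-8, max_passes = 10L) {
  stopifnot(inherits(sample, "aligned_sample"))
  shapes <- sample$shapes
  cons <- sample$consensus
  ss_prev <- total_procrustes_ss(sample)
  log <- sample$iterations
  skipped_total <- 0L
  for (pass in seq_len(max_passes)) {
    sl <- slide_pass(shapes, cons)
    skipped_total <- skipped_total + sl$skipped
    shapes <- sl$shapes
    # re-superimpose: recenter, rescale to unit size, re-rotate to consensus
    for (i in seq_len(dim(shapes)[3L])) {
      x <- center_config(shapes[, , i])
      shapes[, , i] <- x / sqrt(sum(x^2))
    }
    fit <- gpa_core(shapes, tol = 1e-10, max_iter = 100L)
    shapes <- fit$shapes
    cons <- fit$consensus
    ss <- fit$ss
    log <- rbind(log, data.frame(stage = "slide", pass = pass, ss = ss))
    if (abs(ss_prev - ss) <= tol * max(ss_prev, 1e-12)) {
      ss_prev <- ss
      break
    }
    ss_prev <- ss
  }
  if (skipped_total > 0L)
    warning(skipped_total,
            " semilandmark slides skipped (coincident neighbours)")
  dimnames(shapes) <- dimnames(sample$shapes)
  dimnames(cons) <- dimnames(sample$consensus)
  out <- sample
  out$shapes <- shapes
  out$consensus <- cons
  out$iterations <- log
  out
}
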
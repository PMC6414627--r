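# Shared fixture builders; everything is generated in code at test time.

# Uniformly random proper rotation (det +1).
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Unit-radius quarter circle in the xy-plane, from angle 0 to pi/2.
quarter_circle <- function(n = 10001L) {
  th <- seq(0, pi / 2, length.out = n)
  polyline3d(cbind(cos(th), sin(th), 0), source_id = "quarter-circle")
}

# Smooth random space curve with gentle wiggles (simple, non-intersecting).
random_polyline <- function(n = 400L, length_mm = 300) {
  s <- seq(0, 1, length.out = n)
  a <- stats::runif(3L, 2, 8)
  ph <- stats::runif(3L, 0, 2 * pi)
  polyline3d(cbind(a[1L] * sin(pi * s + ph[1L]),
                   a[2L] * sin(2 * pi * s + ph[2L]),
                   -length_mm * s + a[3L] * 0.1 * sin(3 * pi * s + ph[3L])),
             source_id = "random")
}

# Small two-group synthetic sample resampled to semilandmark curves.
make_test_curves <- function(n_per_group = 6L, ap = c(8, 5), seed = 11L,
                             points = c(300L, 320L)) {
  d <- study_design(list(group_params("A", n_per_group,
                                      floor(n_per_group / 2),
                                      ap[1L], 2, 356),
                         group_params("B", n_per_group,
                                      floor(n_per_group / 2),
                                      ap[2L], 4, 356)),
                    points_min = points[1L], points_max = points[2L],
                    seed = seed)
  st <- generate_study(d)
  list(curves = lapply(st, function(sp)
    resample_equidistant(sp$polyline, specimen_id = sp$specimen_id)),
    meta = study_metadata(st), design = d)
}

# Wrap a k x 3 x n array as an aligned_sample (for unit tests of consumers
# that only need shapes + consensus).
fake_aligned <- function(arr) {
  structure(list(shapes = arr, consensus = apply(arr, c(1L, 2L), mean),
                 centroid_sizes = rep(1, dim(arr)[3L]),
                 curve_lengths = rep(NA_real_, dim(arr)[3L]),
                 specimen_ids = dimnames(arr)[[3L]] %||%
                   as.character(seq_len(dim(arr)[3L])),
                 iterations = data.frame(stage = "gpa", pass = 1L,
                                         ss = NA_real_)),
            class = "aligned_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Arc-length position of a point lying on a polyline (independent of the
# resampler: locates the nearest segment by orthogonal projection).
arc_position_on <- function(pts, q) {
  cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  best <- NA_real_
  bestd <- Inf
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]
    ab <- pts[i + 1L, ] - a
    t <- min(max(sum((q - a) * ab) / sum(ab^2), 0), 1)
    d <- sum((q - a - t * ab)^2)
    if (d < bestd) {
      bestd <- d
      best <- cum[i] + t * sqrt(sum(ab^2))
    }
  }
  best
}
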
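test_that("pairwise alignment recovers similarity transforms", {
  sm <- make_test_curves(n_per_group = 1L, seed = 51L)
  a <- sm$curves[[1L]]

  self <- procrustes_align_pair(a, a)
  expect_equal(self$distance, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3L), tolerance = 1e-9)
  expect_equal(self$scale, 1, tolerance = 1e-12)

  set.seed(52)
  r <- rand_rotation()
  b <- a
  b$coords <- 1.7 * a$coords %*% r +
    matrix(c(5, -3, 11), a$k, 3L, byrow = TRUE)
  fit <- procrustes_align_pair(a, b)
  expect_equal(fit$distance, 0, tolerance = 1e-9)
  expect_equal(fit$b_aligned, a$coords, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("pair alignment matches a brute-force rotation grid (flat 3-point
           shapes)", {
  set.seed(53)
  for (rep in 1:3) {
    a <- cbind(matrix(stats::rnorm(6L), 3L), 0)
    b <- cbind(matrix(stats::rnorm(6L), 3L), 0)
    unitc <- function(x) {
      x <- sweep(x, 2L, colMeans(x))
      x / sqrt(sum(x^2))
    }
    au <- unitc(a)
    bu <- unitc(b)
    # proper 3D rotations keeping the plane: in-plane rotation, optionally
    # composed with a half-turn about an in-plane axis
    th <- seq(0, 2 * pi, by = 1e-4)
    d2 <- function(bmat) {
      vapply(th, function(t) {
        rz <- matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3L)
        sum((au - bmat %*% rz)^2)
      }, 0)
    }
    flip <- diag(c(1, -1, -1))
    grid_min <- sqrt(min(d2(bu), d2(bu %*% flip)))
    expect_equal(procrustes_align_pair(a, b)$distance, grid_min,
                 tolerance = 1e-4)
  }
})

test_that("GPA is exact on copies and invariant to input transforms", {
  sm <- make_test_curves(seed = 54L)
  curves <- sm$curves

  copies <- rep(curves[1L], 5L)
  alc <- gpa(copies)
  expect_equal(total_procrustes_ss(alc), 0, tolerance = 1e-15)
  expect_equal(procrustes_distance(alc$consensus, alc$shapes[, , 1L]), 0,
               tolerance = 1e-9)

  al <- gpa(curves)
  expect_lt(max(abs(apply(al$shapes, 3L, colMeans))), 1e-9)  # centered
  sizes <- apply(al$shapes, 3L, function(x) sqrt(sum(x^2)))
  expect_equal(sizes, rep(1, length(curves)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(al$consensus,
               apply(al$shapes, c(1L, 2L), mean) /
                 sqrt(sum(apply(al$shapes, c(1L, 2L), mean)^2)),
               tolerance = 1e-9)

  set.seed(55)
  for (rep in 1:3) {
    moved <- lapply(curves, function(cv) {
      cv$coords <- stats::runif(1L, 0.5, 2) * cv$coords %*% rand_rotation() +
        matrix(stats::rnorm(3L, 0, 50), cv$k, 3L, byrow = TRUE)
      cv
    })
    al2 <- gpa(moved)
    expect_equal(al2$shapes, al$shapes, tolerance = 1e-8)
  }

  al3 <- gpa(rev(curves))
  expect_equal(al3$shapes[, , rev(seq_along(curves))], al$shapes,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two-specimen GPA agrees with the pairwise oracle", {
  sm <- make_test_curves(n_per_group = 1L, seed = 56L)
  al <- gpa(sm$curves)
  d_gpa <- procrustes_distance(al$shapes[, , 1L], al$shapes[, , 2L])
  d_pair <- procrustes_align_pair(sm$curves[[1L]], sm$curves[[2L]])$distance
  expect_equal(d_gpa, d_pair, tolerance = 1e-8)
})

test_that("procrustes distance is a rotation-invariant metric", {
  set.seed(57)
  unitc <- function(x) {
    x <- sweep(x, 2L, colMeans(x))
    x / sqrt(sum(x^2))
  }
  a <- unitc(matrix(stats::rnorm(60L), 20L))
  b <- unitc(matrix(stats::rnorm(60L), 20L))
  expect_equal(procrustes_distance(a, a), 0, tolerance = 1e-12)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
               tolerance = 1e-10)
  expect_equal(procrustes_distance(a, unitc(b %*% rand_rotation())),
               procrustes_distance(a, b), tolerance = 1e-9)
  expect_error(procrustes_distance(a + 1, b), "centered")
  expect_error(procrustes_distance(a * 2, b), "unit centroid")
})

test_that("sliding moves interior points only, monotonically", {
  sm <- make_test_curves(seed = 58L)
  al <- gpa(sm$curves)

  # identical specimens: sliding is a no-op
  alc <- gpa(rep(sm$curves[1L], 4L))
  slc <- slide_semilandmarks(alc)
  expect_equal(slc$shapes, alc$shapes, tolerance = 1e-12)

  # endpoints never move within a sliding pass
  sl <- crestcurve:::slide_pass(al$shapes, al$consensus)
  expect_identical(sl$shapes[c(1L, 20L), , ], al$shapes[c(1L, 20L), , ])

  # total Procrustes SS is non-increasing across passes
  slid <- slide_semilandmarks(al)
  ss <- slid$iterations$ss[slid$iterations$stage == "slide"]
  ss0 <- total_procrustes_ss(al)
  expect_true(all(diff(c(ss0, ss)) <= 1e-10 * ss0))
  expect_lt(ss[length(ss)], ss0)
})

test_that("one sliding pass solves the tangential 1D problem exactly", {
  sm <- make_test_curves(n_per_group = 1L, seed = 59L)
  a <- sm$curves[[1L]]$coords
  a <- sweep(a, 2L, colMeans(a))
  a <- a / sqrt(sum(a^2))
  i <- 9L
  tang <- a[i + 1L, ] - a[i - 1L, ]
  tang <- tang / sqrt(sum(tang^2))
  b <- a
  delta <- 0.05
  b[i, ] <- a[i, ] + delta * tang
  shapes <- array(c(a, b), c(20L, 3L, 2L))
  cons <- (a + b) / 2

  sl <- crestcurve:::slide_pass(shapes, cons)
  # both copies land on the consensus point, eliminating the tangential
  # offset in a single pass
  expect_equal(sl$shapes[i, , 1L], sl$shapes[i, , 2L], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sl$shapes[i, , 2L], cons[i, ], tolerance = 1e-8,
               ignore_attr = TRUE)

  # agreement with a numeric 1D line search along the tangent
  obj <- function(lam) sum((b[i, ] + lam * tang - cons[i, ])^2)
  lam_star <- stats::optimize(obj, c(-1, 1), tol = 1e-12)$minimum
  expect_equal(unname(sl$shapes[i, , 2L]), unname(b[i, ] + lam_star * tang),
               tolerance = 1e-6)
})
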
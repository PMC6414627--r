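test_that("template curve reproduces its closed-form geometry", {
  straight <- template_curve(0, 0, 100, n_points = 101L)
  expect_equal(max(abs(straight[, 1:2])), 0)
  expect_equal(arc_length(straight), 100)

  bow <- template_curve(8, 0, 350, apex_shift = 1, n_points = 2001L)
  expect_equal(max(abs(bow[, 1L])), 8)
  expect_equal(unname(bow[1001L, 1L]), 8)  # apex at s = 0.5
  expect_equal(max(abs(bow[, 2L])), 0)

  full <- template_curve(8, 3, 350, apex_shift = 1, n_points = 2001L)
  pts <- unclass(full)
  chord_sum <- sum(sqrt(rowSums((pts[-1L, ] - pts[-nrow(pts), ])^2)))
  expect_gt(chord_sum, 350)
  expect_equal(arc_length(full), chord_sum, tolerance = 1e-6)

  expect_error(template_curve(8, 3, 0, n_points = 101L), "L must be")
  expect_error(template_curve(8, 3, NaN, n_points = 101L), "L must be")
})

test_that("specimen draws follow the stated noise model", {
  g0 <- group_params("G", 1L, 0L, 8, 3, 350, sd_ap = 0, sd_ml = 0,
                     sd_length = 0)
  d0 <- study_design(list(g0), digitization_noise_mm = 0,
                     points_min = 200L, points_max = 200L, apex_shift = 1)
  set.seed(1)
  sp <- sample_specimen(g0, "F", d0)
  expect_equal(unclass(sp$polyline),
               unclass(template_curve(8, 3, 350, 1, 200L)),
               ignore_attr = TRUE)
  expect_identical(sp$meta$true_A, 8)

  # Monte-Carlo check of the per-point noise SD
  dn <- study_design(list(g0), digitization_noise_mm = 0.5,
                     points_min = 200L, points_max = 200L, apex_shift = 1)
  tpl <- unclass(template_curve(8, 3, 350, 1, 200L))
  set.seed(2)
  devs <- replicate(200L, unclass(sample_specimen(g0, "F", dn)$polyline) -
                      tpl)
  expect_equal(stats::sd(devs), 0.5, tolerance = 0.05)

  # dense point counts stay inside the design range
  set.seed(3)
  ddef <- study_design(list(g0))
  counts <- replicate(5L, nrow(sample_specimen(g0, "F", ddef)$polyline))
  expect_true(all(counts >= 1800L & counts <= 2000L))

  # truncated redraws are counted
  glow <- group_params("LOW", 1L, 0L, 0.2, 3, 350, sd_ap = 2)
  set.seed(4)
  sp2 <- sample_specimen(glow, "F", d0)
  expect_gt(sp2$meta$true_A, 0)
})

test_that("study generation is deterministic and matches the design", {
  d <- default_study_design(seed = 99L)
  st1 <- generate_study(d)
  st2 <- generate_study(d)
  expect_identical(st1, st2)
  meta <- study_metadata(st1)
  expect_equal(nrow(meta), 435L)
  sizes <- table(factor(meta$group, levels = unique(meta$group)))
  expect_equal(as.vector(sizes), c(46L, 79L, 30L, 103L, 57L, 64L, 56L))
  expect_equal(as.vector(table(meta$group, meta$sex)["EMED", c("M", "F")]),
               c(58L, 45L))

  # distinct bow amplitudes change only the x-profile
  dg <- study_design(list(group_params("P", 1L, 0L, 8, 3, 350, sd_ap = 0,
                                       sd_ml = 0, sd_length = 0),
                          group_params("Q", 1L, 0L, 5, 3, 350, sd_ap = 0,
                                       sd_ml = 0, sd_length = 0)),
                     digitization_noise_mm = 0, points_min = 150L,
                     points_max = 150L, seed = 5L)
  st <- generate_study(dg)
  a <- unclass(st[[1L]]$polyline)
  b <- unclass(st[[2L]]$polyline)
  expect_equal(a[, 2:3], b[, 2:3])
  expect_gt(max(abs(a[, 1L] - b[, 1L])), 1)
})

test_that("repeat digitizations behave like independent re-tracings", {
  g <- group_params("G", 1L, 0L, 8, 3, 350, sd_ap = 0, sd_ml = 0,
                    sd_length = 0)
  d <- study_design(list(g), digitization_noise_mm = 0, points_min = 1800L,
                    points_max = 2000L, seed = 6L)
  sp <- generate_study(d)[[1L]]
  expect_error(generate_repeats(sp, k = 1L), "at least 2")

  reps0 <- generate_repeats(sp, k = 3L, noise_mm = 0, seed = 7L)
  slms <- lapply(reps0, resample_equidistant)
  for (r in 2:3)
    expect_equal(slms[[r]]$coords, slms[[1L]]$coords, tolerance = 1e-6)

  # per-semilandmark repeat SD agrees with an independent resampling oracle
  resample_ref <- function(pts, k = 20L) {
    cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
    tg <- seq(0, cum[length(cum)], length.out = k)
    vapply(1:3, function(j) stats::approx(cum, pts[, j], xout = tg)$y,
           numeric(k))
  }
  noise <- 0.3
  set.seed(8)
  reps <- generate_repeats(sp, k = 100L, noise_mm = noise, seed = 9L)
  pkg_coords <- vapply(reps, function(pl) resample_equidistant(pl)$coords,
                       matrix(0, 20L, 3L))
  set.seed(10)
  orc_coords <- replicate(100L, {
    np <- sample(1800:2000, 1L)
    tpl <- unclass(template_curve(8, 3, 350, 0.8, np))
    resample_ref(tpl + matrix(stats::rnorm(3L * np, 0, noise), ncol = 3L))
  })
  sd_pkg <- mean(apply(pkg_coords, c(1L, 2L), stats::sd))
  sd_orc <- mean(apply(orc_coords, c(1L, 2L), stats::sd))
  expect_equal(sd_pkg, sd_orc, tolerance = 0.1)
})
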
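test_that("shape PCA matches a direct eigendecomposition", {
  set.seed(61)
  arr <- array(stats::rnorm(20L * 3L * 10L), c(20L, 3L, 10L))
  pca <- pca_shapes(fake_aligned(arr))

  X <- t(apply(arr, 3L, as.vector))
  ev_oracle <- eigen(stats::cov(X), symmetric = TRUE)$values
  m <- length(pca$eigenvalues)
  expect_equal(pca$eigenvalues, ev_oracle[seq_len(m)], tolerance = 1e-8)

  expect_equal(sum(pca$variance_fractions), 1, tolerance = 1e-9)
  expect_lt(max(abs(colMeans(pca$scores))), 1e-9)
  ortho <- pca$loadings %*% t(pca$loadings)
  expect_equal(ortho, diag(m), tolerance = 1e-8, ignore_attr = TRUE)

  # scores reproduce the centered data through the loadings
  expect_equal(pca$scores %*% pca$loadings,
               sweep(X, 2L, pca$mean_shape_flat), tolerance = 1e-8,
               ignore_attr = TRUE)

  # rank-1 variation loads a single component
  base <- matrix(stats::rnorm(60L), 20L)
  dir <- matrix(stats::rnorm(60L), 20L)
  arr1 <- array(NA_real_, c(20L, 3L, 6L))
  for (i in 1:6) arr1[, , i] <- base + i * 0.1 * dir
  p1 <- pca_shapes(fake_aligned(arr1))
  expect_equal(p1$variance_fractions[1L], 1, tolerance = 1e-9)

  expect_error(pca_shapes(fake_aligned(arr[, , 1:2])), "at least 3")
})

test_that("broken-stick retention follows the closed form", {
  # p = 3: b = (0.6111, 0.2778, 0.1111)
  expect_equal(broken_stick_retain(c(0.7, 0.2, 0.1)), 1L)
  expect_equal(broken_stick_retain(c(0.9, 0.1)), 1L)  # b = (0.75, 0.25)
  expect_equal(broken_stick_retain(rep(1 / 4, 4L)), 0L)
  expect_equal(broken_stick_retain(c(0.7, 0.29, 0.01)), 2L)
  # the leading-run rule ignores later excursions above the stick
  expect_equal(broken_stick_retain(c(0.5, 0.25, 0.13, 0.12)), 0L)
  expect_error(broken_stick_retain(numeric(0)), "empty")

  # direct evaluation of b_j for random spectra
  set.seed(62)
  for (i in 1:5) {
    p <- sample(3:10, 1L)
    vf <- sort(stats::rexp(p), decreasing = TRUE)
    vf <- vf / sum(vf)
    b <- vapply(seq_len(p), function(j) sum(1 / (j:p)) / p, 0)
    run <- 0L
    while (run < p && vf[run + 1L] > b[run + 1L]) run <- run + 1L
    expect_identical(broken_stick_retain(vf), run)
  }
})

test_that("hotelling statistic matches its defining formula", {
  set.seed(63)
  X <- matrix(stats::rnorm(8L), 4L, 2L)
  Y <- matrix(stats::rnorm(8L, mean = 1), 4L, 2L)

  expect_equal(as.numeric(hotelling_t2(X, X)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(hotelling_t2(10 * X, 10 * Y)),
               as.numeric(hotelling_t2(X, Y)), tolerance = 1e-9)

  # term-by-term oracle: pooled covariance inverted with the 2x2 adjugate
  d <- colMeans(X) - colMeans(Y)
  sp <- (stats::cov(X) * 3 + stats::cov(Y) * 3) / 6
  inv <- matrix(c(sp[2, 2], -sp[1, 2], -sp[2, 1], sp[1, 1]), 2L) /
    (sp[1, 1] * sp[2, 2] - sp[1, 2] * sp[2, 1])
  t2_oracle <- (4 * 4 / 8) * drop(t(d) %*% inv %*% d)
  expect_equal(as.numeric(hotelling_t2(X, Y)), t2_oracle, tolerance = 1e-9)

  # invariance under a common invertible linear map
  A <- matrix(c(2, 0.5, -1, 3), 2L)
  expect_equal(as.numeric(hotelling_t2(X %*% A, Y %*% A)),
               as.numeric(hotelling_t2(X, Y)), tolerance = 1e-9)
})

test_that("permutation hotelling test matches exhaustive enumeration", {
  expect_equal(eval(formals(permutation_hotelling)$B), 10000L)

  set.seed(64)
  X <- matrix(stats::rnorm(6L), 3L, 2L)
  p_same <- permutation_hotelling(X, X, B = 199L, seed = 1L)
  expect_equal(p_same$p_value, 1)
  expect_equal(p_same$statistic, 0, tolerance = 1e-9)

  # n = 3 vs 3: all 20 label assignments enumerated with the direct formula
  Y <- matrix(stats::rnorm(6L, mean = 1.5), 3L, 2L)
  Z <- rbind(X, Y)
  t2_direct <- function(i1) as.numeric(
    hotelling_t2(Z[i1, , drop = FALSE], Z[-i1, , drop = FALSE]))
  obs <- t2_direct(1:3)
  splits <- utils::combn(6L, 3L)
  t2_all <- apply(splits, 2L, t2_direct)
  p_exh <- mean(t2_all >= obs - 1e-12)

  B <- 50000L
  res <- permutation_hotelling(X, Y, B = B, seed = 65L)
  expect_equal(res$statistic, obs, tolerance = 1e-9)
  se <- sqrt(p_exh * (1 - p_exh) / B)
  expect_lt(abs(res$p_value - (1 + B * p_exh) / (B + 1)), 3 * se + 1e-9)

  # an enormous separation: only the 2 label splits reproducing the true
  # partition attain the observed statistic, so p floors at 2/20
  Yfar <- Y + 100
  far <- permutation_hotelling(X, Yfar, B = 999L, seed = 2L)
  expect_lt(abs(far$p_value - 0.1), 0.04)
})

test_that("scalar permutation test matches exhaustive enumeration", {
  expect_equal(eval(formals(permutation_mean_diff)$B), 10000L)

  a <- c(1.2, 3.4, 2.2)
  expect_equal(permutation_mean_diff(a, a, B = 99L, seed = 3L)$p_value, 1)

  b <- c(4.1, 5.0, 3.9)
  z <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  splits <- utils::combn(6L, 3L)
  stat_all <- apply(splits, 2L, function(i1)
    abs(mean(z[i1]) - mean(z[-i1])))
  p_exh <- mean(stat_all >= obs - 1e-12)
  B <- 50000L
  res <- permutation_mean_diff(a, b, B = B, seed = 66L)
  se <- sqrt(p_exh * (1 - p_exh) / B)
  expect_lt(abs(res$p_value - (1 + B * p_exh) / (B + 1)), 3 * se + 1e-9)
})

test_that("pairwise tests cover all group pairs with derived seeds", {
  set.seed(67)
  arr <- array(stats::rnorm(20L * 3L * 35L), c(20L, 3L, 35L))
  pca <- pca_shapes(fake_aligned(arr))
  groups <- rep(paste0("G", 1:7), each = 5L)
  pt <- pairwise_group_tests(pca, groups, B = 49L, seed = 68L)
  expect_equal(sum(!is.na(pt$p_values)), 21L)
  expect_equal(pt$labels, paste0("G", 1:7))

  # reruns reproduce bit-identical matrices; cells do not interact
  pt2 <- pairwise_group_tests(pca, groups, B = 49L, seed = 68L)
  expect_identical(pt$p_values, pt2$p_values)
  sub <- pairwise_group_tests(pca, groups, B = 49L, seed = 68L,
                              n_pcs = pt$n_pcs)
  expect_identical(sub$p_values["G4", "G2"], pt$p_values["G4", "G2"])

  # a huge injected offset saturates every cell involving that group
  sco <- pca$scores
  sco[groups == "G7", ] <- sco[groups == "G7", ] + 50
  pca2 <- pca
  pca2$scores <- sco
  pt3 <- pairwise_group_tests(pca2, groups, B = 199L, seed = 69L,
                              n_pcs = 2L)
  expect_equal(unname(pt3$p_values["G7", "G1"]), 1 / 200)

  expect_warning(
    pairwise_group_tests(pca, c(rep("A", 2L), rep("B", 17L), rep("C", 16L)),
                         B = 9L),
    "n < 3")
})

test_that("allometry screening reproduces a hand-computed ANOVA", {
  set.seed(70)
  arr <- array(stats::rnorm(20L * 3L * 12L), c(20L, 3L, 12L))
  pca <- pca_shapes(fake_aligned(arr))

  # constant scores: F = 0 by convention
  pcac <- pca
  pcac$scores[, 1L] <- 0
  lens <- stats::runif(12L, 300, 400)
  r0 <- allometry_anova(pcac, lens, n_pcs = 1L)
  expect_equal(r0$F, 0)

  # scores perfectly linear in length: R^2 = 1
  pcal <- pca
  pcal$scores[, 1L] <- 2.5 * lens - 10
  r1 <- suppressWarnings(allometry_anova(pcal, lens, n_pcs = 1L))
  expect_equal(r1$r_squared, 1, tolerance = 1e-9)
  expect_lt(r1$p, 1e-12)
  expect_equal(r1$slope, 2.5, tolerance = 1e-9)

  # 6-point hand oracle via explicit sums
  x <- c(301, 315, 322, 338, 350, 361)
  y <- c(0.11, -0.02, 0.07, -0.12, -0.30, -0.21)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  r2 <- sxy^2 / (sxx * syy)
  f <- r2 * 4 / (1 - r2)
  pca6 <- pca
  pca6$scores <- pca$scores[1:6, , drop = FALSE]
  pca6$scores[, 1L] <- y
  r6 <- allometry_anova(pca6, x, n_pcs = 1L)
  expect_equal(r6$slope, sxy / sxx, tolerance = 1e-9)
  expect_equal(r6$F, f, tolerance = 1e-9)
  expect_equal(r6$p, stats::pf(f, 1, 4, lower.tail = FALSE),
               tolerance = 1e-9)

  # zero length variance is reported as NA with a warning
  expect_warning(rna <- allometry_anova(pca, rep(350, 12L), n_pcs = 1L),
                 "variance")
  expect_true(is.na(rna$F))
})

test_that("measurement error separates repeat noise from real variation", {
  expect_equal(eval(formals(measurement_error)$threshold), 0.95)

  set.seed(71)
  tpl <- resample_equidistant(template_curve(8, 3, 350))$coords

  # identical repeats: zero error, perfect reliability
  sets_id <- lapply(1:4, function(s) {
    coords <- tpl + matrix(stats::rnorm(60L, 0, 0.5), 20L)
    rep(list(semilandmark_curve(coords, specimen_id = paste0("s", s))), 3L)
  })
  rep_id <- measurement_error(sets_id)
  expect_equal(rep_id$overall_me, 0, tolerance = 1e-10)
  expect_equal(rep_id$reliability, 1)
  expect_true(rep_id$acceptable)

  # noise propagation: package value (with superimposition) vs a direct
  # no-superimposition oracle on the same configurations
  sigma_t <- 0.5
  sigma_e <- 0.05
  S <- 20L
  R <- 4L
  sets <- lapply(seq_len(S), function(s) {
    spec <- tpl + matrix(stats::rnorm(60L, 0, sigma_t), 20L)
    lapply(seq_len(R), function(r)
      semilandmark_curve(spec + matrix(stats::rnorm(60L, 0, sigma_e), 20L),
                         specimen_id = sprintf("s%d_r%d", s, r)))
  })
  rel_oracle <- local({
    arrs <- lapply(sets, function(ss)
      simplify2array(lapply(ss, function(cv) cv$coords)))
    rep_sd <- t(vapply(arrs, function(a) {
      m <- apply(a, c(1L, 2L), mean)
      sqrt(apply(sweep(a, c(1L, 2L), m)^2, 1L, sum) / (R - 1L))
    }, numeric(20L)))
    means <- simplify2array(lapply(arrs, function(a)
      apply(a, c(1L, 2L), mean)))
    grand <- apply(means, c(1L, 2L), mean)
    tot <- mean(sqrt(apply(sweep(means, c(1L, 2L), grand)^2, 1L, sum) /
                       (S - 1L)))
    1 - mean(colMeans(rep_sd))^2 / tot^2
  })
  rep_pkg <- measurement_error(sets, slide = FALSE)
  expect_equal(rep_pkg$reliability, rel_oracle, tolerance = 0.02)
  expect_gt(rep_pkg$reliability, 0.95)

  # sliding can only remove (tangential) repeat noise
  rep_slid <- measurement_error(sets, slide = TRUE)
  expect_gte(rep_slid$reliability + 1e-6, rep_pkg$reliability)

  expect_error(measurement_error(sets[1L]), "at least 2 specimens")
  expect_error(measurement_error(lapply(sets, `[`, 1L)),
               "at least 2 repeats")
})
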
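#' Principal component analysis of aligned shapes
#'
#' Eigendecomposition of the covariance of the flattened (3k-vector)
#' Procrustes shape coordinates. Components are ordered by decreasing
#' eigenvalue; eigenvalues that are numerically zero (below `1e-10` of the
#' leading one) are dropped, so variance fractions sum to one over the
#' retained spectrum. The sign of each component is fixed by making its
#' largest-magnitude loading element positive, which makes the
#' decomposition deterministic.
#'
#' @param sample An `aligned_sample` (n >= 3).
#' @return A `shape_pca`: list with `eigenvalues`, `variance_fractions`,
#'   `scores` (n x m), `loadings` (m x 3k, one component per row),
#'   `mean_shape_flat` (3k), `k`, and `n_retained_broken_stick`.
#' @export
pca_shapes <- function(sample) {
  stopifnot(inherits(sample, "aligned_sample"))
  n <- dim(sample$shapes)[3L]
  if (n < 3L) stop("PCA needs at least 3 specimens")
  k <- dim(sample$shapes)[1L]
  X <- t(apply(sample$shapes, 3L, as.vector))  # n x 3k
  mu <- colMeans(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- ev > max(ev) * 1e-10
  ev <- ev[keep]
  rot <- pc$rotation[, keep, drop = FALSE]
  sco <- pc$x[, keep, drop = FALSE]
  for (j in seq_along(ev)) {     # deterministic sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  vf <- ev / sum(ev)
  structure(list(eigenvalues = ev, variance_fractions = vf,
                 scores = sco, loadings = t(rot), mean_shape_flat = mu,
                 k = k, specimen_ids = sample$specimen_ids,
                 n_retained_broken_stick = broken_stick_retain(vf)),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  m <- min(5L, length(x$variance_fractions))
  cat(sprintf("<shape_pca> %d components; broken-stick retains %d\n",
              length(x$eigenvalues), x$n_retained_broken_stick))
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(m),
                    100 * x$variance_fractions[seq_len(m)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Broken-stick retention count
#'
#' With p components, the broken-stick expectation for the j-th largest
#' piece of a unit stick broken at p - 1 uniform points is
#' `b_j = (1/p) * sum_{i=j}^{p} 1/i`. A component is considered
#' interpretable while its variance fraction exceeds its broken-stick
#' expectation; the returned count is the length of the leading run of such
#' components (possibly zero).
#'
#' @param variance_fractions Non-negative fractions summing to at most 1.
#' @return Integer retention count.
#' @export
broken_stick_retain <- function(variance_fractions) {
  p <- length(variance_fractions)
  if (p == 0L) stop("empty variance fractions")
  stopifnot(all(variance_fractions >= 0),
            sum(variance_fractions) <= 1 + 1e-9)
  b <- rev(cumsum(rev(1 / seq_len(p)))) / p
  above <- variance_fractions > b
  r <- 0L
  while (r < p && above[r + 1L]) r <- r + 1L
  r
}

as_score_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Two-sample Hotelling's T-squared statistic
#'
#' `T2 = (n1 * n2 / (n1 + n2)) * d' S_pooled^-1 d`, with `d` the mean
#' difference and `S_pooled` the pooled covariance. Invariant to any common
#' invertible linear map of the variables. If the pooled covariance is
#' singular, the statistic is computed on the largest leading variable
#' subset with an invertible pooled covariance (with a warning) — sensible
#' when the variables are PC scores ordered by variance.
#'
#' @param X,Y n1 x m and n2 x m score matrices (vectors are treated as
#'   one-column matrices).
#' @return The (non-negative) statistic with attribute `n_vars_used`.
#' @export
hotelling_t2 <- function(X, Y) {
  X <- as_score_matrix(X); Y <- as_score_matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must have the same variables")
  n1 <- nrow(X); n2 <- nrow(Y); m <- ncol(X)
  if (n1 + n2 - 2L <= 0) stop("insufficient sample size")
  use <- m
  repeat {
    if (use == 0L) stop("pooled covariance singular in every leading subset")
    Xs <- X[, seq_len(use), drop = FALSE]
    Ys <- Y[, seq_len(use), drop = FALSE]
    if (n1 + n2 - 2L > use) {
      sp <- ((n1 - 1L) * stats::cov(Xs) + (n2 - 1L) * stats::cov(Ys)) /
        (n1 + n2 - 2L)
      ch <- tryCatch(chol(sp), error = function(e) NULL)
      if (!is.null(ch)) break
    }
    use <- use - 1L
  }
  if (use < m)
    warning("singular pooled covariance: using leading ", use, " of ", m,
            " variables")
  d <- colMeans(Xs) - colMeans(Ys)
  z <- backsolve(ch, d, transpose = TRUE)
  structure((n1 * n2 / (n1 + n2)) * sum(z^2), n_vars_used = use)
}

# Shared fast machinery for label-permutation tests. Under permutation of
# group labels the total scatter S_t about the grand mean is fixed, and
# T2 = (N - 2) c q / (1 - c q) with q = d' S_t^-1 d and c = n1 n2 / N
# (Sherman-Morrison), a strictly increasing function of q. Permutations are
# therefore ranked by q with a single Cholesky factorization.
perm_t2_machine <- function(Z, n1) {
  N <- nrow(Z)
  n2 <- N - n1
  Zc <- sweep(Z, 2L, colMeans(Z))
  use <- ncol(Z)
  repeat {
    if (use == 0L) stop("total scatter singular in every leading subset")
    St <- crossprod(Zc[, seq_len(use), drop = FALSE])
    ch <- tryCatch(chol(St), error = function(e) NULL)
    if (!is.null(ch)) break
    use <- use - 1L
  }
  cc <- n1 * n2 / N
  q_of <- function(idx1) {
    d <- colMeans(Z[idx1, seq_len(use), drop = FALSE]) -
      colMeans(Z[-idx1, seq_len(use), drop = FALSE])
    z <- backsolve(ch, d, transpose = TRUE)
    sum(z^2)
  }
  t2_of_q <- function(q) {
    denom <- pmax(1 - cc * q, 0)
    ifelse(denom <= 0, Inf, (N - 2L) * cc * q / denom)
  }
  list(q_of = q_of, t2_of_q = t2_of_q, n_vars_used = use, N = N, n1 = n1)
}

perm_test_result <- function(statistic, p_value, B, n_vars, group_sizes,
                             seed) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_permutations = B, n_retained_vars = n_vars,
                 group_sizes = group_sizes, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> statistic = %.4g, p = %.4g (B = %d, n = %s)\n",
              x$statistic, x$p_value, x$n_permutations,
              paste(x$group_sizes, collapse = "+")))
  invisible(x)
}

#' Permutation Hotelling's T-squared test
#'
#' Two-sample shape test calibrated by uniformly random label permutations.
#' The p-value uses the add-one convention
#' `p = (1 + #[T2_perm >= T2_obs]) / (B + 1)`, so it is never zero and its
#' minimum attainable value is `1/(B + 1)`.
#'
#' @param X,Y Score matrices (rows = specimens).
#' @param B Number of permutations (default 10000).
#' @param seed Optional RNG seed for reproducibility.
#' @return A `perm_test` result (statistic, p-value, B, variables used,
#'   group sizes, seed).
#' @export
permutation_hotelling <- function(X, Y, B = 10000L, seed = NULL) {
  stopifnot(B >= 1L)
  X <- as_score_matrix(X); Y <- as_score_matrix(Y)
  n1 <- nrow(X)
  Z <- rbind(X, Y)
  mach <- perm_t2_machine(Z, n1)
  q_obs <- mach$q_of(seq_len(n1))
  t2_obs <- mach$t2_of_q(q_obs)
  exceed <- with_seed(seed, {
    qs <- vapply(seq_len(B), function(b)
      mach$q_of(sample.int(mach$N, n1)), 0)
    sum(qs >= q_obs * (1 - 1e-12))
  })
  perm_test_result(as.numeric(t2_obs), (1 + exceed) / (B + 1),
                   as.integer(B), mach$n_vars_used,
                   c(n1, nrow(Y)), seed)
}

#' Pairwise permutation shape tests between groups
#'
#' Runs [permutation_hotelling()] on every unordered pair of groups, using
#' the broken-stick-retained PC scores (at least one PC). Per-cell RNG
#' seeds are derived deterministically from the master seed and the pair's
#' labels, so adding or removing a group leaves other cells untouched.
#' Groups with fewer than 3 specimens are excluded with a warning.
#'
#' @param pca A `shape_pca` from [pca_shapes()].
#' @param groups Group label per specimen (factor or character; factor
#'   level order defines the matrix ordering).
#' @param B Permutations per cell (default 10000).
#' @param alpha Significance level used for flagging (default 0.05).
#' @param seed Master seed.
#' @param n_pcs Override the number of PCs tested (default: broken-stick
#'   retention, minimum 1).
#' @return A `pairwise_tests` object: group labels, lower-triangular
#'   p-value matrix, significance flags, and the per-cell `perm_test`s.
#' @export
pairwise_group_tests <- function(pca, groups, B = 10000L, alpha = 0.05,
                                 seed = NULL, n_pcs = NULL) {
  stopifnot(inherits(pca, "shape_pca"))
  groups <- if (is.factor(groups)) droplevels(groups) else
    factor(groups, levels = unique(groups))
  if (length(groups) != nrow(pca$scores))
    stop("group labels do not match score rows")
  sizes <- table(groups)
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning("excluding groups with n < 3: ", paste(small, collapse = ", "))
    keepi <- !(groups %in% small)
    groups <- droplevels(groups[keepi])
    sco <- pca$scores[keepi, , drop = FALSE]
  } else sco <- pca$scores
  labs <- levels(groups)
  if (length(labs) < 2L) stop("need at least 2 groups with n >= 3")
  m <- n_pcs %||% max(pca$n_retained_broken_stick, 1L)
  m <- min(m, ncol(sco))
  sco <- sco[, seq_len(m), drop = FALSE]
  pmat <- matrix(NA_real_, length(labs), length(labs),
                 dimnames = list(labs, labs))
  cells <- list()
  for (i in seq_along(labs)[-1L]) for (j in seq_len(i - 1L)) {
    key <- paste(labs[j], labs[i], sep = "|")
    res <- permutation_hotelling(sco[groups == labs[i], , drop = FALSE],
                                 sco[groups == labs[j], , drop = FALSE],
                                 B = B,
                                 seed = if (is.null(seed)) NULL else
                                   child_seed(seed, key))
    pmat[i, j] <- res$p_value
    cells[[key]] <- res
  }
  structure(list(labels = labs, p_values = pmat,
                 significant = pmat < alpha, alpha = alpha, B = B,
                 n_pcs = m, cells = cells, group_sizes = as.vector(sizes)),
            class = "pairwise_tests")
}

#' @export
print.pairwise_tests <- function(x, ...) {
  cat(sprintf(
    "<pairwise_tests> %d groups, %d cells, B = %d, alpha = %g, %d PC(s)\n",
    length(x$labels), sum(!is.na(x$p_values)), x$B, x$alpha, x$n_pcs))
  print(round(x$p_values[-1L, -ncol(x$p_values), drop = FALSE], 4))
  invisible(x)
}

#' Permutation test for a difference in means of a scalar measure
#'
#' Two-sided test on `|mean(a) - mean(b)|` with uniformly random label
#' permutations and the add-one p-value convention. Used for maximal-length
#' comparisons between groups.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param B Number of permutations (default 10000).
#' @param seed Optional RNG seed.
#' @return A `perm_test` result.
#' @export
permutation_mean_diff <- function(a, b, B = 10000L, seed = NULL) {
  stopifnot(B >= 1L, length(a) >= 1L, length(b) >= 1L)
  z <- c(a, b)
  n1 <- length(a)
  N <- length(z)
  obs <- abs(mean(a) - mean(b))
  tot <- sum(z)
  exceed <- with_seed(seed, {
    stat <- vapply(seq_len(B), function(i) {
      s1 <- sum(z[sample.int(N, n1)])
      abs(s1 / n1 - (tot - s1) / (N - n1))
    }, 0)
    sum(stat >= obs * (1 - 1e-12))
  })
  perm_test_result(obs, (1 + exceed) / (B + 1), as.integer(B), 1L,
                   c(n1, N - n1), seed)
}

#' Allometry screening by per-component regression on curve length
#'
#' For each retained PC and each stratum, fits the simple linear model
#' `score ~ curve_length` and reports the slope, R-squared, the ANOVA F
#' statistic `F = R2 (n - 2) / (1 - R2)` and its p-value on (1, n - 2)
#' degrees of freedom. A stratum with zero length variance yields NA with a
#' warning; a component with zero score variance in a stratum yields F = 0.
#'
#' @param pca A `shape_pca`.
#' @param curve_lengths Per-specimen curve arc length (mm), aligned with
#'   the PCA score rows.
#' @param strata Optional stratum label per specimen (e.g. sex within
#'   group); default is a single pooled stratum.
#' @param n_pcs Number of leading PCs to screen (default: broken-stick
#'   retention, minimum 1).
#' @return Data frame with one row per stratum x PC: `stratum`, `pc`, `n`,
#'   `slope`, `r_squared`, `F`, `p`.
#' @export
allometry_anova <- function(pca, curve_lengths, strata = NULL,
                            n_pcs = NULL) {
  stopifnot(inherits(pca, "shape_pca"),
            length(curve_lengths) == nrow(pca$scores))
  if (is.null(strata)) strata <- rep("pooled", length(curve_lengths))
  strata <- factor(strata, levels = unique(as.character(strata)))
  m <- min(n_pcs %||% max(pca$n_retained_broken_stick, 1L),
           ncol(pca$scores))
  out <- list()
  for (st in levels(strata)) {
    sel <- strata == st
    n <- sum(sel)
    if (n < 4L) {
      warning("stratum '", st, "' has n < 4; skipped")
      next
    }
    len <- curve_lengths[sel]
    if (stats::var(len) == 0) {
      warning("zero curve-length variance in stratum '", st, "'")
      out[[st]] <- data.frame(stratum = st, pc = seq_len(m), n = n,
                              slope = NA_real_, r_squared = NA_real_,
                              F = NA_real_, p = NA_real_)
      next
    }
    rows <- lapply(seq_len(m), function(j) {
      sc <- pca$scores[sel, j]
      if (stats::var(sc) == 0)
        return(data.frame(stratum = st, pc = j, n = n, slope = 0,
                          r_squared = 0, F = 0, p = 1))
      fit <- stats::lm(sc ~ len)
      r2 <- summary(fit)$r.squared
      Fst <- r2 * (n - 2L) / (1 - r2)
      data.frame(stratum = st, pc = j, n = n,
                 slope = unname(stats::coef(fit)[2L]), r_squared = r2,
                 F = Fst, p = stats::pf(Fst, 1L, n - 2L, lower.tail = FALSE))
    })
    out[[st]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intra-observer measurement error and reliability
#'
#' Quantifies digitization repeatability from repeated semilandmark
#' configurations of the same specimens. All repeats of all specimens are
#' jointly superimposed ([gpa()] followed by [slide_semilandmarks()]), then:
#' per specimen and landmark, the repeat SD is the root mean squared 3D
#' deviation of the landmark from its repeat mean (denominator R - 1);
#' `per_landmark_sd` averages this over specimens, `overall_me` over
#' landmarks. `total_sd` is the between-specimen SD of the repeat-mean
#' landmark positions on the same 3D-norm scale. The reliability
#' coefficient is `1 - overall_me^2 / total_sd^2` (clipped to [0, 1]):
#' 1 at zero error, and comparable to the conventional 0.95 acceptability
#' threshold.
#'
#' @param repeat_sets List (one element per specimen, >= 2 specimens) of
#'   lists of [semilandmark_curve()] repeats (>= 2 per specimen).
#' @param threshold Acceptability threshold for the reliability coefficient
#'   (default 0.95).
#' @param slide Slide semilandmarks during the joint superimposition
#'   (default TRUE, matching the analysis pipeline).
#' @return An `error_report`: `per_landmark_sd`, `overall_me`, `total_sd`,
#'   `reliability`, `threshold`, `acceptable`.
#' @export
measurement_error <- function(repeat_sets, threshold = 0.95, slide = TRUE) {
  S <- length(repeat_sets)
  if (S < 2L) stop("need at least 2 specimens")
  reps <- lengths(repeat_sets)
  if (any(reps < 2L)) stop("every specimen needs at least 2 repeats")
  flat <- unlist(repeat_sets, recursive = FALSE)
  idx <- rep(seq_len(S), reps)
  aligned <- gpa(flat)
  if (slide) aligned <- slide_semilandmarks(aligned)
  shapes <- aligned$shapes
  k <- dim(shapes)[1L]
  rep_sd <- matrix(NA_real_, S, k)     # per specimen x landmark
  means <- array(NA_real_, c(k, 3L, S))
  for (s in seq_len(S)) {
    sub <- shapes[, , idx == s, drop = FALSE]
    m <- apply(sub, c(1L, 2L), mean)
    means[, , s] <- m
    dev2 <- sweep(sub, c(1L, 2L), m)^2
    rep_sd[s, ] <- sqrt(apply(dev2, 1L, sum) / (reps[s] - 1L))
  }
  per_landmark_sd <- colMeans(rep_sd)
  overall_me <- mean(per_landmark_sd)
  grand <- apply(means, c(1L, 2L), mean)
  dev2 <- sweep(means, c(1L, 2L), grand)^2
  total_sd <- mean(sqrt(apply(dev2, 1L, sum) / (S - 1L)))
  if (total_sd == 0) {
    warning("zero between-specimen variation: reliability undefined")
    rel <- NA_real_
  } else {
    rel <- min(max(1 - overall_me^2 / total_sd^2, 0), 1)
  }
  structure(list(per_landmark_sd = per_landmark_sd,
                 overall_me = overall_me, total_sd = total_sd,
                 reliability = rel, threshold = threshold,
                 acceptable = !is.na(rel) && rel >= threshold),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "<error_report> overall ME = %.4g, between-specimen SD = %.4g\n",
    x$overall_me, x$total_sd))
  cat(sprintf("  reliability = %.4f (threshold %.2f: %s)\n",
              x$reliability, x$threshold,
              if (isTRUE(x$acceptable)) "acceptable" else "NOT acceptable"))
  invisible(x)
}
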
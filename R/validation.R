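#' Run one null two-group shape test end to end
#'
#' Draws two groups of specimens from one synthetic curve distribution (no
#' group difference), runs the full analysis chain — equidistant resampling,
#' GPA with semilandmark sliding, shape PCA, broken-stick retention
#' (minimum one PC) — and returns the permutation Hotelling test of the two
#' arbitrary labels. Used to calibrate the empirical type-I error of the
#' pipeline.
#'
#' @param seed RNG seed for this dataset.
#' @param n_per_group Specimens per group (default 20).
#' @param B Permutations (default 1000).
#' @param group A [group_params()] giving the common distribution; default
#'   is a mid-range group from [default_study_design()].
#' @param design_opts List of [study_design()] overrides (noise, point
#'   range, apex shift).
#' @return A `perm_test` result.
#' @export
null_shape_test <- function(seed, n_per_group = 20L, B = 1000L,
                            group = NULL, design_opts = list()) {
  if (is.null(group)) {
    group <- default_study_design()$groups[[4L]]
    group$name <- "NULL"
  }
  group$n <- 2L * n_per_group
  group$n_male <- n_per_group
  # a single distribution: no sex effect, or the block-wise sex assignment
  # would make the two halves genuinely different
  group$sex_effect <- c(0, 0, 0)
  design <- do.call(study_design,
                    c(list(groups = list(group), seed = seed), design_opts))
  specimens <- generate_study(design)
  curves <- lapply(specimens, function(sp)
    resample_equidistant(sp$polyline, specimen_id = sp$specimen_id))
  aligned <- slide_semilandmarks(gpa(curves))
  pca <- pca_shapes(aligned)
  m <- max(pca$n_retained_broken_stick, 1L)
  sco <- pca$scores[, seq_len(m), drop = FALSE]
  # all specimens are iid draws, so the index split is an arbitrary label
  permutation_hotelling(sco[seq_len(n_per_group), , drop = FALSE],
                        sco[-seq_len(n_per_group), , drop = FALSE],
                        B = B, seed = child_seed(seed, "null-test"))
}

#' Empirical type-I error of the pipeline shape test
#'
#' Repeats [null_shape_test()] over independently seeded null datasets and
#' reports the fraction rejected at `alpha`. With a well-calibrated
#' permutation test this fraction matches `alpha` up to binomial noise.
#'
#' @param n_datasets Number of null datasets (default 500).
#' @param n_per_group Specimens per group (default 20).
#' @param B Permutations per test (default 1000).
#' @param alpha Nominal level (default 0.05).
#' @param seed Master seed; per-dataset seeds are derived from it.
#' @param design_opts Passed to [null_shape_test()].
#' @return List: `rate` (rejection fraction), `n_datasets`, `alpha`,
#'   `p_values`.
#' @export
type_i_error_rate <- function(n_datasets = 500L, n_per_group = 20L,
                              B = 1000L, alpha = 0.05, seed = 1L,
                              design_opts = list()) {
  pvals <- vapply(seq_len(n_datasets), function(i)
    null_shape_test(child_seed(seed, paste0("null-dataset-", i)),
                    n_per_group = n_per_group, B = B,
                    design_opts = design_opts)$p_value, 0)
  list(rate = mean(pvals < alpha), n_datasets = n_datasets, alpha = alpha,
       p_values = pvals)
}

#' Between-specimen shape coordinate SD at specimen scale
#'
#' Superimposes noise-free digitizations of a set of specimens (GPA plus
#' sliding) and returns the mean, over landmarks and axes, of the SD of the
#' aligned coordinates across specimens, rescaled to mm by the mean
#' centroid size. This is the scale on which digitization noise competes
#' with real between-specimen shape differences: raw coordinate SDs would
#' be dominated by the position, orientation, and length variation that
#' superimposition removes before any shape comparison.
#'
#' @param curves List of [semilandmark_curve()] objects.
#' @return Between-specimen coordinate SD (mm at specimen scale).
#' @export
between_specimen_sd <- function(curves) {
  aligned <- slide_semilandmarks(gpa(curves))
  sds <- apply(aligned$shapes, c(1L, 2L), stats::sd)
  mean(sds) * mean(aligned$centroid_sizes)
}

#' Simulated intra-observer reliability study
#'
#' Emulates the repeat-digitization protocol: `n_specimens` specimens are
#' drawn from one group, and each is re-digitized `n_repeats` times with
#' per-point noise SD set to `noise_frac` of the between-specimen shape
#' coordinate SD (see [between_specimen_sd()]; measured from noise-free
#' digitizations of the same specimens). All repeats are jointly
#' superimposed and [measurement_error()] summarizes repeatability.
#'
#' @param n_specimens Number of specimens (default 15).
#' @param n_repeats Repeats per specimen (default 3).
#' @param noise_frac Repeat noise SD as a fraction of the between-specimen
#'   shape coordinate SD (default 0.02). Ignored when `noise_mm` is given.
#' @param noise_mm Absolute per-point noise SD in mm (optional; overrides
#'   `noise_frac`).
#' @param seed Master seed.
#' @param threshold Acceptability threshold (default 0.95).
#' @return The `error_report`, with the derived `noise_mm` and
#'   `between_sd_mm` attached as attributes.
#' @export
repeat_reliability_study <- function(n_specimens = 15L, n_repeats = 3L,
                                     noise_frac = 0.02, noise_mm = NULL,
                                     seed = 1L, threshold = 0.95) {
  group <- default_study_design()$groups[[4L]]
  group$name <- "ERR"
  group$n <- n_specimens
  group$n_male <- floor(n_specimens / 2)
  design <- study_design(list(group), digitization_noise_mm = 0,
                         seed = child_seed(seed, "reliability"))
  specimens <- generate_study(design)
  clean <- lapply(specimens, function(sp)
    resample_equidistant(sp$polyline, specimen_id = sp$specimen_id))
  between_sd <- between_specimen_sd(clean)
  if (is.null(noise_mm)) noise_mm <- noise_frac * between_sd
  repeat_sets <- lapply(seq_along(specimens), function(i) {
    reps <- generate_repeats(specimens[[i]], k = n_repeats,
                             noise_mm = noise_mm,
                             seed = child_seed(seed, paste0("rep-", i)))
    lapply(seq_along(reps), function(r)
      resample_equidistant(reps[[r]],
                           specimen_id = sprintf("%s_r%d",
                                                 specimens[[i]]$specimen_id,
                                                 r)))
  })
  rep_report <- measurement_error(repeat_sets, threshold = threshold)
  attr(rep_report, "noise_mm") <- noise_mm
  attr(rep_report, "between_sd_mm") <- between_sd
  rep_report
}

#' Recover per-group mean bow amplitudes from a generated study
#'
#' Resamples every specimen's polyline and estimates its A-P bow amplitude
#' with [estimate_bow_amplitude()]; returns the group means in the design's
#' chronological order. With the default declining-amplitude design the
#' recovered means should decrease strictly — the generator's ground-truth
#' check.
#'
#' @param specimens A `digitized_study` from [generate_study()].
#' @param k Semilandmarks per curve (default 20).
#' @return Named numeric vector of group-mean recovered amplitudes (mm), in
#'   chronological order.
#' @export
recover_group_amplitudes <- function(specimens, k = 20L) {
  meta <- study_metadata(specimens)
  a_hat <- vapply(specimens, function(sp)
    estimate_bow_amplitude(resample_equidistant(sp$polyline, k = k)), 0)
  grp <- factor(meta$group, levels = unique(meta$group))
  tapply(a_hat, grp, mean)
}
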
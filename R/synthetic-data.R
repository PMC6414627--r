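# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Deterministic child seed for a (master seed, string key) pair, so that
# per-group / per-cell streams do not shift when other cells are added.
child_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  if (is.null(seed)) seed <- 0
  as.integer((h + (as.numeric(seed) %% 2147483647) * 2654435) %% 2147483647)
}

#' Parameters of one chronological group
#'
#' Describes the generative shape distribution of one chronological sample:
#' mean anterior-posterior (A-P) bow amplitude, mean medio-lateral (M-L)
#' sigmoid amplitude, mean curve chord length, their between-specimen
#' standard deviations, the male/female split, and an additive sex effect.
#'
#' @param name Group label.
#' @param n Specimen count (>= 1).
#' @param n_male Number of male specimens (rest are female).
#' @param ap_amplitude_mm Mean A-P bow amplitude A (mm, > 0).
#' @param ml_amplitude_mm Mean M-L sigmoid amplitude M (mm, > 0).
#' @param length_mm Mean proximo-distal chord length L (mm, > 0).
#' @param sd_ap,sd_ml,sd_length Between-specimen standard deviations (>= 0).
#' @param sex_effect Numeric length-3 vector `(dA, dM, dL)` added to the
#'   male means (females use the group means unchanged).
#' @return A `group_params` list.
#' @export
group_params <- function(name, n, n_male = floor(n / 2),
                         ap_amplitude_mm, ml_amplitude_mm, length_mm,
                         sd_ap = 0.6, sd_ml = 0.5, sd_length = 18,
                         sex_effect = c(0.2, 0.1, 14)) {
  stopifnot(n >= 1, n_male >= 0, n_male <= n,
            is.finite(ap_amplitude_mm), ap_amplitude_mm >= 0,
            is.finite(ml_amplitude_mm), ml_amplitude_mm >= 0,
            is.finite(length_mm), length_mm > 0,
            sd_ap >= 0, sd_ml >= 0, sd_length >= 0,
            length(sex_effect) == 3L)
  structure(list(name = as.character(name), n = as.integer(n),
                 n_male = as.integer(n_male),
                 ap_amplitude_mm = ap_amplitude_mm,
                 ml_amplitude_mm = ml_amplitude_mm,
                 length_mm = length_mm, sd_ap = sd_ap, sd_ml = sd_ml,
                 sd_length = sd_length, sex_effect = sex_effect),
            class = "group_params")
}

#' Study design for the synthetic generator
#'
#' @param groups List of [group_params()] in chronological order.
#' @param digitization_noise_mm Per-point isotropic digitization noise SD
#'   (mm, >= 0).
#' @param points_min,points_max Range of dense polyline point counts; each
#'   specimen's count is drawn uniformly from this range.
#' @param apex_shift Exponent p of the bow profile `sin(pi * s^p)`; p < 1
#'   shifts the A-P apex toward the proximal half of the shaft.
#' @param seed Random seed for [generate_study()] (`NULL` = current stream).
#' @return A `study_design` list.
#' @export
study_design <- function(groups, digitization_noise_mm = 0.03,
                         points_min = 1800L, points_max = 2000L,
                         apex_shift = 0.8, seed = NULL) {
  stopifnot(length(groups) >= 1L,
            all(vapply(groups, inherits, TRUE, "group_params")),
            points_min >= 21L, points_min <= points_max,
            digitization_noise_mm >= 0, apex_shift > 0)
  structure(list(groups = groups,
                 digitization_noise_mm = digitization_noise_mm,
                 points_min = as.integer(points_min),
                 points_max = as.integer(points_max),
                 apex_shift = apex_shift, seed = seed),
            class = "study_design")
}

#' Default seven-group diachronic study design (synthetic)
#'
#' A synthetic stand-in for a seven-period Central European tibia sample
#' (Eneolithic through 21st century), with the published per-group specimen
#' counts and male/female splits. The shape parameters are NOT estimates
#' from any real sample: they encode the qualitative diachronic pattern the
#' generator is meant to emulate — an A-P bow amplitude declining from 8 to
#' about 4.4 mm, an M-L sigmoid amplitude rising from 2 to 5 mm, roughly
#' constant curve length with a 20th-century dip and a 21st-century peak —
#' with between-specimen spreads a skeletal sample of this kind plausibly
#' shows.
#'
#' @param seed Random seed stored in the design.
#' @return A [study_design()].
#' @export
default_study_design <- function(seed = NULL) {
  labels <- c("ENEOL", "BRONZE", "IRON", "EMED", "LMED", "C20", "C21")
  n      <- c(46L, 79L, 30L, 103L, 57L, 64L, 56L)
  n_male <- c(24L, 32L, 20L, 58L, 37L, 33L, 29L)
  ap     <- c(8.0, 7.5, 6.8, 6.2, 5.6, 4.9, 4.4)
  ml     <- c(2.0, 2.5, 3.0, 3.5, 4.0, 4.5, 5.0)
  len    <- c(356, 357, 356, 357, 355, 349, 362)
  groups <- lapply(seq_along(labels), function(i)
    group_params(labels[i], n[i], n_male[i], ap[i], ml[i], len[i]))
  study_design(groups, seed = seed)
}

#' Parametric template for an anterior crest curve
#'
#' For arc parameter s in `[0, 1]` the template is
#' `x = A * sin(pi * s^p)` (anterior bow), `y = M * sin(2 * pi * s)`
#' (single-period medio-lateral sigmoid), `z = -L * s` (proximo-distal
#' chord), sampled at `n_points` equally spaced values of s. The first point
#' (proximal curve start) is at the origin.
#'
#' @param A A-P bow amplitude (mm, >= 0).
#' @param M M-L sigmoid amplitude (mm, >= 0).
#' @param L Chord length (mm, > 0).
#' @param apex_shift Bow apex exponent p (> 0); p < 1 moves the apex
#'   proximally.
#' @param n_points Number of sampled points (>= 21).
#' @return A [polyline3d()].
#' @export
template_curve <- function(A, M, L, apex_shift = 0.8, n_points = 1900L) {
  if (!is.finite(L) || L <= 0) stop("chord length L must be finite and > 0")
  stopifnot(is.finite(A), A >= 0, is.finite(M), M >= 0,
            is.finite(apex_shift), apex_shift > 0, n_points >= 21L)
  s <- seq(0, 1, length.out = n_points)
  polyline3d(cbind(A * sin(pi * s^apex_shift),
                   M * sin(2 * pi * s),
                   -L * s),
             source_id = sprintf("template(A=%g,M=%g,L=%g,p=%g)",
                                 A, M, L, apex_shift))
}

# Truncated-normal draw: redraw until positive (avoids a point mass at 0
# that clipping would create). Counts redraws in the "truncations" attribute.
rnorm_pos <- function(mean, sd) {
  tries <- 0L
  repeat {
    v <- stats::rnorm(1L, mean, sd)
    if (v > 0 || sd == 0) break
    tries <- tries + 1L
    if (tries > 1000L) stop("cannot draw a positive value from N(",
                            mean, ", ", sd, ")")
  }
  structure(v, truncations = tries)
}

#' Draw one synthetic digitized specimen
#'
#' Individual amplitudes and length are drawn from truncated normal
#' distributions around the group means (male means offset by the group's
#' `sex_effect`); the dense polyline is the parametric template plus
#' isotropic per-point Gaussian digitization noise, with the point count
#' drawn uniformly from the design's range.
#'
#' @param group A [group_params()].
#' @param sex `"M"` or `"F"`.
#' @param design A [study_design()].
#' @param specimen_id Identifier stored with the specimen.
#' @return A `digitized_specimen`: list with `specimen_id`, `polyline`, and
#'   `meta` (group, sex, the drawn true A, M, L, and truncation count).
#' @export
sample_specimen <- function(group, sex = c("F", "M"), design,
                            specimen_id = NA_character_) {
  sex <- match.arg(sex)
  off <- if (sex == "M") group$sex_effect else c(0, 0, 0)
  A <- rnorm_pos(group$ap_amplitude_mm + off[1], group$sd_ap)
  M <- rnorm_pos(group$ml_amplitude_mm + off[2], group$sd_ml)
  L <- rnorm_pos(group$length_mm + off[3], group$sd_length)
  ntrunc <- attr(A, "truncations") + attr(M, "truncations") +
    attr(L, "truncations")
  np <- if (design$points_min == design$points_max) design$points_min else
    sample(design$points_min:design$points_max, 1L)
  tpl <- template_curve(as.numeric(A), as.numeric(M), as.numeric(L),
                        design$apex_shift, np)
  pts <- unclass(tpl) + matrix(stats::rnorm(3L * np, 0,
                                            design$digitization_noise_mm),
                               ncol = 3L)
  structure(list(specimen_id = specimen_id,
                 polyline = polyline3d(pts, source_id = specimen_id),
                 meta = list(group = group$name, sex = sex,
                             true_A = as.numeric(A), true_M = as.numeric(M),
                             true_L = as.numeric(L),
                             apex_shift = design$apex_shift,
                             truncations = ntrunc)),
            class = "digitized_specimen")
}

#' Generate a full synthetic study
#'
#' Deterministic given the design's seed: per-group specimen counts and
#' male/female splits follow the design, specimens are emitted in
#' chronological group order, and per-group RNG substreams are derived from
#' the master seed so one group's draws do not depend on another's.
#'
#' @param design A [study_design()].
#' @return List of `digitized_specimen` objects with attribute `design`.
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  specimens <- list()
  for (g in design$groups) {
    gspec <- with_seed(
      if (is.null(design$seed)) NULL else child_seed(design$seed, g$name), {
        sexes <- c(rep("M", g$n_male), rep("F", g$n - g$n_male))
        lapply(seq_len(g$n), function(i)
          sample_specimen(g, sexes[i], design,
                          specimen_id = sprintf("%s_%03d", g$name, i)))
      })
    specimens <- c(specimens, gspec)
  }
  attr(specimens, "design") <- design
  class(specimens) <- "digitized_study"
  specimens
}

#' @export
print.digitized_study <- function(x, ...) {
  meta <- study_metadata(x)
  cat(sprintf("<digitized_study> %d specimens in %d groups:\n",
              length(x), length(unique(meta$group))))
  print(table(factor(meta$group, levels = unique(meta$group)), meta$sex))
  invisible(x)
}

#' Extract specimen metadata from a generated study
#'
#' @param specimens A `digitized_study` (or plain list of specimens).
#' @return Data frame with one row per specimen: `specimen_id`, `group`,
#'   `sex`, and the true generative parameters `true_A`, `true_M`, `true_L`.
#' @export
study_metadata <- function(specimens) {
  do.call(rbind, lapply(specimens, function(sp)
    data.frame(specimen_id = sp$specimen_id, group = sp$meta$group,
               sex = sp$meta$sex, true_A = sp$meta$true_A,
               true_M = sp$meta$true_M, true_L = sp$meta$true_L,
               stringsAsFactors = FALSE)))
}

#' Simulate repeat digitizations of one specimen
#'
#' Produces `k` independent re-digitizations of the specimen's true
#' underlying curve: each repeat re-samples the template at an independently
#' drawn point count and adds fresh isotropic per-point noise, emulating an
#' observer re-tracing the crest on different days.
#'
#' @param specimen A `digitized_specimen`.
#' @param k Number of repeats (>= 2; the intra-observer error study design
#'   uses 3).
#' @param noise_mm Per-point isotropic digitization noise SD (mm).
#' @param points_min,points_max Dense point-count range for each repeat.
#' @param seed Optional seed.
#' @return List of `k` [polyline3d()] objects.
#' @export
generate_repeats <- function(specimen, k = 3L, noise_mm = 0.03,
                             points_min = 1800L, points_max = 2000L,
                             seed = NULL) {
  if (k < 2L) stop("need at least 2 repeat digitizations")
  m <- specimen$meta
  with_seed(seed, lapply(seq_len(k), function(r) {
    np <- if (points_min == points_max) points_min else
      sample(points_min:points_max, 1L)
    tpl <- template_curve(m$true_A, m$true_M, m$true_L, m$apex_shift, np)
    polyline3d(unclass(tpl) + matrix(stats::rnorm(3L * np, 0, noise_mm),
                                     ncol = 3L),
               source_id = sprintf("%s_rep%d", specimen$specimen_id, r))
  }))
}

#' Write a generated study to disk
#'
#' One `.asc` polyline file per specimen plus a `metadata.csv` with the
#' group, sex and true generative parameters.
#'
#' @param specimens A `digitized_study`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(specimens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in specimens)
    write_asc_polyline(sp$polyline,
                       file.path(dir, paste0(sp$specimen_id, ".asc")))
  utils::write.csv(study_metadata(specimens),
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}
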
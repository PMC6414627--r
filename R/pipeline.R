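#' Configuration for a full analysis run
#'
#' @param design A [study_design()] for synthetic input, or `NULL` when
#'   reading digitized data from `input_dir`.
#' @param input_dir Directory of `.asc` polylines plus a `metadata.csv`
#'   (columns `specimen_id`, `group`, `sex`); ignored when `design` is
#'   given.
#' @param k Semilandmarks per curve (default 20).
#' @param slide Slide interior semilandmarks after GPA (default TRUE).
#' @param B Permutations per test cell (default 10000).
#' @param alpha Significance level (default 0.05).
#' @param by_sex Also run the pairwise shape tests within each sex
#'   (default FALSE).
#' @param seed Master seed; child seeds for simulation and every test cell
#'   are derived from it deterministically.
#' @return A `run_config` list.
#' @export
run_config <- function(design = NULL, input_dir = NULL, k = 20L,
                       slide = TRUE, B = 10000L, alpha = 0.05,
                       by_sex = FALSE, seed = 1L) {
  if (is.null(design) && is.null(input_dir))
    stop("supply a synthetic design or an input directory")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input directory does not exist: ", input_dir)
  stopifnot(k >= 3L, B >= 1L, alpha > 0, alpha < 1)
  structure(list(design = design, input_dir = input_dir, k = as.integer(k),
                 slide = isTRUE(slide), B = as.integer(B), alpha = alpha,
                 by_sex = isTRUE(by_sex), seed = seed),
            class = "run_config")
}

load_input_dir <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  need <- c("specimen_id", "group", "sex")
  if (!all(need %in% names(meta)))
    stop("metadata.csv must contain columns: ", paste(need, collapse = ", "))
  polylines <- lapply(meta$specimen_id, function(id) {
    path <- file.path(dir, paste0(id, ".asc"))
    if (!file.exists(path)) stop("missing polyline for specimen ", id)
    read_asc_polyline(path)
  })
  list(polylines = polylines, meta = meta)
}

#' Run the full diachronic curvature analysis
#'
#' Executes all stages in order: simulate (or load) dense polylines,
#' resample to k semilandmarks, superimpose (GPA, optionally with
#' semilandmark sliding), PCA with broken-stick retention, pairwise
#' permutation shape tests, pairwise permutation curve-length tests,
#' allometry screening per sex, per-group mean shapes and difference fields
#' against the pooled consensus and between chronologically adjacent
#' groups (in a shared anatomical frame from the pooled consensus), and
#' PC1-PC2 group confidence ellipses. The manifest records the seed,
#' settings, group sizes and warnings raised during the run.
#'
#' @param config A [run_config()].
#' @return A `report_bundle` with elements `table` (semilandmark table),
#'   `aligned`, `pca`, `shape_tests`, `length_tests`, `allometry`,
#'   `fields`, `ellipses`, `frame`, `manifest`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warnings_seen <- character(0)
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  withCallingHandlers({
    if (!is.null(config$design)) {
      design <- config$design
      if (is.null(design$seed))
        design$seed <- child_seed(config$seed, "simulate")
      specimens <- stage("simulate", generate_study(design))
      meta <- study_metadata(specimens)
      polylines <- lapply(specimens, `[[`, "polyline")
    } else {
      inp <- stage("load", load_input_dir(config$input_dir))
      polylines <- inp$polylines
      meta <- inp$meta
    }
    curves <- stage("resample", lapply(seq_along(polylines), function(i)
      resample_equidistant(polylines[[i]], k = config$k,
                           specimen_id = meta$specimen_id[i])))
    tab <- semilandmark_table(curves, meta)
    aligned <- stage("align", {
      al <- gpa(curves)
      if (config$slide) al <- slide_semilandmarks(al)
      al
    })
    pca <- stage("pca", pca_shapes(aligned))
    groups <- factor(meta$group, levels = unique(meta$group))
    shape_tests <- list(
      pooled = pairwise_group_tests(pca, groups, B = config$B,
                                    alpha = config$alpha,
                                    seed = child_seed(config$seed,
                                                      "shape|pooled")))
    if (config$by_sex) for (sx in c("M", "F")) {
      sel <- meta$sex == sx
      sub_pca <- pca
      sub_pca$scores <- pca$scores[sel, , drop = FALSE]
      shape_tests[[sx]] <-
        pairwise_group_tests(sub_pca, droplevels(groups[sel]),
                             B = config$B, alpha = config$alpha,
                             seed = child_seed(config$seed,
                                               paste0("shape|", sx)))
    }
    lens <- vapply(curves, function(cv) cv$length_mm, 0)
    labs <- levels(groups)
    lt <- matrix(NA_real_, length(labs), length(labs),
                 dimnames = list(labs, labs))
    for (i in seq_along(labs)[-1L]) for (j in seq_len(i - 1L)) {
      lt[i, j] <- permutation_mean_diff(
        lens[groups == labs[i]], lens[groups == labs[j]], B = config$B,
        seed = child_seed(config$seed,
                          paste("len", labs[j], labs[i], sep = "|"))
      )$p_value
    }
    allom <- allometry_anova(pca, lens,
                             strata = paste(meta$group, meta$sex, sep = ":"))
    frame <- anatomical_frame(aligned$consensus)
    fields <- list()
    for (g in labs) {
      mg <- group_mean(aligned, groups == g)
      fields[[paste0("pooled->", g)]] <-
        difference_field(aligned$consensus, mg, frame, "pooled", g)
    }
    for (i in seq_len(length(labs) - 1L)) {
      ma <- group_mean(aligned, groups == labs[i])
      mb <- group_mean(aligned, groups == labs[i + 1L])
      fields[[paste0(labs[i], "->", labs[i + 1L])]] <-
        difference_field(ma, mb, frame, labs[i], labs[i + 1L])
    }
    if (length(labs) > 2L) {
      ma <- group_mean(aligned, groups == labs[1L])
      mb <- group_mean(aligned, groups == labs[length(labs)])
      fields[[paste0(labs[1L], "->", labs[length(labs)])]] <-
        difference_field(ma, mb, frame, labs[1L], labs[length(labs)])
    }
    ellipses <- list()
    for (g in labs) {
      sel <- groups == g
      if (sum(sel) >= 3L && ncol(pca$scores) >= 2L)
        ellipses[[g]] <- confidence_ellipse(pca$scores[sel, 1:2])
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("crestcurve")),
      seed = config$seed, k = config$k, slide = config$slide,
      B = config$B, alpha = config$alpha,
      n_specimens = nrow(meta),
      group_sizes = as.list(table(groups)),
      n_pcs_tested = shape_tests$pooled$n_pcs,
      broken_stick_retained = pca$n_retained_broken_stick,
      warnings = warnings_seen)
    structure(list(table = tab, meta = meta, aligned = aligned, pca = pca,
                   shape_tests = shape_tests,
                   length_tests = list(labels = labs, p_values = lt),
                   allometry = allom, fields = fields, ellipses = ellipses,
                   frame = frame, manifest = manifest),
              class = "report_bundle")
  }, warning = note)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d specimens, %d groups, %d PCs tested\n",
              x$manifest$n_specimens, length(x$shape_tests$pooled$labels),
              x$manifest$n_pcs_tested))
  cat("Pairwise shape-test p-values (pooled sexes):\n")
  print(pairwise_report(x)$shape)
  invisible(x)
}

format_p_matrix <- function(labels, pmat, alpha) {
  sub <- pmat[-1L, -length(labels), drop = FALSE]
  out <- matrix("", nrow(sub), ncol(sub), dimnames = dimnames(sub))
  for (i in seq_len(nrow(sub))) for (j in seq_len(ncol(sub))) {
    p <- sub[i, j]
    if (is.na(p)) next
    out[i, j] <- paste0(format(round(p, 3), nsmall = 3),
                        if (p < alpha) " *" else "")
  }
  out
}

#' Formatted pairwise p-value matrices
#'
#' Lower-triangular character matrices of the shape-test and length-test
#' p-values, with `*` flagging cells significant at the bundle's alpha.
#'
#' @param bundle A `report_bundle` from [run_study()].
#' @param alpha Significance level for flagging (default: the bundle's).
#' @return List with `shape` and `length` character matrices.
#' @export
pairwise_report <- function(bundle, alpha = NULL) {
  stopifnot(inherits(bundle, "report_bundle"))
  alpha <- alpha %||% bundle$manifest$alpha
  st <- bundle$shape_tests$pooled
  list(shape = format_p_matrix(st$labels, st$p_values, alpha),
       length = format_p_matrix(bundle$length_tests$labels,
                                bundle$length_tests$p_values, alpha))
}

#' Write a report bundle to disk
#'
#' Emits the semilandmark table, PCA summary, pairwise shape- and
#' length-test matrices, allometry table, difference-field tables, ellipse
#' specs and a JSON manifest as plain-text files under `dir`.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_semilandmark_table(bundle$table,
                           file.path(dir, "semilandmarks.csv"))
  pca_sum <- data.frame(pc = seq_along(bundle$pca$eigenvalues),
                        eigenvalue = bundle$pca$eigenvalues,
                        variance_fraction = bundle$pca$variance_fractions)
  utils::write.csv(pca_sum, file.path(dir, "pca_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$shape_tests$pooled$p_values,
                   file.path(dir, "shape_test_pvalues.csv"))
  utils::write.csv(bundle$length_tests$p_values,
                   file.path(dir, "length_test_pvalues.csv"))
  utils::write.csv(bundle$allometry, file.path(dir, "allometry.csv"),
                   row.names = FALSE)
  for (nm in names(bundle$fields))
    utils::write.csv(field_table(bundle$fields[[nm]]),
                     file.path(dir, paste0("field_", gsub("[^A-Za-z0-9]+",
                                                          "_", nm),
                                           ".csv")),
                     row.names = FALSE)
  ell <- do.call(rbind, lapply(names(bundle$ellipses), function(g) {
    e <- bundle$ellipses[[g]]
    data.frame(group = g, center_1 = e$center[1L], center_2 = e$center[2L],
               semi_major = e$semi_axes[1L], semi_minor = e$semi_axes[2L],
               orientation_rad = e$orientation, level = e$level)
  }))
  if (!is.null(ell))
    utils::write.csv(ell, file.path(dir, "ellipses.csv"), row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
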
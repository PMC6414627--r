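#' Read a .asc polyline file
#'
#' Reads a plain-text digitized curve: one "x y z" coordinate triple per line,
#' in digitization order. The dialect is permissive: whitespace or comma
#' separators are accepted, blank lines and lines starting with '#' are
#' skipped. Point order is preserved exactly. Consecutive duplicate points are
#' permitted but counted in the `n_duplicates` attribute.
#'
#' @param path Path to the .asc file.
#' @return A [polyline3d()] with `source_id = path`.
#' @export
read_asc_polyline <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) < 2L)
    stop("polyline file must contain at least 2 coordinate lines: ", path)
  toks <- strsplit(trimws(lines[idx]), "[,[:space:]]+")
  bad <- which(lengths(toks) != 3L)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected 3 fields, got %d",
                 idx[bad[1L]], path, lengths(toks)[bad[1L]]))
  vals <- suppressWarnings(as.numeric(unlist(toks, use.names = FALSE)))
  if (anyNA(vals) || !all(is.finite(vals))) {
    row <- which(!is.finite(matrix(vals, ncol = 3L, byrow = TRUE)),
                 arr.ind = TRUE)[1L, 1L]
    stop(sprintf("malformed line %d in %s: non-numeric coordinate",
                 idx[row], path))
  }
  pts <- matrix(vals, ncol = 3L, byrow = TRUE)
  pl <- polyline3d(pts, source_id = path)
  ndup <- sum(rowSums(abs(diff(pts))) == 0)
  attr(pl, "n_duplicates") <- ndup
  pl
}

#' Write a polyline to a .asc file
#'
#' Inverse of [read_asc_polyline()]: one space-separated "x y z" triple per
#' line at full double precision, so write-then-read round-trips exactly.
#'
#' @param polyline A [polyline3d()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asc_polyline <- function(polyline, path) {
  pts <- unclass(polyline)
  writeLines(sprintf("%.17g %.17g %.17g", pts[, 1], pts[, 2], pts[, 3]), path)
  invisible(path)
}

#' Read vertex records from a Wavefront OBJ file
#'
#' Consumes only `v x y z` vertex records; faces, normals, texture
#' coordinates and other record types are skipped (their count is reported in
#' the `n_skipped` attribute). The pipeline needs the vertex cloud, not mesh
#' topology, to measure maximal caliper length.
#'
#' @param path Path to the OBJ file.
#' @return An unordered point cloud: m x 3 numeric matrix with attributes
#'   `source_id` and `n_skipped`.
#' @export
read_obj_vertices <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  isv <- grepl("^v\\s", lines)
  if (!any(isv)) stop("no vertex ('v') records in ", path)
  toks <- strsplit(trimws(sub("^v\\s+", "", lines[isv])), "\\s+")
  xyz <- vapply(toks, function(tk) as.numeric(tk[1:3]), numeric(3))
  verts <- t(xyz)
  if (!all(is.finite(verts))) stop("non-finite vertex coordinates in ", path)
  colnames(verts) <- c("x", "y", "z")
  structure(verts, source_id = path,
            n_skipped = sum(!isv & nzchar(trimws(lines))))
}

slm_table_columns <- function(k) {
  coord <- as.vector(t(outer(sprintf("%02d", seq_len(k)),
                             c("x", "y", "z"),
                             function(i, a) paste0(a, i))))
  c("specimen_id", "group", "sex", "curve_length_mm", coord)
}

#' Write a semilandmark table to CSV
#'
#' Canonical per-specimen flat format: `specimen_id, group, sex,
#' curve_length_mm, x01, y01, z01, ..., z<k>`. Coordinates are written at
#' full double precision so the round trip through
#' [read_semilandmark_table()] is lossless.
#'
#' @param tab Data frame in canonical semilandmark-table layout (as produced
#'   by [semilandmark_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_semilandmark_table <- function(tab, path) {
  k <- (ncol(tab) - 4L) / 3L
  want <- slm_table_columns(k)
  if (!identical(sort(names(tab)), sort(want)))
    stop("semilandmark table has wrong columns for k = ", k)
  tab <- tab[, want]
  num <- vapply(tab, is.numeric, TRUE)
  out <- tab
  out[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a semilandmark table from CSV
#'
#' Columns may appear in any order; the table is returned in canonical column
#' order. Ragged rows, missing columns, or non-numeric coordinates raise a
#' schema error naming the offending fields.
#'
#' @param path CSV path.
#' @param k Expected semilandmark count per specimen (default 20).
#' @return Data frame in canonical layout.
#' @export
read_semilandmark_table <- function(path, k = 20L) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  want <- slm_table_columns(k)
  missing_cols <- setdiff(want, names(tab))
  if (length(missing_cols))
    stop("semilandmark table missing columns: ",
         paste(utils::head(missing_cols, 5L), collapse = ", "))
  tab <- tab[, want]
  coord <- want[-(1:4)]
  for (cl in c("curve_length_mm", coord)) {
    v <- tab[[cl]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      if (anyNA(v2) && !all(is.na(v)))
        stop("non-numeric values in column ", cl)
      v <- v2
    }
    if (anyNA(v)) stop("missing values in column ", cl)
    tab[[cl]] <- v
  }
  tab
}

#' Flatten semilandmark curves and metadata into a table
#'
#' @param curves List of [semilandmark_curve()] objects.
#' @param meta Data frame with columns `specimen_id`, `group`, `sex` (one row
#'   per curve, matched by `specimen_id`).
#' @return Data frame in canonical semilandmark-table layout.
#' @export
semilandmark_table <- function(curves, meta) {
  ids <- vapply(curves, function(cv) as.character(cv$specimen_id), "")
  m <- meta[match(ids, meta$specimen_id), , drop = FALSE]
  if (anyNA(m$specimen_id))
    stop("metadata missing for specimens: ",
         paste(utils::head(ids[is.na(m$specimen_id)], 5L), collapse = ", "))
  k <- curves[[1L]]$k
  coords <- t(vapply(curves, function(cv) as.vector(t(cv$coords)),
                     numeric(3L * k)))
  tab <- data.frame(specimen_id = ids, group = m$group, sex = m$sex,
                    curve_length_mm = vapply(curves, function(cv)
                      cv$length_mm, 0),
                    coords, stringsAsFactors = FALSE)
  names(tab) <- slm_table_columns(k)
  tab
}

#' Reconstruct semilandmark curves from a table
#'
#' @param tab Data frame in canonical semilandmark-table layout.
#' @return List of [semilandmark_curve()] objects, in table row order.
#' @export
table_to_curves <- function(tab) {
  k <- (ncol(tab) - 4L) / 3L
  lapply(seq_len(nrow(tab)), function(i) {
    semilandmark_curve(matrix(as.numeric(tab[i, -(1:4)]), ncol = 3L,
                              byrow = TRUE),
                       length_mm = tab$curve_length_mm[i],
                       specimen_id = tab$specimen_id[i])
  })
}
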
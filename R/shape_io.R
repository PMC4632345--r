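# Domain types and disk formats for homologous point-set cohorts.
#
# A cohort couples, for every case, an end-diastolic (ED) and an end-systolic
# (ES) point set with a binary disease label and a clinical covariate record.
# Point order defines homologous correspondence: point i of case A corresponds
# anatomically to point i of case B, and every case carries the same number of
# points P per frame.  All downstream matrices use the cohort's case order.

FRAMES <- c("ED", "ES")

#' Construct a single-frame point set
#'
#' A `point_set_shape` holds the ordered homologous 3-D points (in mm, in a
#' common atlas-like coordinate frame) of one case at one cardiac frame,
#' optionally tagged per point with the surface it samples (endocardium or
#' epicardium).
#'
#' @param case_id Character scalar identifying the case.
#' @param frame `"ED"` (end-diastole) or `"ES"` (end-systole).
#' @param points Numeric matrix with P rows and 3 columns (x, y, z in mm).
#'   All coordinates must be finite.
#' @param surface Optional character vector of length P tagging each point
#'   (e.g. `"endo"` / `"epi"`).
#' @return An object of class `point_set_shape`.
#' @export
point_set_shape <- function(case_id, frame, points, surface = NULL) {
  frame <- match.arg(frame, FRAMES)
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stopf("case '%s' frame %s: points must have 3 columns, got %d",
          case_id, frame, ncol(points))
  if (!all(is.finite(points)))
    stopf("case '%s' frame %s: non-finite coordinates", case_id, frame)
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  if (!is.null(surface)) {
    surface <- as.character(surface)
    if (length(surface) != nrow(points))
      stopf("case '%s' frame %s: surface tag length %d != %d points",
            case_id, frame, length(surface), nrow(points))
  }
  structure(list(case_id = as.character(case_id), frame = frame,
                 points = points, surface = surface),
            class = "point_set_shape")
}

#' @export
print.point_set_shape <- function(x, ...) {
  cat(sprintf("<point_set_shape> case %s, frame %s, %d points\n",
              x$case_id, x$frame, nrow(x$points)))
  invisible(x)
}

covariate_columns <- c("sex", "age", "height", "weight",
                       "systolic_bp", "diastolic_bp", "diabetes", "smoking")

validate_covariates <- function(covariates, case_ids) {
  if (!is.data.frame(covariates)) stopf("covariates must be a data.frame")
  need <- c("case_id", covariate_columns)
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    stopf("covariate table missing columns: %s", paste(miss, collapse = ", "))
  covariates$case_id <- as.character(covariates$case_id)
  if (anyDuplicated(covariates$case_id))
    stopf("duplicate case_id in covariate table")
  absent <- setdiff(case_ids, covariates$case_id)
  if (length(absent))
    stopf("missing covariate record for case(s): %s",
          paste(absent, collapse = ", "))
  num <- setdiff(names(covariates), "case_id")
  for (cl in num) {
    v <- covariates[[cl]]
    if (!is.numeric(v) || !all(is.finite(v)))
      stopf("covariate column '%s' must be finite numeric", cl)
  }
  for (cl in c("sex", "diabetes", "smoking")) {
    if (!all(covariates[[cl]] %in% c(0, 1)))
      stopf("covariate column '%s' must be binary 0/1", cl)
  }
  # cohort case order everywhere
  covariates[match(case_ids, covariates$case_id), , drop = FALSE]
}

#' Construct and validate a two-frame shape cohort
#'
#' A `shape_cohort` is the data contract consumed by every analysis stage:
#' ED and ES point sets for each case (equal point count P throughout), a
#' binary label per case (0 = asymptomatic control, 1 = myocardial
#' infarction), and one covariate record per case.  Case order is fixed at
#' construction and defines row order of all derived matrices.
#'
#' @param shapes Named list, one element per case, each a list with elements
#'   `ED` and `ES` of class [point_set_shape].
#' @param labels Named numeric/integer vector of 0/1 labels, names = case ids.
#' @param covariates Data frame with columns `case_id`, `sex`, `age`,
#'   `height` (cm), `weight` (kg), `systolic_bp`, `diastolic_bp` (mmHg),
#'   `diabetes`, `smoking` (0/1), and optionally `edvi`, `esvi` (ml/m^2).
#' @param topology Optional mesh topology (see [lv_topology()]) carried along
#'   for cavity-volume computation and PLY export; `NULL` for cohorts whose
#'   points have no known triangulation.
#' @return An object of class `shape_cohort`.
#' @export
shape_cohort <- function(shapes, labels, covariates, topology = NULL) {
  case_ids <- names(shapes)
  if (is.null(case_ids) || anyDuplicated(case_ids))
    stopf("shapes must be a named list with unique case ids")
  if (is.null(names(labels))) stopf("labels must be named by case id")
  if (!setequal(names(labels), case_ids))
    stopf("label case ids do not match shape case ids")
  labels <- labels[case_ids]
  if (!all(labels %in% c(0, 1)))
    stopf("unknown label value for case(s): %s",
          paste(case_ids[!labels %in% c(0, 1)], collapse = ", "))
  labels <- as.integer(labels)
  names(labels) <- case_ids
  if (length(unique(labels)) < 2L)
    stopf("cohort must contain both classes (labels 0 and 1)")

  P <- NULL
  for (id in case_ids) {
    for (fr in FRAMES) {
      sh <- shapes[[id]][[fr]]
      if (is.null(sh))
        stopf("case '%s' is missing frame %s", id, fr)
      if (!inherits(sh, "point_set_shape"))
        stopf("case '%s' frame %s is not a point_set_shape", id, fr)
      if (is.null(P)) P <- nrow(sh$points)
      if (nrow(sh$points) != P)
        stopf("case '%s' frame %s has %d points, expected %d",
              id, fr, nrow(sh$points), P)
    }
  }
  covariates <- validate_covariates(covariates, case_ids)
  structure(list(case_ids = case_ids, shapes = shapes, labels = labels,
                 covariates = covariates, P = P, topology = topology),
            class = "shape_cohort")
}

#' @export
print.shape_cohort <- function(x, ...) {
  cat(sprintf(
    "<shape_cohort> %d cases (%d control / %d case), P = %d points/frame\n",
    length(x$case_ids), sum(x$labels == 0), sum(x$labels == 1), x$P))
  invisible(x)
}

#' Extract a cohort's point matrix for one frame
#'
#' Rows follow cohort case order; each row is the flattened point set
#' `(x1, y1, z1, ..., xP, yP, zP)` of one case.
#'
#' @param cohort A [shape_cohort].
#' @param frame `"ED"` or `"ES"`.
#' @return Numeric matrix n cases x 3P with attributes `frames` and `P`.
#' @export
cohort_matrix <- function(cohort, frame = c("ED", "ES")) {
  frame <- match.arg(frame)
  X <- t(vapply(cohort$case_ids,
                function(id) as.numeric(t(cohort$shapes[[id]][[frame]]$points)),
                numeric(3L * cohort$P)))
  rownames(X) <- cohort$case_ids
  attr(X, "frames") <- frame
  attr(X, "P") <- cohort$P
  X
}

write_points_csv <- function(shape, path) {
  df <- as.data.frame(apply(shape$points, 2L, function(v) sprintf("%.12g", v)))
  names(df) <- c("x", "y", "z")
  if (!is.null(shape$surface)) df$surface <- shape$surface
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_points_csv <- function(path, case_id, frame) {
  if (!file.exists(path))
    stopf("case '%s': point file for frame %s not found: %s",
          case_id, frame, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df)))
    stopf("case '%s' frame %s: point file must have columns x,y,z", case_id, frame)
  point_set_shape(case_id, frame, as.matrix(df[, need]),
                  surface = df[["surface"]])
}

#' Write a cohort to disk
#'
#' Emits one CSV point file per case per frame (columns x, y, z and,
#' when present, surface; coordinates printed with 12 significant digits),
#' a covariates CSV, and a JSON manifest tying them together.  The manifest
#' preserves case order.
#'
#' @param cohort A [shape_cohort].
#' @param out_dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly usable by [read_cohort()].
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", out_dir)
  pt_dir <- file.path(out_dir, "points")
  dir.create(pt_dir, showWarnings = FALSE)
  cases <- lapply(cohort$case_ids, function(id) {
    files <- list()
    for (fr in FRAMES) {
      rel <- file.path("points", sprintf("%s_%s.csv", id, fr))
      write_points_csv(cohort$shapes[[id]][[fr]], file.path(out_dir, rel))
      files[[fr]] <- rel
    }
    list(id = id, label = unname(cohort$labels[[id]]),
         ED = files$ED, ES = files$ES)
  })
  cov_rel <- "covariates.csv"
  utils::write.csv(cohort$covariates, file.path(out_dir, cov_rel),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(points_per_frame = cohort$P,
                   covariates = cov_rel,
                   cases = cases)
  if (!is.null(cohort$topology))
    manifest$topology <- list(n_rings = cohort$topology$n_rings,
                              n_long = cohort$topology$n_long)
  manifest_path <- file.path(out_dir, "cohort.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Read a cohort from a JSON manifest
#'
#' Inverse of [write_cohort()]; all cohort invariants (both frames per case,
#' uniform point count, known labels, complete covariates) are validated and
#' violations reported with the offending case named.
#'
#' @param manifest_path Path to the JSON manifest written by [write_cohort()].
#' @return A validated [shape_cohort].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stopf("manifest not found: %s", manifest_path)
  root <- dirname(manifest_path)
  man <- jsonlite::read_json(manifest_path)
  if (is.null(man$cases) || !length(man$cases))
    stopf("manifest lists no cases")
  shapes <- list()
  labels <- integer(0)
  for (cs in man$cases) {
    id <- as.character(cs$id)
    if (is.null(cs$label))
      stopf("case '%s': missing label in manifest", id)
    entry <- list()
    for (fr in FRAMES) {
      if (is.null(cs[[fr]]))
        stopf("case '%s': manifest lists no %s point file", id, fr)
      entry[[fr]] <- read_points_csv(file.path(root, cs[[fr]]), id, fr)
    }
    shapes[[id]] <- entry
    labels[[id]] <- as.numeric(cs$label)
  }
  if (is.null(man$covariates))
    stopf("manifest lists no covariate table")
  covariates <- utils::read.csv(file.path(root, man$covariates),
                                stringsAsFactors = FALSE)
  topology <- NULL
  if (!is.null(man$topology))
    topology <- lv_topology(man$topology$n_rings, man$topology$n_long)
  shape_cohort(shapes, labels, covariates, topology = topology)
}

#' Export a triangulated surface as ASCII PLY
#'
#' Visualization convenience for meshed (synthetic) cohorts; PLY is never an
#' input format.
#'
#' @param points Numeric matrix V x 3 of vertices (mm).
#' @param faces Integer matrix F x 3 of 1-based vertex indices.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(points, faces, path) {
  points <- as.matrix(points)
  faces <- as.matrix(faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(points)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f",
                     points[, 1], points[, 2], points[, 3]), con)
  writeLines(sprintf("3 %d %d %d",
                     faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  invisible(path)
}
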
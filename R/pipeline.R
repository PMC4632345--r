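# End-to-end orchestration: simulate/load -> align -> PCA -> standardize ->
# LDA/IMCA -> score -> evaluate -> export, with seeded reproducibility and a
# machine-readable run record.

frame_sets <- function(frames) {
  frames <- match.arg(frames, c("ed", "es", "edes", "all"))
  if (frames == "all") list(ed = "ED", es = "ES", edes = c("ED", "ES"))
  else switch(frames, ed = list(ed = "ED"), es = list(es = "ES"),
              edes = list(edes = c("ED", "ES")))
}

frame_label <- function(fs) if (length(fs) == 2L) "ED&ES" else fs

#' Assemble and validate a pipeline configuration
#'
#' @param input Either a path to a cohort JSON manifest, a
#'   [synthetic_params()] object, or `NULL` for the default desk-scale
#'   synthetic cohort (100 controls / 40 patients, P = 242 points per frame)
#'   whose generator seed is derived from `seed`.
#' @param frames Which shape analyses to run: `"ed"`, `"es"`, `"edes"`, or
#'   `"all"` (ED-only, ES-only, and concatenated ED&ES, each with its own
#'   PCA fit).
#' @param variance_fraction PCA retained-variance threshold (default 0.985).
#' @param methods Discriminant methods to fit: subset of
#'   `c("lda", "imca")`.
#' @param estimator KL estimator for IMCA: `"gaussian"` (default; closed
#'   form, analytic gradient) or `"kde"` (nonparametric plug-in).
#' @param dim IMCA projection dimension (indices and percentile shapes
#'   require 1).
#' @param restarts IMCA restarts (LDA init included).
#' @param seed Global run seed; per-stage child seeds are derived from it
#'   deterministically.
#' @param percentiles Percentiles for the exported mode shapes.
#' @param firth Fit logistic models with Firth penalization.
#' @param out_dir Optional output directory; when given, all report files
#'   are written there.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, frames = "all",
                            variance_fraction = 0.985,
                            methods = c("lda", "imca"),
                            estimator = "gaussian", dim = 1L,
                            restarts = 5L, seed = 7L,
                            percentiles = c(5, 25, 50, 75, 95),
                            firth = FALSE, out_dir = NULL) {
  methods <- match.arg(methods, c("lda", "imca"), several.ok = TRUE)
  estimator <- match.arg(estimator, c("gaussian", "kde"))
  frame_sets(frames)  # validates
  if (any(percentiles <= 0 | percentiles >= 100))
    stopf("percentiles must lie strictly inside (0, 100)")
  if (!is.null(input) && !is.character(input) &&
      !inherits(input, "synthetic_params"))
    stopf("input must be a manifest path, synthetic_params, or NULL")
  structure(list(input = input, frames = frames,
                 variance_fraction = variance_fraction, methods = methods,
                 estimator = estimator, dim = as.integer(dim),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 percentiles = percentiles, firth = firth,
                 out_dir = out_dir),
            class = "pipeline_config")
}

default_desk_params <- function(seed) {
  synthetic_params(n_control = 100, n_case = 40, n_rings = 12, n_long = 10,
                   seed = seed)
}

#' Run the full remodeling analysis pipeline
#'
#' Executes, for each requested frame set: generalized Procrustes alignment
#' (per frame), PCA to the retained-variance threshold, score
#' standardization, and the requested discriminant fits; then assembles the
#' cohort-level reports: per-class index summaries, Pearson correlations
#' among all derived modes, the logistic model suite with goodness-of-fit
#' and AUC, DeLong comparisons of every index model against the baseline
#' model, the demographics table, cavity-volume table and slope comparisons
#' (meshed cohorts only), and percentile shapes of the preferred d = 1 mode.
#' All randomness derives from `config$seed`; rerunning a config reproduces
#' the numbers.
#'
#' @param config A [pipeline_config()].
#' @return An `lv_run` object: fitted stage objects (`analyses`), report
#'   tables, the input cohort (and ground truth when synthetic), and the
#'   paths of files written when `out_dir` was set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start, units = "secs"))
  }

  ts <- Sys.time()
  truth <- NULL
  if (is.character(config$input)) {
    cohort <- read_cohort(config$input)
  } else {
    params <- config$input %||%
      default_desk_params(stage_seed(config$seed, "simulate"))
    gen <- generate_cohort(params)
    cohort <- gen$cohort
    truth <- gen$truth
  }
  tick("input", ts)
  labels <- cohort$labels

  ts <- Sys.time()
  demo <- demographics_table(cohort$covariates, labels)
  volumes <- NULL; slopes <- NULL
  if (!is.null(cohort$topology)) {
    volumes <- withCallingHandlers(derived_volumes(cohort),
                                   warning = function(w) invokeRestart("muffleWarning"))
    slopes <- list(
      esvi_vs_edvi = compare_slopes(volumes$edvi, volumes$esvi, labels),
      ef_vs_esvi = compare_slopes(volumes$esvi, volumes$ef, labels))
  }
  tick("volumes", ts)

  ts <- Sys.time()
  aligned <- list(ED = procrustes_align(cohort, "ED"),
                  ES = procrustes_align(cohort, "ES"))
  tick("alignment", ts)

  analyses <- list()
  indices <- list()
  for (fs_name in names(frame_sets(config$frames))) {
    fs <- frame_sets(config$frames)[[fs_name]]
    ts <- Sys.time()
    X <- if (length(fs) == 2L) concatenate_frames(aligned$ED, aligned$ES)
         else aligned[[fs]]$aligned
    pca <- fit_pca(X, config$variance_fraction)
    std <- project_and_standardize(pca, X)
    models <- list()
    for (method in config$methods) {
      # kde objectives are evaluated with numerically differenced gradients,
      # so tiny relative gains persist indefinitely; the pipeline bounds the
      # ascent and loosens the tolerance there (direction changes are far
      # below what the downstream logistic models resolve)
      model <- if (method == "lda") fit_lda(std, labels)
      else fit_imca(std, labels, d = config$dim,
                    estimator = config$estimator,
                    n_restarts = config$restarts,
                    max_iter = if (config$estimator == "kde") 60L else 500L,
                    tol = if (config$estimator == "kde") 1e-6 else 1e-8,
                    seed = stage_seed(config$seed, paste0("imca-", fs_name)))
      idx <- score_cases(model, std, labels)
      key <- paste(frame_label(fs), toupper(method))
      models[[method]] <- list(model = model, index = idx)
      if (config$dim == 1L) indices[[key]] <- idx
    }
    analyses[[fs_name]] <- list(frames = fs, pca = pca, std = std,
                                models = models)
    tick(paste0("analysis-", fs_name), ts)
  }

  ts <- Sys.time()
  score_summary <- do.call(rbind, lapply(names(indices), function(nm) {
    gs <- indices[[nm]]$group_stats[1L, ]
    data.frame(derivation = nm,
               control = sprintf("%.2f ± %.2f", gs$control_mean, gs$control_sd),
               case = sprintf("%.2f ± %.2f", gs$case_mean, gs$case_sd),
               control_mean = gs$control_mean, control_sd = gs$control_sd,
               case_mean = gs$case_mean, case_sd = gs$case_sd)
  }))
  correlations <- if (length(indices) >= 2L) mode_correlations(indices) else NULL
  suite <- build_model_suite(cohort, indices, volumes, firth = config$firth)
  rocs <- attr(suite, "rocs")
  comparisons <- NULL
  if (length(indices)) {
    comparisons <- do.call(rbind, lapply(
      setdiff(names(rocs), c("Baseline", "MASSVOL + Baseline",
                             "EDVI + ESVI + Baseline")),
      function(nm) {
        cmp <- compare_auc(rocs[[nm]], rocs[["Baseline"]])
        data.frame(model = nm, vs = "Baseline", delta_auc = cmp$delta_auc,
                   z = cmp$z, p = cmp$p)
      }))
  }
  tick("evaluation", ts)

  # percentile shapes from the preferred d = 1 mode: ED&ES IMCA when
  # available, else the last fitted model
  shapes <- NULL
  if (config$dim == 1L) {
    pref <- if (!is.null(analyses$edes)) "edes" else names(analyses)[length(analyses)]
    meths <- analyses[[pref]]$models
    mth <- if (!is.null(meths$imca)) "imca" else names(meths)[length(meths)]
    mm <- meths[[mth]]
    shapes <- backproject_mode(mm$model, analyses[[pref]]$pca,
                               analyses[[pref]]$std, mm$index,
                               config$percentiles)
    shapes_from <- paste(frame_label(analyses[[pref]]$frames), toupper(mth))
  } else shapes_from <- NULL

  run <- structure(list(config = config, cohort = cohort, truth = truth,
                        demographics = demo, volumes = volumes,
                        slopes = slopes, aligned = aligned,
                        analyses = analyses, indices = indices,
                        score_summary = score_summary,
                        correlations = correlations, model_suite = suite,
                        comparisons = comparisons,
                        percentile_shapes = shapes,
                        percentile_shapes_from = shapes_from,
                        timings = timings,
                        total_seconds = as.numeric(difftime(Sys.time(), t0,
                                                            units = "secs"))),
                   class = "lv_run")
  if (!is.null(config$out_dir)) run$files <- write_run(run, config$out_dir)
  run
}

#' @export
print.lv_run <- function(x, ...) {
  cat(sprintf("<lv_run> %d cases, frames = %s, methods = %s\n",
              length(x$cohort$case_ids), x$config$frames,
              paste(x$config$methods, collapse = "+")))
  if (!is.null(x$model_suite))
    print(x$model_suite[, c("model", "k", "deviance", "aic", "bic", "auc_pct")])
  invisible(x)
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", out_dir)
  files <- character(0)
  put_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  cfg <- run$config
  cfg_json <- list(frames = cfg$frames, variance_fraction = cfg$variance_fraction,
                   methods = cfg$methods, estimator = cfg$estimator,
                   dim = cfg$dim, restarts = cfg$restarts, seed = cfg$seed,
                   percentiles = cfg$percentiles, firth = cfg$firth,
                   input = if (is.character(cfg$input)) cfg$input else "synthetic")
  p <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg_json, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, p)

  put_csv(run$demographics, "demographics.csv")
  if (!is.null(run$volumes)) put_csv(run$volumes, "volumes.csv")
  if (!is.null(run$score_summary)) put_csv(run$score_summary, "score_summary.csv")
  if (!is.null(run$correlations))
    put_csv(data.frame(derivation = rownames(run$correlations),
                       run$correlations, check.names = FALSE),
            "mode_correlations.csv")
  put_csv(run$model_suite, "model_suite.csv")
  if (!is.null(run$comparisons)) put_csv(run$comparisons, "auc_comparisons.csv")
  rocs <- attr(run$model_suite, "rocs")
  for (nm in names(rocs)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    put_csv(rocs[[nm]]$curve, sprintf("roc_%s.csv", safe))
  }
  if (!is.null(run$percentile_shapes))
    files <- c(files, export_percentile_shapes(run, out_dir = out_dir))

  record <- list(seed = cfg$seed, timings = run$timings,
                 total_seconds = run$total_seconds,
                 n_cases = length(run$cohort$case_ids),
                 points_per_frame = run$cohort$P,
                 warnings = list(
                   separation = run$model_suite$model[run$model_suite$separation],
                   imca_not_converged = names(Filter(function(a)
                     any(!vapply(a$models, function(m) m$model$converged,
                                 logical(1))), run$analyses))))
  p <- file.path(out_dir, "run_record.json")
  jsonlite::write_json(record, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(files, p)
}

#' Export percentile shapes of the run's d = 1 remodeling mode
#'
#' Writes one point CSV per percentile per frame (plus PLY meshes when the
#' cohort carries a topology) and a CSV mapping percentile to index value.
#'
#' @param run An `lv_run` whose configuration used `dim = 1`.
#' @param percentiles Percentiles in (0, 100); default = the run's.
#' @param out_dir Output directory.
#' @return Character vector of written file paths, invisibly.
#' @export
export_percentile_shapes <- function(run, percentiles = NULL, out_dir) {
  if (is.null(run$percentile_shapes))
    stopf("run has no d = 1 mode to export (config dim != 1)")
  shapes <- run$percentile_shapes
  if (!is.null(percentiles)) {
    pref <- if (!is.null(run$analyses$edes)) "edes"
            else names(run$analyses)[length(run$analyses)]
    meths <- run$analyses[[pref]]$models
    mth <- if (!is.null(meths$imca)) "imca" else names(meths)[length(meths)]
    mm <- meths[[mth]]
    shapes <- backproject_mode(mm$model, run$analyses[[pref]]$pca,
                               run$analyses[[pref]]$std, mm$index, percentiles)
  }
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", out_dir)
  files <- character(0)
  idx_vals <- attr(shapes, "index_values")
  map <- data.frame(percentile = as.numeric(sub("p", "", names(idx_vals))),
                    index_value = as.numeric(idx_vals))
  p <- file.path(out_dir, "percentile_index_values.csv")
  utils::write.csv(map, p, row.names = FALSE)
  files <- c(files, p)
  topo <- run$cohort$topology
  for (nm in names(shapes)) {
    for (fr in names(shapes[[nm]])) {
      sh <- shapes[[nm]][[fr]]
      fp <- file.path(out_dir, sprintf("shape_%s_%s.csv", nm, fr))
      write_points_csv(sh, fp)
      files <- c(files, fp)
      if (!is.null(topo) && nrow(sh$points) == 2L * topo$n_vertices) {
        for (surf in c("endo", "epi")) {
          off <- if (surf == "endo") 0L else topo$n_vertices
          pp <- file.path(out_dir, sprintf("shape_%s_%s_%s.ply", nm, fr, surf))
          write_ply(sh$points[off + seq_len(topo$n_vertices), , drop = FALSE],
                    topo$faces, pp)
          files <- c(files, pp)
        }
      }
    }
  }
  invisible(files)
}
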
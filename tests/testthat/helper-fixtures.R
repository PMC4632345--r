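# Shared fixtures, built in code and cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A minimal 2-case hand-built cohort (P = 4) for I/O contracts.
tiny_cohort <- function() {
  pts <- function(shift) matrix(c(0, 0, 0,  1, 0, 0,  0, 1, 0,  0, 0, 1),
                                ncol = 3, byrow = TRUE) + shift
  shapes <- list(
    a = list(ED = point_set_shape("a", "ED", pts(0)),
             ES = point_set_shape("a", "ES", pts(0.1))),
    b = list(ED = point_set_shape("b", "ED", pts(1)),
             ES = point_set_shape("b", "ES", pts(1.1))))
  covs <- data.frame(case_id = c("a", "b"), sex = c(0, 1),
                     age = c(60, 65), height = c(165, 175),
                     weight = c(70, 85), systolic_bp = c(120, 130),
                     diastolic_bp = c(75, 80), diabetes = c(0, 1),
                     smoking = c(0, 0))
  shape_cohort(shapes, c(a = 0, b = 1), covs)
}

# Desk-scale synthetic cohort parameters (P = 242, as used throughout the
# pipeline examples); sizes overridable.
desk_params <- function(seed, n_control = 100, n_case = 40, ...) {
  synthetic_params(n_control = n_control, n_case = n_case,
                   n_rings = 12, n_long = 10, seed = seed, ...)
}

# A small meshed synthetic cohort shared across test files.
small_cohort <- function() {
  cached("small_cohort",
         generate_cohort(desk_params(421, n_control = 60, n_case = 30)))
}

# One pipeline run on the default desk configuration, shared.
demo_run <- function() {
  cached("demo_run",
         suppressWarnings(run_pipeline(pipeline_config(seed = 7))))
}

# Two-class Gaussian score-space sampler.
gaussian_classes <- function(n0, n1, m, delta = rep(0, m),
                             L0 = diag(m), L1 = diag(m), seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n0 * m), n0) %*% L0,
             sweep(matrix(rnorm(n1 * m), n1) %*% L1, 2, delta, `+`))
  list(X = X, y = rep(0:1, c(n0, n1)))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  sv <- svd(matrix(rnorm(9), 3))
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Apply one rigid transform to every shape of a cohort.
transform_cohort <- function(cohort, R, t) {
  for (id in cohort$case_ids) {
    for (fr in c("ED", "ES")) {
      sh <- cohort$shapes[[id]][[fr]]
      cohort$shapes[[id]][[fr]]$points <-
        sweep(sh$points %*% t(R), 2, t, `+`)
    }
  }
  cohort
}
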
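# Supervised extraction of a global remodeling mode.
#
# Two routes from standardized PCA scores to a single discriminant direction:
# Fisher LDA (pooled within-class scatter), and IMCA -- information
# maximizing component analysis -- which searches the orthonormal D-to-d
# projections A for the one maximizing the Frobenius norm of the 2x2 matrix
# of Kullback-Leibler divergences between the projected class densities.
# The KL matrix approximates the Fisher information distance between the
# class distributions, so IMCA generalizes LDA: it needs neither Gaussian
# classes nor equal covariances.  The projected class densities are by
# default modeled as Gaussians (closed-form KL, smooth analytic gradient);
# a kernel-density plug-in estimator is available as an option.

score_matrix <- function(scores) {
  if (inherits(scores, "standardized_scores")) return(scores$z)
  as.matrix(scores)
}

check_labels <- function(y, n) {
  y <- as.integer(y)
  if (length(y) != n) stopf("labels length %d != %d cases", length(y), n)
  if (!all(y %in% c(0L, 1L))) stopf("labels must be 0/1")
  if (length(unique(y)) < 2L) stopf("both classes must be non-empty")
  y
}

#' Kullback-Leibler divergence between two multivariate Gaussians
#'
#' Closed form, in nats:
#' `0.5 * (tr(S2^-1 S1) + (m2-m1)' S2^-1 (m2-m1) - d + ln det S2 - ln det S1)`.
#'
#' @param mu1,mu2 Mean vectors of equal length d.
#' @param sigma1,sigma2 Symmetric positive-definite d x d covariances
#'   (scalars allowed for d = 1).
#' @return The divergence KL(N1 || N2) in nats (>= 0).
#' @export
gaussian_kl <- function(mu1, sigma1, mu2, sigma2) {
  mu1 <- as.numeric(mu1); mu2 <- as.numeric(mu2)
  S1 <- as.matrix(sigma1); S2 <- as.matrix(sigma2)
  d <- length(mu1)
  if (length(mu2) != d || any(dim(S1) != d) || any(dim(S2) != d))
    stopf("dimension mismatch between means and covariances")
  L1 <- tryCatch(chol(S1), error = function(e) stopf("sigma1 is not positive definite"))
  L2 <- tryCatch(chol(S2), error = function(e) stopf("sigma2 is not positive definite"))
  S2inv <- chol2inv(L2)
  dm <- mu2 - mu1
  0.5 * (sum(S2inv * S1) + as.numeric(dm %*% S2inv %*% dm) - d +
           2 * sum(log(diag(L2))) - 2 * sum(log(diag(L1))))
}

# log-density of rows of `at` under a product-Gaussian KDE built on `sample`
# with per-dimension Silverman bandwidths.  `loo` drops the self kernel
# (valid when `at` IS `sample`), removing the plug-in self-match bias.
kde_log_density <- function(at, sample, loo = FALSE) {
  at <- as.matrix(at); sample <- as.matrix(sample)
  n <- nrow(sample); d <- ncol(sample)
  h <- apply(sample, 2L, stats::sd) * (4 / ((d + 2) * n))^(1 / (d + 4))
  if (any(h < 1e-12)) stopf("zero-variance dimension in KDE sample")
  lk <- matrix(0, nrow(at), n)                # eval points x kernels
  for (j in seq_len(d)) {
    z <- outer(at[, j], sample[, j], `-`) / h[j]
    lk <- lk - 0.5 * z^2 - 0.5 * log(2 * pi) - log(h[j])
  }
  if (loo) diag(lk) <- -Inf
  mx <- apply(lk, 1L, max)
  mx + log(rowSums(exp(lk - mx))) - log(if (loo) n - 1 else n)
}

new_kl_matrix <- function(kl01, kl10) {
  m <- matrix(c(0, kl10, kl01, 0), 2L, 2L,
              dimnames = list(c("class0", "class1"), c("class0", "class1")))
  structure(list(kl = m, frobenius_norm = sqrt(kl01^2 + kl10^2)),
            class = "kl_matrix")
}

#' Estimate the 2x2 KL-divergence matrix between two projected samples
#'
#' With the `gaussian` estimator, per-class sample means and covariances are
#' plugged into the closed form [gaussian_kl()], in both directions.  With
#' `kde`, a product-Gaussian kernel density (Silverman bandwidth) is built
#' per class and the divergences are sample averages of log-density ratios
#' (clamped at zero).  The diagonal is zero by definition.
#'
#' @param projected0,projected1 Matrices n0 x d and n1 x d of projected
#'   samples for class 0 and class 1 (n_i >= d + 2).
#' @param estimator `"gaussian"` (default) or `"kde"`.
#' @return A `kl_matrix`: 2x2 matrix `kl` (entry i, j = KL(class_i || class_j))
#'   and its `frobenius_norm`.
#' @export
estimate_kl_matrix <- function(projected0, projected1,
                               estimator = c("gaussian", "kde")) {
  estimator <- match.arg(estimator)
  X0 <- as.matrix(projected0); X1 <- as.matrix(projected1)
  d <- ncol(X0)
  if (ncol(X1) != d) stopf("projected samples have different dimensions")
  if (nrow(X0) < d + 2L || nrow(X1) < d + 2L)
    stopf("need at least d + 2 samples per class")
  if (estimator == "gaussian") {
    m0 <- colMeans(X0); m1 <- colMeans(X1)
    S0 <- stats::cov(X0); S1 <- stats::cov(X1)
    for (S in list(S0, S1))
      if (inherits(tryCatch(chol(S), error = identity), "error"))
        stopf("singular sample covariance in projected space; try smaller d")
    new_kl_matrix(gaussian_kl(m0, S0, m1, S1), gaussian_kl(m1, S1, m0, S0))
  } else {
    kl01 <- mean(kde_log_density(X0, X0, loo = TRUE) - kde_log_density(X0, X1))
    kl10 <- mean(kde_log_density(X1, X1, loo = TRUE) - kde_log_density(X1, X0))
    new_kl_matrix(max(0, kl01), max(0, kl10))
  }
}

#' IMCA objective for a candidate projection
#'
#' The Frobenius norm of the estimated KL matrix between the two classes
#' after projecting the scores with the orthonormal matrix `A`.
#'
#' @param A Orthonormal D x d projection (columns orthonormal within 1e-6).
#' @param scores Score matrix or `standardized_scores`.
#' @param labels 0/1 labels.
#' @param estimator `"gaussian"` or `"kde"`.
#' @return Scalar objective value (>= 0).
#' @export
imca_objective <- function(A, scores, labels,
                           estimator = c("gaussian", "kde")) {
  estimator <- match.arg(estimator)
  A <- as.matrix(A)
  X <- score_matrix(scores)
  y <- check_labels(labels, nrow(X))
  gram <- crossprod(A)
  if (max(abs(gram - diag(ncol(A)))) > 1e-6)
    stopf("A is not orthonormal")
  estimate_kl_matrix((X[y == 0L, , drop = FALSE] %*% A),
                     (X[y == 1L, , drop = FALSE] %*% A),
                     estimator)$frobenius_norm
}

# ---- gaussian fast path: objective and analytic gradient from class stats --

class_stats <- function(X, y) {
  X0 <- X[y == 0L, , drop = FALSE]; X1 <- X[y == 1L, , drop = FALSE]
  list(mu0 = colMeans(X0), mu1 = colMeans(X1),
       C0 = stats::cov(X0), C1 = stats::cov(X1))
}

# one direction of the projected-Gaussian KL and its gradient in A.
# "a" plays p (left argument), "b" plays q (right argument).
kl_dir_grad <- function(A, Ca, Cb, delta, want_grad = TRUE) {
  d <- ncol(A)
  Sa <- crossprod(A, Ca %*% A); Sb <- crossprod(A, Cb %*% A)
  La <- chol((Sa + t(Sa)) / 2); Lb <- chol((Sb + t(Sb)) / 2)
  Sbi <- chol2inv(Lb); Sai <- chol2inv(La)
  Dl <- as.numeric(crossprod(A, delta))           # d-vector
  kl <- 0.5 * (sum(Sbi * Sa) + sum(Dl * (Sbi %*% Dl)) - d +
                 2 * sum(log(diag(Lb))) - 2 * sum(log(diag(La))))
  if (!want_grad) return(list(kl = kl, grad = NULL))
  CbA <- Cb %*% A
  grad <- Ca %*% A %*% Sbi -
    CbA %*% (Sbi %*% Sa %*% Sbi) +
    (delta %o% as.numeric(Sbi %*% Dl)) -
    CbA %*% (Sbi %*% (Dl %o% Dl) %*% Sbi) +
    CbA %*% Sbi -
    Ca %*% A %*% Sai
  list(kl = kl, grad = grad)
}

gaussian_objective_grad <- function(A, st, want_grad = TRUE) {
  delta <- st$mu1 - st$mu0
  a <- kl_dir_grad(A, st$C0, st$C1, delta, want_grad)   # KL(0 || 1)
  b <- kl_dir_grad(A, st$C1, st$C0, -delta, want_grad)  # KL(1 || 0)
  J <- sqrt(a$kl^2 + b$kl^2)
  if (!want_grad) return(list(objective = J, grad = NULL))
  g <- if (J > 1e-12) (a$kl * a$grad + b$kl * b$grad) / J
       else matrix(0, nrow(A), ncol(A))
  list(objective = J, grad = g)
}

# QR retraction back onto the orthonormal frame, with the R-diagonal sign
# fixed so the retraction is continuous in its argument.
qr_retract <- function(M) {
  qd <- qr(M)
  Q <- qr.Q(qd)
  s <- sign(diag(qr.R(qd)))
  s[s == 0] <- 1
  Q * rep(s, each = nrow(Q))
}

# orthonormal D x d frame whose first column is v (unit-normalized).
complete_frame <- function(v, d, rng_draw) {
  D <- length(v)
  M <- cbind(v, matrix(rng_draw, D, d - 1L))
  Q <- qr_retract(M)
  if (sum(Q[, 1] * v) < 0) Q[, 1] <- -Q[, 1]
  Q
}

new_discriminant_model <- function(method, projection, X, y, estimator,
                                   objective, trace = NULL,
                                   chosen_restart = NA_integer_,
                                   converged = TRUE) {
  proj <- X %*% projection
  # sign convention: positive index points toward the disease class
  for (j in seq_len(ncol(proj))) {
    if (mean(proj[y == 1L, j]) < mean(proj[y == 0L, j])) {
      projection[, j] <- -projection[, j]
      proj[, j] <- -proj[, j]
    }
  }
  center <- colMeans(proj)
  scale <- col_sds(proj)
  structure(list(method = method, projection = projection, d = ncol(projection),
                 estimator = estimator, score_center = center,
                 score_scale = scale, sign_convention = 1,
                 objective = objective, trace = trace,
                 chosen_restart = chosen_restart, converged = converged),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> %s, d = %d, objective = %.4f%s\n",
              x$method, x$d, x$objective,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Fisher linear discriminant direction
#'
#' The classical two-class Fisher direction `w` proportional to
#' `Sw^-1 (mu1 - mu0)` with `Sw` the pooled within-class covariance,
#' normalized to unit length and sign-fixed so the disease class projects
#' higher.  The discriminant score of a case is the weighted linear
#' combination `w' x` of its m standardized predictors, standardized to
#' pooled mean 0 / SD 1 over the training cohort.
#'
#' @param scores Score matrix (n x m) or `standardized_scores`.
#' @param labels 0/1 class labels (0 = control).
#' @return A `discriminant_model` with `method = "LDA"`; its `objective`
#'   field stores the Gaussian-estimator KL objective at `w` so LDA and IMCA
#'   solutions are comparable in-objective.
#' @export
fit_lda <- function(scores, labels) {
  X <- score_matrix(scores)
  y <- check_labels(labels, nrow(X))
  m <- ncol(X)
  st <- class_stats(X, y)
  delta <- st$mu1 - st$mu0
  if (sqrt(sum(delta^2)) < 1e-10)
    stopf("identical class means: Fisher direction undefined")
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  Sw <- ((n0 - 1) * st$C0 + (n1 - 1) * st$C1) / (n0 + n1 - 2)
  w <- tryCatch(solve(Sw, delta), error = function(e) {
    warnf("singular pooled scatter: using ridge-regularized inverse")
    eps <- 1e-8 * sum(diag(Sw)) / m
    solve(Sw + diag(eps, m), delta)
  })
  w <- w / sqrt(sum(w^2))
  obj <- gaussian_objective_grad(matrix(w, ncol = 1L), st,
                                 want_grad = FALSE)$objective
  new_discriminant_model("LDA", matrix(w, ncol = 1L), X, y,
                         estimator = "gaussian", objective = obj)
}

#' Fit IMCA: the KL-divergence-maximizing orthonormal projection
#'
#' Gradient ascent on the Frobenius norm of the between-class KL matrix over
#' orthonormal D-to-d projections, with QR retraction after every step and a
#' backtracking (step-halving) line search that never accepts a decrease.
#' Multi-start: the Fisher LDA direction (completed to d orthonormal
#' columns) plus `n_restarts - 1` seeded random orthonormal frames; the
#' restart with the highest final objective wins, so the solution's
#' objective is never below the LDA direction's.  Convergence is declared
#' after 3 consecutive accepted steps with relative objective change below
#' `tol`; non-convergence returns the best iterate with a warning, never
#' silently.
#'
#' @param scores Score matrix (n x m) or `standardized_scores`.
#' @param labels 0/1 class labels (0 = control).
#' @param d Projection dimension (default 1: a single global remodeling
#'   mode; 2 or 3 give the additional orthogonal modes).
#' @param estimator Projected-density model for the KL matrix:
#'   `"gaussian"` (closed form, analytic gradient) or `"kde"` (plug-in,
#'   numerical gradient).
#' @param n_restarts Number of starts including the LDA initialization.
#' @param max_iter Maximum accepted ascent steps per restart.
#' @param step Initial line-search step length.
#' @param tol Relative objective-change convergence tolerance.
#' @param seed Seed for the random restarts.
#' @return A `discriminant_model` with `method = "IMCA"`, the orthonormal
#'   projection (`A'A = I`), pooled score standardization, the optimizer
#'   trace (per-restart final objectives and the chosen restart's
#'   per-iteration objective sequence), and a convergence flag.
#' @export
fit_imca <- function(scores, labels, d = 1L,
                     estimator = c("gaussian", "kde"),
                     n_restarts = 5L, max_iter = 500L, step = 1,
                     tol = 1e-8, seed = 1L) {
  estimator <- match.arg(estimator)
  X <- score_matrix(scores)
  y <- check_labels(labels, nrow(X))
  D <- ncol(X); d <- as.integer(d)
  if (d < 1L || d > D) stopf("d must lie in [1, %d]", D)
  if (min(sum(y == 0L), sum(y == 1L)) < d + 2L)
    stopf("need at least d + 2 cases per class")

  st <- class_stats(X, y)
  X0 <- X[y == 0L, , drop = FALSE]; X1 <- X[y == 1L, , drop = FALSE]
  if (estimator == "gaussian") {
    f <- function(A) gaussian_objective_grad(A, st, FALSE)$objective
    g <- function(A) gaussian_objective_grad(A, st, TRUE)$grad
  } else {
    f <- function(A) estimate_kl_matrix(X0 %*% A, X1 %*% A,
                                        "kde")$frobenius_norm
    g <- function(A) {        # forward-difference gradient about f(A)
      eps <- 1e-5
      f0 <- f(A)
      G <- matrix(0, D, d)
      for (i in seq_len(D)) for (j in seq_len(d)) {
        Ap <- A; Ap[i, j] <- Ap[i, j] + eps
        G[i, j] <- (f(qr_retract(Ap)) - f0) / eps
      }
      G
    }
  }

  ascend <- function(A0) {
    A <- qr_retract(A0)
    obj <- f(A)
    trace <- obj
    consec <- 0L
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      G <- g(A)
      if (sqrt(sum(G^2)) < 1e-14) { converged <- TRUE; break }
      s <- step
      accepted <- FALSE
      while (s >= 1e-14) {
        A2 <- qr_retract(A + s * G)
        o2 <- f(A2)
        if (o2 >= obj) { accepted <- TRUE; break }
        s <- s / 2
      }
      if (!accepted) { converged <- TRUE; break }  # stationary: no ascent
      rel <- (o2 - obj) / max(abs(obj), 1e-12)
      A <- A2; obj <- o2
      trace <- c(trace, obj)
      consec <- if (rel < tol) consec + 1L else 0L
      if (consec >= 3L) { converged <- TRUE; break }
    }
    list(A = A, objective = obj, trace = trace, converged = converged)
  }

  inits <- list()
  lda_dir <- tryCatch({
    w <- fit_lda(X, y)$projection[, 1L]
    with_seed(stage_seed(seed, "imca-lda-completion"),
              complete_frame(w, d, stats::rnorm(D * (d - 1L))))
  }, error = function(e) NULL)
  if (!is.null(lda_dir)) inits[[length(inits) + 1L]] <- lda_dir
  n_random <- max(n_restarts - length(inits), 1L)
  for (r in seq_len(n_random))
    inits[[length(inits) + 1L]] <-
      with_seed(stage_seed(seed, paste0("imca-restart-", r)),
                qr_retract(matrix(stats::rnorm(D * d), D, d)))

  runs <- lapply(inits, ascend)
  finals <- vapply(runs, `[[`, numeric(1), "objective")
  best <- which.max(finals)
  chosen <- runs[[best]]
  if (!chosen$converged)
    warnf("IMCA did not converge in %d iterations; returning best iterate",
          max_iter)
  trace <- list(restart_objectives = finals, chosen_restart = best,
                objective_path = chosen$trace,
                lda_init_used = !is.null(lda_dir))
  new_discriminant_model("IMCA", chosen$A, X, y, estimator,
                         objective = chosen$objective, trace = trace,
                         chosen_restart = best, converged = chosen$converged)
}

#' Score cases with a fitted discriminant model
#'
#' Projects scores onto the model direction(s) and applies the stored pooled
#' standardization and sign convention, giving the remodeling index:
#' pooled mean 0, SD 1 on the training cohort, positive toward disease.
#'
#' @param model A `discriminant_model`.
#' @param scores Score matrix or `standardized_scores` (same m as training).
#' @param labels Optional 0/1 labels; when given, per-class mean +/- SD
#'   summaries are attached.
#' @return A `remodeling_index`: `values` (vector for d = 1, else matrix)
#'   and, with labels, `group_stats`.
#' @export
score_cases <- function(model, scores, labels = NULL) {
  X <- score_matrix(scores)
  if (ncol(X) != nrow(model$projection))
    stopf("scores have %d columns, model expects %d",
          ncol(X), nrow(model$projection))
  z <- sweep(sweep(X %*% model$projection, 2L, model$score_center),
             2L, model$score_scale, `/`)
  values <- if (model$d == 1L) as.numeric(z) else z
  if (!is.null(rownames(X)) && model$d == 1L) names(values) <- rownames(X)
  group_stats <- NULL
  if (!is.null(labels)) {
    y <- check_labels(labels, nrow(X))
    zz <- as.matrix(z)
    group_stats <- do.call(rbind, lapply(seq_len(ncol(zz)), function(j)
      data.frame(mode = j,
                 control_mean = mean(zz[y == 0L, j]),
                 control_sd = stats::sd(zz[y == 0L, j]),
                 case_mean = mean(zz[y == 1L, j]),
                 case_sd = stats::sd(zz[y == 1L, j]))))
  }
  structure(list(values = values, method = model$method, d = model$d,
                 group_stats = group_stats),
            class = "remodeling_index")
}

#' Pearson correlations among remodeling indices
#'
#' @param indices Named list of `remodeling_index` objects (d = 1) or
#'   numeric vectors over the same cases in the same order.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
mode_correlations <- function(indices) {
  vecs <- lapply(indices, function(x)
    if (inherits(x, "remodeling_index")) as.numeric(x$values) else as.numeric(x))
  lens <- vapply(vecs, length, integer(1))
  if (length(unique(lens)) != 1L)
    stopf("indices cover different numbers of cases")
  if (length(vecs) < 2L) stopf("need at least two indices")
  stats::cor(do.call(cbind, vecs))
}

# direction in concatenated point space corresponding to a unit increase of
# the (standardized) remodeling index; used for planted-direction recovery.
#' Back-project the discriminant mode into point space as a direction
#'
#' @param model A d = 1 `discriminant_model`.
#' @param pca The `pca_model` the scores came from.
#' @param std The `standardized_scores` standardization in force.
#' @return Unit-norm direction vector in the (possibly concatenated) point
#'   space: the shape displacement per unit index.
#' @export
backproject_direction <- function(model, pca, std) {
  if (model$d != 1L) stopf("direction back-projection needs a d = 1 model")
  w <- model$projection[, 1L] * model$score_scale[1L]
  v <- as.numeric(pca$modes %*% (w * std$scale))
  v / sqrt(sum(v^2))
}

#' Reconstruct shapes at percentiles of a remodeling index
#'
#' For each requested percentile p of the empirical index distribution
#' (type-7 quantiles), the standardizations are inverted -- index value to
#' raw projection, to standardized PCA scores along the mode direction, to
#' raw PCA scores, to `mean + modes %*% scores` -- and the resulting shape
#' vector is split back into ED and ES frames when the model was fitted on
#' concatenated frames.  This renders the remodeling continuum: walking up
#' the index shows the transition toward the diseased phenotype.
#'
#' @param model A d = 1 `discriminant_model`.
#' @param pca The `pca_model` in force.
#' @param std The `standardized_scores` standardization in force.
#' @param index A `remodeling_index` over the cohort.
#' @param percentiles Percentiles in (0, 100).
#' @return Named list (one element per percentile) of lists of
#'   [point_set_shape]s keyed by frame, with attribute `index_values`.
#' @export
backproject_mode <- function(model, pca, std, index,
                             percentiles = c(5, 25, 50, 75, 95)) {
  if (model$d != 1L) stopf("percentile shapes need a d = 1 model")
  if (any(percentiles <= 0 | percentiles >= 100))
    stopf("percentiles must lie strictly inside (0, 100)")
  vals <- as.numeric(index$values)
  frames <- pca$frames %||% "ED"
  P <- pca$P %||% (length(pca$mean) / (3L * length(frames)))
  out <- list()
  idx_at <- numeric(length(percentiles))
  for (k in seq_along(percentiles)) {
    p <- percentiles[k]
    v <- as.numeric(stats::quantile(vals, p / 100, type = 7))
    idx_at[k] <- v
    y <- v * model$score_scale[1L] + model$score_center[1L]
    z_std <- model$projection[, 1L] * y
    z_raw <- z_std * std$scale + std$center
    shape_vec <- pca$mean + as.numeric(pca$modes %*% z_raw)
    blocks <- split(shape_vec,
                    rep(seq_along(frames), each = 3L * P))
    shapes <- list()
    for (fi in seq_along(frames))
      shapes[[frames[fi]]] <- point_set_shape(
        sprintf("pct%02d", round(p)), frames[fi],
        matrix(blocks[[fi]], ncol = 3L, byrow = TRUE))
    out[[sprintf("p%02d", round(p))]] <- shapes
  }
  attr(out, "index_values") <- stats::setNames(idx_at,
                                               sprintf("p%02d", round(percentiles)))
  out
}
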
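# Statistical shape space: generalized Procrustes rigid alignment (scale
# preserved, since heart size is itself a disease indicator), frame
# concatenation, covariance PCA to a retained-variance threshold, and score
# standardization.

# Optimal rigid (rotation + translation, no scale, no reflection) transform
# mapping X onto Y, both k x 3: the Kabsch solution of the orthogonal
# Procrustes problem with the determinant constrained to +1.
kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2L, cx), sweep(Y, 2L, cy))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, t = cy - as.numeric(R %*% cx))
}

apply_rigid <- function(X, R, t) sweep(X %*% t(R), 2L, t, `+`)

#' Generalized Procrustes alignment of a cohort frame
#'
#' Iteratively rotates and translates every case onto the current mean shape
#' (least squares over homologous points), recomputes the mean, and repeats
#' until the mean moves less than `tol` (RMS per coordinate) or `max_iter`
#' is reached.  Scale is deliberately preserved and reflections are forbidden
#' (rotation determinant +1): anatomy is chiral and heart size carries
#' disease information.  The first case initializes the reference.
#'
#' @param cohort A [shape_cohort].
#' @param frame `"ED"` or `"ES"`.
#' @param max_iter Maximum mean-update iterations.
#' @param tol Convergence tolerance on RMS mean displacement (mm).
#' @return An `aligned_cohort`: list with `aligned` (n x 3P matrix, cohort
#'   case order), `mean` (length-3P mean shape), `rotations`,
#'   `translations`, `frame`, `P`, `ss` (per-iteration total sum of squared
#'   distances to the mean), and `iterations`.
#' @export
procrustes_align <- function(cohort, frame = c("ED", "ES"),
                             max_iter = 100L, tol = 1e-9) {
  frame <- match.arg(frame)
  X <- cohort_matrix(cohort, frame)
  n <- nrow(X); P <- cohort$P
  if (n < 2L) stopf("alignment needs >= 2 cases")
  as_pts <- function(row) matrix(row, ncol = 3L, byrow = TRUE)
  spread <- apply(X, 1L, function(r) sum(diag(stats::var(as_pts(r)))))
  if (any(spread < 1e-12))
    stopf("degenerate case (all points identical): %s",
          paste(rownames(X)[spread < 1e-12], collapse = ", "))

  mean_shape <- X[1L, ]
  rot <- vector("list", n); tra <- vector("list", n)
  aligned <- X
  ss_trace <- numeric(0)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    M <- as_pts(mean_shape)
    for (i in seq_len(n)) {
      tr <- kabsch(as_pts(X[i, ]), M)
      rot[[i]] <- tr$R; tra[[i]] <- tr$t
      aligned[i, ] <- as.numeric(t(apply_rigid(as_pts(X[i, ]), tr$R, tr$t)))
    }
    new_mean <- colMeans(aligned)
    ss_trace <- c(ss_trace, sum(sweep(aligned, 2L, new_mean)^2))
    shift <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    iterations <- it
    if (it > 1L && shift < tol) break
  }
  attr(aligned, "frames") <- frame
  attr(aligned, "P") <- P
  structure(list(aligned = aligned, mean = mean_shape, rotations = rot,
                 translations = tra, frame = frame, P = P,
                 case_ids = cohort$case_ids, ss = ss_trace,
                 iterations = iterations),
            class = "aligned_cohort")
}

#' Concatenate aligned ED and ES frames into one shape vector per case
#'
#' @param aligned_ed,aligned_es `aligned_cohort` objects for the ED and ES
#'   frames over the same cases in the same order.
#' @return Matrix n x 6P; each row is the ED block followed by the ES block.
#' @export
concatenate_frames <- function(aligned_ed, aligned_es) {
  if (!identical(aligned_ed$case_ids, aligned_es$case_ids))
    stopf("ED and ES alignments cover different cases or a different order")
  X <- cbind(aligned_ed$aligned, aligned_es$aligned)
  rownames(X) <- aligned_ed$case_ids
  attr(X, "frames") <- c("ED", "ES")
  attr(X, "P") <- aligned_ed$P
  X
}

#' Principal component analysis to a retained-variance threshold
#'
#' Eigendecomposition of the sample covariance (n-1 denominator) of the
#' mean-centered rows, performed on raw coordinates (covariance, not
#' correlation, so size variation is retained).  The number of modes m is
#' the smallest count whose cumulative eigenvalue share reaches
#' `variance_fraction`.  Mode signs are fixed deterministically (largest
#' absolute loading positive).
#'
#' @param data Numeric matrix n x D (rows = cases).
#' @param variance_fraction Retained-variance threshold in (0, 1];
#'   default 0.985.
#' @return A `pca_model`: `mean` (length D), `modes` (D x m, orthonormal),
#'   `eigenvalues` (all n-limited eigenvalues, non-increasing),
#'   `total_variance`, `variance_fraction_retained`, `m`, plus the `frames` /
#'   `P` attributes of the input when present.
#' @export
fit_pca <- function(data, variance_fraction = 0.985) {
  data <- as.matrix(data)
  n <- nrow(data); D <- ncol(data)
  if (n < 3L) stopf("PCA needs >= 3 cases")
  if (variance_fraction <= 0 || variance_fraction > 1)
    stopf("variance_fraction must lie in (0, 1]")
  mu <- colMeans(data)
  Xc <- sweep(data, 2L, mu)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (n - 1)
  total <- sum(ev)
  if (total <= 1e-300) stopf("zero total variance")
  cum <- cumsum(ev) / total
  m <- which(cum >= variance_fraction - 1e-12)[1L]
  modes <- sv$v[, seq_len(m), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each mode positive
  for (j in seq_len(m)) {
    i <- which.max(abs(modes[, j]))
    if (modes[i, j] < 0) modes[, j] <- -modes[, j]
  }
  structure(list(mean = mu, modes = modes, eigenvalues = ev,
                 total_variance = total,
                 variance_fraction_retained = cum[m],
                 variance_fraction = variance_fraction, m = m,
                 frames = attr(data, "frames"), P = attr(data, "P")),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d modes retaining %.2f%% of total variance\n",
              x$m, 100 * x$variance_fraction_retained))
  invisible(x)
}

#' Project data into a PCA basis and standardize the scores
#'
#' Scores are `(data - mean) %*% modes`, then each mode's column is centered
#' and scaled to unit pooled SD (n-1 denominator).  The center/scale pair is
#' stored so new cases can be mapped into the identical standardized space
#' with [apply_standardization()].
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param data Matrix n x D with D matching the model.
#' @return A `standardized_scores` object: `z` (n x m standardized matrix),
#'   `raw` (unstandardized scores), `center`, `scale`, and the model's
#'   frame bookkeeping.
#' @export
project_and_standardize <- function(model, data) {
  data <- as.matrix(data)
  if (ncol(data) != length(model$mean))
    stopf("data has %d columns, model expects %d", ncol(data),
          length(model$mean))
  raw <- sweep(data, 2L, model$mean) %*% model$modes
  center <- colMeans(raw)
  scale <- col_sds(raw)
  zero <- which(scale < 1e-12)
  if (length(zero))
    stopf("zero-variance score for PCA mode(s): %s",
          paste(zero, collapse = ", "))
  z <- sweep(sweep(raw, 2L, center), 2L, scale, `/`)
  rownames(z) <- rownames(data)
  structure(list(z = z, raw = raw, center = center, scale = scale,
                 frames = model$frames, P = model$P, m = model$m),
            class = "standardized_scores")
}

#' Standardize new cases with stored constants
#'
#' @param std A `standardized_scores` object (training standardization).
#' @param model The `pca_model` the standardization was built on.
#' @param data New data matrix (rows = cases, D columns).
#' @return Standardized score matrix in the training space.
#' @export
apply_standardization <- function(std, model, data) {
  raw <- sweep(as.matrix(data), 2L, model$mean) %*% model$modes
  sweep(sweep(raw, 2L, std$center), 2L, std$scale, `/`)
}
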
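test_that("gaussian KL matches closed forms", {
  expect_equal(gaussian_kl(c(0, 0), diag(2), c(0, 0), diag(2)), 0)
  # 1-D shifted unit Gaussians: (mu1 - mu2)^2 / 2
  expect_equal(gaussian_kl(1, 1, 0, 1), 0.5, tolerance = 1e-12)
  expect_equal(gaussian_kl(0, 9, 0, 1), 0.5 * (9 - 1 + log(1 / 9)),
               tolerance = 1e-12)
  expect_error(gaussian_kl(c(0, 0), matrix(c(1, 2, 2, 1), 2), c(0, 0), diag(2)),
               "positive definite")
  expect_error(gaussian_kl(c(0, 0), diag(2), 0, 1), "dimension")
})

test_that("gaussian KL agrees with Monte-Carlo integration", {
  set.seed(7)
  d <- 3
  A1 <- matrix(rnorm(d * d), d); S1 <- crossprod(A1) + diag(d)
  A2 <- matrix(rnorm(d * d), d); S2 <- crossprod(A2) + diag(d)
  mu1 <- rnorm(d); mu2 <- rnorm(d)
  n <- 2e5
  Z <- matrix(rnorm(n * d), n) %*% chol(S1)
  X <- sweep(Z, 2, mu1, `+`)
  ldens <- function(X, mu, S) {
    L <- chol(S)
    Xc <- sweep(X, 2, mu)
    B <- forwardsolve(t(L), t(Xc))
    -0.5 * colSums(B^2) - sum(log(diag(L))) - d / 2 * log(2 * pi)
  }
  r <- ldens(X, mu1, S1) - ldens(X, mu2, S2)
  mc <- mean(r); se <- stats::sd(r) / sqrt(n)
  expect_lt(abs(gaussian_kl(mu1, S1, mu2, S2) - mc), 3 * se)
})

test_that("KL matrix estimation honors its contracts", {
  set.seed(8)
  X <- matrix(rnorm(400), ncol = 2)
  same <- estimate_kl_matrix(X, X, "gaussian")
  expect_lt(max(same$kl), 1e-10)
  expect_equal(diag(same$kl), c(class0 = 0, class1 = 0))

  x0 <- matrix(rnorm(50000), ncol = 1)
  x1 <- matrix(rnorm(50000, 1), ncol = 1)
  km <- estimate_kl_matrix(x0, x1, "gaussian")
  expect_lt(abs(km$kl[1, 2] - 0.5) / 0.5, 0.10)
  expect_lt(abs(km$kl[2, 1] - 0.5) / 0.5, 0.10)
  expect_equal(km$frobenius_norm, sqrt(km$kl[1, 2]^2 + km$kl[2, 1]^2))

  # kde estimator lands in the same ballpark on the same data
  kk <- estimate_kl_matrix(x0[1:2000, , drop = FALSE],
                           x1[1:2000, , drop = FALSE], "kde")
  expect_gt(kk$kl[1, 2], 0.25); expect_lt(kk$kl[1, 2], 0.8)
  expect_true(all(kk$kl >= 0))

  expect_error(estimate_kl_matrix(matrix(rnorm(4), 2), matrix(rnorm(4), 2)),
               "d \\+ 2")
})

test_that("LDA recovers the closed-form Fisher direction", {
  set.seed(9)
  n <- 5000
  L <- chol(matrix(c(2, 0.7, 0.7, 1), 2))
  mu0 <- c(0, 0); mu1 <- c(1.2, -0.5)
  X <- rbind(sweep(matrix(rnorm(n * 2), n) %*% L, 2, mu0, `+`),
             sweep(matrix(rnorm(n * 2), n) %*% L, 2, mu1, `+`))
  y <- rep(0:1, each = n)
  w <- fit_lda(X, y)$projection[, 1]
  w_true <- solve(crossprod(L), mu1 - mu0)
  cosv <- abs(sum(w * w_true) / sqrt(sum(w_true^2)))
  expect_gte(cosv, 1 - 1e-3)
})

test_that("LDA agrees with the MASS reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(10)
  g <- gaussian_classes(300, 200, 4, delta = c(1, 0.5, 0, -0.3), seed = 10)
  w <- fit_lda(g$X, g$y)$projection[, 1]
  w_ref <- as.numeric(MASS::lda(g$X, grouping = g$y)$scaling)
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_gt(abs(sum(w * w_ref)), 1 - 1e-8)
})

test_that("LDA sign convention and degenerate inputs", {
  g <- gaussian_classes(200, 200, 3, delta = c(1, 0, 0), seed = 11)
  m1 <- fit_lda(g$X, g$y)
  m2 <- fit_lda(g$X, 1 - g$y)
  expect_equal(m1$projection, -m2$projection, tolerance = 1e-12)
  s1 <- score_cases(m1, g$X)$values
  s2 <- score_cases(m2, g$X)$values
  expect_equal(s1, -s2, tolerance = 1e-10)
  # identical class means
  X <- rbind(matrix(1:12, 4, 3), matrix(1:12, 4, 3))
  expect_error(fit_lda(X, rep(0:1, each = 4)), "identical class means")
})

test_that("IMCA objective contracts: identity, Fisher optimality, rotation", {
  g0 <- gaussian_classes(150, 150, 3, seed = 12)
  A <- diag(3)[, 1, drop = FALSE]
  expect_lt(imca_objective(A, rbind(g0$X[1:150, ], g0$X[1:150, ]),
                           rep(0:1, each = 150)), 1e-10)
  expect_error(imca_objective(matrix(c(1, 1, 1), 3), g0$X, g0$y),
               "orthonormal")

  # homoscedastic case: the Fisher direction beats a 180-direction grid
  g <- gaussian_classes(800, 800, 4, delta = c(1, 0.4, 0, 0), seed = 13)
  w <- fit_lda(g$X, g$y)$projection[, 1]
  obj_f <- imca_objective(matrix(w), g$X, g$y)
  set.seed(13)
  Q <- qr.Q(qr(cbind(w, rnorm(4))))          # random 2-D subspace incl. w
  for (th in seq(0, pi, length.out = 180)) {
    v <- Q %*% c(cos(th), sin(th))
    expect_lte(imca_objective(v, g$X, g$y), obj_f + 1e-9)
  }

  # invariance under right-rotation of a d = 2 frame
  A2 <- lvremodel:::qr_retract(matrix(rnorm(8), 4, 2))
  th <- 0.83
  Rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(imca_objective(A2, g$X, g$y),
               imca_objective(A2 %*% Rot, g$X, g$y), tolerance = 1e-8)
})

test_that("IMCA analytic gradient matches central differences", {
  g <- gaussian_classes(300, 200, 5, delta = c(1, 0, 0.5, 0, 0),
                        L1 = diag(sqrt(c(2, 1, 1, 0.5, 1))), seed = 14)
  st <- lvremodel:::class_stats(g$X, g$y)
  A <- lvremodel:::qr_retract(matrix(rnorm(10), 5, 2))
  an <- lvremodel:::gaussian_objective_grad(A, st, TRUE)$grad
  eps <- 1e-6
  num <- matrix(0, 5, 2)
  for (i in 1:5) for (j in 1:2) {
    Ap <- A; Ap[i, j] <- Ap[i, j] + eps
    Am <- A; Am[i, j] <- Am[i, j] - eps
    num[i, j] <-
      (lvremodel:::gaussian_objective_grad(Ap, st, FALSE)$objective -
       lvremodel:::gaussian_objective_grad(Am, st, FALSE)$objective) / (2 * eps)
  }
  expect_lt(max(abs(an - num)), 1e-7)
})

test_that("IMCA reduces to LDA for homoscedastic Gaussian classes", {
  g <- gaussian_classes(2000, 2000, 10,
                        delta = c(1.5, rep(0.3, 9)), seed = 15)
  lda <- fit_lda(g$X, g$y)
  imca <- fit_imca(g$X, g$y, seed = 15)
  expect_gte(abs(sum(lda$projection * imca$projection)), 0.99)
  expect_gte(imca$objective, lda$objective - 1e-9)
})

test_that("IMCA finds variance-only separation where LDA has no signal", {
  set.seed(16)
  m <- 10; n <- 1000
  X <- rbind(matrix(rnorm(n * m), n),
             matrix(rnorm(n * m), n) %*% diag(c(3, rep(1, m - 1))))
  y <- rep(0:1, each = n)
  imca <- fit_imca(X, y, seed = 16)
  expect_gte(abs(imca$projection[1, 1]), 0.99)

  # objective matches the closed-form KL pair once sampling noise is small
  set.seed(17)
  m <- 3; n <- 50000
  X <- rbind(matrix(rnorm(n * m), n),
             matrix(rnorm(n * m), n) %*% diag(c(3, 1, 1)))
  y <- rep(0:1, each = n)
  imca <- fit_imca(X, y, n_restarts = 3, seed = 17)
  kl_a <- 0.5 * (9 - 1 + log(1 / 9))
  kl_b <- 0.5 * (1 / 9 - 1 + log(9))
  expect_lt(abs(imca$objective - sqrt(kl_a^2 + kl_b^2)) /
              sqrt(kl_a^2 + kl_b^2), 0.02)
})

test_that("IMCA optimizer keeps its line-search and orthonormality contracts", {
  g <- gaussian_classes(300, 200, 6, delta = c(1, 0.5, rep(0, 4)),
                        L1 = diag(sqrt(c(2, 1, 1, 1, 0.7, 1))), seed = 18)
  imca <- fit_imca(g$X, g$y, d = 2, seed = 18)
  expect_lt(max(abs(crossprod(imca$projection) - diag(2))), 1e-8)
  expect_true(all(diff(imca$trace$objective_path) >= 0))
  expect_true(imca$trace$lda_init_used)
  # kde path obeys the same contracts on a small problem
  sub <- c(1:75, 301:375)
  kimca <- fit_imca(g$X[sub, ], g$y[sub], estimator = "kde",
                    n_restarts = 2, max_iter = 25, tol = 1e-5, seed = 18)
  expect_true(all(diff(kimca$trace$objective_path) >= -1e-12))
  expect_equal(sum(kimca$projection^2), 1, tolerance = 1e-8)
})

test_that("remodeling indices are pooled-standardized and disease-positive", {
  gen <- small_cohort()
  run <- demo_run()
  idx <- run$indices[["ED&ES IMCA"]]
  v <- idx$values
  expect_lt(abs(mean(v)), 1e-10)
  expect_equal(stats::sd(v), 1, tolerance = 1e-10)
  gs <- idx$group_stats
  expect_gt(gs$case_mean, gs$control_mean)
  # pooled standardization: size-weighted group means cancel
  y <- run$cohort$labels
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  expect_lt(abs((n0 * gs$control_mean + n1 * gs$case_mean) / (n0 + n1)), 1e-10)
})

test_that("mode correlations are Pearson and match the direct formula", {
  set.seed(19)
  x <- rnorm(80); z <- 0.6 * x + 0.8 * rnorm(80)
  M <- mode_correlations(list(a = x, b = -x, c = z))
  expect_equal(diag(M), rep(1, 3), ignore_attr = TRUE)
  expect_equal(M[1, 2], -1, tolerance = 1e-12)
  r <- sum((x - mean(x)) * (z - mean(z))) /
    sqrt(sum((x - mean(x))^2) * sum((z - mean(z))^2))
  expect_equal(M[1, 3], r, tolerance = 1e-12)
  expect_error(mode_correlations(list(a = x, b = z[1:10])), "different")
})

test_that("back-projection inverts the standardization chain", {
  run <- demo_run()
  a <- run$analyses$edes
  model <- a$models$imca$model
  # a symmetric index makes the 50th percentile exactly zero
  sym_idx <- structure(list(values = seq(-2, 2, length.out = 101),
                            method = "IMCA", d = 1L),
                       class = "remodeling_index")
  shp <- backproject_mode(model, a$pca, a$std, sym_idx, c(25, 50, 75))
  mean_ed <- matrix(a$pca$mean[seq_len(3 * run$cohort$P)], ncol = 3,
                    byrow = TRUE)
  expect_lt(max(abs(shp$p50$ED$points - mean_ed)), 1e-8)
  # reconstruction is affine in the index value
  d1 <- shp$p75$ED$points - shp$p50$ED$points
  d2 <- shp$p50$ED$points - shp$p25$ED$points
  expect_lt(max(abs(d1 - d2)), 1e-8)
  expect_error(backproject_mode(model, a$pca, a$std, sym_idx, c(0, 50)),
               "\\(0, 100\\)")
})

test_that("a planted pure-scale effect orders percentile cavity volumes", {
  g <- generate_cohort(desk_params(31, n_control = 120, n_case = 80,
                                   effect_sizes = list(
                                     scale = 0.08, sphericity = 0,
                                     wall_thickness = 0, apical_bulge = 0,
                                     contraction = 0),
                                   severe_fraction = 0))
  co <- g$cohort
  al <- procrustes_align(co, "ED")
  pca <- fit_pca(al$aligned, 0.985)
  std <- project_and_standardize(pca, al$aligned)
  model <- fit_imca(std, co$labels, seed = 31)
  idx <- score_cases(model, std)
  shp <- backproject_mode(model, pca, std, idx, c(5, 95))
  topo <- co$topology
  vol <- function(s) {
    m <- lvremodel:::close_surface(s$points[seq_len(topo$n_vertices), ], topo)
    mesh_volume(m$points, m$faces)
  }
  expect_gt(vol(shp$p95$ED), vol(shp$p05$ED))
})
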
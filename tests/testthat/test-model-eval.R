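test_that("logistic fits reproduce closed forms", {
  # intercept-only: beta0 = logit of the positive rate
  y <- rep(c(1, 0), c(30, 70))
  fit0 <- fit_logistic(y, matrix(numeric(0), 100, 0))
  expect_equal(unname(fit0$coefficients[1]), log(0.3 / 0.7), tolerance = 1e-6)
  expect_equal(fit0$k, 1L)

  # 2x2 table: slope = log odds ratio ln(ad/bc)
  y2 <- rep(c(1, 1, 0, 0), c(10, 5, 3, 12))
  x2 <- rep(c(1, 0, 1, 0), c(10, 5, 3, 12))
  fit2 <- fit_logistic(y2, cbind(exposure = x2))
  expect_equal(unname(fit2$coefficients["exposure"]), log(8), tolerance = 1e-6)
  expect_equal(fit2$k, 2L)

  # a perfectly separating predictor raises the separation flag
  ysep <- rep(0:1, each = 20)
  xsep <- c(rnorm(20, -3), rnorm(20, 3))
  fit3 <- fit_logistic(ysep, cbind(s = xsep))
  expect_true(fit3$separation)
  # ... and Firth keeps the estimate finite there
  fitF <- fit_logistic(ysep, cbind(s = xsep), firth = TRUE)
  expect_lt(abs(fitF$coefficients["s"]), 20)
  expect_identical(fitF$method, "firth")
})

test_that("Firth penalization matches ML where ML is well behaved", {
  set.seed(20)
  x <- rnorm(400); y <- rbinom(400, 1, plogis(-0.5 + 0.8 * x))
  f_ml <- fit_logistic(y, cbind(x = x))
  f_fi <- fit_logistic(y, cbind(x = x), firth = TRUE)
  expect_equal(unname(f_fi$coefficients), unname(f_ml$coefficients),
               tolerance = 0.05)
})

test_that("invalid designs fail with the offending term named", {
  y <- rep(0:1, each = 10)
  expect_error(fit_logistic(y, cbind(const = rep(1, 20))), "const")
  X <- cbind(a = rnorm(20), b = rnorm(20))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(fit_logistic(y, X), "collinear")
  expect_error(fit_logistic(c(y[-1], 2), cbind(x = rnorm(20))), "binary")
})

test_that("deviance, AIC, and BIC identities hold exactly", {
  fake <- structure(list(logLik = -50, k = 3L, n = 100L),
                    class = "logistic_model")
  gof <- goodness_of_fit(fake)
  expect_equal(unname(gof), c(100, 106, 100 + 3 * log(100)))
  expect_equal(gof[["bic"]], 113.8155, tolerance = 1e-4)

  set.seed(21)
  y <- rbinom(80, 1, 0.4)
  fit <- fit_logistic(y, cbind(x = rnorm(80)))
  g <- goodness_of_fit(fit)
  expect_equal(g[["aic"]] - g[["deviance"]], 2 * fit$k)
  expect_equal(g[["bic"]] - g[["deviance"]], fit$k * log(fit$n))
})

test_that("odds ratios and Wald intervals are mutually consistent", {
  set.seed(22)
  y <- rbinom(300, 1, 0.3)
  x <- rnorm(300) + y
  fit <- fit_logistic(y, cbind(x = x, z = rnorm(300)))
  o <- odds_ratio(fit, "x")
  expect_equal(o[["or"]], exp(o[["beta"]]))
  expect_equal(o[["lo"]], exp(o[["beta"]] - 1.96 * o[["se"]]))
  # CI excludes 1 <=> two-sided Wald p < 0.05 (1.96 cutoff)
  excl <- o[["lo"]] > 1 || o[["hi"]] < 1
  expect_identical(excl, o[["p"]] < 2 * stats::pnorm(-1.96))
  o0 <- odds_ratio(fit, "z")
  expect_error(odds_ratio(fit, "nope"), "unknown term")
})

test_that("AUC equals all-pairs concordance counting, including ties", {
  brute_auc <- function(s, y) {
    s1 <- s[y == 1]; s0 <- s[y == 0]
    cmp <- outer(s1, s0, `-`)
    (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(s1) * length(s0))
  }
  for (r in 1:10) {
    set.seed(r)
    n <- 60
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(round(rnorm(n), 1))      # coarse scores force ties
    expect_equal(roc_auc(s, y)$auc, brute_auc(s, y), tolerance = 1e-12)
  }
  y <- rep(0:1, each = 10)
  expect_equal(roc_auc(c(rnorm(10), rnorm(10) + 100), y)$auc, 1)
  expect_equal(roc_auc(rep(3, 20), y)$auc, 0.5)
  # invariance under strictly increasing transforms
  set.seed(23)
  s <- rnorm(50); y <- rbinom(50, 1, 0.5)
  expect_equal(roc_auc(s, y)$auc, roc_auc(exp(s), y)$auc)
})

test_that("DeLong comparison: identity, antisymmetry, and power", {
  set.seed(24)
  y <- rep(0:1, each = 100)
  s1 <- rnorm(200) + y * 2
  s2 <- rnorm(200) + y * 0.5
  ra <- roc_auc(s1, y); rb <- roc_auc(s2, y)
  self <- compare_auc(ra, ra)
  expect_equal(self$delta_auc, 0); expect_equal(self$p, 1)
  ab <- compare_auc(ra, rb); ba <- compare_auc(rb, ra)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)

  # scores with true AUCs ~0.95 vs ~0.75 are distinguished reliably
  hits <- 0
  for (r in 1:60) {
    set.seed(r + 100)
    y <- rep(0:1, each = 250)
    sa <- rnorm(500) + y * 2.326          # ~AUC 0.95
    sb <- rnorm(500) + y * 0.954          # ~AUC 0.75
    p <- compare_auc(roc_auc(sa, y), roc_auc(sb, y))$p
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.95)
})

test_that("assumption tests reject when assumptions are violated", {
  # covariance inequality: power at a 4x variance inflation
  g <- gaussian_classes(500, 500, 3, L1 = diag(3) * 2, seed = 25)
  out <- test_lda_assumptions(g$X, g$y)
  expect_lt(out$covariance_equality$p, 0.01)
  # heavy tails: normality rejected for the t3 class
  set.seed(26)
  Xt <- rbind(matrix(rnorm(1000 * 3), 1000), matrix(rt(1000 * 3, 3), 1000))
  out2 <- test_lda_assumptions(Xt, rep(0:1, each = 1000))
  expect_lt(out2$normality$p[out2$normality$class == 1], 0.01)
  expect_gt(out2$normality$p[out2$normality$class == 0], 0.01)
})

test_that("the default cohort violates the LDA assumptions as designed", {
  run <- demo_run()
  std <- run$analyses$edes$std
  out <- test_lda_assumptions(std$z[, 1:5], run$cohort$labels)
  expect_lt(out$covariance_equality$p, 0.05)
})

test_that("demographics table: identity, power, and layout", {
  gen <- small_cohort()
  cv <- gen$cohort$covariates
  # same sample duplicated into both classes: nothing to detect
  cv2 <- rbind(cv, cv)
  cv2$case_id <- sprintf("c%03d", seq_len(nrow(cv2)))
  d0 <- demographics_table(cv2, rep(0:1, each = nrow(cv)))
  expect_true(all(d0$p > 0.99))
  # planted 0.8 SD shift is detected
  set.seed(27)
  cv3 <- data.frame(case_id = sprintf("x%03d", 1:600),
                    sex = rbinom(600, 1, 0.5), age = rnorm(600, 60, 10),
                    height = c(rnorm(300, 170, 8), rnorm(300, 176.4, 8)),
                    weight = rnorm(600, 80, 15),
                    systolic_bp = rnorm(600, 125, 18),
                    diastolic_bp = rnorm(600, 75, 10),
                    diabetes = rbinom(600, 1, 0.2),
                    smoking = rbinom(600, 1, 0.15))
  d1 <- demographics_table(cv3, rep(0:1, each = 300))
  expect_lt(d1$p[d1$variable == "height"], 0.01)
  expect_identical(d1$signif[d1$variable == "height"], "**")
  expect_setequal(d1$type, c("categorical", "continuous"))
})

test_that("chi-square null calibration is near nominal", {
  rej <- mean(vapply(1:200, function(s) {
    set.seed(s)
    x <- rbinom(1000, 1, 0.3)
    y <- rbinom(1000, 1, 0.5)
    suppressWarnings(stats::chisq.test(table(y, x), correct = FALSE)$p.value) < 0.05
  }, logical(1)))
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})

test_that("slope comparison equals per-group OLS and detects differences", {
  set.seed(28)
  x <- rnorm(200); g <- rep(0:1, each = 100)
  y <- 2 + x * (1 + g) + rnorm(200, sd = 0.1)
  out <- compare_slopes(x, y, g)
  s0 <- stats::coef(stats::lm(y[g == 0] ~ x[g == 0]))[[2]]
  s1 <- stats::coef(stats::lm(y[g == 1] ~ x[g == 1]))[[2]]
  expect_equal(out$slope0, s0, tolerance = 1e-12)
  expect_equal(out$slope1, s1, tolerance = 1e-12)
  expect_lt(out$p, 0.001)
  # identical groups: interaction exactly zero
  out0 <- compare_slopes(c(x[1:100], x[1:100]), c(y[1:100], y[1:100]), g)
  expect_lt(abs(out0$interaction), 1e-10)
})

test_that("the model suite reports the configured family coherently", {
  run <- demo_run()
  ms <- run$model_suite
  expect_equal(ms$aic - ms$deviance, 2 * ms$k)
  expect_equal(ms$bic - ms$deviance, ms$k * log(length(run$cohort$case_ids)))
  expect_identical(ms$model[1], "Baseline")
  expect_equal(ms$k[ms$model == "Baseline"], 9L)   # 8 covariates + intercept
  expect_true(all(c("MASSVOL + Baseline", "EDVI + ESVI + Baseline") %in%
                    ms$model))
  # every index model carries its coefficient and odds ratio
  idx_rows <- grepl("Score", ms$model)
  expect_true(all(is.finite(ms$beta1[idx_rows])))
  expect_true(all(ms$or_[idx_rows] > 1))
  # planted signal: the ED&ES IMCA model dominates the baseline AUC
  expect_gte(ms$auc_pct[ms$model == "ED&ES IMCA Score + Baseline"],
             ms$auc_pct[ms$model == "Baseline"])

  # with no indices and no volumes the suite is just the baseline
  base_only <- build_model_suite(run$cohort)
  expect_identical(base_only$model, "Baseline")
})
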
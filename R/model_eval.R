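# Evaluation of remodeling indices: multivariable logistic-regression models
# with clinical baseline covariates, goodness-of-fit (deviance, AIC, BIC),
# odds ratios, ROC/AUC with DeLong comparisons, LDA assumption tests
# (multivariate normality, covariance homogeneity), demographics summaries,
# and between-group regression-slope comparisons.

baseline_terms <- c("sex", "age", "height", "weight",
                    "systolic_bp", "diastolic_bp", "smoking", "diabetes")

#' Maximum-likelihood logistic regression with separation monitoring
#'
#' Fits `y ~ X` by IRLS (via [stats::glm]), exposing the exact
#' log-likelihood and the number of estimated parameters k (intercept
#' included).  (Quasi-)complete separation -- a predictor splitting the
#' classes so well that coefficients diverge -- is detected and flagged,
#' never hidden; with `firth = TRUE` the model is refitted with Firth's
#' bias-reducing penalized likelihood, which stays finite under separation.
#'
#' @param y Binary 0/1 response.
#' @param X Design matrix with named columns (no intercept column; one is
#'   added internally).
#' @param firth Refit with Firth penalization (adjusted-score IRLS).
#' @param max_iter IRLS iteration cap.
#' @return A `logistic_model`: `terms`, `coefficients`, `se`, `vcov`,
#'   `logLik`, `n`, `k`, `fitted`, `separation`, `converged`, `method`.
#' @export
fit_logistic <- function(y, X, firth = FALSE, max_iter = 100L) {
  X <- as.matrix(X)
  if (!is_binary01(y)) stopf("response must be binary 0/1 with no missing values")
  if (nrow(X) != length(y)) stopf("design has %d rows for %d responses",
                                  nrow(X), length(y))
  if (ncol(X) && is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  const <- which(apply(X, 2L, stats::sd) < 1e-12)
  if (length(const))
    stopf("zero-variance design column(s): %s",
          paste(colnames(X)[const], collapse = ", "))

  separation <- FALSE
  df <- if (ncol(X)) data.frame(y = y, X, check.names = FALSE)
        else data.frame(y = y)
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(maxit = max_iter)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("did not converge", msg)) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::coef(fit)
  if (any(is.na(beta)))
    stopf("collinear design: aliased term(s) %s",
          paste(names(beta)[is.na(beta)], collapse = ", "))
  if (sqrt(sum(beta^2)) > 1e3) separation <- TRUE

  if (firth) {
    fr <- firth_logistic(y, cbind(`(Intercept)` = 1, X), max_iter = max_iter)
    beta <- fr$beta
    V <- fr$vcov
    eta <- as.numeric(cbind(1, X) %*% beta)
    p <- stats::plogis(eta)
    ll <- sum(y * log(p) + (1 - y) * log1p(-p))
    out <- list(terms = names(beta), coefficients = beta,
                se = sqrt(diag(V)), vcov = V, logLik = ll,
                n = length(y), k = length(beta), fitted = p,
                separation = separation, converged = fr$converged,
                method = "firth")
  } else {
    V <- stats::vcov(fit)
    out <- list(terms = names(beta), coefficients = beta,
                se = sqrt(diag(V)), vcov = V,
                logLik = as.numeric(stats::logLik(fit)),
                n = length(y), k = length(beta),
                fitted = stats::fitted(fit),
                separation = separation, converged = fit$converged,
                method = "ml")
  }
  structure(out, class = "logistic_model")
}

# Firth's penalized logistic regression: Newton steps on the adjusted score
# U*(b) = X'(y - p + h (1/2 - p)) with h the hat-matrix diagonal.
firth_logistic <- function(y, Xi, max_iter = 100L, tol = 1e-8) {
  beta <- rep(0, ncol(Xi))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(as.numeric(Xi %*% beta))
    w <- pmax(p * (1 - p), 1e-12)
    XW <- Xi * w
    info <- crossprod(Xi, XW)
    Li <- chol(info)
    H <- XW %*% chol2inv(Li) %*% t(Xi)
    h <- diag(H)
    U <- crossprod(Xi, y - p + h * (0.5 - p))
    delta <- backsolve(Li, forwardsolve(t(Li), U))
    # damp outsized steps for stability under near-separation
    sn <- sqrt(sum(delta^2))
    if (sn > 5) delta <- delta * 5 / sn
    beta <- beta + as.numeric(delta)
    if (max(abs(U)) < tol) { converged <- TRUE; break }
  }
  p <- stats::plogis(as.numeric(Xi %*% beta))
  info <- crossprod(Xi, Xi * pmax(p * (1 - p), 1e-12))
  list(beta = stats::setNames(as.numeric(beta), colnames(Xi)),
       vcov = chol2inv(chol(info)), converged = converged)
}

#' Deviance, AIC, and BIC of a fitted logistic model
#'
#' `deviance = -2 log L`, `AIC = deviance + 2k`,
#' `BIC = deviance + k log(n)`, with k counting the intercept.  Lower is
#' better for all three.
#'
#' @param model A `logistic_model`.
#' @return Named numeric vector `c(deviance, aic, bic)`.
#' @export
goodness_of_fit <- function(model) {
  dev <- -2 * model$logLik
  c(deviance = dev, aic = dev + 2 * model$k,
    bic = dev + model$k * log(model$n))
}

#' Odds ratio of a model term with Wald 95% confidence interval
#'
#' @param model A `logistic_model`.
#' @param term Name of the coefficient.
#' @return Named vector `c(or, lo, hi, beta, se, p)`.
#' @export
odds_ratio <- function(model, term) {
  if (!term %in% model$terms) stopf("unknown term '%s'", term)
  b <- model$coefficients[[term]]
  s <- model$se[[term]]
  z <- b / s
  c(or = exp(b), lo = exp(b - 1.96 * s), hi = exp(b + 1.96 * s),
    beta = b, se = s, p = 2 * stats::pnorm(-abs(z)))
}

#' ROC curve and AUC of a score against binary labels
#'
#' AUC equals the Mann-Whitney statistic with ties counted one half (the
#' probability that a random diseased case scores above a random control).
#' The DeLong variance of the AUC is attached for nonparametric comparisons.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 labels (1 = disease; higher score = more diseased).
#' @return A `roc_result`: `auc`, `delong_var`, `curve`
#'   (threshold/sensitivity/specificity), plus internals used by
#'   [compare_auc()].
#' @export
roc_auc <- function(scores, labels) {
  y <- check_labels(labels, length(scores))
  roc <- pROC::roc(response = y, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))
  dv <- suppressWarnings(as.numeric(pROC::var(roc, method = "delong")))
  curve <- data.frame(threshold = roc$thresholds,
                      sensitivity = roc$sensitivities,
                      specificity = roc$specificities)
  structure(list(auc = auc, delong_var = dv, curve = curve,
                 roc = roc, scores = as.numeric(scores), labels = y),
            class = "roc_result")
}

#' Compare two correlated AUCs by the DeLong method
#'
#' Two-sided nonparametric test of equal AUC for two scores computed over
#' the same cases.
#'
#' @param roc_a,roc_b `roc_result` objects from [roc_auc()] over identical
#'   cases and labels.
#' @return List `delta_auc`, `z`, `p`.
#' @export
compare_auc <- function(roc_a, roc_b) {
  if (!identical(roc_a$labels, roc_b$labels))
    stopf("the two ROC results cover different cases or labels")
  delta <- roc_a$auc - roc_b$auc
  if (isTRUE(all.equal(roc_a$scores, roc_b$scores, tolerance = 1e-15)))
    return(list(delta_auc = 0, z = 0, p = 1))
  tst <- suppressWarnings(
    pROC::roc.test(roc_a$roc, roc_b$roc, method = "delong", paired = TRUE))
  z <- as.numeric(tst$statistic)
  p <- as.numeric(tst$p.value)
  if (!is.finite(z)) {            # zero DeLong variance (e.g. both perfect)
    z <- if (abs(delta) < 1e-15) 0 else sign(delta) * Inf
    p <- if (abs(delta) < 1e-15) 1 else 0
  }
  list(delta_auc = delta, z = z, p = p)
}

# Mardia's multivariate skewness and kurtosis tests of multinormality.
mardia_test <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 2L) stopf("too few cases (%d) for dimension %d", n, p)
  Xc <- sweep(X, 2L, colMeans(X))
  S <- crossprod(Xc) / n                    # ML covariance
  Si <- tryCatch(chol2inv(chol(S)),
                 error = function(e) stopf("singular class covariance"))
  G <- Xc %*% Si %*% t(Xc)
  b1 <- sum(G^3) / n^2
  df1 <- p * (p + 1) * (p + 2) / 6
  p_skew <- stats::pchisq(n * b1 / 6, df1, lower.tail = FALSE)
  b2 <- mean(diag(G)^2)
  z <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  p_kurt <- 2 * stats::pnorm(-abs(z))
  list(skewness = b1, kurtosis = b2, p_skew = p_skew, p_kurt = p_kurt,
       p = min(1, 2 * min(p_skew, p_kurt)))
}

# Box's M statistic with Bartlett's chi-square approximation; for two
# groups this is Bartlett's modification of the likelihood-ratio test of
# covariance-matrix equality.
box_m_test <- function(X, y) {
  X <- as.matrix(X)
  p <- ncol(X)
  groups <- split(seq_len(nrow(X)), y)
  g <- length(groups)
  ni <- vapply(groups, length, integer(1))
  n <- sum(ni)
  logdet <- function(S) {
    L <- tryCatch(chol(S), error = function(e) stopf("singular class covariance"))
    2 * sum(log(diag(L)))
  }
  Ss <- lapply(groups, function(ix) stats::cov(X[ix, , drop = FALSE]))
  Sp <- Reduce(`+`, Map(function(S, m) (m - 1) * S, Ss, ni)) / (n - g)
  M <- (n - g) * logdet(Sp) - sum((ni - 1) * vapply(Ss, logdet, numeric(1)))
  c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (g - 1)) *
    (sum(1 / (ni - 1)) - 1 / (n - g))
  stat <- M * (1 - c1)
  df <- p * (p + 1) * (g - 1) / 2
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Test the distributional assumptions behind LDA
#'
#' Multivariate normality within each class is assessed with Mardia's
#' skewness and kurtosis statistics (combined per class by a Bonferroni
#' doubling of the smaller p); equality of the class covariance matrices is
#' assessed with Box's M statistic under Bartlett's chi-square
#' approximation.
#'
#' @param scores Score matrix or `standardized_scores`.
#' @param labels 0/1 class labels.
#' @return List with `normality` (data frame: class, p_skew, p_kurt, p) and
#'   `covariance_equality` (statistic, df, p).
#' @export
test_lda_assumptions <- function(scores, labels) {
  X <- score_matrix(scores)
  y <- check_labels(labels, nrow(X))
  norm <- do.call(rbind, lapply(c(0L, 1L), function(cl) {
    mt <- mardia_test(X[y == cl, , drop = FALSE])
    data.frame(class = cl, p_skew = mt$p_skew, p_kurt = mt$p_kurt, p = mt$p)
  }))
  list(normality = norm, covariance_equality = box_m_test(X, y))
}

#' Demographics comparison table between classes
#'
#' Continuous covariates are summarized as mean +/- SD per class and
#' compared with the two-sample Wilcoxon rank-sum test; binary covariates
#' as proportions compared with Pearson's chi-square test (no continuity
#' correction).  Missing values are excluded per variable with counts
#' reported.
#'
#' @param covariates Covariate data frame (as in a [shape_cohort]).
#' @param labels 0/1 labels aligned with the covariate rows.
#' @return Data frame: variable, type, per-class summaries, n_missing, p,
#'   and significance marker (`*` p < 0.05, `**` p < 0.01).
#' @export
demographics_table <- function(covariates, labels) {
  y <- check_labels(labels, nrow(covariates))
  cont <- intersect(c("age", "height", "weight", "systolic_bp",
                      "diastolic_bp", "edvi", "esvi"), names(covariates))
  catg <- intersect(c("sex", "diabetes", "smoking"), names(covariates))
  rows <- list()
  for (v in c(catg, cont)) {
    x <- covariates[[v]]
    ok <- !is.na(x)
    miss <- sum(!ok)
    x0 <- x[ok & y == 0L]; x1 <- x[ok & y == 1L]
    if (v %in% cont) {
      p <- suppressWarnings(stats::wilcox.test(x0, x1, exact = FALSE)$p.value)
      s0 <- sprintf("%.2f ± %.2f", mean(x0), stats::sd(x0))
      s1 <- sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1))
      ty <- "continuous"
    } else {
      tab <- table(factor(y[ok], levels = c(0, 1)), factor(x[ok], levels = c(0, 1)))
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      s0 <- sprintf("%.1f%%", 100 * mean(x0))
      s1 <- sprintf("%.1f%%", 100 * mean(x1))
      ty <- "categorical"
    }
    rows[[v]] <- data.frame(variable = v, type = ty, control = s0, case = s1,
                            n_missing = miss, p = p,
                            signif = if (is.na(p)) "" else if (p < 0.01) "**"
                                     else if (p < 0.05) "*" else "")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare regression slopes between the two classes
#'
#' Per-class ordinary least-squares slopes of `y ~ x`, with the interaction
#' test from the pooled model `y ~ x * group`.  Used for the ESVI-vs-EDVI
#' and EF-vs-ESVI relationships, whose slopes separate infarct patients
#' from controls.
#'
#' @param x,y Numeric vectors.
#' @param labels 0/1 group labels.
#' @return List `slope0`, `slope1`, `interaction` (slope difference),
#'   `p` (two-sided interaction p-value).
#' @export
compare_slopes <- function(x, y, labels) {
  g <- check_labels(labels, length(x))
  if (min(table(g)) < 3L) stopf("need >= 3 cases per class")
  for (cl in c(0L, 1L))
    if (stats::sd(x[g == cl]) < 1e-12)
      stopf("zero x-variance in class %d", cl)
  s0 <- stats::coef(stats::lm(y[g == 0L] ~ x[g == 0L]))[[2L]]
  s1 <- stats::coef(stats::lm(y[g == 1L] ~ x[g == 1L]))[[2L]]
  fit <- stats::lm(y ~ x * g)
  sm <- stats::summary.lm(fit)$coefficients
  list(slope0 = s0, slope1 = s1,
       interaction = sm["x:g", "Estimate"],
       p = sm["x:g", "Pr(>|t|)"])
}

#' Fit the full logistic model family and report goodness-of-fit
#'
#' Fits, over the cohort's cases: a Baseline model (sex, age, height,
#' weight, systolic/diastolic blood pressure, smoking, diabetes); when
#' volumes are supplied, a MASSVOL model (baseline + EDV + ESV + LV mass)
#' and an EDVI+ESVI model (baseline + indexed volumes); and one model per
#' supplied remodeling index (baseline + index).  Each row reports k
#' (intercept counted), deviance, AIC, BIC, AUC of the fitted
#' probabilities, and for index models the index coefficient, its standard
#' error, and odds ratio with 95% CI.
#'
#' @param cohort A [shape_cohort] (covariates and labels are taken from it).
#' @param indices Named list of `remodeling_index` objects or numeric
#'   vectors aligned with cohort case order (e.g.
#'   `list("ED&ES IMCA" = idx)`); entries that are `NULL` are skipped with
#'   a warning.
#' @param volumes Optional [derived_volumes()] table.
#' @param firth Fit all models with Firth penalization.
#' @return Data frame (one row per model) with attribute `"fits"` (the
#'   `logistic_model` objects) and `"rocs"` (`roc_result` per model).
#' @export
build_model_suite <- function(cohort, indices = list(), volumes = NULL,
                              firth = FALSE) {
  cov <- cohort$covariates
  y <- as.numeric(cohort$labels)
  base <- as.matrix(cov[, baseline_terms])
  designs <- list(Baseline = list(X = base, index_term = NA))
  if (!is.null(volumes)) {
    vol <- volumes[match(cohort$case_ids, volumes$case_id), ]
    designs[["MASSVOL + Baseline"]] <- list(
      X = cbind(base, edv = vol$edv, esv = vol$esv, lv_mass = vol$lv_mass),
      index_term = NA)
    designs[["EDVI + ESVI + Baseline"]] <- list(
      X = cbind(base, edvi = vol$edvi, esvi = vol$esvi), index_term = NA)
  }
  for (nm in names(indices)) {
    ix <- indices[[nm]]
    if (is.null(ix)) { warnf("index '%s' missing: row skipped", nm); next }
    v <- if (inherits(ix, "remodeling_index")) as.numeric(ix$values)
         else as.numeric(ix)
    X <- cbind(base, v)
    colnames(X)[ncol(X)] <- "index"
    designs[[paste(nm, "Score + Baseline")]] <- list(X = X,
                                                     index_term = "index")
  }

  fits <- list(); rocs <- list(); rows <- list()
  for (nm in names(designs)) {
    de <- designs[[nm]]
    fit <- fit_logistic(y, de$X, firth = firth)
    gof <- goodness_of_fit(fit)
    roc <- roc_auc(fit$fitted, y)
    row <- data.frame(model = nm, k = fit$k,
                      deviance = gof[["deviance"]], aic = gof[["aic"]],
                      bic = gof[["bic"]], auc_pct = 100 * roc$auc,
                      beta1 = NA_real_, se_beta1 = NA_real_,
                      or_ = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
                      separation = fit$separation)
    if (!is.na(de$index_term)) {
      o <- odds_ratio(fit, de$index_term)
      row$beta1 <- o[["beta"]]; row$se_beta1 <- o[["se"]]
      row$or_ <- o[["or"]]; row$or_lo <- o[["lo"]]; row$or_hi <- o[["hi"]]
    }
    fits[[nm]] <- fit; rocs[[nm]] <- roc; rows[[nm]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "rocs") <- rocs
  out
}
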
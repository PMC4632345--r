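---
title: "Methods: supervised shape analysis of left-ventricular remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supervised shape analysis of left-ventricular remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After myocardial infarction the left ventricle (LV) remodels: it dilates,
becomes more spherical, its wall thins, and the apex may bulge.  Clinical
practice summarizes this with a handful of scalar measures (mass, volumes,
ejection fraction) that discard most of the available shape information.
`lvremodel` instead treats each heart as a pair of high-dimensional
homologous point sets — the endo- and epicardial surfaces at end-diastole
(ED) and end-systole (ES), with point *i* corresponding anatomically across
all cases — and extracts a *single standardized remodeling index* that best
separates infarct patients from asymptomatic controls.

## The pipeline

1. **Rigid alignment.** Generalized Procrustes analysis aligns every case to
   the evolving mean shape by rotation and translation only.  Scale is
   *not* removed: heart size is itself a disease signal.  Reflections are
   forbidden (the rotation determinant is constrained to +1) because
   anatomy is chiral.  The first case initializes the reference; iteration
   stops when the mean moves less than 1e-9 mm RMS (at most 100 rounds).
   ED and ES are aligned per frame; for the combined analysis the aligned
   frames are concatenated into one shape vector per case.

2. **PCA.** Covariance PCA (raw coordinates, n−1 denominator) reduces the
   3P- or 6P-dimensional shape space to the smallest number of modes m
   explaining 98.5% of the total variance (a configurable threshold).  This
   is a preliminary conditioning step: it bounds the dimension the
   discriminant estimators must handle.  Each of the ED-only, ES-only and
   ED&ES analyses gets its own PCA basis.  Mode scores are standardized to
   pooled mean 0 / SD 1, and the constants are stored so new cases map into
   the identical space.

3. **Discriminant direction.** Two supervised reductions of the m
   standardized scores to a scalar:

   * **LDA** (Fisher): w ∝ Sw⁻¹(μ₁ − μ₀) with Sw the pooled within-class
     covariance.  Optimal when both classes are Gaussian with equal
     covariances.
   * **IMCA** (information maximizing component analysis): the orthonormal
     projection A maximizing ‖D_KL(AX₀, AX₁)‖_F, the Frobenius norm of the
     2×2 matrix of Kullback–Leibler divergences between the projected class
     densities.  The KL matrix approximates the Fisher information distance
     between the class distributions, so IMCA needs neither Gaussianity nor
     homoscedasticity.  The projected densities are modeled either as
     Gaussians (closed-form KL, analytic gradient — the default) or by a
     product-Gaussian-kernel density estimate with Silverman bandwidths
     (`estimator = "kde"`).

   The optimizer is multi-start gradient ascent with QR re-orthonormalization
   after every step and a step-halving line search that never accepts a
   decrease.  The LDA direction (completed to d orthonormal columns) is
   always one start, so the returned objective can never fall below LDA's;
   the remaining starts are seeded random frames.  Convergence is declared
   after three consecutive accepted steps with relative gain below 1e-8
   (500-iteration cap; non-convergence returns the best iterate with a
   warning, never silently).  For the KDE estimator the gradient is a
   forward difference on the retraction, and the pipeline bounds that path
   at 60 iterations with a 1e-6 tolerance — direction changes beyond that
   point are far below what the downstream logistic models resolve.

   The resulting per-case score is standardized to pooled mean 0 / SD 1
   (pooled, not per class, so the size-weighted group means cancel) with
   the sign fixed positive toward disease.  d defaults to 1 — a single
   global mode of remodeling; d = 2, 3 yield the further orthogonal modes.

4. **Evaluation.** Logistic regression quantifies each index against the
   clinical baseline: deviance = −2 log L, AIC = deviance + 2k,
   BIC = deviance + k log n (k counts the intercept, so the 8-covariate
   baseline has k = 9; the accounting is uniform across models so
   comparisons are unaffected).  ROC curves use the rank (Mann–Whitney)
   AUC with ties counted one half; correlated AUCs are compared with the
   DeLong method, two-sided, uncorrected for multiplicity.  Quasi-complete
   separation — expected when discrimination approaches 100% — is detected
   and flagged rather than hidden; Firth's penalized likelihood is
   available as an option when finite estimates are required.  The LDA
   assumptions themselves are testable: Mardia's skewness/kurtosis per
   class for multinormality and Box's M (Bartlett's χ² approximation) for
   covariance equality.

5. **Visualization.** Because the index is a direction in shape space, it
   back-projects: index value → raw projection → standardized PCA scores
   along the mode → raw scores → μ + modes·scores.  Shapes reconstructed at
   index percentiles (type-7 quantiles) render the remodeling continuum
   from healthy to diseased.

## The synthetic cohort generator

External clinical shape cohorts are access-controlled, so the generator is
a first-class module: every downstream stage is testable against planted
ground truth.

The LV is modeled as two nested truncated prolate spheroids sampled on a
fixed apex + rings × longitudes grid (homologous correspondence by grid
position).  Five latent factors drive each case: overall scale, sphericity
(radius-to-length ratio), wall thickness, a Gaussian-falloff apical bulge,
and a systolic radial contraction.  Disease-class means are offset on all
five — larger, rounder, thinner-walled, more bulging, weaker-contracting —
the canonical post-infarction phenotypes.  Defaults (desk scale): base
long semi-axis 50 mm, equatorial radius 27 mm, wall 9 mm, basal truncation
at 0.3·a, ES long-axis shortening 12%, mean radial contraction 0.28 with
systolic wall thickening ×1.35; class offsets +5% scale, +5% sphericity,
−1.0 mm wall, +1.5 mm bulge, −0.05 contraction.  These give control
ejection fractions near 0.55 and a population single-index AUC around
0.98–0.99, so desk-scale model comparisons are informative rather than
saturated.  Covariate records are drawn per class from published-style
demographics (the disease class is more male, taller, heavier); covariate
correlations are deliberately not modeled.

Three design choices deserve emphasis:

* **Smooth, low-rank shape noise.** Case-to-case variability beyond the
  latent factors is a smooth random deformation field on a 6-function
  tensor basis of the surface parameters (shared by endo- and epicardium,
  drawn per frame), plus 0.1 mm iid jitter.  Surface models fitted to
  images vary smoothly, not pointwise; with iid noise alone a 98.5%
  variance cutoff would retain nearly as many modes as cases, which is not
  the regime of clinical shape atlases.

* **Heteroscedasticity.** Disease-class latent SDs are inflated
  (`hetero_factor`, default 1.5): patient shape variability exceeds
  control variability, and the LDA equal-covariance assumption is
  violated by construction — Box's M rejects on default cohorts.

* **A severe-remodeling subgroup.** 35% of patients draw additional
  offsets (aneurysmal: +3.5 mm bulge, −0.06 contraction, +5% scale),
  making the disease-class latent distribution bimodal and within-class
  normality testably false.

Ground truth records the per-case latents and the *planted direction*: the
unit-norm difference between the noise-free class-mean shapes in
concatenated ED&ES point space.  Parameter-recovery tests compare it (after
projection onto the retained PCA subspace) with the back-projected fitted
mode.

ES shapes derive from the same latents as ED plus contraction, and the
disease effect on contraction is only visible at ES, while ES size
confounds scale with contraction; knowing ED disambiguates.  Hence
ES-only analyses outperform ED-only, and ED&ES outperforms both — an
ordering the test suite checks over repeated seeds.

Volumes close the sampled endocardial surface with a basal cap and apply
the divergence theorem; EF = (EDV − ESV)/EDV; volume indices divide by
Mosteller body-surface area √(height·weight/3600) (the BSA rule is a
package choice — sources rarely state theirs); LV mass is the ED
myocardial shell volume × 1.05 g/ml.

## What the tests do and do not show

The suite verifies the machinery against independent oracles (closed-form
and Monte-Carlo KL, Kabsch/vegan rigid fits, all-pairs AUC counting,
closed-form logistic slopes), the method's internal contracts
(orthonormality, line-search monotonicity, standardization identities,
determinism under a fixed seed), and the qualitative structure the planted
effects imply: supervised indices dominate mass/volume models, ES beats
ED, ED&ES beats both, LDA and IMCA modes are strongly correlated, IMCA
recovers variance-only separation where LDA is at chance, and the planted
direction is recovered with |cos| ≥ 0.9.

One documented expectation does **not** hold on synthetic cohorts: the
combined-frame IMCA logistic model does not systematically attain the
lowest deviance of the family — the LDA model usually edges it.  This is a
property of the objectives, not a bug: maximizing the projected-class KL
divergence is not the same functional as minimizing in-sample logistic
deviance of a linear score, and direct experiments across Gaussian,
mixture, heavy-tailed and skewed class structures (both estimators) show
LDA's pooled weighting is essentially deviance-optimal for a single linear
index at these sample sizes.  Clinical reports of IMCA outperforming LDA
on that metric therefore reflect structure in real data that a
Gaussian-mixture generator does not reproduce.  The corresponding
acceptance test states the expectation honestly and is expected to fail;
the orderings listed above all hold.

Passing tests on synthetic cohorts show the implementation is correct and
the planted structure is recovered; they do not show that real infarct
remodeling is a five-factor spheroid process, that real noise is low-rank
smooth, or that real cohorts order the models identically.

## Numerical choices and edge cases

* Pooled scatter singularity in LDA falls back to a ridge
  (ε = 1e-8·tr(Sw)/m) with a warning; identical class means are an error.
* Non-PD covariances are errors in `gaussian_kl`; singular projected
  covariances in `estimate_kl_matrix` suggest a smaller d.
* KDE KL uses leave-one-out self-densities (removing the self-match bias)
  and clamps negative plug-in estimates at zero.
* PCA mode signs are fixed (largest-|loading| entry positive) so runs are
  reproducible; quantiles are type-7 throughout; SDs use n−1.
* Problem sizes in tests and the acceptance script are desk scale
  (P = 242, cohorts of 100–1000 cases); the full-scale configuration
  (P = 1682, n = 2291) is the generator default and runs unchanged.
* Demographic tables compare independent groups with the two-sample
  Wilcoxon rank-sum test (some sources label such comparisons
  "signed-rank"; the paired test does not apply to independent cohorts)
  and Pearson χ² without continuity correction.
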
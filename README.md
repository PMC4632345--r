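# lvremodel

Supervised statistical shape analysis of left-ventricular (LV) remodeling.

After myocardial infarction the left ventricle dilates, becomes more
spherical, its wall thins, and the apex may bulge — changes that predict
morbidity and mortality but that routine clinical indices (mass, volumes,
ejection fraction) capture only crudely. `lvremodel` condenses whole-surface
shape information into a **single standardized remodeling index**: homologous
3-D point sets at end-diastole (ED) and end-systole (ES) are rigidly aligned
by generalized Procrustes analysis (scale preserved), reduced by PCA to the
modes explaining 98.5 % of variance, and projected onto a supervised
discriminant direction obtained either by

* **LDA** — Fisher's direction `w ∝ Sw⁻¹(μ₁ − μ₀)`, optimal for Gaussian
  classes with equal covariances, or
* **IMCA** — *information maximizing component analysis*: the orthonormal
  projection `A = argmax_{AᵀA=I} ‖D_KL(AX₀, AX₁)‖_F`, where `D_KL` is the
  2×2 matrix of Kullback–Leibler divergences between the projected class
  densities (Gaussian or kernel-density estimates). The KL matrix
  approximates the Fisher information distance between the classes, so IMCA
  drops LDA's normality and homoscedasticity assumptions. The optimizer is
  multi-start gradient ascent with QR retraction, always seeded from the
  LDA direction among others.

Indices are evaluated the way cardiology papers evaluate them: logistic
regression against a clinical baseline (sex, age, height, weight, blood
pressures, smoking, diabetes), with deviance / AIC / BIC (`AIC = −2 log L +
2k`, `BIC = −2 log L + k log n`), odds ratios, ROC/AUC, and DeLong
comparisons of correlated AUCs. Mardia's and Box's M tests check the LDA
assumptions themselves; the fitted mode back-projects into shape space to
render the remodeling continuum at index percentiles.

Because clinical shape cohorts are access-controlled, the package ships a
first-class **synthetic LV cohort generator**: two-class populations of
nested truncated-spheroid surfaces with planted effects on size, sphericity,
wall thickness, apical bulge and systolic contraction, heteroscedastic and
bimodal disease-class structure, published-style covariate demographics, and
recorded ground truth (per-case latent factors and the planted discriminant
direction) for parameter-recovery testing.

Audience: researchers in cardiac image analysis / statistical shape
modeling who want a reproducible reference pipeline for supervised
remodeling indices, and methodologists comparing supervised linear
reductions on anatomically structured data.

## Worked example

```r
library(lvremodel)

run <- run_pipeline(pipeline_config(seed = 7))
print(run)
```

```
<lv_run> 140 cases, frames = all, methods = lda+imca
                        model  k  deviance       aic       bic auc_pct
1                    Baseline  9 108.28614 126.28614 152.76092  87.925
2          MASSVOL + Baseline 12  49.86577  73.86577 109.16548  97.350
3      EDVI + ESVI + Baseline 11  61.57656  83.57656 115.93463  96.475
4     ED LDA Score + Baseline 10  38.00909  58.00909  87.42552  98.600
5    ED IMCA Score + Baseline 10  34.82874  54.82874  84.24516  98.925
6     ES LDA Score + Baseline 10  20.28582  40.28582  69.70224  99.550
7    ES IMCA Score + Baseline 10  25.27000  45.27000  74.68643  99.450
8  ED&ES LDA Score + Baseline 10  13.39312  33.39312  62.80954  99.825
9 ED&ES IMCA Score + Baseline 10  12.89681  32.89681  62.31323  99.825
```

Reading the table: every single-index shape model outperforms the clinical
baseline and the mass/volume models on all four measures; ES frames beat ED
frames; the concatenated ED&ES analyses do best (here the ED&ES IMCA row
attains the family minimum deviance 12.90). When discrimination approaches
100 % the suite flags quasi-complete separation in a `separation` column
rather than hiding it. The per-class index summary and the mode correlation
matrix show a single underlying remodeling continuum:

```r
run$score_summary[, c("derivation", "control", "case")]
```

```
  derivation      control        case
1     ED LDA -0.45 ± 0.54 1.14 ± 0.99
2    ED IMCA -0.44 ± 0.49 1.09 ± 1.12
3     ES LDA -0.48 ± 0.48 1.21 ± 0.94
4    ES IMCA -0.46 ± 0.41 1.15 ± 1.11
5  ED&ES LDA -0.49 ± 0.48 1.23 ± 0.91
6 ED&ES IMCA -0.46 ± 0.38 1.15 ± 1.14
```

Group index means are ≈ −0.5 SD for controls and ≈ +1.1–1.2 SD for patients
(pooled standardization: the size-weighted means cancel, and the patient
class is visibly more dispersed — its shape variability is larger), and all
six derived modes correlate at 0.87–0.99 (`round(run$correlations, 2)`):
LDA and IMCA find essentially the same continuum from either frame.
Percentile shapes of the best mode are
exported as CSV/PLY by `export_percentile_shapes(run, out_dir = "shapes/")`;
walking the percentiles shows the ventricle growing, rounding, thinning and
bulging apically.

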
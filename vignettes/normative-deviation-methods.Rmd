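---
title: "Methods: normative modeling of cognitive development and its relation to psychopathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative modeling of cognitive development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Subtle cognitive deficits often accompany — and may precede — emerging mental
illness in youth. Rather than comparing diagnostic groups, this package takes
the growth-charting view: estimate the *normative* trajectory of general
cognitive ability over age 8–21 for each sex, place every individual as a
deviation from that norm, and ask whether individuals who fall below their
expected level carry more psychopathological symptoms or higher polygenic
liability for psychiatric disorders.

The pipeline has six analytic stages, each exposed as ordinary R functions
and orchestrated by `run_pipeline()` / the `normdev` CLI:

1. **General cognition (g).** A battery of 17 performance scores (16 test
   scores plus an achievement test) is cleaned — subjects missing more than 5
   scores excluded, remaining gaps mean-imputed — and decomposed by
   correlation-scale PCA. The first component is the general-cognition
   factor, sign-anchored to the achievement test and standardized.
2. **Normative model.** Gaussian-process regression of g on age and sex under
   10-fold cross-validation. Each subject's deviation is the out-of-sample
   z-statistic `z = (observed − predicted) / predictive SD`.
3. **Symptom components.** 129 ordinal clinical items are nearest-neighbor
   imputed and decomposed into 7 independent components by FastICA with
   Icasso-style restart clustering; the mean of the 7 standardized component
   scores is the general-psychopathology proxy.
4. **Polygenic scores.** SNP-dosage weighted sums at a dense grid of 6002
   GWAS p-value thresholds spanning 5e-8 to 0.5, collapsed to their first
   principal component to avoid choosing a threshold.
5. **Associations.** Bayesian linear regression of z on each predictor
   (adjusting for age and sex) with a Normal(0, 0.5) shrinkage prior on all
   standardized slopes, and Savage-Dickey Bayes factors with the conventional
   evidence ladder.
6. **Risk enrichment.** Subjects are binned into performance deciles; the
   proportion above clinical thresholds (1, 1.5, 2, 3 SD above the cohort
   mean) is tabulated per bin, and the worst-vs-best-bin odds ratio
   `OR = (n_exposed cases × n_unexposed noncases) / (n_exposed noncases ×
   n_unexposed cases)` summarizes the contrast.

# The synthetic cohort: a stated world

The original cohort (a large developmental sample, restricted access) cannot
ship with the package, so `generate_cohort()` produces data with the
statistical structure the analysis assumes, plus the latent truth needed for
parameter-recovery tests.

**Generative model.**

- Ages uniform on 8–21 years; sex Bernoulli with the study's female fraction
  (3377/6481).
- Latent cognition `g = a + b·log(age) + c·sex + ε`. The log-age mean gives
  the decelerating improvement characteristic of developmental growth
  curves; the source analysis reports no functional form, so this is a
  modeling choice, stated once here. Defaults `a = −5.27, b = 2, c = 0.2`
  with residual SD 0.53 were fixed so that (i) the latent mean is ~0 on the
  standardized scale and (ii) age and sex explain roughly 45% of the variance
  of the extracted g out of sample — the level of age/sex dependence the real
  analysis reports (a seeded n = 2000 run of the full cognition + normative
  stages gives EV 0.44, MSLL −0.29, SMSE 0.56). Residual SD may be linear in age (`residual_sd = c(base, slope)`)
  to stress heteroscedasticity; the default is homoscedastic.
- Test scores `t_j = λ_j·g_std + τ_j·e_j` with loadings decaying 0.72→0.40
  and unit total variance, chosen so PC1 explains about a third of the
  battery variance (as reported for the real battery) and the first (anchor)
  test contributes most.
- Seven symptom factors `f_k = s_k·ε_std + sqrt(1−s_k²)·u_k` with `u_k`
  centered exponentials. The skewness matters twice: real symptom-load
  distributions are right-skewed, and non-Gaussianity is what makes the ICA
  identifiable. The effects `s_k` default to the reported association
  magnitudes (0.167, 0.117, 0.133, 0.171, −0.055, −0.015, −0.030 — attention,
  anxiety, norm-violating, psychosis, depression, mania, OCD), under the
  package's single sign convention: **higher z = better than expected
  performance, higher component score = more symptoms**, so domains linked to
  poorer performance carry negative `s_k`.
- 129 ordinal items: each loads 0.8 on one factor (block-sparse), the latent
  item value is cut at the 70% and 90% quantiles into levels 0/1/2 —
  emulating rare symptom endorsement. Missingness is MCAR at configurable
  per-cell rates (defaults 1% cognitive, 2% clinical, inside the ranges the
  real data reports); the real mechanism is unknown, so nothing fancier is
  claimed.
- Genotypes are independent Binomial(2, maf) dosages with a null summary-
  statistics table (betas ~ N(0, 0.1), p ~ U(0,1)). No LD: clumping is out of
  scope, and independent SNPs are all the PRS matrix algebra needs.

**What a green test does and does not establish.** The generator reproduces
the *assumed* structure: monotone growth, one-factor battery, sparse
independent symptom sources, MCAR missingness. Real data add item-response
artifacts, informative missingness, LD, ancestry structure, and
age-heteroscedastic residuals, none of which are claimed. Green tests
establish that the estimators recover the stated world's parameters; they do
not certify the substantive point estimates of any real cohort.

# Numerical choices

**GP kernel and fitting.** `k((a,s),(a',s')) = σ_f²·exp(−(a−a')²/2ℓ²) +
σ_v²·s·s' + σ_n²·δ` with age standardized internally. This is the smallest
kernel giving a smooth age trend plus a sex offset; the hyperparameters
(all positive, optimized as logs) maximize the exact log marginal likelihood
by L-BFGS with analytic gradients from multiple starting points (default 3:
a deterministic moment-based start plus seeded log-uniform draws). A fixed
jitter of 1e-8 stabilizes Cholesky factorization independent of the fitted
noise. For training sets above `max_opt_n` (default 2000) the *optimizer*
sees a seeded subsample — bounding the cubic cost — while prediction always
conditions on the full training set. Cross-validation folds after the first
warm-start from fold 1's optimum (plus the default start); fold optima are
near-identical, and no data cross folds.

**z-scores.** The predictive SD includes the noise variance; dividing by the
latent-function SD alone would overdisperse z badly. Each subject is scored
exactly once, by the model that never saw it (folds are seeded uniform
random; the analysis offers no stratification to copy).

**Fit metrics.** Pooled out of sample: `EV = 1 − SSE/SST` (SST about the
overall mean — a definition choice, not squared correlation), `RMSE`,
`SMSE = MSE/var(y)` (≈1 for a mean predictor), and `MSLL` = mean negative
log predictive density minus that of a Gaussian fitted to the same fold's
training targets, so 0 = trivial predictor and negative = better.

**Bayesian regression.** All variables are standardized; slopes get
independent Normal(0, 0.5²) priors, the intercept a flat prior (it drops out
exactly after centering). The residual SD is the empirical-Bayes maximizer
of the marginal likelihood `y ~ N(0, σ²I + 0.25·XX')`, computed via an SVD
identity; the coefficient posterior is then exact Gaussian algebra. One
departure from the pure plug-in scheme proved necessary: the Savage-Dickey
numerator (posterior density at 0) is computed by 81-point quadrature of the
conditional Gaussian density over the σ posterior (Jeffreys prior on σ),
because the plug-in Gaussian tail under-weights σ uncertainty and can be off
by tens of percent at n = 50 when the coefficient sits 3 SD from zero. The
quadrature is deterministic, costs microseconds, and matches a brute-force
2-D grid-integration oracle to better than 0.1% (see the test suite); the
reported `beta_mean`/`beta_sd`/CI remain the EB Gaussian summaries. With
known σ the plug-in closed form is used unchanged. No multiplicity
correction is applied — the shrinkage prior is the regularizer, and each
predictor is tested in its own model.

**Savage-Dickey.** `BF01 = p(β=0 | y) / p(β=0)`; values below 1 favor the
alternative. The evidence ladder: 0.3–1/1–3 anecdotal, 0.1–0.3/3–10
moderate, 0.03–0.1/10–30 strong, 0.01–0.03/30–100 very strong, beyond that
extreme; exactly 1 is equipoise. Boundary values are assigned to the
less-extreme category.

**ICA.** Items are standardized (an unstated choice in the source analysis;
ordinal items on different prevalence scales make it the defensible one) and
whitened to k = 7 dimensions. FastICA (logcosh, symmetric decorrelation,
tolerance 1e-6) runs from 20 seeded rotations; all 140 estimated components
are clustered by absolute loading correlation (average-linkage), each
cluster's centrotype is kept, and the stability index is mean within-cluster
minus mean out-of-cluster absolute correlation. Fewer than 7 clusters with
stability ≥ 0.5 is an error, not a silent degradation. Components are
sign-flipped so scores correlate positively with their strongly loaded items
(positive = more symptoms); the general-psychopathology proxy averages the
*standardized* component scores (also unstated in the source; standardized
keeps the proxy from being dominated by whichever component happens to have
the largest raw scale).

**kNN imputation.** Donors are restricted to complete rows (which guarantees
every missing cell has a defined donor value); distance is the mean squared
difference over the recipient's observed items, on standardized items, ties
to the lowest row index. k = 1, per "the nearest neighbor value". The
operation is idempotent.

**PRS thresholds.** `seq(5e-8, 0.5, length.out = 6002)`: the exact grid
recipe of the original scoring tool is not recoverable, so the simplest grid
honoring the printed endpoints and count is used, configurable. Columns are
standardized before PCA (otherwise dense-threshold columns dominate by
scale); constant columns (the genome-wide-significant end, when no SNP
passes) are dropped with a message.

**Deciles and odds ratios.** Bin 1 = best performance; with `n mod 10 = r`
the first r bins get the extra subject, which reproduces the modal bin size
648 at n = 6481 (the original's remainder handling is not stated; this is a
reconstruction). Exposure cutoffs use the whole-cohort mean and SD — the
only reading under which "t SD above the mean" is a single cutoff. A zero
denominator yields NA with a warning; the Haldane-Anscombe +0.5 correction
is available behind `correction = TRUE` but off by default.

# Open decisions taken

- Out-of-sample z (per fold) rather than refit-on-all-data z: the only
  choice consistent with detecting individual deviations *under*
  cross-validation.
- Exclusion before imputation in the cognitive cleaning (ordering unstated
  in the source); column means are computed on the post-exclusion sample.
- Correlation-scale (standardized) PCA for the battery: the tests are on
  incommensurate scales.
- Fit metrics are reported on the pipeline's own standardized g scale; the
  scale of the original's RMSE is not recoverable.
- Phenotype is an opaque label for PRS: the module runs once per
  summary-statistics table supplied.

# Limitations

The GP is exact (cubic in fold size): cohorts beyond ~10⁴ subjects need the
`max_opt_n` cap and patience, or an approximate GP outside this package's
scope. Warped/non-Gaussian likelihood normative models, site effects, LD-aware
polygenic scoring, and MCMC posterior diagnostics are deliberately out of
scope. The ICA's k = 7 is taken as given, with no model-order estimation.
Every empirical number quoted in the package documentation is computed by the
test suite or the acceptance script at run time; none are hard-coded
expectations of real-data results.
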
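---
title: "Twin modelling of hair cortisol: models, generator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin modelling of hair cortisol: models, generator, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cortwin` implements a complete twin-study analysis of hair cortisol
concentration (HCC) — a hair-segment measure integrating roughly three
months of hypothalamus–pituitary–adrenal (HPA) axis activity — together
with three psychological phenotypes: perceived stress, depressive symptoms,
and neuroticism. This vignette is the package's own account of the methods:
the statistical models and their assumptions, what the synthetic cohort
generator does and does not emulate, and every numerical choice a
maintainer might want to revisit.

## The classical twin design

Monozygotic (MZ) co-twins share all additive genetic influences; dizygotic
(DZ) co-twins share them half, on average, under the standard additive
model. Both kinds share their family environment. Comparing MZ and DZ
within-pair resemblance therefore decomposes phenotypic variance into
additive genetic (A), shared environmental (C), and unique environmental
(E, which absorbs measurement error) components. The package's DZ (and
sibling) A-sharing coefficient is fixed at 0.5 throughout.

### Multivariate Cholesky parameterization

For $p$ traits the A, C and E covariance contributions are parameterized as
products of lower-triangular path matrices, $A = XX'$, $C = YY'$,
$E = ZZ'$, which keeps every implied component matrix positive
semidefinite. Trait order matters for interpreting the triangular paths
(each factor loads only on its own trait and later ones); the package's
convention places perceived stress first, then depressive symptoms,
neuroticism, and HCC last, so the last diagonal entry captures genetic
variance in HCC *independent* of the psychological traits.

The expected covariance of a twin pair stacks the within-person covariance
$\Sigma = A + C + E$ on the diagonal blocks, with cross-twin blocks
$A + C$ (MZ) or $0.5A + C$ (DZ). Singleton records (unpaired twins,
triplet-derived singletons, extra siblings) contribute the $p$-variate
within-person block. By default singletons enter the likelihood as
independent records — they still sharpen means and variances, which is the
point of full-information estimation — and an optional
`sibling_mode = "dz_like"` keeps whole families together with 0.5
A-relatedness between all non-MZ members. The default follows the usual
reading of "all data points including unpaired twins and singletons"; the
alternative matches the generator's ground truth, and the package supports
both because the distinction is not settled by the design itself.

### Full-information maximum likelihood

Each likelihood unit contributes the multivariate-normal deviance of its
*observed* entries (`neg2ll_fiml()`):
$k\log 2\pi + \log\lvert\Sigma_{obs}\rvert +
(y-\mu)'\Sigma_{obs}^{-1}(y-\mu)$, so missing traits marginalize out by
subsetting. Means are modelled inside the likelihood (not pre-residualized)
on intercept, sex (0/1), centered age, age$^2$, sex$\times$age and
sex$\times$age$^2$ per trait — the curvilinear, sex-specific age trends one
expects across adolescence. Age is centered at the sample mean purely for
conditioning.

`fit_model()` minimizes the deviance over the path parameters with
L-BFGS-B. Two numerical choices matter:

* **Sign indeterminacy.** $XX'$ is invariant to column sign flips; the
  Cholesky diagonals are constrained $\ge 0$, which selects one
  representative. A variance component at zero therefore sits on the
  boundary of the parameter space.
* **Concentration of the mean model.** For fixed covariance parameters the
  mean coefficients are a GLS problem with a closed-form solution, so they
  are solved exactly at every objective evaluation rather than searched.
  This shrinks, e.g., the four-trait AE search from 44 to 20 dimensions and
  changes nothing about the optimum (the concentrated criterion equals
  `neg2ll_fiml()` at the solved coefficients, a property the tests check to
  machine precision).

Starting points: a moment estimator (within-person and cross-twin residual
covariance matrices solved for A/C/E the classic way, projected onto the
positive-definite cone and Cholesky-factored) followed by diagonal starts
at fractions (balanced, A-heavy, E-heavy, AC-heavy) of the observed
residual SDs; five starts in total by default. Convergence tolerances:
`factr = 4.5e4` (about $10^{-8}$ absolute on the deviance scale) and
gradient tolerance $10^{-6}$. A line-search failure whose restart cannot
improve the criterion by more than $10^{-6}$ is treated as converged — this
is the familiar L-BFGS-B "code 52 at the optimum" behaviour. All starts'
endpoints are kept in the fit's `start_log`.

### Model selection, standardization, intervals

AE and CE sub-models are compared with the ACE model by likelihood-ratio
chi-square (`compare_lrt()`), with degrees of freedom equal to the
difference in free parameter counts — dropping the C factor of a 4-variate
model removes its $4(4+1)/2 = 10$ paths. Variance components at zero lie on
the boundary, so the nominal chi-square reference is conservative; the
plain chi-square is what is implemented, consistent with how such tests are
conventionally reported.

`standardize()` converts squared paths to percentages of each trait's total
model variance (rows sum to 100% before rounding); per-trait heritability
is the A-row sum. `component_correlations()` forms
$r_{A,jk} = A_{jk}/\sqrt{A_{jj}A_{kk}}$ and likewise for C, E, and the
phenotypic correlation.

Interval estimation uses profile likelihood where the profile is
one-dimensional and cheap: free path parameters, the univariate-model
heritability (by fixing the A share and re-optimizing the total variance),
and the twin correlations. Bounds solve
$-2\ln L(\theta) = -2\ln L_{\min} + \chi^2_1(0.95)$; a bound that runs into
the boundary is reported at the boundary and flagged one-sided. Derived
quantities of multivariate fits (multivariate heritabilities, genetic
correlations) use a family-resampling bootstrap (`bootstrap_ci()`), and
every interval records which method produced it.

### Twin correlations and the median split

`twin_correlations()` estimates the within-pair correlation per zygosity by
maximum likelihood under an exchangeable bivariate normal: common
covariate-adjusted means and a common variance across twin order. For fixed
$r$ the means and variance profile out by GLS on whitened pairs, leaving a
one-dimensional profile in $r$; with no covariates the estimate reduces
exactly to the double-entry intraclass correlation. This estimator carries
the usual small downward finite-sample bias (order $10^{-2}$ at a hundred
pairs), which the recovery simulations quantify. Two-year stability is a
plain Pearson correlation on the retest subsample. The median age split
assigns *whole families* by family mean age relative to the cohort median
(no family straddles the halves; the assignment rule is a package choice,
as nothing in the design fixes it) and reruns the chosen Cholesky model per
half.

## Phenotype preparation

* **HCC**: raw pg/mg values are log10-transformed after adding the smallest
  measurable value (default offset 0.1 pg/mg, configurable or derivable as
  the minimum positive observation); winsorized at mean ± 3 SD computed on
  the time-1 log values, outliers included in the SD (the same bounds clip
  time-2 values); and residualized by OLS on dummy-coded batch, storage
  group, assay month and study phase, with one pooled regression across
  time points (shared coefficients). Residualizing per time point
  separately is the documented alternative; pooled coefficients keep the
  two time points on one scale. `covariate_screen()` reports, per factor,
  the residual-variance increase when it is dropped from the full joint
  model — convention $(\mathrm{Var}_{reduced} -
  \mathrm{Var}_{full})/\mathrm{Var}_{full}\times 100$ with mean-squared
  residuals — plus the partial F-test.
* **Stress and depressive symptoms**: Samejima's graded response model
  (GRM, logistic link), the standard IRT family for ordered symptom items.
  Calibration is marginal maximum likelihood via EM over fixed
  Gauss–Hermite quadrature with the latent trait fixed standard normal.
  The two stress instruments (a child/adolescent scale below age 16, an
  adult scale from 16) are calibrated *concurrently*: one latent scale, all
  items, with the 16–19-year-olds who completed both instruments anchoring
  the common metric — a zero-overlap request is an error. Persons are
  scored by expected a posteriori (EAP) under the standard-normal prior;
  time-2 responses are scored with the time-1 calibration (no separate
  linking across occasions). Items may be polytomous or dichotomized;
  empty categories are collapsed with a warning.
* **Neuroticism**: per-instrument sum scores z-standardized within
  instrument and concatenated (`z_combine()`); time-2 sums reuse the time-1
  centers and scales.

Numerical defaults: 61 Gauss–Hermite nodes, EM tolerance $10^{-5}$ on the
marginal log-likelihood, at most 500 iterations (non-convergence is an
error carrying the likelihood trace). The pipeline entry point
(`run_study()`) uses 31 nodes and $10^{-4}$, which changes scores by far
less than their posterior SD; tests use 11–21 nodes on the same grounds.
Item M-steps run BFGS on log-discrimination and log-threshold-gaps, which
enforces $a > 0$ and strictly increasing thresholds.

## The polygenic-score pipeline

Genotype QC drops persons then variants below 95% call rate, variants with
minor allele frequency below 1%, and variants failing a Hardy–Weinberg
*exact* test (full enumeration of heterozygote counts) at $p < 10^{-6}$;
HWE uses one person per family to avoid relatedness inflation. Discovery
effect sizes are aligned to the target's counted (ALT) allele with sign
flips for swapped alleles, complement resolution for strand flips, and
removal of strand-ambiguous A/T and C/G variants. LD clumping is the greedy
procedure: visit variants by ascending p (ties: chromosome, position, id)
and keep those whose squared dosage correlation with every kept variant
within 500 kb is at most 0.1 — conventional defaults, configurable, since
the procedure's source does not print values. Scores at the eight nested
thresholds (5e-8, 1e-5, 0.001, 0.01, 0.05, 0.1, 0.5, 1.0) sum beta-weighted
dosages, imputing missing dosages to twice the target allele frequency, and
are z-standardized per threshold by default (the association tests are
invariant to this, but standardized effect sizes are easier to read).

Association uses a two-variance-component linear mixed model,
$y = W\gamma + s\beta + g + \varepsilon$ with
$g \sim N(0, \sigma^2_g K)$ for the pedigree relatedness matrix $K$ (1 for
MZ pairs, 0.5 for DZ/siblings), fitted by REML in the eigenbasis of $K$ —
the cohort is small, so one eigendecomposition reduces the variance-ratio
profile to a cheap one-dimensional optimization (an average-information
scheme would be the fallback at larger scale). Covariates: sex, age,
age$^2$, interactions, five ancestry PCs (axes estimated on one seeded
member per family, all persons projected, orientation fixed by the
largest-magnitude loading), and genotyping wave, mirroring an imputation
batch covariate. The PRS test reports a *one-sided* p for the hypothesis of
positive association and a signed incremental $R^2$:
$\mathrm{sign}(\beta)(R^2_{full}-R^2_{null})$ computed on the GLS-whitened
scale with the variance ratio held at the full-model fit.

## What the generator emulates — and what it does not

The generator's defaults are the study conditions the package targets, set
once and documented here:

* **Cohort**: 116 MZ pairs, 173 ordinary DZ pairs, 14 triplet sets (each a
  DZ pair plus a singleton in the same family) and 51 extra siblings — 671
  persons in 303 families; ~62% female (Bernoulli per person, MZ co-twins
  share sex); ages truncated-normal (mean 14.5, SD 2.4, range 10.1–31.1
  years), co-twins and triplet members sharing the family age; 146/671
  retested two years later; all 16–19-year-olds complete both stress
  scales (the emulated overlap group of ~168 is essentially everyone in
  that age band).
* **Trait structure**: a four-trait AE truth whose standardized paths are
  the square roots of the fitted standardized components the package's
  acceptance checks reconstruct (C = 0), scaled to observed units by trait
  SDs 0.58, 0.92, 1.01, and 0.42 — the last being the log10-scale HCC SD
  implied by a winsorization bound of 64.7 pg/mg at mean + 3 SD with
  log-mean 0.55, which also reproduces a raw HCC mean near 5–6 pg/mg.
  Deviation stabilities 0.61/0.51/0.58/0.32 generate the two-year retest
  correlations.
* **Assay effects**, additive on the log10 scale: 35 batches (SD 0.10), 5
  storage groups (linear decline, amplitude 0.08 — older samples lose
  cortisol), 12 months (sinusoid, amplitude 0.115, peak March, trough
  September), 6 study phases (SD 0.105). The scales are calibrated to
  drop-one residual-variance increases of roughly 6/2/4/6 percent, making
  all four factors clearly significant at n = 671.
* **Items**: graded-response banks (30 four-category child stress items, 10
  five-category adult stress items, 34 three-category depressive-symptom
  items, 20 binary junior neuroticism items, 12 five-category adult
  neuroticism items), log-normal(0, 0.3) discriminations, equally spaced
  jittered thresholds; whole-instrument missingness at 1/671 (stress),
  55/671 (depressive symptoms), 51/671 (neuroticism).
* **Genotypes**: founder haplotypes per family transmitted Mendelian-style
  (MZ co-twins receive identical gametes), optional block LD via a Markov
  copying process with per-block recombination; causal variants feed the A
  factor of mapped traits (defaults: depressive symptoms 0.10, neuroticism
  0.10, HCC 0.05 of A variance from the measured causal sets — a weak
  cortisol-score/HCC link and clear psychological-trait links, matching the
  qualitative pattern the association sweep is meant to display); discovery
  summary statistics by per-variant marginal regression in an independent
  simulated population.

Not emulated, deliberately: genotyping intensity data and imputation
uncertainty (genotypes are generated clean; the "wave" label stands in for
an imputation-batch covariate), realistic genome-wide LD (block LD
suffices to exercise clumping), X-chromosome inheritance, assay chemistry,
hair-growth physiology, age-varying heritability (the split-half tests
construct it directly instead), and selection or attrition. Passing tests
therefore demonstrate correctness of the estimators under the stated
statistical structure — multivariate normality of liabilities, additive
genetics, category-valid item responses — not robustness to the
violations real cohorts bring (floor effects in symptom items,
non-normal HCC residuals, informative missingness).

Reproducibility: every stochastic component draws from a sub-stream seed
derived as `(seed * 1000003 + label_hash) mod (2^31 - 1)` from one global
seed (`substream_seed()`), so a single integer reproduces cohort,
genotypes, items and all downstream tables; report rendering is
deterministic and byte-identical across reruns.

## Problem sizes used by the tests

The test suite runs the estimators at sizes chosen to make each check
informative while keeping the suite fast: parameter-recovery of the
univariate AE model at the study's 115 + 183 pairs (20 replicates in the
unit tests; 200 replicates in the acceptance checks); twin-correlation
recovery at 500 replicates; profile-interval coverage at 300 replicates
with an a-priori acceptance band of 0.95 ± 0.035; the four-trait AE
recovery at one doubled cohort with intercept-only means, checking a median
absolute standardized-component error under 3 percentage points; IRT
recovery at n = 3000 with 30 items and 21 quadrature nodes; and type-I
calibration of the one-sided mixed-model test at 1000 replicates of a
60-family cohort. The end-to-end orchestration test uses a ~200-person
cohort with 300 variants.

## Known limitations

* Boundary LRTs use the plain chi-square (conservative for variance
  components at zero).
* Profile intervals for derived multivariate quantities are bootstrap-based
  rather than constrained-reparameterization profiles.
* The ML twin correlation inherits the double-entry ICC's small-sample
  downward bias (about 0.005–0.008 at the study's pair counts), visible in
  the recovery means.
* The REML mixed model fits exactly two variance components; multiple
  random effects (e.g. dominance) are out of scope.
* IRT calibration assumes local independence and a standard-normal latent
  distribution; differential item functioning across age groups is not
  modelled.
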
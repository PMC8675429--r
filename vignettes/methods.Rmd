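---
title: "Methods: lifespan trajectories and normative centiles of subcortical volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifespan trajectories and normative centiles of subcortical volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifespanvol)
```

# Overview

`lifespanvol` implements a complete cross-sectional analysis of age effects
on subcortical brain volumes pooled over many MRI acquisition sites: quality
control and intracranial-volume (ICV) adjustment, empirical-Bayes site
harmonization, fractional-polynomial (FP) trajectory estimation with formal
model selection, age-band inter-individual variability analysis, and LMS
normative centile curves. Eight structures are analyzed per hemisphere —
lateral ventricle, thalamus, caudate, putamen, pallidum, nucleus accumbens,
hippocampus and amygdala — giving 16 region-hemisphere series.

Because individual-level multi-site volume tables of this kind are
restricted-access, the package ships a synthetic cohort generator whose
site structure follows a bundled table of 88 real sample descriptors
(sizes, age means/SDs/ranges, sex counts; total N = 18,605). Every stage is
exercised end to end against this generator, whose ground truth is known
exactly.

# The synthetic cohort generator

For participant $j$ at site $i$ (age $a$, sex $s$, intracranial volume
$\mathrm{ICV}_j$), the observed volume of region $r$ in one hemisphere is

$$v = \delta_{ir}\left\{m_r(a, s) + b\,(\mathrm{ICV}_j - \overline{\mathrm{ICV}}) + e\right\} + \gamma_{ir},$$

with additive site offsets $\gamma_{ir} \sim N(0, \tau^2)$, multiplicative
site factors $\delta_{ir} \sim U(0.9, 1.1)$, ICV coupling slope $b$
(default 0.002 mm³ per mm³), and Gaussian noise $e$ whose left/right pair is
correlated at 0.8 (hemispheric volumes are strongly correlated
empirically). The multiplicative site effect is applied after the ICV
coupling so the location–scale model assumed by ComBat matches the
generator exactly. A small fraction of rows (0.5%) has all 16 volumes
displaced by six noise SDs, emulating segmentation failures that survive
visual QC.

Mean trajectories $m_r$ are piecewise linear, in three archetypes chosen
for exact testability:

* **early peak + decline** (caudate, putamen, pallidum, accumbens): rise to
  a peak at age 8, then linear decline;
* **flattened inverted U** (thalamus, hippocampus, amygdala): rise to age
  25, plateau, then linear decline after a structure-specific plateau end
  (55–60 years);
* **monotonic increase** (lateral ventricles): linear growth across life.

Sex enters additively with a sum-to-zero ±1/2 coding, so the reference
curve is the cross-sex mean.

**Noise calibration.** Residual SDs are fixed so that the fraction of
variance explained by age under the reference age distribution matches the
range reported for real pooled lifespan data — smallest for the amygdala
(≈7%) and largest for the lateral ventricles (≈38%) — with intermediate
values for the other structures (e.g. putamen ≈0.30, thalamus ≈0.15,
hippocampus ≈0.12). For the heteroscedastic regions (ventricles,
hippocampus, amygdala) the noise SD grows linearly with age, roughly
doubling from age 3 to 90.

What the generator does **not** emulate: longitudinal (within-person)
structure, FreeSurfer segmentation artifacts, scanner-specific
nonlinearity beyond location/scale, age×sex interactions, and skewed
(non-Gaussian) residuals. Passing tests therefore demonstrate the
correctness and calibration of the pipeline under its own statistical
assumptions, not its behavior on every real-data pathology.

# Quality control and ICV adjustment

Only complete cases (age, sex, ICV, all 16 volumes) are analyzed.
Multivariate outliers are then removed by the squared Mahalanobis distance
of each 16-volume vector from the pooled mean and covariance, with a
chi-square threshold at tail probability $\alpha = 0.001$ (df = 16). The
cut-off and the variable set are configurable (per-site distances
optional), because conventions differ across consortia; a small ridge
($10^{-6}\,\mathrm{tr}(S)/16$) keeps the covariance invertible.

ICV adjustment uses the covariance-approach formula, per site and per
region-hemisphere:

$$\text{adjusted} = \text{raw} - b\,(\mathrm{ICV} - \overline{\mathrm{ICV}}_{\text{site}}),$$

where $b$ is the within-site OLS slope of the volume on ICV. By
construction the adjusted volumes are exactly orthogonal to ICV within
site and keep their within-site means. Sites with fewer than 10 complete
rows inherit the pooled slope (recentered at their own mean ICV) — a
within-site slope from a handful of points is noisier than the pooled one.
A pipeline flag skips this stage entirely for ICV-unadjusted sensitivity
runs, whose outputs are name-tagged.

# Site harmonization (parametric ComBat)

Volumes are harmonized across sites with the standard parametric
empirical-Bayes location–scale model: feature-wise standardization from a
pooled OLS fit on batch indicators (size-weighted, sum-to-zero) plus the
biological design; method-of-moments hyperpriors across the 16 features
(normal for location, inverse-gamma for scale); iterative conditional
posterior updates until the largest relative parameter change falls below
$10^{-4}$ (cap 100 iterations — standard reference values). The in-package
implementation agrees with the `sva` reference implementation to ~1e-6 on
shared inputs (verified in the test suite) while exposing the fit/apply
split, hyperparameters and iteration trace needed for auditable pipelines.

The preserved design is an intercept, the ±1/2 sex contrast, and a cubic
polynomial in age centered at 45 years and scaled by 1/45. A cubic is
flexible enough not to bend lifespan trajectories while keeping the
standardization linear; the basis is configurable, as is per-hemisphere
harmonization (default: all 16 features jointly). A single-site table
passes through with a warning so single-site and sensitivity paths remain
runnable.

# Fractional-polynomial trajectories

Each region-hemisphere volume is regressed on an FP basis of age/10
(the usual preliminary scaling), powers drawn from
$\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ with 0 meaning $\ln$, repeated powers
multiplying by $\ln x$. Models include the sex contrast, so the intercept
is the cross-sex mean at the age origin. Standard errors are adjusted for
site clustering with the cluster-robust sandwich estimator (degenerating
to heteroscedasticity-robust SEs, with a warning, when only one site is
present).

Model selection is a closed test from the highest degree down: best FP3 vs
best FP2 by a chi-square likelihood-ratio test with 2 df per degree step
(power + coefficient, the standard FP df convention); if not significant,
FP2 vs FP1; then best FP1 against the straight line by a partial F-test
with 1 numerator df (the chosen power treated as fixed); finally the line
against the sex-only null. The cut-off is the strict $\alpha = 0.01$ to
avoid over-fitting at densely sampled ages, configurable, and the full
selection trace (statistics, df, p-values, decisions) is stored so
alternative read-offs can be audited. Gaussian deviance
($n\log(\mathrm{RSS}/n)$ + constant) underlies the LRT, appropriate for
continuous volumes fitted by OLS. Degenerate inputs (near-zero residual
variance, collinear bases from degenerate age distributions) raise
informative errors rather than spurious selections.

Supplementary analyses mirror the main fit: sex-stratified FP selection
(sex column dropped; a sex below 50 rows is skipped with a warning) and
Pearson correlations between volume and age within the early (6–29),
middle (30–59) and late-life (60–90) bands, pooled and by sex. Band
membership uses completed years (`floor(age)`) since the band limits are
whole years.

# Inter-individual variability

Residuals from the selected pooled-sex FP model of each structure are
summarized per band as $\ln(\sum_i e_i^2 / n_t)$ — the log mean squared
residual. Band variances are compared with a Brown–Forsythe
(median-centered Levene) omnibus test, chosen over Bartlett for robustness
to non-normal residuals (Bartlett remains available behind a flag). With
16 structures tested, the Bonferroni-corrected threshold is
$0.05/16 = 0.003125$ (0.003 at three decimals). Ages 3–5 fall outside all
bands; such rows are excluded from band analyses only and counted in the
report.

The complementary meta-analytic view computes each site's SD of the
adjusted volume within each band and pools $\ln \mathrm{SD}$ across sites
by DerSimonian–Laird random effects, using the small-sample estimator
$y_i = \ln s_i + \tfrac{1}{2(n_i-1)}$ with sampling variance
$\tfrac{1}{2(n_i-1)}$ (the bias term is toggleable). Sites with $n < 2$ or
$s \le 0$ are dropped with a warning; a band needs two usable sites.

# LMS normative centiles

Centile curves per structure × hemisphere × sex use the LMS (Box-Cox
Cole–Green) model: a Box-Cox power $\lambda$, median-type location
$\mu(\mathrm{age})$ and coefficient of variation $\sigma(\mathrm{age})$,
with $z = ((y/\mu)^\lambda - 1)/(\lambda\sigma)$ (the $\ln$ branch at
$\lambda = 0$; computed with `expm1`, continuous through 0). $\ln\mu$ and
$\ln\sigma$ are natural-spline expansions in age with df on a grid
(defaults: 3–6 for $\mu$, 2–4 for $\sigma$), $\lambda$ an age-constant
scalar — a scalar stabilizes the small-df regime and matches common LMS
practice (a linear-in-age $\lambda$ would be a straightforward extension).
Each candidate is fitted by BFGS maximum likelihood with analytic
gradients; the returned model minimizes
$\mathrm{GAIC} = -2\ell + k\cdot\mathrm{edf}$ with $k = 3$ (between AIC's 2
and BIC's $\ln n$; the penalty is configurable since published analyses
rarely state it). With unpenalized bases the effective degrees of freedom
equal the parameter counts, so the df grid plays the role of smoothness
selection.

Numerical safeguards: the positivity truncation term of the BCCG density
is omitted (standard LMS practice, negligible for $\sigma \ll 1$); the
optimizer is constrained to the region where $1 + \lambda\sigma z > 0$
across the 0.5th–99.5th centile span, so every requested centile in that
range is defined even for high-CV strata such as young ventricles; and
candidates that fail to converge are rejected, with an error only if the
whole grid fails. Centile levels default to {5, 25, 50, 75, 95} and are
configuration-driven. Querying a model outside its fitted age range is an
error unless extrapolation is explicitly allowed.

These curves are methodological reference outputs for synthetic and pooled
research data; they are not clinical normative values.

# Pipeline, reproducibility and problem sizes

`run_pipeline()` executes: simulate-or-read → complete-case filter →
Mahalanobis exclusion → ICV adjustment (optional) → ComBat → FP selection
for the 16 series (+ sex-stratified fits and band correlations) → 16
variance reports and per-band meta-analyses → 32 LMS strata, writing
delimited tables, JSON model dumps and a manifest (config hash, seed,
versions, artifact list). All randomness derives from one root seed via
named stage substreams; the same configuration and seed reproduce every
number bit-identically.

The bundled demonstration cohort scales the 88 reference sites to ≈12,000
participants, a size at which the full pipeline completes in about a
minute on a single CPU while the age range and site diversity of the full
compilation are preserved. Simulation-based tests use 1,000–10,000 rows
(10,000 where calibration bounds are asserted; e.g. Brown–Forsythe type-I
rates over 1,000 replicates, centile coverage at n = 10,000, FP selection
consistency over 50 seeds at n = 2,000).

# Known limitations

* FP curves are global smooth functions: piecewise-linear truths with
  sharp plateaus are approximated, not reproduced; the fitted-vs-true
  curve correlation for flat inverted-U shapes plateaus near 0.99 even at
  negligible noise.
* The closed-test selection controls over-fitting, so at realistic
  signal-to-noise it may prefer degree 2 where the generating mechanism
  has three segments — by design.
* Parametric ComBat harmonizes location and scale only; covariance
  differences between sites are untouched, and there is no longitudinal
  variant.
* The BCCG family models skewness only; kurtosis extensions (BCT/BCPE)
  are out of scope.
* Band analyses use fixed age groups; no continuous variance-trajectory
  (location-scale regression) model is provided.
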
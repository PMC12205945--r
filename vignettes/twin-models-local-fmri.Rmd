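---
title: "Twin modelling of local resting-state fMRI metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin modelling of local resting-state fMRI metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinlocal)
```

## The scientific problem

Resting-state fMRI yields two widely used voxelwise summaries of *local*
brain function: regional homogeneity (ReHo), the temporal coherence of a
voxel with its 26 neighbors, and the fractional amplitude of low-frequency
fluctuations (fALFF), the share of a voxel's spectral amplitude that lies
in the canonical 0.01–0.08 Hz band. In a longitudinal twin cohort these
regional measures can be decomposed into additive genetic (A), common
environment (C) and unique environment plus error (E) sources, and — with
two measurement waves — into influences that *continue* from the first
wave versus influences that are *new* at the second.

`twinlocal` implements that full chain: image-level metric computation
with motion quality control, saturated and bivariate Cholesky twin models
fitted by full-information maximum likelihood (FIML), likelihood-ratio
tests and AIC selection, profile-likelihood confidence intervals, latent
genetic/environmental correlations, mixed-model brain–behavior screens,
and Benjamini–Hochberg FDR control — together with a synthetic-data
generator with known ground truth so every stage is testable without any
external download.

## The model

For one trait measured at waves 1 and 2, each source X in {A, C, E} has a
lower-triangular path matrix

$$L_X = \begin{pmatrix} x_{11} & 0 \\ x_{21} & x_{22} \end{pmatrix},$$

so the within-twin covariance is $\Sigma_W = L_A L_A' + L_C L_C' + L_E
L_E'$ and the cross-twin covariance is $k\,L_A L_A' + L_C L_C'$ with $k =
1$ for MZ and $0.5$ for DZ pairs (C fully shared, E unshared). The
Cholesky form guarantees a positive semi-definite implied covariance for
any real paths; we remove the reflection indeterminacy by reporting
solutions with $x_{11} \ge 0$ and $x_{22} \ge 0$.

Squared paths are variances: wave-1 heritability is
$a_{11}^2 / (a_{11}^2 + c_{11}^2 + e_{11}^2)$; at wave 2 the genetic
variance splits into a continuing part $a_{21}^2$ (carried by the wave-1
factor) and a new part $a_{22}^2$. Two 1-df likelihood-ratio tests probe
the longitudinal structure: fixing $a_{22} = 0$ tests for *new* genetic
influences at wave 2, and equating $a_{21} = a_{11}$ tests whether the
continuing influence changed in strength (with $a_{21} < a_{11}$ reported
as deamplification). The same tests exist for C. When the two "waves"
slots instead hold two different traits from the same wave, the latent
correlation $r_X = x_{21} / \sqrt{x_{21}^2 + x_{22}^2}$ measures the
overlap of the sources driving the two traits — 1 means one shared set of
influences, 0 means independent ones.

Covariates (age in years, sex coded 0/1, mean framewise displacement in
mm) enter the *means model* — each wave's expectation is
$\mu_w + \beta_w' x$ — fitted jointly with the covariance parameters,
rather than being regressed out beforehand; betas are shared across
co-twins and zygosity groups. Age and FD are wave-specific.

### FIML and missingness

Families contribute the multivariate-normal density of whatever subset of
the four slots (twin 1/2 by wave 1/2) they were observed on. This makes
unpaired twins and families who missed wave 2 informative for means and
variances, which matters at realistic cohort sizes. Internally, families
are grouped by (zygosity, missingness pattern); with no covariates each
group collapses to its sufficient statistics (mean and divide-by-n
scatter), which makes the deviance evaluation independent of sample size,
and with covariates a compiled kernel evaluates the row-wise densities.
Analytic gradients are supplied for both paths.

### Saturated models and assumption checks

The saturated model estimates 4 means and a full 4x4 covariance per
zygosity group. The covariance is parameterized as $D R D$ with log
standard deviations in $D$ and a correlation matrix $R$ built from
hyperspherical angles, so equality constraints on means or variances
across birth order or zygosity — the classical twin-design assumption
tests — are plain parameter-sharing constraints while $R$ stays positive
definite. Twin correlations are read off the covariate-adjusted saturated
MLE, with Fisher-z delta-method intervals. Covariate likelihood-ratio
tests drop both waves' betas for one covariate (2 df); they only report —
covariates are always carried forward.

### Estimation and numerical choices

* Optimizer: BFGS with moment-based starting values (Falconer-style
  decomposition of cross-twin covariances; pooled regressions for betas)
  and 5 jittered restarts by default. All restarts run at a coarse
  relative tolerance (1e-8) and the best solution is polished at 1e-10
  (1e-12 for saturated fits, whose moment starts are essentially exact on
  complete data). Restart jitter comes from a private RNG stream so fits
  never disturb the caller's seed.
* Non-positive-definite proposals are answered with a large penalized
  deviance rather than an error, keeping line searches inside bounds.
* Likelihood-ratio p-values use the standard chi-square reference with df
  = number of constraints. For the $a_{22} = 0$ test the null pins a
  variance to the boundary of its parameter space, making the standard
  reference conservative; `mixture_null = TRUE` applies the 50:50
  $\chi^2_0{:}\chi^2_1$ mixture for sensitivity analysis.
* Model selection minimizes AIC = deviance + 2 (free parameters), breaks
  ties toward fewer parameters, and flags selections whose runner-up is
  within 2 AIC units.
* Profile CIs invert the likelihood-ratio test: a bound is the value of
  the quantity at which the constrained deviance (all other parameters
  re-optimized) rises by $\chi^2_1(0.95) = 3.84$. Standardized
  proportions, raw variances and latent correlations are pinned by exact
  reparameterizations (for example, fixing the wave-2 A share at $v$
  rewrites $(a_{21}, a_{22})$ in polar form with the radius implied by
  $v$ and the other sources' paths). Bounds are bracketed outward from
  the estimate with warm-started refits and found by root bisection to
  about 3 decimal places; a bound that reaches the edge of the parameter
  space (a proportion hitting 0 or 1) is reported at the edge, and a
  failed profile falls back to a Wald interval with a warning. The
  phenotypic correlation is Wald-only.

## Local metrics

The image chain mirrors standard resting-state practice: Power-style
framewise displacement (translation deltas plus 50 mm-projected rotation
deltas; first volume 0), Friston-24 nuisance regression (optionally with
extra tissue regressors), linear detrending, FD scrubbing (default
threshold 0.5 mm, censoring 1 volume back and 2 forward, censored volumes
removed), then: ideal DFT bandpass (0.01–0.08 Hz inclusive, DC removed)
before ReHo; no bandpass before fALFF. Acquisition-level exclusion uses
mean FD > 0.3 mm (strict inequality), taking the worse of the AP and PA
runs; mean FD is computed before scrubbing over all retained volumes.

ReHo is Kendall's W over the 3x3x3 neighborhood with midranks for ties
and, by default, no tie-correction term in the denominator (the common
neuroimaging convention; a `tie_correction` switch implements the
corrected denominator). fALFF is the ratio of amplitude-spectrum mass
(square-rooted periodogram; a `mode = "power"` switch uses raw power) in
0.01–0.08 Hz to the mass in (0, 0.25] Hz. Maps are Z-standardized with
the population (divide-by-n) SD within the mask, then smoothed with a
6-mm FWHM separable Gaussian whose weights are renormalized over the
in-mask support, then averaged within atlas ROIs, and the AP/PA vectors
averaged (a missing run excludes the subject under the default policy).
After scrubbing, spectra are computed on the surviving volumes at the
nominal TR spacing — the conventional approximation.

## What the generator emulates — and what it does not

`simulate_twin_cohort` draws latent A factors with cross-twin correlation
1 (MZ) / 0.5 (DZ), fully shared C and independent E, maps them through
the true paths, and adds covariate effects. Defaults mirror an
early-adolescent twin imaging study: 56 MZ and 49 DZ families, baseline
age 11.5 ± 1.2 years shared within pair with a 1.7-year wave gap, sex
drawn independently per individual, mean FD from a gamma distribution
with mean 0.15 mm and SD 0.05 mm (right-skewed, essentially all passing
the 0.3 mm gate), a 0.08-phenotype-unit shift per 1-SD of FD
(beta 0.8 per mm), small age and sex effects, 28% family-level wave-2
attrition and 10% unpaired twins (one co-twin's phenotypes removed,
record retained). These are the package's study conditions; recovery
tests use larger cohorts because the estimator's sampling error at ~100
families is far larger than any tolerance worth asserting.

`simulate_fmri_run` builds each ROI's voxel series as
$\sqrt{w}\,s_{\text{ROI}} + \sqrt{1-w}\,\varepsilon$ so the pairwise
voxel correlation equals the coherence target $w$, with both components
synthesized in the DFT domain (random phases; flat amplitude inside the
0.01–0.08 Hz band and a second level outside it up to 0.25 Hz) so the
expected in-band amplitude fraction matches the fALFF target. Motion
parameters are random walks. A coherence of 1 with no noise is flagged as
degenerate (every voxel identical; ranks tie everywhere).

The generator does not attempt anatomy, physiological noise, scanner
drift, susceptibility artifacts or spatial normalization; passing tests
demonstrate that the estimators recover the generative quantities they
target, not that real acquisitions satisfy the generative assumptions.
The demonstration pipeline maps latent phenotypes through a logistic link
to per-subject coherence/band-fraction targets, so the *measured* ReHo
and fALFF inherit twin structure through a monotone nonlinearity plus
measurement noise — deliberately harder than feeding the model its own
phenotypes, and a reason demo-scale heritability estimates are attenuated
relative to the latent truth.

## The pipeline

`run_pipeline` chains simulate, metrics, twin, assoc, report. Every
random draw flows from one master seed through
`stage_seed(seed, k) = (7919 seed + k) mod (2^31 - 1)`; the same
configuration and seed reproduce byte-identical result tables. BH-FDR is
applied within each of four separate families — covariate effects,
assumption tests, new-influence/amplification tests, and behavioral
associations — never across. The default configuration (16 + 16
families, 2-ROI atlas on a 20 x 20 x 12 grid, 64 volumes per run) is
sized for demonstration and continuous testing; the test suite's
replication studies use 2000 pairs per zygosity for parameter recovery,
calibration and power checks, and 5000 for cross-trait correlations.
Brain–behavior screens use `lme4` random intercepts for participant
nested in family with Wald z p-values; a singular participant-level fit
is refitted with the family intercept only.

## Known limitations

* The boundary behavior of the standard chi-square reference makes the
  new-influence tests conservative near $x_{22} = 0$; the mixture option
  mitigates but the package does not attempt the full mixture theory for
  multi-parameter boundary constraints.
* Profile bounds are located to ~3 decimal places to keep refit counts
  low; quantities whose deviance is extremely flat may show bound noise
  of that order.
* Scale equivariance of fitted components holds to roughly 1e-4 relative
  (the optimizer's parameter precision), not to machine precision.
* Nonadditive genetic (D) models are out of scope, as are ordinal
  behavioral scores, spatial normalization and surface plotting.

## A minimal session

```{r, eval = FALSE}
truth <- cholesky_params(a = c(sqrt(.5), .42, .32),
                         c = c(sqrt(.2), .27, .18),
                         e = c(sqrt(.3), .21, .44))
sim <- simulate_twin_cohort(twin_sim_config(cholesky_truth = truth,
                                            seed = 7))
fits <- lapply(c("ACE", "AE", "CE", "E"), fit_cholesky, data = sim$data)
sel <- select_model(setNames(fits, c("ACE", "AE", "CE", "E")))
decompose_variance(sel$chosen)
profile_ci(sel$chosen, "std_A1")
test_new_influence(fits[[1]], "A")
```
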
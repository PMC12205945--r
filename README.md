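# twinlocal

Genetic and environmental decomposition of *local* resting-state fMRI
metrics in longitudinal twin cohorts.

Two voxelwise summaries of local brain function — **ReHo** (regional
homogeneity: Kendall's coefficient of concordance between a voxel and its
26 neighbors) and **fALFF** (the fraction of spectral amplitude in
0.01–0.08 Hz) — can be decomposed, in a classical twin design, into
additive genetic (A), common environment (C) and unique environment plus
error (E) variance. With two measurement waves, a bivariate Cholesky
model further separates influences that *continue* from wave 1 from
influences that are *new* at wave 2.

`twinlocal` provides the full chain as a tested R package:

* **Local metrics** — Power framewise displacement, scrubbing,
  Friston-24 nuisance regression, linear detrending, ideal bandpass,
  KCC-ReHo, fALFF, Z-standardization, masked 6-mm FWHM Gaussian
  smoothing, atlas ROI extraction with AP/PA run averaging, and the
  mean-FD > 0.3 mm exclusion rule. NIfTI-1 in and out (via RNifti).
* **Twin models** — saturated and ACE/AE/CE/E bivariate Cholesky models
  fitted by full-information maximum likelihood (unpaired twins and
  missed waves contribute their marginal densities), with a compiled
  likelihood/gradient kernel; assumption and covariate likelihood-ratio
  tests; twin correlations; AIC selection with a ΔAIC < 2 ambiguity
  flag; tests for new wave-2 influences (x22 = 0) and for
  (de)amplification (x21 = x11); raw and standardized variance
  components; 95% profile-likelihood confidence intervals; latent
  genetic/environmental correlations between traits.
* **Associations** — two-level random-intercept mixed models
  (participant nested in family, via lme4) for brain–behavior screens,
  with multivariate twin follow-up.
* **Pipeline** — `run_pipeline()` orchestrates simulate → metrics →
  twin → assoc → report with one master seed, Benjamini–Hochberg FDR
  within each of four test families, TSV/JSON outputs and a run
  manifest. A thin CLI lives at `inst/cli/twinlocal.R`.
* **Synthetic data** — a twin-cohort generator with known Cholesky
  ground truth (latent A/C/E drawn explicitly, so the decomposition is
  auditable per twin) and a 4D fMRI generator with controllable
  neighborhood coherence and in-band amplitude fraction per ROI.

In the Cholesky parameterization each source X ∈ {A, C, E} has paths
x11, x21, x22; the within-twin covariance is Σ L_X L_X′ and the
cross-twin covariance k·L_A L_A′ + L_C L_C′ with k = 1 (MZ) or 0.5 (DZ).
Wave-1 heritability is a11²/(a11² + c11² + e11²); a21² is continuing and
a22² new genetic variance at wave 2; the genetic correlation between two
traits is a21/√(a21² + a22²).

## Worked example

Simulate a two-wave cohort of 2000 MZ and 2000 DZ pairs whose true
wave-1 variance shares are A/C/E = 0.50/0.20/0.30, with realistic wave-2
attrition and unpaired twins, then fit and compare the four models:

```r
library(twinlocal)
truth <- cholesky_params(a = c(sqrt(.5), .42, .32),
                         c = c(sqrt(.2), .27, .18),
                         e = c(sqrt(.3), .21, .44))
sim <- simulate_twin_cohort(twin_sim_config(
  n_mz_pairs = 2000, n_dz_pairs = 2000, cholesky_truth = truth,
  beta_age = 0, beta_sex = 0, beta_fd = 0,
  p_missing_wave2 = 0.28, p_unpaired = 0.1, seed = 7))
fits <- lapply(c("ACE", "AE", "CE", "E"),
               function(m) fit_cholesky(sim$data, m, seed = 1))
names(fits) <- c("ACE", "AE", "CE", "E")
sel <- select_model(fits)
sel$aic_table
#>  model      aic n_free minus2ll  delta_aic
#>    ACE 29263.47     11 29241.47    0.00000
#>     AE 29283.67      8 29267.67   20.19862
#>     CE 29519.07      8 29503.07  255.60520
#>      E 31381.61      5 31371.61 2118.14484

decompose_variance(sel$chosen)$standardized
#>   wave1 wave2
#> A 0.530 0.502
#> C 0.189 0.137
#> E 0.281 0.361

profile_ci(sel$chosen, "std_A1")
#>    lo    hi
#> 0.455 0.608

test_new_influence(fits$ACE, "A")
#>                                 test    chisq df            p
#>  new A influence at wave 2 (a22 = 0) 36.35511  1 1.644479e-09
```

The ACE model wins on AIC (unambiguously: the runner-up is 20 AIC units
behind); the estimated wave-1 shares 0.53/0.19/0.28 recover the 0.50/
0.20/0.30 truth within sampling error, and the profile interval for
wave-1 heritability (0.455, 0.608) covers it. The new-influence test
correctly detects the genuine wave-2-specific genetic variance
(a22 = 0.32 in the truth).

The image-level demo — synthetic 4D runs through metrics, QC, twin
models and behavioral screens — is one call:

```r
run_pipeline(pipeline_config(out_dir = "demo_out", seed = 42))
```

which writes `metrics.tsv`, `twin_*.tsv`, `assoc_results.tsv`, a JSON
manifest and a text summary under `demo_out/`.

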
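#' Configuration for the synthetic fMRI run generator
#'
#' Defaults emulate a multiband adolescent resting-state acquisition:
#' 2 mm isotropic voxels, TR = 0.93 s, 322 retained volumes per run, with
#' per-ROI targets for neighborhood temporal coherence (what ReHo measures)
#' and for the fraction of spectral amplitude inside 0.01-0.08 Hz (what
#' fALFF measures).
#'
#' @param grid_shape integer length-3 voxel counts.
#' @param voxel_size voxel edge length in mm.
#' @param n_volumes retained volumes per run (>= 64 so the low-frequency
#'   band contains several DFT bins).
#' @param tr repetition time in seconds.
#' @param coherence_by_roi named vector (names = ROI ids) of target
#'   pairwise correlations in \[0, 1\] between voxels of the ROI.
#' @param band_fraction_by_roi named vector of target in-band amplitude
#'   fractions in \[0, 1\].
#' @param motion_scale standard deviation (mm) of the per-volume random-walk
#'   translation increments; rotation increments use `motion_scale / 50`
#'   radians. 0 gives motionless runs.
#' @param seed integer seed.
#' @return A list of class `fmri_sim_config`.
#' @export
fmri_sim_config <- function(grid_shape = c(20, 20, 12), voxel_size = 2,
                            n_volumes = 322, tr = 0.93,
                            coherence_by_roi = NULL,
                            band_fraction_by_roi = NULL,
                            motion_scale = 0.02, seed = 1L) {
  stopifnot(length(grid_shape) == 3, n_volumes >= 64, tr > 0,
            motion_scale >= 0)
  if (!is.null(coherence_by_roi))
    stopifnot(all(coherence_by_roi >= 0), all(coherence_by_roi <= 1))
  if (!is.null(band_fraction_by_roi))
    stopifnot(all(band_fraction_by_roi >= 0), all(band_fraction_by_roi <= 1))
  structure(as.list(environment()), class = "fmri_sim_config")
}

# Spectral synthesis: series whose expected amplitude-spectrum fraction in
# `band` equals band_fraction, with no power above fmax. Returns t x nser.
synth_series <- function(n, tr, band_fraction, nser, band = c(0.01, 0.08),
                         fmax = 0.25) {
  k <- seq_len(floor(n / 2))
  f <- k / (n * tr)
  in_band <- f >= band[1] & f <= band[2]
  out_band <- f <= fmax & !in_band
  if (!any(in_band)) stop("no DFT bins inside the band; increase n_volumes")
  amp <- numeric(length(k))
  amp[in_band] <- band_fraction / sum(in_band)
  if (any(out_band)) amp[out_band] <- (1 - band_fraction) / sum(out_band)
  phases <- matrix(stats::runif(length(k) * nser, 0, 2 * pi), length(k), nser)
  spec <- matrix(0 + 0i, n, nser)
  spec[k + 1, ] <- amp * exp(1i * phases)
  # hermitian symmetry for a real series
  spec[n + 1 - k, ] <- Conj(spec[k + 1, ])
  if (n %% 2 == 0) spec[n / 2 + 1, ] <- Re(spec[n / 2 + 1, ])
  x <- Re(stats::mvfft(spec, inverse = TRUE))
  scale(x, center = TRUE, scale = apply(x, 2, stats::sd))
}

#' Simulate an AP/PA pair of synthetic fMRI runs
#'
#' Each ROI gets a shared low-frequency signal; voxel time series are
#' `sqrt(coherence) * shared + sqrt(1 - coherence) * noise`, with shared and
#' noise components spectrally shaped (by DFT synthesis with random phases)
#' so the expected in-band amplitude fraction matches the ROI's
#' `band_fraction` target. Pairwise voxel correlation within an ROI then
#' equals the coherence target. Motion parameters are smooth random walks.
#' A coherence of 1 (zero noise) is flagged as degenerate: every voxel in
#' the ROI shares one series and rank-based metrics tie everywhere.
#'
#' @param config an [fmri_sim_config()].
#' @param atlas an [atlas_labels()] on `config$grid_shape`.
#' @return list with `ap`, `pa` ([fmri_run()] objects) and `motion`
#'   (list of t x 6 matrices `AP`, `PA`).
#' @export
simulate_fmri_run <- function(config, atlas) {
  stopifnot(inherits(config, "fmri_sim_config"),
            inherits(atlas, "atlas_labels"),
            identical(dim(atlas$labels), as.integer(config$grid_shape)))
  coh <- config$coherence_by_roi
  if (is.null(coh))
    coh <- stats::setNames(rep(0.5, length(atlas$roi_ids)), atlas$roi_ids)
  bf <- config$band_fraction_by_roi
  if (is.null(bf))
    bf <- stats::setNames(rep(0.5, length(atlas$roi_ids)), atlas$roi_ids)
  if (any(coh >= 1 - 1e-12))
    warning("coherence target of 1: all voxels in the ROI share one series",
            " (rank ties everywhere); ReHo is degenerate there")
  n <- config$n_volumes
  with_seed(config$seed, {
    make_run <- function(phase_dir) {
      data <- array(0, c(config$grid_shape, n))
      vol <- matrix(data, prod(config$grid_shape), n)
      for (id in atlas$roi_ids) {
        vox <- which(atlas$labels == id)
        if (!length(vox)) next
        w <- sqrt(coh[as.character(id)])
        shared <- synth_series(n, config$tr, bf[as.character(id)], 1)
        noise <- synth_series(n, config$tr, bf[as.character(id)], length(vox))
        vol[vox, ] <- t(w * shared[, rep(1, length(vox))] +
                          sqrt(1 - w^2) * noise)
      }
      bg <- which(atlas$labels == 0)
      if (length(bg))
        vol[bg, ] <- t(synth_series(n, config$tr, 0.5, length(bg)))
      mask <- array(atlas$labels > 0, config$grid_shape)
      fmri_run(array(vol, c(config$grid_shape, n)), tr = config$tr,
               mask = mask, phase_dir = phase_dir)
    }
    make_motion <- function() {
      steps <- cbind(matrix(stats::rnorm(3 * n, 0, config$motion_scale), n, 3),
                     matrix(stats::rnorm(3 * n, 0, config$motion_scale / 50),
                            n, 3))
      apply(steps, 2, cumsum)
    }
    list(ap = make_run("AP"), pa = make_run("PA"),
         motion = list(AP = make_motion(), PA = make_motion()))
  })
}
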
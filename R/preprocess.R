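#' Friston 24-parameter motion confound matrix
#'
#' The six rigid-body parameters, their one-volume lags, and both sets
#' squared.
#'
#' @param mp t x 6 motion parameter matrix.
#' @return t x 24 matrix.
#' @export
friston24 <- function(mp) {
  mp <- as.matrix(mp)
  stopifnot(ncol(mp) == 6)
  lag <- rbind(0, mp[-nrow(mp), , drop = FALSE])
  cbind(mp, lag, mp^2, lag^2)
}

#' Voxelwise nuisance regression
#'
#' Regresses the confound matrix out of every in-mask voxel time series by
#' OLS and restores the voxel mean. An intercept is always included.
#' Collinear confound columns are dropped with a warning.
#'
#' @param run an [fmri_run()].
#' @param confounds t x k numeric matrix (e.g. [friston24()] output plus
#'   tissue signals).
#' @return The run with residualized time series.
#' @export
regress_confounds <- function(run, confounds) {
  Y <- mask_series(run)
  t_ <- nrow(Y)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != t_)
    stop("confound rows (", nrow(confounds), ") != volumes (", t_, ")")
  X <- cbind(1, confounds)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    warning("dropping ", ncol(X) - q$rank, " collinear confound column(s)")
    X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
    q <- qr(X)
  }
  mu <- colMeans(Y)
  beta <- solve(crossprod(X), crossprod(X, Y))
  res <- Y - X %*% beta
  set_mask_series(run, sweep(res, 2, mu, "+"))
}

#' Voxelwise linear detrend
#'
#' Removes each in-mask voxel's best-fit line over time and restores the
#' voxel mean.
#'
#' @param run an [fmri_run()].
#' @return The detrended run.
#' @export
detrend_linear <- function(run) {
  t_ <- dim(run$data)[4]
  if (t_ < 3) stop("need at least 3 volumes to detrend")
  Y <- mask_series(run)
  X <- cbind(1, seq_len(t_))
  mu <- colMeans(Y)
  res <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
  set_mask_series(run, sweep(res, 2, mu, "+"))
}

# DFT bin frequencies for an n-point series sampled at 1/tr Hz
# (bins 0 .. n-1; bin k maps to k/(n*tr), mirrored above Nyquist)
dft_freqs <- function(n, tr) {
  k <- seq_len(n) - 1
  f <- k / (n * tr)
  pmin(f, 1 / tr - f)
}

#' Ideal frequency-domain bandpass filter
#'
#' Zeroes DFT coefficients whose frequency lies outside `[low, high]`
#' (inclusive at both edges; the DC component is always removed) and
#' inverse-transforms. The filtered series are therefore zero-mean.
#'
#' @param run an [fmri_run()].
#' @param low,high band edges in Hz; `high` must be below Nyquist.
#' @return The filtered run.
#' @export
bandpass <- function(run, low = 0.01, high = 0.08) {
  if (low >= high) stop("low must be < high")
  nyq <- 1 / (2 * run$tr)
  if (high >= nyq) stop("high (", high, " Hz) must be below Nyquist (",
                        signif(nyq, 4), " Hz)")
  Y <- mask_series(run)
  n <- nrow(Y)
  f <- dft_freqs(n, run$tr)
  keep <- f >= low & f <= high
  keep[1] <- FALSE
  Yf <- stats::mvfft(Y)
  Yf[!keep, ] <- 0
  set_mask_series(run, Re(stats::mvfft(Yf, inverse = TRUE)) / n)
}
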
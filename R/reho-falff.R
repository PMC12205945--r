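NEIGHBOR_OFFSETS <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g$order <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  g
})

# columnwise midranks via one global order() call; columns containing ties
# fall back to rank() so midranks stay exact
rank_columns <- function(Y) {
  n <- nrow(Y); V <- ncol(Y)
  cols <- rep.int(seq_len(V), rep.int(n, V))
  ord <- order(cols, as.vector(Y))
  r <- integer(n * V)
  r[ord] <- rep.int(seq_len(n), V)
  R <- matrix(as.numeric(r), n, V)
  sorted <- as.vector(Y)[ord]
  tied <- c(FALSE, diff(sorted) == 0 & diff(cols[ord]) == 0)
  if (any(tied)) {
    tie_cols <- unique(cols[ord][tied])
    for (j in tie_cols) R[, j] <- rank(Y[, j])
  }
  R
}

#' Voxelwise regional homogeneity (Kendall's W)
#'
#' For each in-mask voxel, Kendall's coefficient of concordance between the
#' voxel's time series and those of its neighbors in the 3x3x3 cube
#' (neighborhood sizes 7, 19 or 27 select face-, edge- or
#' corner-connected neighbors). Ranks are computed per voxel over time with
#' midranks for ties; with K concordant series of length n and across-voxel
#' rank sums R_t,
#' \deqn{W = \frac{12 \sum_t (R_t - \bar R)^2}{K^2 (n^3 - n)}}
#' Optionally the tie-corrected denominator \eqn{K^2(n^3-n) - K \sum T}
#' is used. Voxels with fewer than 2 in-mask series get `NA`.
#'
#' @param run an [fmri_run()] (bandpass-filtered input is expected for the
#'   conventional metric; the function itself is agnostic).
#' @param neighborhood 7, 19 or 27 (the voxel plus 6, 18 or 26 neighbors).
#' @param tie_correction subtract the standard tie term from the
#'   denominator.
#' @return 3D map of W in \[0, 1\], `NA` outside the mask.
#' @export
compute_reho <- function(run, neighborhood = 27, tie_correction = FALSE) {
  stopifnot(neighborhood %in% c(7, 19, 27))
  d <- dim(run$data)
  n <- d[4]
  if (n < 3) stop("need at least 3 time points")
  ord <- switch(as.character(neighborhood), "7" = 1, "19" = 2, "27" = 3)
  offsets <- NEIGHBOR_OFFSETS[NEIGHBOR_OFFSETS$order <= ord, ]
  V <- prod(d[1:3])
  m3 <- which(run$mask)
  Y <- mask_series(run)
  rkmat <- matrix(0, n, V)
  rkmat[, m3] <- rank_columns(Y)  # midranks for ties
  tie_terms <- numeric(V)
  if (tie_correction) {
    tie_terms[m3] <- apply(Y, 2, function(y) {
      tb <- tabulate(match(y, unique(y)))
      sum(tb^3 - tb)
    })
  }
  off <- as.matrix(offsets[, c("dx", "dy", "dz")])
  storage.mode(off) <- "integer"
  res <- reho_kernel(rkmat, as.integer(run$mask), d[1], d[2], d[3],
                     off, tie_terms)
  K <- res$K
  denom <- K^2 * (n^3 - n)
  if (tie_correction) denom <- denom - K * res$T
  W <- 12 * res$S / denom
  W[K < 2] <- NA_real_
  W[!as.vector(run$mask)] <- NA_real_
  array(W, d[1:3])
}

#' Voxelwise fractional amplitude of low-frequency fluctuations
#'
#' Ratio of the amplitude spectrum summed over the low-frequency band to
#' the amplitude summed over the full range (DC excluded). The amplitude at
#' each DFT bin is the square root of the periodogram (modulus of the DFT
#' coefficient); setting `mode = "power"` uses the raw periodogram
#' instead. Input should be detrended but not bandpass-filtered.
#'
#' @param run an [fmri_run()].
#' @param band numerator band in Hz (edges inclusive).
#' @param full_range denominator range in Hz (`(0, high]`).
#' @param mode `"amplitude"` (default) or `"power"`.
#' @return 3D map in \[0, 1\]; zero-variance voxels get `NA`.
#' @export
compute_falff <- function(run, band = c(0.01, 0.08),
                          full_range = c(0, 0.25),
                          mode = c("amplitude", "power")) {
  mode <- match.arg(mode)
  d <- dim(run$data)
  n <- d[4]
  Y <- mask_series(run)
  Y <- sweep(Y, 2, colMeans(Y))
  amp <- Mod(stats::mvfft(Y))
  k <- seq_len(floor(n / 2))  # positive-frequency bins
  f <- k / (n * run$tr)
  amp <- amp[k + 1, , drop = FALSE]
  if (mode == "power") amp <- amp^2
  num <- colSums(amp[f >= band[1] & f <= band[2], , drop = FALSE])
  den <- colSums(amp[f > full_range[1] & f <= full_range[2], , drop = FALSE])
  val <- ifelse(den > 1e-12, num / den, NA_real_)
  out <- array(NA_real_, d[1:3])
  out[which(run$mask)] <- val
  out
}
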
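#' Z-standardize a map within a mask
#'
#' Subtracts the in-mask mean and divides by the in-mask population
#' (divide-by-n) standard deviation. Voxels outside the mask become `NA`.
#'
#' @param map 3D numeric array.
#' @param mask 3D logical array; defaults to all finite voxels.
#' @return The standardized map.
#' @export
zscore_map <- function(map, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(map)
  v <- map[mask & is.finite(map)]
  if (!length(v)) stop("empty mask")
  s <- sqrt(mean((v - mean(v))^2))
  if (s < 1e-12) stop("constant map: cannot Z-standardize")
  out <- (map - mean(v)) / s
  out[!mask] <- NA_real_
  out
}

gauss_kernel_1d <- function(fwhm, voxel_size) {
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

convolve_axis <- function(arr, k, axis) {
  r <- (length(k) - 1) / 2
  d <- dim(arr)
  out <- array(0, d)
  for (j in seq_along(k)) {
    off <- j - r - 1
    n <- d[axis]
    dst <- max(1, 1 + off):min(n, n + off)
    src <- dst - off
    idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_src <- idx_dst
    idx_dst[[axis]] <- dst
    idx_src[[axis]] <- src
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]], drop = FALSE] +
      k[j] * arr[idx_src[[1]], idx_src[[2]], idx_src[[3]], drop = FALSE]
  }
  out
}

#' Masked isotropic Gaussian smoothing
#'
#' Separable Gaussian with `sigma = fwhm / (2 sqrt(2 ln 2))` per axis in
#' voxel units. Voxels outside the mask contribute no signal and the
#' kernel weights are renormalized over the in-mask support, so a constant
#' in-mask map is unchanged.
#'
#' @param map 3D numeric array (`NA` allowed outside the mask).
#' @param fwhm kernel full width at half maximum in mm.
#' @param voxel_size voxel edge length in mm (isotropic).
#' @param mask 3D logical; defaults to finite voxels of `map`.
#' @return The smoothed map, `NA` outside the mask.
#' @export
smooth_gaussian <- function(map, fwhm = 6, voxel_size = 2, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(map)
  k <- gauss_kernel_1d(fwhm, voxel_size)
  num <- map
  num[!mask | !is.finite(num)] <- 0
  den <- array(0, dim(map)); den[mask] <- 1
  for (axis in 1:3) {
    num <- convolve_axis(num, k, axis)
    den <- convolve_axis(den, k, axis)
  }
  out <- num / den
  out[!mask] <- NA_real_
  out
}

#' ROI mean extraction
#'
#' Mean of the map over the voxels of each atlas label; `NA` voxels are
#' excluded, and ROIs with no (finite) voxels yield `NA`.
#'
#' @param map 3D numeric array.
#' @param atlas an [atlas_labels()] object on the same grid.
#' @return Named numeric vector, one entry per `roi_ids`.
#' @export
extract_roi_means <- function(map, atlas) {
  stopifnot(identical(dim(map), dim(atlas$labels)))
  out <- vapply(atlas$roi_ids, function(id) {
    v <- map[atlas$labels == id]
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  names(out) <- paste0("roi_", atlas$roi_ids)
  out
}

#' Average AP and PA ROI vectors
#'
#' Elementwise mean of the two phase-encoding runs' ROI vectors. Under the
#' default policy a missing run (or any `NA` entry pair) leaves `NA`,
#' signalling subject exclusion downstream; `"use_available"` keeps the
#' non-missing run's value instead.
#'
#' @param v_ap,v_pa equal-length ROI vectors (either may be `NULL`).
#' @param na_policy `"exclude"` (default) or `"use_available"`.
#' @return ROI vector of the same length.
#' @export
average_runs <- function(v_ap, v_pa, na_policy = c("exclude", "use_available")) {
  na_policy <- match.arg(na_policy)
  if (is.null(v_ap) && is.null(v_pa)) stop("both runs missing")
  if (is.null(v_ap) || is.null(v_pa)) {
    present <- if (is.null(v_ap)) v_pa else v_ap
    if (na_policy == "use_available") return(present)
    return(stats::setNames(rep(NA_real_, length(present)), names(present)))
  }
  stopifnot(length(v_ap) == length(v_pa))
  out <- (v_ap + v_pa) / 2
  if (na_policy == "use_available") {
    out[is.na(v_ap)] <- v_pa[is.na(v_ap)]
    out[is.na(v_pa)] <- v_ap[is.na(v_pa)]
  }
  out
}
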
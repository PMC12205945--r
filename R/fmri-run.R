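#' 4D fMRI run container
#'
#' Light wrapper holding a 4D array of BOLD-like intensities, the
#' repetition time, a brain mask and the phase-encoding direction.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr repetition time in seconds.
#' @param mask 3D logical array matching the spatial grid; default all
#'   `TRUE`.
#' @param phase_dir `"AP"` or `"PA"`.
#' @return An object of class `fmri_run`.
#' @export
fmri_run <- function(data, tr, mask = NULL, phase_dir = c("AP", "PA")) {
  phase_dir <- match.arg(phase_dir)
  stopifnot(length(dim(data)) == 4, tr > 0, dim(data)[4] >= 2)
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  stopifnot(identical(dim(mask), dim(data)[1:3]))
  structure(list(data = data, tr = tr, mask = mask, phase_dir = phase_dir),
            class = "fmri_run")
}

#' @export
print.fmri_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("fmri_run %s: %dx%dx%d grid, %d volumes, TR %.3g s, %d mask voxels\n",
              x$phase_dir, d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

#' Atlas label container
#'
#' @param labels 3D integer array, 0 = background.
#' @param roi_ids ordered ROI ids expected in the atlas; defaults to the
#'   sorted positive labels present.
#' @return An object of class `atlas_labels`.
#' @export
atlas_labels <- function(labels, roi_ids = NULL) {
  stopifnot(length(dim(labels)) == 3)
  present <- sort(unique(as.integer(labels[labels > 0])))
  if (is.null(roi_ids)) roi_ids <- present
  structure(list(labels = labels, roi_ids = as.integer(roi_ids)),
            class = "atlas_labels")
}

#' Partition a grid into box-shaped ROIs (synthetic atlas)
#'
#' Splits the grid into `n_roi` contiguous slabs along the x axis —
#' a deliberately simple stand-in for a cortical parcellation, used by the
#' simulator and tests.
#'
#' @param grid_shape integer length-3 voxel counts.
#' @param n_roi number of ROIs.
#' @return An [atlas_labels()] object covering the whole grid.
#' @export
make_box_atlas <- function(grid_shape, n_roi) {
  stopifnot(n_roi >= 1, grid_shape[1] >= n_roi)
  cuts <- ceiling(seq_len(grid_shape[1]) * n_roi / grid_shape[1])
  labels <- array(0L, grid_shape)
  for (i in seq_len(grid_shape[1])) labels[i, , ] <- cuts[i]
  atlas_labels(labels, seq_len(n_roi))
}

# in-mask voxel time series as a t x V matrix
mask_series <- function(run) {
  d <- dim(run$data)
  m <- which(run$mask)
  mat <- matrix(run$data, prod(d[1:3]), d[4])[m, , drop = FALSE]
  t(mat)
}

# write a t x V matrix back into the run
set_mask_series <- function(run, series) {
  d <- dim(run$data)
  mat <- matrix(run$data, prod(d[1:3]), d[4])
  mat[which(run$mask), ] <- t(series)
  run$data <- array(mat, d)
  run
}

#' Read / write NIfTI volumes and motion parameter files
#'
#' Thin wrappers over RNifti for the 4D runs, 3D atlas labels and the
#' 6-column whitespace-delimited motion parameter files (translations mm,
#' rotations radians).
#'
#' @param path file path (`.nii` / `.nii.gz` for images).
#' @param tr repetition time in seconds for [read_fmri_nifti()].
#' @param phase_dir phase-encoding tag for the returned run.
#' @return `read_fmri_nifti` an [fmri_run()]; `read_atlas_nifti` an
#'   [atlas_labels()]; `read_motion_params` a t x 6 matrix.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
read_fmri_nifti <- function(path, tr = NULL, phase_dir = "AP") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) stop("expected a 4D image: ", path)
  if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
  fmri_run(arr, tr = tr, phase_dir = phase_dir)
}

#' @param run an [fmri_run()].
#' @param voxel_size voxel edge length in mm.
#' @rdname nifti_io
#' @export
write_fmri_nifti <- function(run, path, voxel_size = 2) {
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(rep(voxel_size, 3), run$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_atlas_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 4) arr <- arr[, , , 1]
  atlas_labels(array(as.integer(round(arr)), dim(arr)))
}

#' @param atlas an [atlas_labels()].
#' @rdname nifti_io
#' @export
write_atlas_nifti <- function(atlas, path, voxel_size = 2) {
  img <- RNifti::asNifti(atlas$labels + 0L)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_motion_params <- function(path) {
  mp <- as.matrix(utils::read.table(path))
  if (ncol(mp) != 6) stop("motion parameter file must have 6 columns")
  unname(mp)
}

#' @param mp t x 6 motion parameter matrix.
#' @rdname nifti_io
#' @export
write_motion_params <- function(mp, path) {
  utils::write.table(format(mp, digits = 8), path, sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
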
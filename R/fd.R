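#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the three translations (mm) plus the three rotations
#' (radians) projected onto a sphere of `head_radius` mm. The first volume
#' has no predecessor and is assigned FD = 0; the mean is taken over
#' volumes 2..t.
#'
#' @param mp numeric t x 6 matrix: translations x/y/z in mm, then rotations
#'   in radians.
#' @param head_radius sphere radius (mm) converting rotation to arc length.
#' @return list with `fd` (length-t vector, mm) and `mean_fd` (mm).
#' @export
compute_fd <- function(mp, head_radius = 50) {
  mp <- as.matrix(mp)
  if (ncol(mp) != 6) stop("motion parameters must have 6 columns")
  if (nrow(mp) < 2) stop("need at least 2 volumes")
  d <- abs(diff(mp))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd[-1]))
}

#' Motion-scrubbing keep mask
#'
#' Marks volumes whose FD exceeds `threshold`, extends the censoring to
#' `extend_before` preceding and `extend_after` following volumes, and
#' returns the logical keep mask.
#'
#' @param fd per-volume framewise displacement (mm).
#' @param threshold censoring threshold (mm).
#' @param extend_before,extend_after neighbors censored around each spike.
#' @return logical vector, `TRUE` = keep.
#' @export
scrub_mask <- function(fd, threshold = 0.5, extend_before = 1,
                       extend_after = 2) {
  stopifnot(all(is.finite(fd)))
  t_ <- length(fd)
  bad <- which(fd > threshold)
  if (length(bad)) {
    ext <- unique(unlist(lapply(bad, function(i)
      seq(i - extend_before, i + extend_after))))
    bad <- ext[ext >= 1 & ext <= t_]
  }
  keep <- rep(TRUE, t_)
  keep[bad] <- FALSE
  keep
}

#' Flag acquisitions exceeding the motion exclusion threshold
#'
#' Sets the `excluded` flag for subjects whose mean framewise displacement
#' exceeds the threshold (strict inequality: exactly at the threshold is
#' kept). `mean_fd` in the table is the per-subject maximum over the AP and
#' PA runs, so exclusion triggers if either run exceeds the threshold.
#'
#' @param table a ROI metric table (see [extract_roi_means()] /
#'   [run_metrics()]) with a `mean_fd` column.
#' @param threshold exclusion threshold in mm.
#' @return the table with its `excluded` column updated.
#' @export
apply_motion_exclusion <- function(table, threshold = 0.3) {
  stopifnot("mean_fd" %in% names(table))
  table$excluded <- table$mean_fd > threshold
  table
}
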
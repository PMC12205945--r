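#' Compute ReHo and fALFF ROI tables for one acquisition
#'
#' Full local-metrics chain for a subject's AP/PA run pair: framewise
#' displacement from the motion parameters, Friston-24 nuisance regression
#' (plus any extra confound columns), linear detrending, motion scrubbing
#' (censored volumes removed), then per branch: bandpass filtering and
#' KCC-ReHo, or fALFF on the unfiltered series. Maps are Z-standardized,
#' smoothed and averaged over atlas ROIs; the AP and PA ROI vectors are
#' averaged. The stage order is fixed here so that bandpass always precedes
#' ReHo and never precedes fALFF.
#'
#' @param subject,wave identifiers copied into the output rows.
#' @param runs list with elements `ap` and `pa` ([fmri_run()] objects).
#' @param motion list with t x 6 matrices `AP` and `PA`.
#' @param atlas an [atlas_labels()].
#' @param fd_threshold acquisition-level mean-FD exclusion threshold (mm).
#' @param scrub_threshold per-volume FD censoring threshold (mm).
#' @param band ReHo bandpass / fALFF numerator band (Hz).
#' @param full_range fALFF denominator range (Hz).
#' @param fwhm smoothing kernel FWHM (mm); 0 disables smoothing.
#' @param voxel_size voxel edge (mm).
#' @param falff_mode `"amplitude"` or `"power"`.
#' @param extra_confounds optional t x k matrix appended to the Friston-24
#'   design (e.g. WM/CSF signals), per run: list(AP = , PA = ).
#' @param na_policy AP/PA averaging policy, see [average_runs()].
#' @return data.frame with two rows (metrics `ReHo`, `fALFF`): columns
#'   `subject`, `wave`, `metric`, `roi_<id>`..., `mean_fd` (max of the two
#'   runs, mm), `excluded`.
#' @export
run_metrics <- function(subject, wave, runs, motion, atlas,
                        fd_threshold = 0.3, scrub_threshold = 0.5,
                        band = c(0.01, 0.08), full_range = c(0, 0.25),
                        fwhm = 6, voxel_size = 2,
                        falff_mode = "amplitude",
                        extra_confounds = NULL,
                        na_policy = "exclude") {
  per_run <- lapply(c("ap", "pa"), function(which_run) {
    run <- runs[[which_run]]
    mp <- motion[[toupper(which_run)]]
    if (is.null(run) || is.null(mp)) return(NULL)
    fd <- compute_fd(mp)
    conf <- friston24(mp)
    xc <- extra_confounds[[toupper(which_run)]]
    if (!is.null(xc)) conf <- cbind(conf, xc)
    run <- regress_confounds(run, conf)
    run <- detrend_linear(run)
    keep <- scrub_mask(fd$fd, scrub_threshold)
    if (sum(keep) < 8)
      return(list(mean_fd = fd$mean_fd, reho = NULL, falff = NULL))
    scrubbed <- run
    scrubbed$data <- run$data[, , , keep, drop = FALSE]
    reho_map <- compute_reho(bandpass(scrubbed, band[1], band[2]))
    falff_map <- compute_falff(scrubbed, band = band,
                               full_range = full_range, mode = falff_mode)
    post <- function(map) {
      z <- zscore_map(map, run$mask)
      if (fwhm > 0) z <- smooth_gaussian(z, fwhm, voxel_size, run$mask)
      extract_roi_means(z, atlas)
    }
    list(mean_fd = fd$mean_fd, reho = post(reho_map),
         falff = post(falff_map))
  })
  names(per_run) <- c("ap", "pa")
  mean_fd <- max(vapply(per_run, function(r)
    if (is.null(r)) NA_real_ else r$mean_fd, numeric(1)), na.rm = TRUE)
  row_for <- function(metric, field) {
    v_ap <- if (is.null(per_run$ap)) NULL else per_run$ap[[field]]
    v_pa <- if (is.null(per_run$pa)) NULL else per_run$pa[[field]]
    v <- if (is.null(v_ap) && is.null(v_pa))
      stats::setNames(rep(NA_real_, length(atlas$roi_ids)),
                      paste0("roi_", atlas$roi_ids))
    else average_runs(v_ap, v_pa, na_policy = na_policy)
    out <- data.frame(subject = subject, wave = wave, metric = metric,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(as.list(v)))
    out$mean_fd <- mean_fd
    out$excluded <- FALSE
    out
  }
  tab <- rbind(row_for("ReHo", "reho"), row_for("fALFF", "falff"))
  apply_motion_exclusion(tab, fd_threshold)
}

#' Read / write the ROI metric table TSV
#'
#' @param tab,path table and file path.
#' @export
write_metric_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_tsv
#' @export
read_metric_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
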
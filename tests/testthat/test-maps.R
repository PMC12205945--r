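test_that("Z-standardization uses the population SD within the mask", {
  set.seed(16)
  m <- array(rnorm(60, 5, 2), c(5, 4, 3))
  z <- zscore_map(m)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-12)

  # 2-voxel mask {1, 3}: population SD 1 -> {-1, +1}
  m2 <- array(0, c(2, 1, 1)); m2[1] <- 1; m2[2] <- 3
  z2 <- zscore_map(m2)
  expect_equal(as.vector(z2), c(-1, 1))

  expect_error(zscore_map(array(2, c(3, 3, 3))), "constant")
})

test_that("Gaussian smoothing preserves constants and has the right FWHM", {
  const <- array(3, c(9, 9, 9))
  expect_equal(smooth_gaussian(const, 6, 2), const, tolerance = 1e-12)

  # delta input on a fine grid: half-max at half the FWHM from the peak
  d <- array(0, c(31, 31, 31))
  d[16, 16, 16] <- 1
  sm <- smooth_gaussian(d, fwhm = 6, voxel_size = 1)
  prof <- sm[, 16, 16] / sm[16, 16, 16]
  # fwhm 6 mm at 1 mm voxels: value at offset 3 equals 1/2
  expect_equal(prof[19], 0.5, tolerance = 0.01)
  # normalized kernel preserves the total for an interior delta (up to the
  # boundary renormalization touching the kernel's outermost tail)
  expect_equal(sum(sm), 1, tolerance = 1e-4)
})

test_that("masked smoothing renormalizes at the boundary", {
  m <- array(1, c(8, 8, 8))
  mask <- array(TRUE, c(8, 8, 8)); mask[1:2, , ] <- FALSE
  m[!mask] <- NA
  sm <- smooth_gaussian(m, 6, 2, mask)
  expect_true(all(is.na(sm[1:2, , ])))
  expect_equal(sm[mask], rep(1, sum(mask)), tolerance = 1e-12)
})

test_that("ROI means follow the atlas labels", {
  atlas <- make_box_atlas(c(6, 2, 2), 2)
  m <- array(5, c(6, 2, 2))
  expect_equal(unname(extract_roi_means(m, atlas)), c(5, 5))

  m2 <- array(0, c(6, 2, 2))
  m2[atlas$labels == 1] <- 1:12
  m2[atlas$labels == 2] <- 100
  v <- extract_roi_means(m2, atlas)
  expect_equal(unname(v), c(mean(1:12), 100))

  # NA voxels are excluded; an absent ROI is flagged missing
  m2[1, 1, 1] <- NA
  v2 <- extract_roi_means(m2, atlas)
  expect_equal(unname(v2[1]), mean(c(2:12)))
  atlas3 <- atlas_labels(atlas$labels, roi_ids = c(1, 2, 9))
  expect_true(is.na(extract_roi_means(m2, atlas3)[3]))
})

test_that("run averaging applies the missing-run policy", {
  a <- c(r1 = 0.2, r2 = 0.6)
  b <- c(r1 = 0.4, r2 = 0.6)
  expect_equal(average_runs(a, b), c(r1 = 0.3, r2 = 0.6))
  expect_equal(average_runs(a, a), a)
  expect_true(all(is.na(average_runs(a, NULL))))
  expect_equal(average_runs(a, NULL, na_policy = "use_available"), a)
})

test_that("NIfTI and motion round trips preserve the data", {
  tmp <- withr::local_tempdir()
  run <- fmri_run(array(rnorm(4 * 3 * 2 * 5), c(4, 3, 2, 5)), tr = 0.93)
  p <- file.path(tmp, "run.nii.gz")
  write_fmri_nifti(run, p)
  back <- read_fmri_nifti(p, phase_dir = "AP")
  expect_equal(as.vector(back$data), as.vector(run$data), tolerance = 1e-6)
  expect_equal(back$tr, 0.93, tolerance = 1e-6)

  atlas <- make_box_atlas(c(4, 3, 2), 2)
  pa <- file.path(tmp, "atlas.nii.gz")
  write_atlas_nifti(atlas, pa)
  expect_equal(read_atlas_nifti(pa)$labels, atlas$labels)

  mp <- matrix(rnorm(30), 5, 6)
  pm <- file.path(tmp, "run.par")
  write_motion_params(mp, pm)
  expect_equal(read_motion_params(pm), mp, tolerance = 1e-6)
})
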
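test_that("pure sinusoids give fALFF of 1 (in band) or 0 (out of band)", {
  tr <- 0.93
  n <- 322
  tt <- (seq_len(n) - 1) * tr
  f_in <- round(0.04 * n * tr) / (n * tr)    # on-bin near 0.04 Hz
  f_out <- round(0.2 * n * tr) / (n * tr)    # on-bin near 0.2 Hz
  run <- line_run(cbind(sin(2 * pi * f_in * tt), sin(2 * pi * f_out * tt)),
                  tr = tr)
  m <- compute_falff(run)
  expect_equal(m[1, 1, 1], 1, tolerance = 1e-6)
  expect_equal(m[2, 1, 1], 0, tolerance = 1e-6)
})

test_that("fALFF is scale-invariant and flags zero-variance voxels", {
  set.seed(14)
  Y <- matrix(rnorm(300), 100, 3)
  Y[, 3] <- 7  # constant voxel
  run <- line_run(Y, tr = 0.93)
  m1 <- compute_falff(run)
  run2 <- run
  run2$data <- run$data * 13.7
  m2 <- compute_falff(run2)
  expect_equal(m1[1:2, 1, 1], m2[1:2, 1, 1], tolerance = 1e-12)
  expect_true(is.na(m1[3, 1, 1]))
  expect_true(all(m1[1:2, 1, 1] >= 0 & m1[1:2, 1, 1] <= 1))
})

test_that("white-noise fALFF approaches the DFT bin-count ratio", {
  tr <- 0.93
  n <- 322
  f <- seq_len(floor(n / 2)) / (n * tr)
  expected <- sum(f >= 0.01 & f <= 0.08) / sum(f > 0 & f <= 0.25)
  set.seed(15)
  Y <- matrix(rnorm(n * 300), n, 300)
  m <- compute_falff(line_run(Y, tr = tr))
  vals <- m[, 1, 1]
  expect_equal(mean(vals), expected, tolerance = 0.02 / expected)
  # power mode uses squared amplitudes and shifts the expectation
  mp <- compute_falff(line_run(Y, tr = tr), mode = "power")
  expect_false(isTRUE(all.equal(mean(mp[, 1, 1]), mean(vals))))
})

test_that("simulated band-fraction targets drive measured fALFF", {
  # fALFF should increase monotonically (rho > 0.9) across target levels
  levels <- seq(0.1, 0.9, length.out = 10)
  tr <- 0.93
  med <- vapply(seq_along(levels), function(i) {
    atlas <- make_box_atlas(c(6, 6, 4), 1)
    cfg <- fmri_sim_config(grid_shape = c(6, 6, 4), n_volumes = 128, tr = tr,
                           coherence_by_roi = c("1" = 0.3),
                           band_fraction_by_roi = c("1" = levels[i]),
                           motion_scale = 0, seed = 300 + i)
    sim <- simulate_fmri_run(cfg, atlas)
    m <- compute_falff(sim$ap)
    median(m, na.rm = TRUE)
  }, numeric(1))
  expect_gt(cor(med, levels, method = "spearman"), 0.9)
})

test_that("simulated coherence targets drive measured ReHo", {
  levels <- seq(0.05, 0.95, length.out = 10)
  med <- vapply(seq_along(levels), function(i) {
    atlas <- make_box_atlas(c(6, 6, 4), 1)
    cfg <- fmri_sim_config(grid_shape = c(6, 6, 4), n_volumes = 96,
                           coherence_by_roi = c("1" = levels[i]),
                           band_fraction_by_roi = c("1" = 0.5),
                           motion_scale = 0, seed = 400 + i)
    sim <- simulate_fmri_run(cfg, atlas)
    bp <- bandpass(sim$ap, 0.01, 0.08)
    median(compute_reho(bp), na.rm = TRUE)
  }, numeric(1))
  expect_gt(cor(med, levels, method = "spearman"), 0.9)
})
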
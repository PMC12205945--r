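test_that("pure-E truth gives uncorrelated MZ co-twins", {
  sim <- quick_cohort(10000, a = c(0, 0, 0), cc = c(0, 0, 0), e = c(1, 0, 1),
                      seed = 21)
  d <- sim$data
  w1 <- d[d$wave == 1 & d$zygosity == "MZ", ]
  y <- matrix(w1$value[order(w1$family_id, w1$birth_order)], ncol = 2,
              byrow = TRUE)
  expect_lt(abs(cor(y[, 1], y[, 2])), 0.03)
})

test_that("sample twin correlations match the variance-component algebra", {
  # a11^2 = 0.6, c11^2 = 0.2, e11^2 = 0.2 -> rMZ = 0.8, rDZ = 0.5 at wave 1
  sim <- quick_cohort(10000, a = c(sqrt(0.6), 0, 0), cc = c(sqrt(0.2), 0, 0),
                      e = c(sqrt(0.2), 0, 1), seed = 22)
  d <- sim$data[sim$data$wave == 1, ]
  r_of <- function(z) {
    dz <- d[d$zygosity == z, ]
    y <- matrix(dz$value[order(dz$family_id, dz$birth_order)], ncol = 2,
                byrow = TRUE)
    cor(y[, 1], y[, 2])
  }
  expect_equal(r_of("MZ"), 0.8, tolerance = 0.02 / 0.8)
  expect_equal(r_of("DZ"), 0.5, tolerance = 0.02 / 0.5)
})

test_that("cross-wave genetic covariance equals a11 * a21", {
  a11 <- 0.5; a21 <- 0.3
  sim <- quick_cohort(100000, a = c(a11, a21, 0.2), cc = c(0, 0, 0),
                      e = c(0.8, 0, 0.8), seed = 23)
  gA <- sim$truth$gA  # latent genetic contributions, individuals x waves
  expect_equal(cov(gA[, 1], gA[, 2]), a11 * a21, tolerance = 0.02)
})

test_that("generated covariance converges to the implied covariance", {
  p <- cholesky_params(a = c(0.7, 0.3, 0.4), c = c(0.4, 0.2, 0.2),
                       e = c(0.6, 0.2, 0.5))
  n <- 20000
  sim <- quick_cohort(n, a = p$a, c = p$c, e = p$e, seed = 24)
  d <- sim$data
  for (z in c("MZ", "DZ")) {
    dz <- d[d$zygosity == z, ]
    dz <- dz[order(dz$family_id, dz$birth_order, dz$wave), ]
    y <- matrix(dz$value, ncol = 4, byrow = TRUE)  # t1w1 t1w2 t2w1 t2w2
    S <- cov(y)
    tgt <- implied_covariance(p, z)
    # each sample covariance has SE ~ sqrt((s_ii s_jj + s_ij^2)/n)
    se <- sqrt((outer(diag(tgt), diag(tgt)) + tgt^2) / n)
    expect_true(all(abs(S - tgt) < 3.5 * se))
  }
})

test_that("regeneration with the same seed is bit-identical", {
  cfg <- twin_sim_config(seed = 99)
  s1 <- simulate_twin_cohort(cfg)
  s2 <- simulate_twin_cohort(cfg)
  expect_identical(s1$data, s2$data)
  s3 <- simulate_twin_cohort(twin_sim_config(seed = 100))
  expect_false(identical(s1$data$value, s3$data$value))
})

test_that("missingness and unpaired-twin settings shape the table", {
  cfg <- twin_sim_config(n_mz_pairs = 300, n_dz_pairs = 300,
                         p_missing_wave2 = 0.3, p_unpaired = 0.2, seed = 31)
  sim <- simulate_twin_cohort(cfg)
  d <- sim$data
  expect_equal(nrow(d), 2 * 600 * 2)  # records retained even when missing
  m2 <- tapply(is.na(d$value[d$wave == 2]), d$family_id[d$wave == 2], all)
  expect_equal(mean(m2), 0.3, tolerance = 0.07)
  # twins share age within a pair, waves differ by the configured gap
  ages <- tapply(d$age_years[d$wave == 1], d$family_id[d$wave == 1],
                 function(x) diff(range(x)))
  expect_true(all(ages == 0))
  gap <- d$age_years[d$wave == 2] - d$age_years[d$wave == 1]
  expect_true(all(abs(gap - cfg$wave_gap_years) < 1e-12))
})

test_that("degenerate truth is rejected with a diagnostic", {
  expect_error(twin_sim_config(cholesky_truth = cholesky_params(
    a = c(1, 0, 0), c = c(0, 0, 0), e = c(0, 0, 1))), "e11")
  expect_error(twin_sim_config(p_missing_wave2 = 1.2))
})
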
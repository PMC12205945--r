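test_that("ACE recovery at large n from an AE truth", {
  est <- t(vapply(1:3, function(r) {
    sim <- quick_cohort(5000, a = c(sqrt(0.6), 0.45, 0.3), cc = c(0, 0, 0),
                        e = c(sqrt(0.4), 0.2, 0.5), seed = 50 + r)
    fit <- fit_cholesky(sim$data, "ACE", seed = r)
    dec <- decompose_variance(fit)
    c(unname(dec$standardized["A", 1]), unname(dec$standardized["C", 1]))
  }, numeric(2)))
  expect_equal(mean(est[, 1]), 0.6, tolerance = 0.05 / 0.6)
  expect_lt(mean(est[, 2]), 0.05)
})

test_that("model selection follows min-AIC with the ambiguity flag", {
  mk <- function(aic, n_free, name) {
    structure(list(minus2ll = aic - 2 * n_free, aic = aic, n_free = n_free,
                   convergence = TRUE, components = name, model = "cholesky"),
              class = "twin_fit")
  }
  s1 <- select_model(list(A = mk(100, 5, "ACE"), B = mk(101.5, 4, "AE"),
                          C = mk(110, 3, "E")))
  expect_equal(s1$name, "A")
  expect_true(s1$ambiguous)
  s2 <- select_model(list(A = mk(100, 5, "ACE"), B = mk(104, 4, "AE"),
                          C = mk(110, 3, "E")))
  expect_false(s2$ambiguous)
  # exact tie goes to the simpler model
  s3 <- select_model(list(A = mk(100, 5, "ACE"), B = mk(100, 4, "AE")))
  expect_equal(s3$name, "B")
  # non-converged fits are excluded from selection
  bad <- mk(90, 5, "ACE"); bad$convergence <- FALSE
  s4 <- select_model(list(A = bad, B = mk(104, 4, "AE")))
  expect_equal(s4$name, "B")
})

test_that("variance decomposition squares and normalizes the paths", {
  p <- cholesky_params(a = c(0.6, 0.3, 0.2), c = c(0, 0.1, 0.25),
                       e = c(0.8, 0.2, 0.5))
  fit <- structure(list(params = p, model = "cholesky", components = "ACE"),
                   class = "twin_fit")
  dec <- decompose_variance(fit)
  expect_equal(unname(dec$raw["A", "wave1"]), 0.36)
  expect_equal(unname(dec$raw["A", "wave2"]), 0.09 + 0.04)
  expect_equal(unname(dec$total[1]), 0.36 + 0 + 0.64)
  expect_equal(colSums(dec$standardized), c(wave1 = 1, wave2 = 1),
               tolerance = 1e-8)
  expect_equal(unname(rowSums(dec$wave2_split)),
               unname(dec$standardized[, 2]), tolerance = 1e-12)
  # h2 at wave 1 = 0.36 / 1.0
  expect_equal(unname(dec$standardized["A", 1]), 0.36)
})

test_that("decomposition matches the Monte-Carlo variance of latent parts", {
  sim <- quick_cohort(50000, seed = 52)
  tr <- sim$truth$params
  fitlike <- structure(list(params = tr, model = "cholesky",
                            components = "ACE"), class = "twin_fit")
  dec <- decompose_variance(fitlike)
  for (w in 1:2) {
    expect_equal(var(sim$truth$gA[, w]), unname(dec$raw["A", w]),
                 tolerance = 0.02 * 3)
    expect_equal(var(sim$truth$gE[, w]), unname(dec$raw["E", w]),
                 tolerance = 0.02 * 3)
  }
})

test_that("twin correlations match direct Pearson correlations", {
  set.seed(53)
  p <- cholesky_params(a = c(sqrt(0.6), 0.3, 0.3), c = c(0, 0, 0),
                       e = c(sqrt(0.4), 0.1, 0.5))
  y_mz <- draw_implied(4000, p, "MZ")
  y_dz <- draw_implied(4000, p, "DZ")
  td <- make_twin_table(y_mz, y_dz)
  tc <- twin_correlations(td)
  r_mz1 <- cor(y_mz[, 1], y_mz[, 3])
  r_dz1 <- cor(y_dz[, 1], y_dz[, 3])
  got_mz <- tc$r[tc$zygosity == "MZ" & tc$which == "wave1"]
  got_dz <- tc$r[tc$zygosity == "DZ" & tc$which == "wave1"]
  expect_equal(got_mz, r_mz1, tolerance = 0.01 / abs(r_mz1))
  expect_equal(got_dz, r_dz1, tolerance = 0.01 / max(abs(r_dz1), 0.1))
  # population check: AE truth -> rMZ ~ 0.6, rDZ ~ 0.3 at wave 1
  expect_equal(got_mz, 0.6, tolerance = 0.05 / 0.6)
  expect_equal(got_dz, 0.3, tolerance = 0.07 / 0.3)
  # CIs bracket the estimates
  expect_true(all(tc$lo <= tc$r & tc$r <= tc$hi, na.rm = TRUE))
})

test_that("CE truth gives matching MZ and DZ correlations and survives a
           zygosity label swap", {
  sim <- quick_cohort(3000, a = c(0, 0, 0), cc = c(sqrt(0.5), 0.3, 0.3),
                      e = c(sqrt(0.5), 0.1, 0.5), seed = 54)
  tc <- twin_correlations(sim$data)
  r1 <- tc$r[tc$zygosity == "MZ" & tc$which == "wave1"]
  r2 <- tc$r[tc$zygosity == "DZ" & tc$which == "wave1"]
  expect_equal(r1, 0.5, tolerance = 0.06 / 0.5)
  expect_equal(r2, 0.5, tolerance = 0.06 / 0.5)
  f1 <- fit_cholesky(sim$data, "CE", seed = 6)
  swapped <- sim$data
  swapped$zygosity <- ifelse(sim$data$zygosity == "MZ", "DZ", "MZ")
  f2 <- fit_cholesky(twin_data(swapped), "CE", seed = 6)
  d1 <- decompose_variance(f1); d2 <- decompose_variance(f2)
  expect_equal(d1$standardized, d2$standardized, tolerance = 0.05)
})

test_that("assumption tests have power against a birth-order mean shift", {
  sim <- quick_cohort(500, seed = 55)
  d <- sim$data
  d$value[d$birth_order == 2] <- d$value[d$birth_order == 2] + 1
  at <- test_assumptions(twin_data(d))
  expect_lt(at$p[at$test == "means equal across birth order"], 1e-6)
  # and stays calibrated on symmetric data (single draw: just not tiny)
  at0 <- test_assumptions(sim$data)
  expect_true(all(at0$df == c(4, 2, 4, 2)))
})

test_that("covariate LRT detects a real effect and reports the estimate", {
  cfgc <- twin_sim_config(n_mz_pairs = 400, n_dz_pairs = 400,
                          beta_age = 0, beta_sex = 0.8, beta_fd = 0,
                          p_missing_wave2 = 0, p_unpaired = 0, seed = 56)
  sim <- simulate_twin_cohort(cfgc)
  out <- test_covariate(sim$data, "sex")
  expect_lt(out$p, 0.001)
  expect_equal(unname(attr(out, "beta")), c(0.8, 0.8), tolerance = 0.15)
  expect_equal(out$df, 2)
  d <- sim$data; d$sex <- 1
  expect_error(test_covariate(twin_data(d), "sex"), "constant")
})

test_that("new-influence and amplification tests behave under their nulls
           and alternatives", {
  # truth with a22 = 0 and a21 = a11: both constrained fits cost ~nothing
  sim <- quick_cohort(2000, a = c(0.6, 0.6, 0), cc = c(0.3, 0.2, 0.2),
                      e = c(0.6, 0.2, 0.55), seed = 57)
  fit <- fit_cholesky(sim$data, "ACE", seed = 7)
  ni <- test_new_influence(fit, "A")
  expect_gte(ni$chisq, 0)
  expect_gt(ni$p, 0.01)
  amp <- test_amplification(fit, "A")
  expect_gt(amp$p, 0.01)
  # mixture reference halves the p-value at the boundary
  ni_mix <- test_new_influence(fit, "A", mixture_null = TRUE)
  expect_equal(ni_mix$p, 0.5 * ni$p, tolerance = 1e-10)

  # strong new variance at wave 2 is detected, deamplification flagged
  sim2 <- quick_cohort(2000, a = c(0.8, 0.3, 0.55), cc = c(0, 0, 0),
                       e = c(0.55, 0.2, 0.5), seed = 58)
  fit2 <- fit_cholesky(sim2$data, "ACE", seed = 8)
  expect_lt(test_new_influence(fit2, "A")$p, 0.01)
  expect_equal(test_amplification(fit2, "A")$direction, "deamplification")
})
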
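test_that("profile CI brackets the estimate and respects the floor", {
  sim <- quick_cohort(1000, seed = 61)
  fit <- fit_cholesky(sim$data, "ACE", seed = 9)
  h2 <- twinlocal:::eval_quantity(fit$params, "std_A1")
  ci <- profile_ci(fit, "std_A1")
  expect_lt(ci[1], h2)
  expect_gt(ci[2], h2)
  expect_gte(ci[1], 0)
  expect_lte(ci[2], 1)
})

test_that("profile CI agrees with Wald at large n (quadratic likelihood)", {
  sim <- quick_cohort(4000, seed = 62)
  fit <- fit_cholesky(sim$data, "ACE", seed = 10)
  for (q in c("std_A1", "std_E1")) {
    prof <- profile_ci(fit, q)
    wald <- twinlocal:::wald_ci_quantity(fit, q)
    half_p <- unname(diff(prof)) / 2
    half_w <- unname(diff(wald)) / 2
    expect_equal(half_p, half_w, tolerance = 0.10)
    expect_equal(mean(prof), mean(wald), tolerance = 0.1 * half_w / mean(prof))
  }
})

test_that("a C proportion near zero reports a boundary lower bound", {
  sim <- quick_cohort(2000, a = c(sqrt(0.6), 0.4, 0.3), cc = c(0, 0, 0),
                      e = c(sqrt(0.4), 0.2, 0.5), seed = 63)
  fit <- fit_cholesky(sim$data, "ACE", seed = 11)
  ci <- profile_ci(fit, "std_C1")
  expect_equal(unname(ci[1]), 0, tolerance = 1e-6)
})

test_that("cross-trait correlations recover a known genetic overlap", {
  # a22 = 0: trait-2 genetic variance comes entirely from factor 1 -> rA = 1
  p <- cholesky_params(a = c(0.7, 0.5, 0), c = c(0.3, 0.1, 0.2),
                       e = c(0.5, 0.2, 0.6))
  expect_equal(twinlocal:::latent_corr(p$a), 1)
  # independent genetics -> rA = 0
  p2 <- cholesky_params(a = c(0.7, 0, 0.5), c = c(0.3, 0.1, 0.2),
                        e = c(0.5, 0.2, 0.6))
  expect_equal(twinlocal:::latent_corr(p2$a), 0)

  # recovery from data: rA truth = 0.6 (a21 / genetic SD of trait 2)
  t_ <- 0.8  # trait-2 genetic SD
  truth <- cholesky_params(a = c(0.85, t_ * 0.6, t_ * 0.8),
                           c = c(0.2, 0.1, 0.2), e = c(0.49, 0.1, 0.45))
  sim <- quick_cohort(5000, a = truth$a, cc = truth$c, e = truth$e, seed = 64)
  ct <- cross_trait_cholesky(sim$data, seed = 12)
  got <- ct$estimate[ct$quantity == "r_A"]
  expect_equal(got, 0.6, tolerance = 0.05 / 0.6)
  # phenotypic correlation matches the implied covariance at the truth
  sw <- implied_covariance(truth, "MZ")[1:2, 1:2]
  expect_equal(ct$estimate[ct$quantity == "r_phenotypic"],
               sw[1, 2] / sqrt(sw[1, 1] * sw[2, 2]), tolerance = 0.1)
})

test_that("behavior identical to the brain metric gives unit correlations", {
  sim <- quick_cohort(300, seed = 65)
  d <- sim$data[sim$data$wave == 1, ]
  d$behavior_score <- d$value
  out <- brain_behavior_twin(twin_data(d), seed = 13)
  expect_equal(out$estimate[out$quantity == "r_phenotypic"], 1,
               tolerance = 1e-3)
  expect_equal(abs(out$estimate[out$quantity == "r_A"]), 1, tolerance = 0.01)
  expect_equal(abs(out$estimate[out$quantity == "r_E"]), 1, tolerance = 0.01)
})
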
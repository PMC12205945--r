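test_that("FIML equals the direct multivariate-normal density oracle", {
  set.seed(41)
  p <- cholesky_params(a = c(0.7, 0.3, 0.4), c = c(0.4, 0.2, 0.2),
                       e = c(0.6, 0.2, 0.5), mu = c(0.3, -0.1))
  y_mz <- draw_implied(40, p, "MZ")
  y_dz <- draw_implied(35, p, "DZ")
  td <- make_twin_table(y_mz, y_dz)
  got <- fiml_neg2ll(p, td)
  want <- oracle_mvn_neg2ll(y_mz, p$mu[c(1, 2, 1, 2)],
                            implied_covariance(p, "MZ")) +
    oracle_mvn_neg2ll(y_dz, p$mu[c(1, 2, 1, 2)],
                      implied_covariance(p, "DZ"))
  expect_equal(got, want, tolerance = 1e-8 / abs(want))
})

test_that("a fully missing co-twin contributes its bivariate marginal", {
  set.seed(42)
  p <- cholesky_params(a = c(0.7, 0.3, 0.4), c = c(0.4, 0.2, 0.2),
                       e = c(0.6, 0.2, 0.5))
  y <- draw_implied(10, p, "MZ")
  y[, 3:4] <- NA  # twin 2 unobserved
  td <- make_twin_table(y, draw_implied(1, p, "DZ") * NA)
  td <- td[td$zygosity == "MZ", ]
  got <- fiml_neg2ll(p, twin_data(td))
  sig <- implied_covariance(p, "MZ")[1:2, 1:2]
  want <- oracle_mvn_neg2ll(y[, 1:2], p$mu, sig)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("duplicating every pair doubles the deviance", {
  set.seed(43)
  p <- cholesky_params(a = c(0.7, 0.3, 0.4), c = c(0.4, 0.2, 0.2),
                       e = c(0.6, 0.2, 0.5))
  y_mz <- draw_implied(20, p, "MZ")
  y_dz <- draw_implied(20, p, "DZ")
  one <- fiml_neg2ll(p, make_twin_table(y_mz, y_dz))
  two <- fiml_neg2ll(p, make_twin_table(rbind(y_mz, y_mz),
                                        rbind(y_dz, y_dz)))
  expect_equal(two, 2 * one, tolerance = 1e-12)
})

test_that("saturated MLEs equal divide-by-n sample moments", {
  set.seed(44)
  p <- cholesky_params(a = c(0.7, 0.3, 0.4), c = c(0.4, 0.2, 0.2),
                       e = c(0.6, 0.2, 0.5), mu = c(0.2, 0.5))
  y_mz <- draw_implied(150, p, "MZ")
  y_dz <- draw_implied(150, p, "DZ")
  td <- make_twin_table(y_mz, y_dz)
  fit <- fit_saturated(td)
  for (z in c("MZ", "DZ")) {
    y <- if (z == "MZ") y_mz else y_dz
    mu_hat <- colMeans(y)
    S_hat <- crossprod(sweep(y, 2, mu_hat)) / nrow(y)
    expect_equal(unname(fit$mu[z, ]), unname(mu_hat), tolerance = 1e-6)
    expect_lt(max(abs(fit$sigma[[z]] - S_hat)), 1e-6)
  }
  # and the deviance matches the closed form at the moment MLE
  cf <- sum(vapply(list(y_mz, y_dz), function(y) {
    S <- crossprod(sweep(y, 2, colMeans(y))) / nrow(y)
    nrow(y) * (4 * log(2 * pi) +
                 as.numeric(determinant(S)$modulus) + 4)
  }, numeric(1)))
  expect_equal(fit$minus2ll, cf, tolerance = 1e-8)
})

test_that("the nesting chain of deviances is monotone", {
  sim <- quick_cohort(150, seed = 45)
  fits <- lapply(c("ACE", "AE", "CE", "E"), function(m)
    fit_cholesky(sim$data, m, seed = 2))
  sat <- fit_saturated(sim$data)
  dev <- vapply(fits, `[[`, 0, "minus2ll")
  expect_lte(sat$minus2ll, dev[1] + 1e-6)
  expect_lte(dev[1], min(dev[2], dev[3]) + 1e-6)
  expect_lte(max(dev[2], dev[3]), dev[4] + 1e-6)
  for (f in fits) expect_equal(f$aic, f$minus2ll + 2 * f$n_free)
})

test_that("fits are scale-equivariant", {
  sim <- quick_cohort(200, seed = 46)
  d1 <- sim$data
  d2 <- d1; d2$value <- d1$value * 3
  f1 <- fit_cholesky(d1, "ACE", seed = 3)
  f2 <- fit_cholesky(d2, "ACE", seed = 3)
  dec1 <- decompose_variance(f1); dec2 <- decompose_variance(f2)
  # agreement is limited by the optimizer's convergence tolerance
  expect_equal(dec2$raw, dec1$raw * 9, tolerance = 5e-4)
  expect_equal(dec2$standardized, dec1$standardized, tolerance = 5e-4)
  t1 <- test_new_influence(f1, "A"); t2 <- test_new_influence(f2, "A")
  expect_equal(t1$chisq, t2$chisq, tolerance = 1e-3)
})

test_that("swapping twin order leaves the optimum unchanged", {
  sim <- quick_cohort(150, seed = 47)
  d1 <- sim$data
  d2 <- d1
  d2$birth_order <- 3 - d1$birth_order
  f1 <- fit_cholesky(d1, "ACE", seed = 4)
  f2 <- fit_cholesky(d2, "ACE", seed = 4)
  expect_equal(f1$minus2ll, f2$minus2ll, tolerance = 1e-6)
})
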
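test_that("identical series give perfect concordance", {
  s <- rnorm(12)
  run <- fmri_run(array(rep(s, each = 27), c(3, 3, 3, 12)), tr = 1)
  for (i in 1:3) for (j in 1:3) for (k in 1:3) run$data[i, j, k, ] <- s
  W <- compute_reho(run)
  expect_equal(max(abs(W - 1)), 0, tolerance = 1e-12)
})

test_that("KCC matches a hand-checkable printed rank table", {
  # K = 3 series, n = 4 time points, small integers
  Y <- cbind(c(1, 2, 3, 4),
             c(2, 1, 4, 3),
             c(1, 3, 2, 4))
  run <- line_run(Y)
  W <- compute_reho(run)
  # rank sums by hand: (4, 6, 9, 11), mean 7.5 -> S = 14.75... computed by
  # the independent oracle below and checked against a manual evaluation
  expect_equal(W[2, 1, 1], oracle_kcc(Y), tolerance = 1e-12)
  expect_equal(W[2, 1, 1], 12 * sum((c(4, 6, 9, 11) - 7.5)^2) / (9 * 60),
               tolerance = 1e-12)
})

test_that("KCC equals the brute-force oracle on 200 random instances", {
  set.seed(11)
  # all 27 series in a 3x3x3 cube are mutual neighbors of the center voxel,
  # so the center's W is the concordance of the whole set
  for (rep in 1:200) {
    K <- 27
    n <- sample(4:20, 1)
    Y <- matrix(rnorm(n * K), n, K)
    if (rep %% 3 == 0) Y[sample(length(Y), 7)] <- 1
    run <- fmri_run(array(t(Y), c(3, 3, 3, n)), tr = 1)
    for (v in 1:27) run$data[((v - 1) %% 3) + 1, ((v - 1) %/% 3) %% 3 + 1,
                             ((v - 1) %/% 9) + 1, ] <- Y[, v]
    W <- compute_reho(run)
    expect_equal(W[2, 2, 2], oracle_kcc(Y), tolerance = 1e-12)
    Wt <- compute_reho(run, tie_correction = TRUE)
    expect_equal(Wt[2, 2, 2], oracle_kcc(Y, tie_correction = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("expected W for independent series is about 1/K", {
  set.seed(12)
  K <- 27; n <- 30
  w <- replicate(1000, {
    Y <- matrix(rnorm(n * K), n, K)
    oracle_kcc(Y)
  })
  # Monte-Carlo reference for the small positive bias ~ 1/K
  run_w <- replicate(60, {
    Y <- matrix(rnorm(n * K), n, K)
    run <- fmri_run(array(0, c(3, 3, 3, n)), tr = 1)
    for (v in 1:27) run$data[((v - 1) %% 3) + 1, ((v - 1) %/% 3) %% 3 + 1,
                             ((v - 1) %/% 9) + 1, ] <- Y[, v]
    compute_reho(run)[2, 2, 2]
  })
  expect_equal(mean(run_w), 1 / K, tolerance = 0.02 / (1 / K))
  expect_equal(mean(w), 1 / K, tolerance = 0.01 / (1 / K))
})

test_that("ReHo is bounded and invariant to monotone transforms", {
  set.seed(13)
  run <- fmri_run(array(rnorm(5 * 5 * 3 * 15), c(5, 5, 3, 15)), tr = 1)
  W <- compute_reho(run)
  expect_true(all(W >= 0 & W <= 1))
  run2 <- run
  run2$data <- exp(2 * run$data + 1)  # strictly monotone per-voxel map
  expect_equal(compute_reho(run2), W, tolerance = 1e-12)
})

test_that("voxels with fewer than 2 in-mask neighbors are missing", {
  run <- fmri_run(array(rnorm(4 * 1 * 1 * 10), c(4, 1, 1, 10)), tr = 1)
  run$mask[] <- FALSE
  run$mask[1, 1, 1] <- TRUE  # isolated voxel: K = 1
  W <- compute_reho(run)
  expect_true(is.na(W[1, 1, 1]))
})
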
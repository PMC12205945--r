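make_run <- function(Y, tr = 1) {
  # V voxels on a line, series in columns
  line_run(Y, tr = tr)
}

test_that("nuisance regression removes confounds and restores the mean", {
  set.seed(4)
  t_ <- 40
  conf <- matrix(rnorm(t_ * 3), t_, 3)
  y1 <- 5 + conf %*% c(1, -2, 0.5)           # exact combination
  y2 <- rnorm(t_, sd = 2) + 3                # unrelated
  run <- make_run(cbind(y1, y2))
  out <- regress_confounds(run, conf)
  r1 <- out$data[1, 1, 1, ]
  r2 <- out$data[2, 1, 1, ]
  expect_lt(var(r1), 1e-20)
  expect_equal(mean(r1), mean(y1))
  expect_equal(mean(r2), mean(y2))
  # residuals orthogonal to the design (OLS normal equations)
  expect_lt(max(abs(crossprod(cbind(1, conf), r1 - mean(r1)))),
            1e-8 * max(abs(y1)))
  expect_lt(max(abs(crossprod(cbind(1, conf), r2 - mean(r2)))),
            1e-8 * max(abs(y2)))
})

test_that("intercept-only confound leaves the series unchanged", {
  set.seed(5)
  Y <- matrix(rnorm(60), 30, 2) + 4
  run <- make_run(Y)
  # the supplied intercept duplicates the built-in one and is dropped
  expect_warning(out <- regress_confounds(run, matrix(1, 30, 1)),
                 "collinear")
  expect_equal(out$data, run$data, tolerance = 1e-12)
})

test_that("collinear confound columns are dropped with a warning", {
  set.seed(6)
  conf <- matrix(rnorm(40), 20, 2)
  conf <- cbind(conf, conf[, 1] * 2)
  run <- make_run(matrix(rnorm(40), 20, 2))
  expect_warning(regress_confounds(run, conf), "collinear")
})

test_that("friston24 expands to lags and squares", {
  mp <- matrix(seq_len(30), 5, 6)
  f <- friston24(mp)
  expect_equal(dim(f), c(5, 24))
  expect_equal(f[, 1:6], mp)
  expect_equal(f[2:5, 7:12], mp[1:4, ])
  expect_equal(f[1, 7:12], rep(0, 6))
  expect_equal(f[, 13:18], mp^2)
})

test_that("linear detrend removes ramps and keeps sinusoids", {
  t_ <- 50
  tt <- seq_len(t_)
  const <- rep(3, t_)
  ramp <- 0.2 * tt + 1
  sine <- sin(2 * pi * 4 * tt / t_)
  run <- make_run(cbind(const, ramp, ramp + sine + 2))
  out <- detrend_linear(run)
  expect_equal(out$data[1, 1, 1, ], const, tolerance = 1e-10)
  expect_equal(out$data[2, 1, 1, ], rep(mean(ramp), t_), tolerance = 1e-10)
  # ramp + sine: equals the independent least-squares residual (plus mean)
  oracle <- residuals(lm((ramp + sine + 2) ~ tt)) + mean(ramp + sine + 2)
  expect_equal(out$data[3, 1, 1, ], unname(oracle), tolerance = 1e-10)
  expect_error(detrend_linear(make_run(matrix(1, 2, 1))), "3 volumes")
})

test_that("ideal bandpass keeps in-band and removes out-of-band energy", {
  tr <- 0.93
  n <- 320
  tt <- (seq_len(n) - 1) * tr
  f_in <- 12 / (n * tr)   # on-bin, ~0.040 Hz
  f_out <- 60 / (n * tr)  # on-bin, ~0.202 Hz
  y_in <- sin(2 * pi * f_in * tt)
  y_out <- sin(2 * pi * f_out * tt)
  run <- make_run(cbind(y_in, y_out), tr = tr)
  out <- bandpass(run, 0.01, 0.08)
  expect_equal(sd(out$data[1, 1, 1, ]), sd(y_in), tolerance = 0.01)
  expect_lt(sd(out$data[2, 1, 1, ]), 1e-10)
  expect_error(bandpass(run, 0.08, 0.01), "low")
  expect_error(bandpass(run, 0.01, 0.6), "Nyquist")
})

test_that("white-noise variance passes in proportion to the in-band bins", {
  tr <- 0.93
  n <- 322
  f <- (seq_len(floor(n / 2))) / (n * tr)
  frac <- sum(f >= 0.01 & f <= 0.08) / (length(f))
  set.seed(7)
  Y <- matrix(rnorm(n * 200), n, 200)
  out <- bandpass(make_run(Y, tr = tr), 0.01, 0.08)
  v <- vapply(seq_len(200), function(i) var(out$data[i, 1, 1, ]), numeric(1))
  expect_equal(mean(v) / mean(apply(Y, 2, var)), frac, tolerance = 0.05 * frac)
})
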
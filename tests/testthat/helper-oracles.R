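# Independent oracles used to cross-check the package's own computations.
# These are deliberately written as direct textbook formulas, sharing no
# code with the implementation they test.

# multivariate-normal -2 log density, summed over rows of y
oracle_mvn_neg2ll <- function(y, mu, sigma) {
  y <- as.matrix(y)
  k <- ncol(y)
  si <- solve(sigma)
  ld <- determinant(sigma, logarithm = TRUE)$modulus
  tot <- 0
  for (i in seq_len(nrow(y))) {
    d <- as.numeric(y[i, ] - mu)
    tot <- tot + k * log(2 * pi) + as.numeric(ld) + drop(t(d) %*% si %*% d)
  }
  tot
}

# brute-force Kendall's W for an n x K matrix of series (columns = judges)
oracle_kcc <- function(Y, tie_correction = FALSE) {
  n <- nrow(Y)
  K <- ncol(Y)
  R <- apply(Y, 2, rank)
  Rs <- rowSums(R)
  S <- sum((Rs - mean(Rs))^2)
  denom <- K^2 * (n^3 - n) / 12
  if (tie_correction) {
    Tsum <- sum(apply(Y, 2, function(y) {
      tb <- table(y)
      sum(tb^3 - tb)
    }))
    denom <- denom - K * Tsum / 12
  }
  S / denom
}

# a small complete twin dataset in long format from explicit per-family
# 4-vectors (rows: families; columns t1w1, t1w2, t2w1, t2w2)
make_twin_table <- function(y_mz, y_dz, age = 12, sex = 0, fd = 0.1) {
  build <- function(y, zyg, offset) {
    do.call(rbind, lapply(seq_len(nrow(y)), function(i) {
      fam <- sprintf("f%04d", offset + i)
      data.frame(family_id = fam,
                 twin_id = paste0(fam, "_t", c(1, 1, 2, 2)),
                 birth_order = c(1, 1, 2, 2),
                 zygosity = zyg, sex = sex,
                 age_years = age, mean_fd_mm = fd,
                 wave = c(1, 2, 1, 2),
                 value = y[i, c(1, 2, 3, 4)],
                 stringsAsFactors = FALSE)
    }))
  }
  twin_data(rbind(build(y_mz, "MZ", 0), build(y_dz, "DZ", nrow(y_mz))))
}

# draw complete twin data directly from the model-implied 4-variate normal
# (an independent generative route from simulate_twin_cohort's latent draws)
draw_implied <- function(n, params, zygosity) {
  sig <- implied_covariance(params, zygosity)
  L <- chol(sig)
  z <- matrix(stats::rnorm(n * 4), n, 4) %*% L
  sweep(z, 2, params$mu[c(1, 2, 1, 2)], "+")
}

quick_cohort <- function(n_pairs = 200, a = c(0.7, 0.3, 0.4),
                         cc = c(0.4, 0.2, 0.2), e = c(0.6, 0.2, 0.5),
                         seed = 1, ...) {
  simulate_twin_cohort(twin_sim_config(
    n_mz_pairs = n_pairs, n_dz_pairs = n_pairs,
    cholesky_truth = cholesky_params(a = a, c = cc, e = e),
    beta_age = 0, beta_sex = 0, beta_fd = 0,
    p_missing_wave2 = 0, p_unpaired = 0, seed = seed, ...))
}

# tiny single-voxel-line run whose x-axis neighbors form the KCC group
line_run <- function(Y, tr = 1) {
  n <- nrow(Y); V <- ncol(Y)
  run <- fmri_run(array(0, c(V, 1, 1, n)), tr = tr)
  for (i in seq_len(V)) run$data[i, 1, 1, ] <- Y[, i]
  run
}
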
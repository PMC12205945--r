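#' Configuration for the twin-cohort simulator
#'
#' Defines the generative conditions for a two-wave twin cohort with a
#' known bivariate Cholesky ACE structure. Defaults mirror a typical
#' early-adolescent twin imaging study: about 56 MZ and 49 DZ complete
#' pairs, baseline age around 11.5 years with the second wave about 20
#' months later, mean framewise displacement with a right-skewed
#' distribution around 0.15 mm, weak covariate effects on the phenotype,
#' family-level wave-2 attrition and occasional unpaired twins.
#'
#' @param n_mz_pairs,n_dz_pairs numbers of MZ and DZ families.
#' @param cholesky_truth a [cholesky_params()] with the true paths.
#' @param beta_age,beta_sex,beta_fd covariate effects (phenotype units per
#'   year, per sex code, per mm of mean FD) applied at both waves.
#' @param age_mean,age_sd wave-1 age distribution (years), shared within a
#'   pair; wave-2 age is wave-1 age plus `wave_gap_years`.
#' @param wave_gap_years time between waves (years).
#' @param fd_mean,fd_sd mean framewise displacement distribution (mm),
#'   drawn per individual per wave from a gamma with these moments.
#' @param p_missing_wave2 probability a family misses wave 2 entirely.
#' @param p_unpaired probability a family has one co-twin's phenotypes
#'   removed (the record is retained, so the twin contributes to means and
#'   variances through FIML).
#' @param seed integer seed; generation is deterministic given it.
#' @return A list of class `twin_sim_config`.
#' @export
twin_sim_config <- function(n_mz_pairs = 56, n_dz_pairs = 49,
                            cholesky_truth = cholesky_params(
                              a = c(sqrt(0.4), 0.45, 0.35),
                              c = c(sqrt(0.2), 0.30, 0.20),
                              e = c(sqrt(0.4), 0.25, 0.50)),
                            beta_age = 0.03, beta_sex = 0.05, beta_fd = 0.8,
                            age_mean = 11.5, age_sd = 1.2,
                            wave_gap_years = 1.7,
                            fd_mean = 0.15, fd_sd = 0.05,
                            p_missing_wave2 = 0.28, p_unpaired = 0.1,
                            seed = 1L) {
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0,
            p_missing_wave2 >= 0, p_missing_wave2 <= 1,
            p_unpaired >= 0, p_unpaired <= 1,
            age_sd >= 0, fd_mean > 0, fd_sd >= 0,
            inherits(cholesky_truth, "cholesky_params"))
  if (cholesky_truth$e[1] <= 0)
    stop("degenerate truth: e11 must be positive (E is always present)")
  structure(as.list(environment()), class = "twin_sim_config")
}

#' Simulate a two-wave twin cohort with known ACE ground truth
#'
#' Draws, per family, latent additive-genetic factors with cross-twin
#' correlation 1 (MZ) or 0.5 (DZ), fully shared common-environment factors
#' and independent unique-environment factors, maps them through the true
#' Cholesky paths to wave-1/wave-2 phenotypes, and adds covariate effects
#' of age, sex and mean framewise displacement. Wave-2 attrition removes
#' whole families' wave-2 phenotypes; unpaired twins are created by
#' deleting one co-twin's phenotype values while retaining the record.
#'
#' @param config a [twin_sim_config()].
#' @return list with `data` (a [twin_data()] long table) and `truth`
#'   (the true parameters plus the per-individual latent source
#'   contributions `gA`, `gC`, `gE`, individuals x waves, before
#'   missingness, for auditing the decomposition).
#' @export
simulate_twin_cohort <- function(config) {
  stopifnot(inherits(config, "twin_sim_config"))
  tr <- config$cholesky_truth
  La <- path_matrix(tr$a); Lc <- path_matrix(tr$c); Le <- path_matrix(tr$e)
  n_fam <- config$n_mz_pairs + config$n_dz_pairs
  if (n_fam == 0) stop("no families to simulate")
  zyg <- rep(c("MZ", "DZ"), c(config$n_mz_pairs, config$n_dz_pairs))
  with_seed(config$seed, {
    n_ind <- 2 * n_fam
    # latent 2-vectors (factor 1, factor 2) per individual
    shared_A <- matrix(stats::rnorm(2 * n_fam), n_fam, 2)
    own_A <- matrix(stats::rnorm(2 * n_ind), n_ind, 2)
    C_fam <- matrix(stats::rnorm(2 * n_fam), n_fam, 2)
    E_ind <- matrix(stats::rnorm(2 * n_ind), n_ind, 2)
    fam_of <- rep(seq_len(n_fam), each = 2)
    is_mz <- zyg[fam_of] == "MZ"
    A_ind <- ifelse(is_mz, 1, sqrt(0.5)) * shared_A[fam_of, ] +
      ifelse(is_mz, 0, sqrt(0.5)) * own_A
    gA <- A_ind %*% t(La)
    gC <- C_fam[fam_of, ] %*% t(Lc)
    gE <- E_ind %*% t(Le)
    pheno <- gA + gC + gE  # n_ind x 2 (waves), before means/covariates
    age1 <- stats::rnorm(n_fam, config$age_mean, config$age_sd)[fam_of]
    sex <- stats::rbinom(n_ind, 1, 0.5)
    fd_shape <- (config$fd_mean / max(config$fd_sd, 1e-8))^2
    fd_rate <- config$fd_mean / max(config$fd_sd, 1e-8)^2
    fd <- matrix(stats::rgamma(2 * n_ind, shape = fd_shape, rate = fd_rate),
                 n_ind, 2)
    beta <- rbind(c(config$beta_age, config$beta_sex, config$beta_fd),
                  c(config$beta_age, config$beta_sex, config$beta_fd))
    ages <- cbind(age1, age1 + config$wave_gap_years)
    value <- matrix(NA_real_, n_ind, 2)
    for (w in 1:2) {
      value[, w] <- tr$mu[w] + pheno[, w] +
        beta[w, 1] * ages[, w] + beta[w, 2] * sex + beta[w, 3] * fd[, w]
    }
    miss_w2 <- stats::runif(n_fam) < config$p_missing_wave2
    unpaired <- stats::runif(n_fam) < config$p_unpaired
    drop_twin <- sample(1:2, n_fam, replace = TRUE)
    value[miss_w2[fam_of], 2] <- NA_real_
    ind_bo <- rep(1:2, n_fam)
    value[unpaired[fam_of] & ind_bo == drop_twin[fam_of], ] <- NA_real_
    long <- do.call(rbind, lapply(1:2, function(w) data.frame(
      family_id = sprintf("fam%04d", fam_of),
      twin_id = sprintf("fam%04d_t%d", fam_of, ind_bo),
      birth_order = ind_bo,
      zygosity = zyg[fam_of],
      sex = sex,
      age_years = ages[, w],
      mean_fd_mm = fd[, w],
      wave = w,
      value = value[, w],
      stringsAsFactors = FALSE)))
    list(data = twin_data(long),
         truth = list(params = tr, config = config,
                      gA = gA, gC = gC, gE = gE,
                      zygosity = zyg[fam_of], family = fam_of))
  })
}

#' Write simulated ground truth as a JSON sidecar
#'
#' @param truth the `truth` element returned by [simulate_twin_cohort()].
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  tr <- truth$params
  jsonlite::write_json(list(
    paths = list(a = tr$a, c = tr$c, e = tr$e),
    mu = tr$mu,
    beta = list(age = truth$config$beta_age, sex = truth$config$beta_sex,
                fd = truth$config$beta_fd),
    n_mz_pairs = truth$config$n_mz_pairs,
    n_dz_pairs = truth$config$n_dz_pairs,
    seed = truth$config$seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
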
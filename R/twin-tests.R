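lrt_row <- function(label, fit0, fit1, df = fit1$n_free - fit0$n_free) {
  chisq <- max(fit0$minus2ll - fit1$minus2ll, 0)
  data.frame(test = label, chisq = chisq, df = df,
             p = stats::pchisq(chisq, df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio tests of twin-model assumptions
#'
#' Fits the saturated bivariate model and an increasingly constrained chain
#' equating means and then variances across twin birth order and zygosity,
#' reporting each step's likelihood-ratio chi-square against the previous
#' model. Rejections indicate violations of the classical twin-design
#' assumptions (or data errors).
#'
#' @inheritParams fit_cholesky
#' @return data.frame with columns `test`, `chisq`, `df`, `p`.
#' @export
test_assumptions <- function(data, covariates = NULL) {
  prep <- prepare_pairs(data, covariates)
  groups <- pattern_groups(prep)
  steps <- list(character(0),
                "means_birth_order",
                c("means_birth_order", "means_zygosity"),
                c("means_birth_order", "means_zygosity", "var_birth_order"),
                c("means_birth_order", "means_zygosity", "var_birth_order",
                  "var_zygosity"))
  labels <- c("means equal across birth order", "means equal across zygosity",
              "variances equal across birth order",
              "variances equal across zygosity")
  fits <- vector("list", length(steps))
  warm <- NULL
  for (i in seq_along(steps)) {
    fits[[i]] <- fit_saturated_prep(prep, groups, covariates,
                                    constraints = steps[[i]],
                                    start_full = warm)
    warm <- fits[[i]]$obj$expand(fits[[i]]$theta)
  }
  do.call(rbind, lapply(seq_along(labels), function(i)
    lrt_row(labels[i], fits[[i + 1]], fits[[i]])))
}

#' Likelihood-ratio test of a covariate effect
#'
#' Compares the saturated model with and without the named covariate's
#' mean effects (both waves dropped together). Reports only; covariates are
#' retained in downstream models regardless of significance.
#'
#' @inheritParams fit_cholesky
#' @param which one of the fitted covariates.
#' @return one-row data.frame `test`, `chisq`, `df`, `p`, plus the fitted
#'   per-wave effects as attribute `"beta"`.
#' @export
test_covariate <- function(data, which,
                           covariates = c("age_years", "sex", "mean_fd_mm")) {
  stopifnot(which %in% covariates)
  vals <- data[[which]][!is.na(data$value)]
  if (length(unique(vals[!is.na(vals)])) < 2)
    stop("covariate '", which, "' is constant")
  prep <- prepare_pairs(data, covariates)
  groups <- pattern_groups(prep)
  full <- fit_saturated_prep(prep, groups, covariates)
  covariate_lrt(full, which, prep, groups, covariates)
}

covariate_lrt <- function(full, which, prep, groups, covariates) {
  warm <- full$obj$expand(full$theta)
  red <- fit_saturated_prep(prep, groups, covariates,
                            drop_covariate = which, start_full = warm)
  out <- lrt_row(paste0("covariate ", which), red, full)
  attr(out, "beta") <- full$beta[, which]
  out
}

# all covariate LRTs sharing one full fit
test_covariates_all <- function(data, covariates) {
  prep <- prepare_pairs(data, covariates)
  groups <- pattern_groups(prep)
  full <- fit_saturated_prep(prep, groups, covariates)
  do.call(rbind, lapply(covariates, function(cn)
    covariate_lrt(full, cn, prep, groups, covariates)))
}

#' Twin-pair correlations from the saturated model
#'
#' MZ and DZ cross-twin correlations per wave and across waves, and the
#' within-person cross-wave phenotypic correlation, derived from the
#' covariate-adjusted saturated FIML covariance matrices. Confidence
#' intervals are Wald intervals from the observed information (delta
#' method on the Fisher-z scale).
#'
#' @inheritParams fit_cholesky
#' @param level confidence level.
#' @return data.frame with `zygosity`, `which`, `r`, `lo`, `hi`.
#' @export
twin_correlations <- function(data, covariates = NULL, level = 0.95) {
  fit <- fit_saturated(data, covariates)
  defs <- list(wave1 = c(1, 3), wave2 = c(2, 4),
               cross_12 = c(1, 4), cross_21 = c(2, 3),
               within_person = c(1, 2))
  corr_fun <- function(theta, z, ij) {
    p <- fit$obj$expand(theta)
    S <- sat_sigma(p[paste0(z, ".ls", 1:4)], p[paste0(z, ".th", 1:6)])
    S[ij[1], ij[2]] / sqrt(S[ij[1], ij[1]] * S[ij[2], ij[2]])
  }
  H <- stats::optimHess(fit$theta, fit$obj$fn)
  V <- tryCatch(2 * solve(H), error = function(e) NULL)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  out <- list()
  for (z in c("mz", "dz")) for (w in names(defs)) {
    r <- corr_fun(fit$theta, z, defs[[w]])
    lo <- hi <- NA_real_
    if (!is.null(V)) {
      g <- numeric(length(fit$theta))
      eps <- 1e-5
      for (i in seq_along(fit$theta)) {
        tp <- tm <- fit$theta
        tp[i] <- tp[i] + eps; tm[i] <- tm[i] - eps
        g[i] <- (corr_fun(tp, z, defs[[w]]) - corr_fun(tm, z, defs[[w]])) / (2 * eps)
      }
      se_r <- sqrt(max(drop(t(g) %*% V %*% g), 0))
      if (abs(r) < 1) {
        se_z <- se_r / (1 - r^2)  # delta method through atanh
        lo <- tanh(atanh(r) - zc * se_z); hi <- tanh(atanh(r) + zc * se_z)
      }
    }
    out[[length(out) + 1]] <- data.frame(zygosity = toupper(z), which = w,
                                         r = r, lo = lo, hi = hi,
                                         stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Test for new latent influences at wave 2
#'
#' Refits the bivariate Cholesky model with the wave-2-specific path of the
#' chosen source fixed at zero (a22 for A, c22 for C) and reports the
#' likelihood-ratio chi-square on 1 df against the unconstrained fit. A
#' significant result indicates latent influences at wave 2 that are
#' independent of those at wave 1. The chi-square reference is the standard
#' 1-df distribution; because the null pins a variance path to the boundary
#' of its (squared) parameter space the test is conservative, and an
#' optional 50:50 chi0:chi1 mixture reference is provided.
#'
#' @param fit a converged `twin_fit` from [fit_cholesky()].
#' @param component `"A"` or `"C"`.
#' @param mixture_null use the 50:50 mixture reference for the p-value.
#' @return one-row data.frame `test`, `chisq`, `df`, `p` with the
#'   constrained fit attached as attribute `"fit0"`.
#' @export
test_new_influence <- function(fit, component = c("A", "C"),
                               mixture_null = FALSE) {
  component <- match.arg(component)
  path <- paste0(tolower(component), "22")
  fixed <- stats::setNames(list(0), path)
  fit0 <- refit_constrained(fit, fixed = fixed)
  out <- lrt_row(paste0("new ", component, " influence at wave 2 (",
                        path, " = 0)"), fit0, fit, df = 1)
  if (mixture_null) out$p <- 0.5 * stats::pchisq(out$chisq, 1, lower.tail = FALSE)
  attr(out, "fit0") <- fit0
  out
}

#' Test for (de)amplification of continuing influences
#'
#' Refits with the continuing path equated to the wave-1 path (a21 = a11
#' for A, c21 = c11 for C) and reports the 1-df likelihood-ratio test. The
#' sign of the unconstrained difference gives the direction: a21 < a11 is
#' deamplification (the continuing influence weakens at wave 2), a21 > a11
#' amplification.
#'
#' @inheritParams test_new_influence
#' @return one-row data.frame `test`, `chisq`, `df`, `p`, `direction`.
#' @export
test_amplification <- function(fit, component = c("A", "C")) {
  component <- match.arg(component)
  src <- tolower(component)
  p1 <- paste0(src, "11"); p2 <- paste0(src, "21")
  fit0 <- refit_constrained(fit, equal = list(c(p1, p2)))
  out <- lrt_row(paste0("equal continuing ", component, " influence (",
                        p2, " = ", p1, ")"), fit0, fit, df = 1)
  paths <- stats::setNames(c(fit$params$a, fit$params$c, fit$params$e),
                           PATH_NAMES)
  out$direction <- if (abs(paths[p2]) < abs(paths[p1])) "deamplification"
                   else "amplification"
  attr(out, "fit0") <- fit0
  out
}

#' AIC model selection with ambiguity flag
#'
#' Picks the converged fit with the lowest AIC; ties are broken toward the
#' model with fewer free parameters. The ambiguity flag is set when the
#' runner-up is within 2 AIC units (substantial support for both models).
#'
#' @param fits list of `twin_fit` objects (e.g. ACE/AE/CE/E).
#' @return list with `chosen` (the fit), `name`, `ambiguous` (logical),
#'   `aic_table` (data.frame, ascending AIC).
#' @export
select_model <- function(fits) {
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$components %||% "?", "")
  ok <- vapply(fits, function(f) isTRUE(f$convergence), TRUE)
  if (!any(ok)) stop("no converged fits to select from")
  tab <- data.frame(model = names(fits)[ok],
                    aic = vapply(fits[ok], `[[`, 0, "aic"),
                    n_free = vapply(fits[ok], `[[`, 0, "n_free"),
                    minus2ll = vapply(fits[ok], `[[`, 0, "minus2ll"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic, tab$n_free), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  ambiguous <- nrow(tab) > 1 && tab$delta_aic[2] < 2
  list(chosen = fits[[tab$model[1]]], name = tab$model[1],
       ambiguous = ambiguous, aic_table = tab)
}

#' Variance decomposition of a fitted Cholesky model
#'
#' Squares and sums the fitted paths into raw A/C/E variance components per
#' wave, standardized proportions of the per-wave total, and the wave-2
#' split into continuing (from the wave-1 latent factor, squared 21 path)
#' versus new (wave-2-specific, squared 22 path) variance.
#'
#' @param fit a `twin_fit` from [fit_cholesky()].
#' @return list with `raw` (3x2 matrix A/C/E by wave), `standardized`
#'   (same, proportions), `total` (length 2), and `wave2_split` (matrix
#'   with columns `continuing`, `new` per source, as proportions of the
#'   wave-2 total).
#' @export
decompose_variance <- function(fit) {
  p <- fit$params
  raw <- rbind(A = c(p$a[1]^2, p$a[2]^2 + p$a[3]^2),
               C = c(p$c[1]^2, p$c[2]^2 + p$c[3]^2),
               E = c(p$e[1]^2, p$e[2]^2 + p$e[3]^2))
  colnames(raw) <- c("wave1", "wave2")
  total <- colSums(raw)
  std <- sweep(raw, 2, total, "/")
  split2 <- rbind(A = c(p$a[2]^2, p$a[3]^2),
                  C = c(p$c[2]^2, p$c[3]^2),
                  E = c(p$e[2]^2, p$e[3]^2)) / total[2]
  colnames(split2) <- c("continuing", "new")
  list(raw = raw, standardized = std, total = total, wave2_split = split2)
}

#' Cross-trait genetic and environmental correlations
#'
#' Fits a bivariate Cholesky model to a two-trait twin table (the two
#' "waves" slots holding the two traits measured in the same wave) and
#' returns the phenotypic, genetic, common-environment and
#' unique-environment correlations between the traits. For source X with
#' paths (x11, x21, x22), the latent correlation is
#' \deqn{r_X = x_{21} / \sqrt{x_{21}^2 + x_{22}^2}}
#' (with the x11 >= 0 sign convention), and the phenotypic correlation
#' comes from the implied within-twin covariance.
#'
#' @param data a [twin_data()] table whose `wave` column indexes the two
#'   traits.
#' @param covariates,n_starts,seed passed to [fit_cholesky()].
#' @param components model for the fit (default ACE).
#' @param ci compute profile-likelihood CIs for r_A/r_C/r_E (Wald for r_P).
#' @param level confidence level.
#' @return data.frame with `quantity` (`r_phenotypic`, `r_A`, `r_C`,
#'   `r_E`), `estimate`, `lo`, `hi`; the fit attached as attribute `"fit"`.
#' @export
cross_trait_cholesky <- function(data, covariates = NULL, components = "ACE",
                                 ci = FALSE, level = 0.95, n_starts = 5,
                                 seed = 1) {
  fit <- fit_cholesky(data, components = components, covariates = covariates,
                      n_starts = n_starts, seed = seed)
  rows <- cross_trait_correlations(fit, ci = ci, level = level)
  attr(rows, "fit") <- fit
  rows
}

latent_corr <- function(x) {
  den <- sqrt(x[2]^2 + x[3]^2)
  if (den < 1e-12 || abs(x[1]) < 1e-12) return(NA_real_)
  x[2] / den
}

cross_trait_correlations <- function(fit, ci = FALSE, level = 0.95) {
  p <- fit$params
  Sw <- tcrossprod(path_matrix(p$a)) + tcrossprod(path_matrix(p$c)) +
    tcrossprod(path_matrix(p$e))
  est <- c(r_phenotypic = Sw[1, 2] / sqrt(Sw[1, 1] * Sw[2, 2]),
           r_A = latent_corr(p$a), r_C = latent_corr(p$c),
           r_E = latent_corr(p$e))
  out <- data.frame(quantity = names(est), estimate = unname(est),
                    lo = NA_real_, hi = NA_real_, stringsAsFactors = FALSE)
  if (ci) {
    for (src in c("A", "C", "E")) {
      if (!grepl(src, fit$components)) next
      q <- paste0("r", src)
      ci_r <- tryCatch(profile_ci(fit, q, level = level),
                       error = function(e) c(NA, NA))
      out[out$quantity == paste0("r_", src), c("lo", "hi")] <- ci_r
    }
    ci_p <- tryCatch(wald_ci_quantity(fit, "r_phenotypic", level),
                     error = function(e) c(NA, NA))
    out[out$quantity == "r_phenotypic", c("lo", "hi")] <- ci_p
  }
  out
}
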
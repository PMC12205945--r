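#' Brain-behavior association by two-level mixed model
#'
#' Fits `behavior ~ brain + age + sex + mean_fd + wave` with random
#' intercepts for participant nested in family, pooling both waves (wave
#' coded 0/1). The family intercept absorbs twin relatedness, the
#' participant intercept repeated measurements. The direction of the
#' regression can be switched so the brain metric is the response.
#'
#' @param rows data.frame with columns `participant_id`, `family_id`,
#'   `wave` (0/1), `age_years`, `sex`, `mean_fd`, `roi_value`,
#'   `behavior_score`.
#' @param response `"behavior"` (default) or `"brain"`.
#' @param reml fit by REML (default) or ML.
#' @return list with `estimate`, `se`, `z`, `p` (Wald) for the predictor,
#'   the fitted `model`, and `singular_refit` (TRUE when the participant
#'   intercept was dropped because the full random structure was singular).
#' @export
fit_lmm <- function(rows, response = c("behavior", "brain"), reml = TRUE) {
  response <- match.arg(response)
  need <- c("participant_id", "family_id", "wave", "age_years", "sex",
            "mean_fd", "roi_value", "behavior_score")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  stopifnot(all(rows$wave %in% 0:1))
  lhs <- if (response == "behavior") "behavior_score" else "roi_value"
  pred <- if (response == "behavior") "roi_value" else "behavior_score"
  fml <- stats::as.formula(paste(
    lhs, "~", pred, "+ age_years + sex + mean_fd + wave",
    "+ (1 | family_id / participant_id)"))
  fit <- suppressMessages(lme4::lmer(fml, data = rows, REML = reml))
  singular_refit <- FALSE
  if (lme4::isSingular(fit, tol = 1e-5)) {
    singular_refit <- TRUE
    fml2 <- stats::as.formula(paste(
      lhs, "~", pred, "+ age_years + sex + mean_fd + wave + (1 | family_id)"))
    fit <- suppressMessages(lme4::lmer(fml2, data = rows, REML = reml))
    warning("singular random-effects structure; participant intercept dropped")
  }
  co <- summary(fit)$coefficients
  est <- co[pred, "Estimate"]; se <- co[pred, "Std. Error"]
  z <- est / se
  list(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
       model = fit, singular_refit = singular_refit)
}

#' Brain-behavior genetic and environmental correlations
#'
#' Builds a two-trait twin table from a brain metric and a behavior score
#' measured in the same wave and delegates to [cross_trait_cholesky()],
#' returning the latent genetic (r_A) and unique-environment (r_E)
#' correlations with the phenotypic correlation for context.
#'
#' @param data a [twin_data()]-shaped long table for one wave, with
#'   `value` holding the brain metric and an extra `behavior_score` column.
#' @param covariates,components,ci,level,n_starts,seed passed through.
#' @return the [cross_trait_cholesky()] result.
#' @export
brain_behavior_twin <- function(data, covariates = NULL, components = "ACE",
                                ci = FALSE, level = 0.95, n_starts = 5,
                                seed = 1) {
  stopifnot("behavior_score" %in% names(data))
  brain <- data
  brain$wave <- 1
  behav <- data
  behav$wave <- 2
  behav$value <- behav$behavior_score
  two <- rbind(brain[setdiff(names(brain), "behavior_score")],
               behav[setdiff(names(behav), "behavior_score")])
  cross_trait_cholesky(twin_data(two), covariates = covariates,
                       components = components, ci = ci, level = level,
                       n_starts = n_starts, seed = seed)
}
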
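# Quantities of a fitted Cholesky model that can be profiled:
#   A1,C1,E1        raw wave-1 variance of a source (x11^2)
#   A2,C2,E2        raw wave-2 variance (x21^2 + x22^2)
#   std_A1,...      standardized proportion of the wave-1 total
#   std_A2,...      standardized proportion of the wave-2 total
#   rA,rC,rE        latent cross-variable correlation x21/sqrt(x21^2+x22^2)
#   r_phenotypic    implied within-twin cross-variable correlation

eval_quantity <- function(params, quantity) {
  px <- list(a = params$a, c = params$c, e = params$e)
  v1 <- vapply(px, function(x) x[1]^2, 0)
  v2 <- vapply(px, function(x) x[2]^2 + x[3]^2, 0)
  switch(quantity,
    A1 = v1[["a"]], C1 = v1[["c"]], E1 = v1[["e"]],
    A2 = v2[["a"]], C2 = v2[["c"]], E2 = v2[["e"]],
    std_A1 = v1[["a"]] / sum(v1), std_C1 = v1[["c"]] / sum(v1),
    std_E1 = v1[["e"]] / sum(v1),
    std_A2 = v2[["a"]] / sum(v2), std_C2 = v2[["c"]] / sum(v2),
    std_E2 = v2[["e"]] / sum(v2),
    rA = latent_corr(params$a), rC = latent_corr(params$c),
    rE = latent_corr(params$e),
    r_phenotypic = {
      Sw <- tcrossprod(path_matrix(params$a)) +
        tcrossprod(path_matrix(params$c)) + tcrossprod(path_matrix(params$e))
      Sw[1, 2] / sqrt(Sw[1, 1] * Sw[2, 2])
    },
    stop("unknown quantity: ", quantity))
}

present_sources <- function(components) {
  switch(components, ACE = c("a", "c", "e"), AE = c("a", "e"),
         CE = c("c", "e"), E = "e")
}

# Build the constrained reparameterization pinning `quantity` at value v.
quantity_reparam <- function(fit, quantity, v) {
  src <- if (grepl("^r[ACE]$", quantity)) tolower(substr(quantity, 2, 2))
         else tolower(substr(sub("^std_", "", quantity), 1, 1))
  others <- setdiff(present_sources(fit$components), src)
  paths_hat <- stats::setNames(c(fit$params$a, fit$params$c, fit$params$e),
                               PATH_NAMES)
  if (src %in% c("a", "c", "e") && !(src %in% present_sources(fit$components)))
    stop("source absent from the ", fit$components, " model")
  p11 <- paste0(src, "11"); p21 <- paste0(src, "21"); p22 <- paste0(src, "22")
  if (grepl("^std_[ACE]1$", quantity)) {
    list(reparam = list(remove = p11, add = character(0),
           apply = function(paths, extra) {
             rest <- sum(paths[paste0(others, "11")]^2)
             paths[p11] <- sqrt(v / (1 - v) * rest)
             paths
           }),
         start_extra = NULL)
  } else if (grepl("^std_[ACE]2$", quantity)) {
    th <- paste0("th_", src)
    list(reparam = list(remove = c(p21, p22), add = th,
           apply = function(paths, extra) {
             rest <- sum(paths[as.vector(outer(others, c("21", "22"), paste0))]^2)
             s <- sqrt(v / (1 - v) * rest)
             paths[p21] <- s * cos(extra[th]); paths[p22] <- s * sin(extra[th])
             paths
           }),
         start_extra = stats::setNames(atan2(paths_hat[p22], paths_hat[p21]), th))
  } else if (grepl("^[ACE]1$", quantity)) {
    list(reparam = list(remove = p11, add = character(0),
           apply = function(paths, extra) { paths[p11] <- sqrt(v); paths }),
         start_extra = NULL)
  } else if (grepl("^[ACE]2$", quantity)) {
    th <- paste0("th_", src)
    list(reparam = list(remove = c(p21, p22), add = th,
           apply = function(paths, extra) {
             s <- sqrt(v)
             paths[p21] <- s * cos(extra[th]); paths[p22] <- s * sin(extra[th])
             paths
           }),
         start_extra = stats::setNames(atan2(paths_hat[p22], paths_hat[p21]), th))
  } else if (grepl("^r[ACE]$", quantity)) {
    tn <- paste0("t_", src)
    list(reparam = list(remove = c(p21, p22), add = tn,
           apply = function(paths, extra) {
             t_ <- abs(extra[tn])
             paths[p21] <- t_ * v; paths[p22] <- t_ * sqrt(1 - v^2)
             paths
           }),
         start_extra = stats::setNames(sqrt(paths_hat[p21]^2 + paths_hat[p22]^2), tn))
  } else stop("quantity '", quantity, "' cannot be profiled")
}

quantity_range <- function(quantity, vhat) {
  if (grepl("^std_", quantity)) c(0, 0.9999)
  else if (grepl("^r[ACE]$", quantity)) c(-0.9999, 0.9999)
  else c(0, Inf)
}

#' Profile-likelihood confidence interval for a model quantity
#'
#' Likelihood-based CI: each bound is the value of the quantity at which
#' the constrained -2 log likelihood (all other free parameters
#' re-optimized under a reparameterization that pins the quantity) exceeds
#' the minimum by the chi-square(1) quantile of the requested level.
#' Bounds that run into the edge of the parameter space (e.g. a proportion
#' reaching 0 or 1) are reported at the edge.
#'
#' @param fit a converged `twin_fit` from [fit_cholesky()].
#' @param quantity one of the names documented above, e.g. `"std_A1"` for
#'   wave-1 heritability or `"rA"` for the latent genetic correlation.
#' @param level confidence level (default 0.95, i.e. a 3.84 deviance rise).
#' @param max_refits cap on constrained refits per bound; on failure the
#'   bound falls back to a Wald interval with a warning.
#' @return numeric `c(lo, hi)`.
#' @export
profile_ci <- function(fit, quantity, level = 0.95, max_refits = 60) {
  stopifnot(fit$model == "cholesky")
  vhat <- eval_quantity(fit$params, quantity)
  if (!is.finite(vhat)) stop("quantity undefined at the fitted parameters")
  target <- fit$minus2ll + stats::qchisq(level, 1)
  rng <- quantity_range(quantity, vhat)
  budget <- new.env(); budget$n <- 0; budget$warm <- NULL
  dev <- function(v) {
    budget$n <- budget$n + 1
    if (budget$n > max_refits) stop("profile refit budget exhausted")
    qr_ <- quantity_reparam(fit, quantity, v)
    ft <- refit_constrained(fit, reparam = qr_$reparam,
                            start_extra = qr_$start_extra, n_starts = 1,
                            start_params = budget$warm)
    if (isTRUE(ft$convergence)) budget$warm <- ft$params
    ft$minus2ll
  }
  f <- function(v) dev(v) - target
  bound <- function(side) {
    budget$warm <- NULL
    lim <- rng[side]
    dir <- if (side == 1) -1 else 1
    step <- if (is.finite(lim)) 0.08 * max(abs(lim - vhat), 0.1)
            else 0.25 * max(abs(vhat), 0.5)
    v <- vhat; f_v <- -stats::qchisq(level, 1); v_next <- NA; fv <- NA
    for (i in 1:15) {
      v_next <- v + dir * step
      at_lim <- is.finite(lim) &&
        ((dir < 0 && v_next <= lim) || (dir > 0 && v_next >= lim))
      if (at_lim) v_next <- lim
      fv <- tryCatch(f(v_next), error = function(e) NA)
      if (is.na(fv)) return(NA_real_)
      if (fv > 0) break
      if (at_lim) return(lim)
      v <- v_next; f_v <- fv; step <- step * 2
    }
    if (is.na(fv) || fv <= 0) return(if (is.finite(lim)) lim else dir * Inf)
    ends <- if (dir > 0) c(v, v_next) else c(v_next, v)
    fends <- if (dir > 0) c(f_v, fv) else c(fv, f_v)
    tryCatch(stats::uniroot(f, ends, f.lower = fends[1], f.upper = fends[2],
                            tol = max(diff(ends) * 5e-3, 1e-5),
                            maxiter = 40)$root,
             error = function(e) NA_real_)
  }
  out <- tryCatch(c(bound(1), bound(2)), error = function(e) c(NA, NA))
  if (anyNA(out)) {
    warning("profile CI failed for ", quantity, "; falling back to Wald")
    w <- wald_ci_quantity(fit, quantity, level)
    out[is.na(out)] <- w[is.na(out)]
  }
  stats::setNames(out, c("lo", "hi"))
}

# Wald CI via the observed information and a numerical delta method.
wald_ci_quantity <- function(fit, quantity, level = 0.95) {
  obj <- cholesky_objective(fit$prep, fit$groups, fit$components,
                            fit$covariates, fit$fixed, fit$equal, fit$reparam)
  value_at <- function(theta) {
    names(theta) <- obj$theta_names
    b <- obj$build(theta)
    eval_quantity(paths_to_params(b$paths, b$mu, b$beta), quantity)
  }
  H <- stats::optimHess(fit$theta, obj$fn)
  V <- 2 * solve(H)
  g <- numeric(length(fit$theta)); eps <- 1e-5
  for (i in seq_along(fit$theta)) {
    tp <- tm <- fit$theta
    tp[i] <- tp[i] + eps; tm[i] <- tm[i] - eps
    g[i] <- (value_at(tp) - value_at(tm)) / (2 * eps)
  }
  se <- sqrt(max(drop(t(g) %*% V %*% g), 0))
  vhat <- eval_quantity(fit$params, quantity)
  zc <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(vhat - zc * se, vhat + zc * se)
  rng <- quantity_range(quantity, vhat)
  pmin(pmax(ci, rng[1]), rng[2])
}
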
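PATH_NAMES <- c("a11", "a21", "a22", "c11", "c21", "c22", "e11", "e21", "e22")

# Evaluate code with a private RNG stream, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

paths_to_params <- function(paths, mu, beta) {
  cholesky_params(a = paths[c("a11", "a21", "a22")],
                  c = paths[c("c11", "c21", "c22")],
                  e = paths[c("e11", "e21", "e22")],
                  mu = mu, beta = beta)
}

# Build the objective for a (possibly constrained) Cholesky model.
#   components  "ACE" | "AE" | "CE" | "E"
#   fixed       named list, path -> value (paths of absent sources are
#               implicitly fixed at 0)
#   equal       list of character vectors of paths forced equal (the first
#               name stays free and carries the shared value)
#   reparam     optional list(remove=, add=, apply=function(paths, extra))
#               substituting some paths by a function of auxiliary
#               parameters, used for profile confidence intervals
cholesky_objective <- function(prep, groups, components = "ACE",
                               covariates = NULL, fixed = list(),
                               equal = list(), reparam = NULL) {
  sources <- switch(components,
                    ACE = c("a", "c", "e"), AE = c("a", "e"),
                    CE = c("c", "e"), E = "e",
                    stop("unknown component set: ", components))
  absent <- setdiff(c("a", "c", "e"), sources)
  fixed <- c(fixed, stats::setNames(
    as.list(rep(0, 3 * length(absent))),
    as.vector(outer(absent, c("11", "21", "22"), paste0))))
  free <- setdiff(PATH_NAMES, names(fixed))
  for (grp in equal) free <- setdiff(free, grp[-1])
  if (!is.null(reparam)) free <- setdiff(free, reparam$remove)
  k <- length(covariates)
  extra <- if (!is.null(reparam)) reparam$add else character(0)
  beta_names <- if (k) as.vector(outer(c("w1", "w2"), covariates, paste, sep = ".")) else character(0)
  theta_names <- c(free, extra, "mu1", "mu2", beta_names)

  build <- function(theta) {
    paths <- stats::setNames(numeric(9), PATH_NAMES)
    paths[free] <- theta[free]
    for (nm in names(fixed)) paths[nm] <- fixed[[nm]]
    for (grp in equal) paths[grp] <- paths[grp[1]]
    if (!is.null(reparam)) paths <- reparam$apply(paths, theta[extra])
    mu <- theta[c("mu1", "mu2")]
    beta <- if (k) matrix(theta[beta_names], 2, k,
                          dimnames = list(NULL, covariates))
    list(paths = paths, mu = mu, beta = beta)
  }
  fn <- function(theta) {
    names(theta) <- theta_names
    b <- build(theta)
    pa <- b$paths
    A <- tcrossprod(matrix(c(pa[1L], pa[2L], 0, pa[3L]), 2, 2))
    C <- tcrossprod(matrix(c(pa[4L], pa[5L], 0, pa[6L]), 2, 2))
    E <- tcrossprod(matrix(c(pa[7L], pa[8L], 0, pa[9L]), 2, 2))
    W <- A + C + E
    bmz <- A + C
    bdz <- 0.5 * A + C
    smz <- rbind(cbind(W, bmz), cbind(bmz, W))
    sdz <- rbind(cbind(W, bdz), cbind(bdz, W))
    M <- slot_means(prep, b$mu, b$beta)
    neg2ll_groups(groups, prep$y, M, smz, sdz)
  }
  # Analytic gradient. For the sufficient-statistic (no-covariate) path,
  # dL/dSigma = n (S^-1 - S^-1 (Shat + dd') S^-1) per group; with
  # covariates the compiled row-wise kernel supplies dL/dSigma and dL/dM.
  # Both are chained to the paths via dSigma/dl_ij and to theta via the
  # (mostly identity) build map.
  X0 <- NULL
  if (k) { X0 <- prep$X; X0[is.na(X0)] <- 0 }
  gr <- function(theta) {
    names(theta) <- theta_names
    b <- build(theta)
    pa <- b$paths
    Ls <- list(matrix(c(pa[1L], pa[2L], 0, pa[3L]), 2, 2),
               matrix(c(pa[4L], pa[5L], 0, pa[6L]), 2, 2),
               matrix(c(pa[7L], pa[8L], 0, pa[9L]), 2, 2))
    A <- tcrossprod(Ls[[1]]); C <- tcrossprod(Ls[[2]]); E <- tcrossprod(Ls[[3]])
    W <- A + C + E
    smz <- rbind(cbind(W, A + C), cbind(A + C, W))
    sdz <- rbind(cbind(W, 0.5 * A + C), cbind(0.5 * A + C, W))
    Gz <- list(MZ = matrix(0, 4, 4), DZ = matrix(0, 4, 4))
    dmu4 <- numeric(4)
    dbeta <- NULL
    if (k == 0) {
      mu4 <- b$mu[c(1, 2, 1, 2)]
      for (g in groups$groups) {
        sg <- if (g$zyg == "MZ") smz else sdz
        s <- sg[g$slots, g$slots, drop = FALSE]
        ch <- tryCatch(chol(s), error = function(e) NULL)
        if (is.null(ch)) return(numeric_grad(fn, theta))
        sinv <- chol2inv(ch)
        d <- g$ybar - mu4[g$slots]
        Gsub <- g$n * (sinv - sinv %*% (g$scatter + tcrossprod(d)) %*% sinv)
        Gz[[g$zyg]][g$slots, g$slots] <- Gz[[g$zyg]][g$slots, g$slots] + Gsub
        dmu4[g$slots] <- dmu4[g$slots] - 2 * g$n * (sinv %*% d)
      }
    } else {
      M <- slot_means(prep, b$mu, b$beta)
      kr <- fiml_grad_kernel(prep$y, M, smz, sdz, groups$rows0,
                             groups$slots0, groups$zyg_mz)
      if (!isTRUE(kr$ok)) return(numeric_grad(fn, theta))
      Gz <- list(MZ = kr$Gmz, DZ = kr$Gdz)
      dmu4 <- colSums(kr$dM)
      dbeta <- matrix(0, 2, k)
      wave_of <- c(1, 2, 1, 2)
      for (s in 1:4) for (j in seq_len(k))
        dbeta[wave_of[s], j] <- dbeta[wave_of[s], j] +
          sum(kr$dM[, s] * X0[, s, j])
    }
    path_grad <- numeric(9)
    for (z in c("MZ", "DZ")) {
      G <- Gz[[z]]
      H <- G[1:2, 1:2] + G[3:4, 3:4]; H <- H + t(H)
      X_ <- G[1:2, 3:4] + G[3:4, 1:2]; X_ <- X_ + t(X_)
      ka <- if (z == "MZ") 1 else 0.5
      kx <- c(ka, 1, 0)
      for (si in 1:3) {
        Gm <- (H + kx[si] * X_) %*% Ls[[si]]
        path_grad[(si - 1) * 3 + 1:3] <-
          path_grad[(si - 1) * 3 + 1:3] + Gm[c(1, 2, 4)]
      }
    }
    gth <- stats::setNames(numeric(length(theta)), theta_names)
    if (is.null(reparam)) {
      gth[free] <- path_grad[match(free, PATH_NAMES)]
      for (grp in equal)
        gth[grp[1]] <- gth[grp[1]] + sum(path_grad[match(grp[-1], PATH_NAMES)])
    } else {
      eps <- 1e-6
      for (i in seq_along(theta)) {
        nm <- theta_names[i]
        if (nm %in% c("mu1", "mu2")) next
        tp <- tm <- theta
        tp[i] <- tp[i] + eps; tm[i] <- tm[i] - eps
        dpaths <- (build(tp)$paths - build(tm)$paths) / (2 * eps)
        gth[i] <- sum(dpaths * path_grad)
      }
    }
    gth["mu1"] <- gth["mu1"] + dmu4[1] + dmu4[3]
    gth["mu2"] <- gth["mu2"] + dmu4[2] + dmu4[4]
    if (k) gth[beta_names] <- as.vector(dbeta)
    gth
  }
  list(fn = fn, gr = gr, build = build, theta_names = theta_names,
       free = free, extra = extra, beta_names = beta_names,
       n_free = length(theta_names))
}

numeric_grad <- function(fn, theta, eps = 1e-6) {
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    tp <- tm <- theta
    tp[i] <- tp[i] + eps; tm[i] <- tm[i] - eps
    g[i] <- (fn(tp) - fn(tm)) / (2 * eps)
  }
  g
}

# Moment-based starting values: Falconer-style decomposition of the
# cross-twin covariances, with covariate betas from a pooled regression.
moment_start <- function(prep, components = "ACE", covariates = NULL) {
  y <- prep$y
  k <- length(covariates)
  beta <- NULL
  if (k) {
    beta <- matrix(0, 2, k, dimnames = list(NULL, covariates))
    for (w in 1:2) {
      slots <- c(w, w + 2)
      yy <- as.vector(y[, slots])
      xx <- do.call(rbind, lapply(slots, function(s) {
        m <- prep$X[, s, , drop = FALSE]; dim(m) <- c(nrow(y), k); m
      }))
      ok <- !is.na(yy) & stats::complete.cases(xx)
      if (sum(ok) > k + 2) {
        fit <- stats::lm.fit(cbind(1, xx[ok, , drop = FALSE]), yy[ok])
        beta[w, ] <- fit$coefficients[-1]
        y[, slots][is.na(y[, slots])] <- NA  # keep NA pattern
        for (s in slots) {
          m <- prep$X[, s, , drop = FALSE]; dim(m) <- c(nrow(y), k)
          adj <- m %*% beta[w, ]; adj[is.na(adj)] <- 0
          y[, s] <- y[, s] - adj
        }
      }
    }
  }
  mu <- c(mean(y[, c(1, 3)], na.rm = TRUE), mean(y[, c(2, 4)], na.rm = TRUE))
  cv <- function(i, j, z) {
    sel <- prep$zyg == z & !is.na(y[, i]) & !is.na(y[, j])
    if (sum(sel) < 3) return(NA_real_)
    stats::cov(y[sel, i], y[sel, j])
  }
  v1 <- stats::var(as.vector(y[, c(1, 3)]), na.rm = TRUE)
  v2 <- stats::var(as.vector(y[, c(2, 4)]), na.rm = TRUE)
  if (!is.finite(v2) || v2 <= 0) v2 <- v1
  dec <- function(v, cmz, cdz) {
    if (!is.finite(cmz)) cmz <- 0.4 * v
    if (!is.finite(cdz)) cdz <- 0.2 * v
    a <- 2 * (cmz - cdz); c <- 2 * cdz - cmz; e <- v - cmz
    x <- pmax(c(a, c, e), 0.05 * v)
    x / sum(x) * v
  }
  d1 <- dec(v1, mean(c(cv(1, 3, "MZ"), cv(2, 4, "MZ") * v1 / v2), na.rm = TRUE),
            mean(c(cv(1, 3, "DZ"), cv(2, 4, "DZ") * v1 / v2), na.rm = TRUE))
  d2 <- dec(v2, cv(2, 4, "MZ"), cv(2, 4, "DZ"))
  d1 <- pool_components(d1, components); d2 <- pool_components(d2, components)
  c12 <- stats::cov(y[, 1], y[, 2], use = "complete.obs")
  if (!is.finite(c12)) c12 <- 0.3 * sqrt(v1 * v2)
  share1 <- d1 / v1
  paths <- stats::setNames(numeric(9), PATH_NAMES)
  for (i in 1:3) {
    src <- c("a", "c", "e")[i]
    x11 <- sqrt(d1[i])
    x21 <- if (x11 > 1e-8) share1[i] * c12 / x11 else 0
    x21 <- sign(x21) * min(abs(x21), 0.95 * sqrt(d2[i]))
    x22 <- sqrt(max(d2[i] - x21^2, 0.02 * v2))
    paths[paste0(src, c("11", "21", "22"))] <- c(x11, x21, x22)
  }
  list(paths = paths, mu = mu, beta = beta)
}

pool_components <- function(d, components) {
  # fold variance of absent sources into the retained ones
  if (components == "ACE") return(d)
  if (components == "AE") { d[1] <- d[1] + d[2]; d[2] <- 0 }
  if (components == "CE") { d[2] <- d[2] + d[1]; d[1] <- 0 }
  if (components == "E")  { d[3] <- sum(d); d[1] <- d[2] <- 0 }
  d
}

# Multi-start BFGS: all starts are run at a coarse tolerance, then the best
# solution is polished at the full tolerance.
run_fit <- function(obj, start_theta, n_starts = 5, seed = 1,
                    reltol = 1e-10, maxit = 500) {
  jitters <- with_seed(seed, lapply(seq_len(max(n_starts - 1, 0)), function(i) {
    stats::rnorm(length(start_theta), 0, 0.2)
  }))
  starts <- c(list(start_theta),
              lapply(jitters, function(j) start_theta * exp(j) + 0.01 * j))
  coarse <- max(reltol, if (n_starts > 1) 1e-8 else reltol)
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, obj$fn, gr = obj$gr, method = "BFGS",
                   control = list(maxit = maxit, reltol = coarse)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) return(NULL)
  if (coarse > reltol) {
    polish <- tryCatch(
      stats::optim(best$par, obj$fn, gr = obj$gr, method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) best <- polish
  }
  names(best$par) <- obj$theta_names
  best
}

#' Fit a bivariate Cholesky twin model by FIML
#'
#' Minimizes [fiml_neg2ll()] over the free paths, means and covariate
#' effects of an ACE, AE, CE or E bivariate Cholesky model, using BFGS with
#' moment-based starting values and a configurable number of jittered
#' restarts to guard against local minima. Paths of sources excluded from
#' the submodel are fixed at 0.
#'
#' @param data a [twin_data()] table.
#' @param components one of `"ACE"`, `"AE"`, `"CE"`, `"E"`.
#' @param covariates covariate columns entering the mean model (see
#'   [fiml_neg2ll()]).
#' @param fixed named list of paths held at fixed values (e.g.
#'   `list(a22 = 0)` for the no-new-genetic-influence model).
#' @param equal list of character vectors of paths constrained equal (e.g.
#'   `list(c("a11","a21"))` for equal continuing influence).
#' @param n_starts number of optimizer starts (first from moments, the rest
#'   jittered).
#' @param seed integer seed controlling the jitter; fits are deterministic
#'   given it and do not disturb the caller's RNG stream.
#' @return A `twin_fit` object with elements `minus2ll`, `n_free`, `aic`,
#'   `params` ([cholesky_params()], sign-normalized), `convergence`
#'   (TRUE/FALSE) and bookkeeping used by the test and CI helpers.
#' @export
fit_cholesky <- function(data, components = c("ACE", "AE", "CE", "E"),
                         covariates = NULL, fixed = list(), equal = list(),
                         n_starts = 5, seed = 1) {
  components <- match.arg(components)
  prep <- prepare_pairs(data, covariates)
  groups <- pattern_groups(prep)
  fit_cholesky_prep(prep, groups, components, covariates, fixed, equal,
                    n_starts = n_starts, seed = seed)
}

fit_cholesky_prep <- function(prep, groups, components, covariates = NULL,
                              fixed = list(), equal = list(), reparam = NULL,
                              start = NULL, n_starts = 5, seed = 1) {
  obj <- cholesky_objective(prep, groups, components, covariates, fixed, equal,
                            reparam)
  if (is.null(start)) start <- moment_start(prep, components, covariates)
  theta0 <- stats::setNames(numeric(obj$n_free), obj$theta_names)
  theta0[intersect(obj$free, names(start$paths))] <-
    start$paths[intersect(obj$free, names(start$paths))]
  if (length(obj$extra) && !is.null(start$extra)) theta0[obj$extra] <- start$extra
  theta0[c("mu1", "mu2")] <- start$mu
  if (length(obj$beta_names)) theta0[obj$beta_names] <- as.vector(start$beta)
  opt <- run_fit(obj, theta0, n_starts = n_starts, seed = seed)
  if (is.null(opt)) {
    return(structure(list(minus2ll = Inf, n_free = obj$n_free, aic = Inf,
                          convergence = FALSE, model = "cholesky",
                          components = components),
                     class = "twin_fit"))
  }
  b <- obj$build(opt$par)
  paths <- b$paths
  for (src in c("a", "c", "e")) {
    idx <- paste0(src, c("11", "21", "22"))
    paths[idx] <- normalize_paths(paths[idx])
  }
  params <- paths_to_params(paths, b$mu, b$beta)
  structure(list(minus2ll = opt$value, n_free = obj$n_free,
                 aic = opt$value + 2 * obj$n_free,
                 params = params, convergence = opt$convergence == 0,
                 theta = opt$par, model = "cholesky",
                 components = components, covariates = covariates,
                 fixed = fixed, equal = equal, reparam = reparam,
                 prep = prep, groups = groups, seed = seed),
            class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("%s twin model (%s): -2lnL = %.4f, free parameters = %d, AIC = %.4f\n",
              x$model, x$components %||% "", x$minus2ll, x$n_free, x$aic))
  if (!x$convergence) cat("  WARNING: optimizer did not converge\n")
  if (!is.null(x$params) && inherits(x$params, "cholesky_params")) print(x$params)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Refit the same data under additional constraints, warm-started from the
# fitted solution. Used by the LRT helpers and profile CIs.
refit_constrained <- function(fit, fixed = list(), equal = list(),
                              reparam = NULL, start_extra = NULL,
                              n_starts = 1, start_params = NULL) {
  stopifnot(fit$model == "cholesky")
  sp <- start_params %||% fit$params
  paths <- stats::setNames(c(sp$a, sp$c, sp$e), PATH_NAMES)
  for (nm in names(fixed)) paths[nm] <- fixed[[nm]]
  for (grp in equal) paths[grp] <- mean(paths[grp])
  start <- list(paths = paths, mu = sp$mu, beta = sp$beta,
                extra = start_extra)
  fit_cholesky_prep(fit$prep, fit$groups, fit$components, fit$covariates,
                    fixed = c(fit$fixed, fixed), equal = c(fit$equal, equal),
                    reparam = reparam, start = start,
                    n_starts = n_starts, seed = fit$seed + 1L)
}
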
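# Saturated bivariate twin model: free 4-vector of slot means and free 4x4
# covariance per zygosity group, plus covariate betas shared across groups.
# The covariance is parameterized as D R D with D = diag(exp(log-SDs)) and R
# a correlation matrix built from hyperspherical angles, so that equality
# constraints on variances (and means) across birth order or zygosity are
# plain parameter-sharing constraints while R stays positive definite.

# unit-length row of a correlation Cholesky factor from angles
sphere_row <- function(theta, len) {
  x <- numeric(len)
  s <- 1
  if (len == 1) return(1)
  for (j in seq_len(len - 1)) {
    x[j] <- s * cos(theta[j])
    s <- s * sin(theta[j])
  }
  x[len] <- s
  x
}

angles_to_corr <- function(theta) {
  L <- matrix(0, 4, 4)
  L[1, 1] <- 1
  L[2, 1:2] <- sphere_row(theta[1], 2)
  L[3, 1:3] <- sphere_row(theta[2:3], 3)
  L[4, 1:4] <- sphere_row(theta[4:6], 4)
  tcrossprod(L)
}

corr_to_angles <- function(R) {
  L <- t(chol(R))
  th <- numeric(6)
  inv <- function(x) {
    # hyperspherical inverse of a unit vector
    n <- length(x)
    t_ <- numeric(n - 1)
    for (j in seq_len(n - 1)) t_[j] <- atan2(sqrt(sum(x[(j + 1):n]^2)), x[j])
    t_
  }
  th[1] <- inv(L[2, 1:2])
  th[2:3] <- inv(L[3, 1:3])
  th[4:6] <- inv(L[4, 1:4])
  th
}

sat_sigma <- function(logsd, theta) {
  d <- exp(logsd)
  R <- angles_to_corr(theta)
  d * R * rep(d, each = 4)
}

sat_theta_names <- function(covariates) {
  base <- c(paste0("mu", 1:4), paste0("ls", 1:4), paste0("th", 1:6))
  nm <- c(paste0("mz.", base), paste0("dz.", base))
  if (length(covariates))
    nm <- c(nm, as.vector(outer(c("w1", "w2"), covariates, paste, sep = ".")))
  nm
}

# equality-constraint groups for the assumption tests; each group's first
# member stays free
sat_equal_groups <- function(constraints) {
  g <- list()
  if ("means_birth_order" %in% constraints)
    g <- c(g, list(c("mz.mu1", "mz.mu3"), c("mz.mu2", "mz.mu4"),
                   c("dz.mu1", "dz.mu3"), c("dz.mu2", "dz.mu4")))
  if ("means_zygosity" %in% constraints)
    g <- c(g, lapply(1:4, function(i) paste0(c("mz.mu", "dz.mu"), i)))
  if ("var_birth_order" %in% constraints)
    g <- c(g, list(c("mz.ls1", "mz.ls3"), c("mz.ls2", "mz.ls4"),
                   c("dz.ls1", "dz.ls3"), c("dz.ls2", "dz.ls4")))
  if ("var_zygosity" %in% constraints)
    g <- c(g, lapply(1:4, function(i) paste0(c("mz.ls", "dz.ls"), i)))
  g
}

# merge possibly-overlapping equality groups into disjoint classes
merge_groups <- function(groups, names_all) {
  rep_of <- stats::setNames(names_all, names_all)
  find <- function(x) { while (rep_of[x] != x) x <- rep_of[x]; x }
  for (g in groups) for (m in g[-1]) rep_of[find(m)] <- find(g[1])
  vapply(names_all, find, character(1))
}

saturated_objective <- function(prep, groups, covariates = NULL,
                                constraints = character(0),
                                drop_beta = character(0)) {
  k <- length(covariates)
  all_names <- sat_theta_names(covariates)
  all_names <- setdiff(all_names, drop_beta)
  rep_of <- merge_groups(sat_equal_groups(constraints), all_names)
  free <- unique(rep_of)
  expand <- function(theta) stats::setNames(theta[rep_of], names(rep_of))
  beta_names <- if (k) setdiff(
    as.vector(outer(c("w1", "w2"), covariates, paste, sep = ".")), drop_beta)
  fn <- function(theta) {
    names(theta) <- free
    p <- expand(theta)
    sig <- lapply(c("mz", "dz"), function(z) {
      sat_sigma(p[paste0(z, ".ls", 1:4)], p[paste0(z, ".th", 1:6)])
    })
    mu_mat <- rbind(p[paste0("mz.mu", 1:4)], p[paste0("dz.mu", 1:4)])
    n <- nrow(prep$y)
    if (!k) {
      M <- structure(list(mu4_by_zyg = mu_mat), class = "uniform_means")
      return(neg2ll_groups(groups, prep$y, M, sig[[1]], sig[[2]]))
    }
    M <- mu_mat[ifelse(prep$zyg == "MZ", 1, 2), , drop = FALSE]
    if (k) {
      beta <- matrix(0, 2, k, dimnames = list(NULL, covariates))
      for (nm in beta_names) {
        w <- as.integer(substr(nm, 2, 2))
        cv <- sub("^w[12]\\.", "", nm)
        beta[w, cv] <- p[nm]
      }
      wave_of <- c(1, 2, 1, 2)
      for (s in 1:4) {
        xb <- prep$X[, s, , drop = FALSE]; dim(xb) <- c(n, k)
        contrib <- xb %*% beta[wave_of[s], ]
        contrib[is.na(contrib)] <- 0
        M[, s] <- M[, s] + contrib
      }
    }
    neg2ll_groups(groups, prep$y, M, sig[[1]], sig[[2]])
  }
  # Gradient: dL/dSigma and dL/dM come from the compiled kernel; the chain
  # to log-SDs and correlation angles is differentiated per parameter on
  # the tiny 4x4 sat_sigma map (central differences), which is exact to
  # O(eps^2) and far cheaper than differencing the full likelihood.
  is_mz_row <- prep$zyg == "MZ"
  X0 <- NULL
  if (k) { X0 <- prep$X; X0[is.na(X0)] <- 0 }
  wave_of <- c(1, 2, 1, 2)
  gr <- function(theta) {
    names(theta) <- free
    p <- expand(theta)
    sig <- lapply(c("mz", "dz"), function(z)
      sat_sigma(p[paste0(z, ".ls", 1:4)], p[paste0(z, ".th", 1:6)]))
    n <- nrow(prep$y)
    mu_mat <- rbind(p[paste0("mz.mu", 1:4)], p[paste0("dz.mu", 1:4)])
    M <- mu_mat[ifelse(is_mz_row, 1, 2), , drop = FALSE]
    if (k) {
      beta <- matrix(0, 2, k, dimnames = list(NULL, covariates))
      for (nm in beta_names) {
        beta[as.integer(substr(nm, 2, 2)), sub("^w[12]\\.", "", nm)] <- p[nm]
      }
      for (s in 1:4) {
        xb <- X0[, s, , drop = FALSE]; dim(xb) <- c(n, k)
        obs <- !is.na(prep$y[, s])
        M[obs, s] <- M[obs, s] + (xb %*% beta[wave_of[s], ])[obs]
      }
    }
    kr <- fiml_grad_kernel(prep$y, M, sig[[1]], sig[[2]],
                           groups$rows0, groups$slots0, groups$zyg_mz)
    if (!isTRUE(kr$ok)) return(numeric_grad(fn, theta))
    Gz <- list(mz = kr$Gmz, dz = kr$Gdz)
    dM <- kr$dM
    eps <- 1e-6
    gth <- stats::setNames(numeric(length(theta)), free)
    for (nm in free) {
      members <- names(rep_of)[rep_of == nm]
      acc <- 0
      for (mem in members) {
        z <- substr(mem, 1, 2)
        body_ <- sub("^(mz|dz|w[12])\\.", "", mem)
        if (grepl("^mu", body_)) {
          i <- as.integer(sub("mu", "", body_))
          rows_z <- if (z == "mz") is_mz_row else !is_mz_row
          acc <- acc + sum(dM[rows_z, i])
        } else if (grepl("^(ls|th)", body_)) {
          pp <- p; pm <- p
          pp[mem] <- pp[mem] + eps; pm[mem] <- pm[mem] - eps
          dS <- (sat_sigma(pp[paste0(z, ".ls", 1:4)], pp[paste0(z, ".th", 1:6)]) -
                   sat_sigma(pm[paste0(z, ".ls", 1:4)], pm[paste0(z, ".th", 1:6)])) /
            (2 * eps)
          acc <- acc + sum(Gz[[z]] * dS)
        } else {
          w <- as.integer(substr(mem, 2, 2))
          cv <- sub("^w[12]\\.", "", mem)
          for (s in which(wave_of == w))
            acc <- acc + sum(dM[, s] * X0[, s, cv])
        }
      }
      gth[nm] <- acc
    }
    gth
  }
  list(fn = fn, gr = gr, free = free, theta_names = free, rep_of = rep_of,
       expand = expand, n_free = length(free))
}

sat_moment_start <- function(prep, covariates = NULL) {
  y <- prep$y
  k <- length(covariates)
  beta <- NULL
  if (k) {
    ms <- moment_start(prep, "ACE", covariates)
    beta <- ms$beta
    wave_of <- c(1, 2, 1, 2)
    for (s in 1:4) {
      m <- prep$X[, s, , drop = FALSE]; dim(m) <- c(nrow(y), k)
      adj <- m %*% beta[wave_of[s], ]; adj[is.na(adj)] <- 0
      y[, s] <- y[, s] - adj
    }
  }
  start <- numeric(0)
  for (z in c("MZ", "DZ")) {
    yz <- y[prep$zyg == z, , drop = FALSE]
    mu <- colMeans(yz, na.rm = TRUE)
    S <- stats::cov(yz, use = "pairwise.complete.obs")
    S <- S * (nrow(yz) - 1) / nrow(yz)  # ML scaling, exact for complete data
    S[is.na(S)] <- 0
    diag(S)[diag(S) <= 0] <- stats::var(as.vector(yz), na.rm = TRUE)
    ev <- eigen(S, symmetric = TRUE)
    ev$values <- pmax(ev$values, 1e-4 * max(ev$values))
    S <- ev$vectors %*% (ev$values * t(ev$vectors))
    d <- sqrt(diag(S))
    R <- S / tcrossprod(d)
    th <- corr_to_angles(R)
    start <- c(start, mu, log(d), th)
  }
  names(start) <- sat_theta_names(NULL)
  if (k) {
    bn <- as.vector(outer(c("w1", "w2"), covariates, paste, sep = "."))
    start <- c(start, stats::setNames(as.vector(beta), bn))
  }
  start
}

#' Fit the saturated bivariate twin model
#'
#' Freely estimates the four slot means (twin 1/2 by wave 1/2) and the full
#' 4x4 covariance matrix separately for MZ and DZ groups by FIML, with
#' covariate effects on the means shared across groups. Optional equality
#' constraints implement the classical twin-model assumption tests.
#'
#' @inheritParams fit_cholesky
#' @param constraints character subset of `"means_birth_order"`,
#'   `"means_zygosity"`, `"var_birth_order"`, `"var_zygosity"`.
#' @param drop_covariate covariate name whose (both-wave) effects are fixed
#'   to zero, for covariate LRTs.
#' @return A `twin_fit` with `model = "saturated"`, fitted `sigma` (list
#'   `MZ`, `DZ`) and `mu` (2x4 matrix, rows MZ/DZ), and `beta`.
#' @export
fit_saturated <- function(data, covariates = NULL,
                          constraints = character(0),
                          drop_covariate = NULL, n_starts = 1, seed = 1) {
  prep <- prepare_pairs(data, covariates)
  groups <- pattern_groups(prep)
  fit_saturated_prep(prep, groups, covariates, constraints, drop_covariate,
                     n_starts, seed)
}

fit_saturated_prep <- function(prep, groups, covariates = NULL,
                               constraints = character(0),
                               drop_covariate = NULL, n_starts = 1,
                               seed = 1, start_full = NULL) {
  drop_beta <- if (!is.null(drop_covariate))
    paste(c("w1", "w2"), drop_covariate, sep = ".") else character(0)
  obj <- saturated_objective(prep, groups, covariates, constraints, drop_beta)
  if (is.null(start_full)) start_full <- sat_moment_start(prep, covariates)
  start_full <- start_full[setdiff(names(start_full), drop_beta)]
  theta0 <- vapply(obj$free, function(nm) {
    mean(start_full[names(obj$rep_of)[obj$rep_of == nm]])
  }, numeric(1))
  opt <- run_fit(obj, theta0, n_starts = n_starts, seed = seed,
                 reltol = 1e-12)
  if (is.null(opt)) stop("saturated model failed to optimize")
  p <- obj$expand(opt$par)
  sigma <- list(MZ = sat_sigma(p[paste0("mz.ls", 1:4)], p[paste0("mz.th", 1:6)]),
                DZ = sat_sigma(p[paste0("dz.ls", 1:4)], p[paste0("dz.th", 1:6)]))
  mu <- rbind(MZ = p[paste0("mz.mu", 1:4)], DZ = p[paste0("dz.mu", 1:4)])
  k <- length(covariates)
  beta <- NULL
  if (k) {
    beta <- matrix(0, 2, k, dimnames = list(NULL, covariates))
    for (cv in covariates) for (w in 1:2) {
      nm <- paste0("w", w, ".", cv)
      if (nm %in% names(p)) beta[w, cv] <- p[nm]
    }
  }
  structure(list(minus2ll = opt$value, n_free = obj$n_free,
                 aic = opt$value + 2 * obj$n_free,
                 sigma = sigma, mu = mu, beta = beta,
                 convergence = opt$convergence == 0,
                 theta = opt$par, obj = obj, model = "saturated",
                 covariates = covariates, constraints = constraints,
                 prep = prep, groups = groups, seed = seed),
            class = "twin_fit")
}
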
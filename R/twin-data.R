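#' Assemble a long twin phenotype table
#'
#' Validates and normalizes a long-format twin table: one row per individual
#' per wave. This is the exchange format written by the cohort simulator and
#' by the image-metrics stage, and the input to all twin models.
#'
#' @param df data.frame with columns `family_id`, `twin_id`, `birth_order`
#'   (1 or 2), `zygosity` ("MZ"/"DZ"), `sex` (0 male / 1 female),
#'   `age_years`, `mean_fd_mm`, `wave` (1 or 2), `value` (the phenotype;
#'   `NA` allowed).
#' @return The validated data.frame with class `twin_data` prepended.
#' @export
twin_data <- function(df) {
  need <- c("family_id", "twin_id", "birth_order", "zygosity", "sex",
            "age_years", "mean_fd_mm", "wave", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$zygosity %in% c("MZ", "DZ"))) stop("zygosity must be MZ or DZ")
  if (!all(df$birth_order %in% 1:2)) stop("birth_order must be 1 or 2")
  if (!all(df$wave %in% 1:2)) stop("wave must be 1 or 2")
  df <- df[order(df$family_id, df$birth_order, df$wave), , drop = FALSE]
  class(df) <- c("twin_data", class(df))
  df
}

#' Read / write the twin table TSV
#'
#' @param path file path.
#' @return `read_twin_tsv` returns a `twin_data` object.
#' @export
read_twin_tsv <- function(path) {
  twin_data(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @param data a `twin_data` table.
#' @rdname read_twin_tsv
#' @export
write_twin_tsv <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Reshape the long table into per-family structures used by the FIML engine:
#   y    n x 4 phenotype matrix, slots (t1w1, t1w2, t2w1, t2w2), NA = missing
#   X    n x 4 x k covariate array aligned with y (k = 0 when covariates
#        are not modelled); age and mean FD are wave-specific, sex is not
#   zyg  character vector "MZ"/"DZ" per family
# Families with no observed phenotype at all are dropped. Slots whose
# covariates are missing are treated as unobserved (FIML marginalizes them).
prepare_pairs <- function(data, covariates = NULL) {
  fams <- unique(data$family_id)
  n <- length(fams)
  k <- length(covariates)
  y <- matrix(NA_real_, n, 4)
  X <- if (k) array(NA_real_, c(n, 4, k), dimnames = list(NULL, NULL, covariates))
  fidx <- match(data$family_id, fams)
  slot <- (data$birth_order - 1L) * 2L + data$wave
  y[cbind(fidx, slot)] <- data$value
  zyg <- character(n)
  zyg[fidx] <- data$zygosity
  if (k) for (j in seq_len(k)) X[cbind(fidx, slot, j)] <- data[[covariates[j]]]
  if (k) {
    bad <- !is.na(y) & apply(X, c(1, 2), function(v) any(is.na(v)))
    y[bad] <- NA_real_
  }
  keep <- rowSums(!is.na(y)) > 0
  list(y = y[keep, , drop = FALSE],
       X = if (k) X[keep, , , drop = FALSE],
       zyg = zyg[keep], family_id = fams[keep])
}

# Group families by (zygosity, missingness pattern) so each group shares one
# marginal covariance matrix; the per-family mean vectors stay free. Indices
# are stored 0-based for the compiled kernel.
pattern_groups <- function(prep) {
  obs <- !is.na(prep$y)
  key <- paste(prep$zyg, apply(obs, 1, function(r) paste(as.integer(r), collapse = "")))
  idx <- split(seq_len(nrow(prep$y)), key)
  g <- lapply(idx, function(rows) {
    slots <- which(obs[rows[1], ])
    yg <- prep$y[rows, slots, drop = FALSE]
    ybar <- colMeans(yg)
    yc <- sweep(yg, 2, ybar)
    list(rows = rows, slots = slots, zyg = prep$zyg[rows[1]],
         n = length(rows), ybar = ybar, scatter = crossprod(yc) / length(rows))
  })
  list(groups = g,
       rows0 = lapply(g, function(x) x$rows - 1L),
       slots0 = lapply(g, function(x) x$slots - 1L),
       zyg_mz = vapply(g, function(x) as.integer(x$zyg == "MZ"), 1L))
}

# Sufficient-statistic evaluation, valid when the mean matrix is constant
# within each pattern group (no covariates in the means model): each group
# contributes n (k log 2pi + log|S|) + n tr(S^-1 (Shat + d d')) with Shat
# the divide-by-n scatter about the group mean and d = ybar - mu. `M` is a
# `uniform_means` object: `mu4` (all rows equal) or `mu4_by_zyg` (2 x 4,
# rows MZ/DZ).
neg2ll_suff <- function(groups, M, sigma_mz, sigma_dz, penalty = 1e10) {
  total <- 0
  for (g in groups$groups) {
    mz <- g$zyg == "MZ"
    sg <- if (mz) sigma_mz else sigma_dz
    mu4 <- if (is.null(M[["mu4"]])) M[["mu4_by_zyg"]][if (mz) 1 else 2, ]
           else M[["mu4"]]
    s <- sg[g$slots, g$slots, drop = FALSE]
    if (!all(is.finite(s))) return(10 * penalty)
    ch <- tryCatch(chol(s), error = function(e) NULL)
    if (is.null(ch)) return(penalty + sum(abs(s)))
    sinv <- chol2inv(ch)
    d <- g$ybar - mu4[g$slots]
    total <- total + g$n * (length(g$slots) * log(2 * pi) +
                              2 * sum(log(diag(ch))) +
                              sum(sinv * g$scatter) +
                              drop(crossprod(d, sinv %*% d)))
  }
  total
}

# FIML -2 log likelihood over prepared pairs for given 4x4 covariances per
# zygosity and an n x 4 matrix of slot means. Returns a large penalized value
# if any marginal covariance is not positive definite, keeping optimizers in
# bounds.
neg2ll_groups <- function(groups, y, M, sigma_mz, sigma_dz, penalty = 1e10) {
  if (inherits(M, "uniform_means"))
    return(neg2ll_suff(groups, M, sigma_mz, sigma_dz, penalty))
  fiml_neg2ll_kernel(y, M, sigma_mz, sigma_dz,
                     groups$rows0, groups$slots0, groups$zyg_mz, penalty)
}

# Slot mean matrix mu + X beta. beta is a 2 x k matrix (rows = wave).
slot_means <- function(prep, mu, beta = NULL) {
  if (is.null(beta) || !length(beta))
    return(structure(list(mu4 = mu[c(1, 2, 1, 2)]), class = "uniform_means"))
  n <- nrow(prep$y)
  M <- matrix(mu[c(1, 2, 1, 2)], n, 4, byrow = TRUE)
  if (!is.null(beta) && length(beta)) {
    wave_of <- c(1, 2, 1, 2)
    for (s in 1:4) {
      xb <- prep$X[, s, , drop = FALSE]
      dim(xb) <- c(n, dim(prep$X)[3])
      contrib <- xb %*% beta[wave_of[s], ]
      contrib[is.na(contrib)] <- 0
      M[, s] <- M[, s] + contrib
    }
  }
  M
}

#' FIML -2 log-likelihood of a bivariate Cholesky twin model
#'
#' Sums, over twin pairs, the multivariate-normal -2 log density of each
#' family's observed phenotype subvector, with means given by the model's
#' means (plus covariate effects when `params$beta` is present) and
#' covariance given by [implied_covariance()] marginalized to the observed
#' entries. Families with partially missing phenotypes (unpaired twins,
#' missed waves) contribute through their marginal densities, which is what
#' makes full-information maximum likelihood valid under that missingness.
#'
#' @param params a [cholesky_params()] object.
#' @param data a [twin_data()] table.
#' @param covariates character vector of covariate columns used in the mean
#'   model, subset of `c("age_years","sex","mean_fd_mm")`; must match the
#'   columns of `params$beta`. `NULL` for an unadjusted means model.
#' @return The scalar -2 log likelihood.
#' @export
fiml_neg2ll <- function(params, data, covariates = NULL) {
  if (!nrow(data)) stop("empty data")
  prep <- prepare_pairs(data, covariates)
  groups <- pattern_groups(prep)
  M <- slot_means(prep, params$mu, params$beta)
  neg2ll_groups(groups, prep$y, M,
                implied_covariance(params, "MZ"),
                implied_covariance(params, "DZ"))
}
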
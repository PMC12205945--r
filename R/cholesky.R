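#' Bivariate Cholesky path parameters
#'
#' Container for the path coefficients of a bivariate ACE Cholesky
#' decomposition, together with the wave means and (optionally) covariate
#' effects on the means. The three latent sources are additive genetic (A),
#' common environment (C) and unique environment (E); each is parameterized
#' by a lower-triangular 2x2 path matrix, e.g. for A
#' \deqn{L_A = \begin{pmatrix} a_{11} & 0 \\ a_{21} & a_{22} \end{pmatrix}}
#' so that the A contribution to the within-twin covariance is
#' \eqn{L_A L_A'}. Path 21 carries the first-wave latent factor forward into
#' the second variable (wave or trait); path 22 is variance specific to the
#' second variable.
#'
#' @param a,c,e numeric length-3 vectors of paths `(x11, x21, x22)` for the
#'   A, C and E sources. Paths of sources absent from a submodel are 0.
#' @param mu numeric length-2 vector of means for variable 1 and 2.
#' @param beta optional 2x3 matrix of covariate effects on the means; rows
#'   index the variable (wave), columns the covariates
#'   `(age_years, sex, mean_fd_mm)`. `NULL` means no covariate adjustment.
#' @return An object of class `cholesky_params`.
#' @examples
#' p <- cholesky_params(a = c(0.6, 0.4, 0.3), c = c(0.3, 0.2, 0.1),
#'                      e = c(0.7, 0.2, 0.6))
#' implied_covariance(p, "MZ")
#' @export
cholesky_params <- function(a = base::c(0, 0, 0), c = base::c(0, 0, 0),
                            e = base::c(1, 0, 1), mu = base::c(0, 0),
                            beta = NULL) {
  stopifnot(length(a) == 3, length(c) == 3, length(e) == 3, length(mu) == 2)
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    if (nrow(beta) != 2) stop("beta must have one row per wave")
  }
  structure(list(a = as.numeric(a), c = as.numeric(c), e = as.numeric(e),
                 mu = as.numeric(mu), beta = beta),
            class = "cholesky_params")
}

path_matrix <- function(x) matrix(c(x[1], x[2], 0, x[3]), 2, 2)

#' @export
print.cholesky_params <- function(x, ...) {
  cat("Bivariate Cholesky paths (x11, x21, x22):\n")
  cat(sprintf("  a: %s\n", paste(signif(x$a, 4), collapse = ", ")))
  cat(sprintf("  c: %s\n", paste(signif(x$c, 4), collapse = ", ")))
  cat(sprintf("  e: %s\n", paste(signif(x$e, 4), collapse = ", ")))
  cat(sprintf("  mu: %s\n", paste(signif(x$mu, 4), collapse = ", ")))
  if (!is.null(x$beta)) {
    cat("  covariate betas (rows = wave):\n")
    print(signif(x$beta, 4))
  }
  invisible(x)
}

#' Model-implied twin-pair covariance matrix
#'
#' Expands Cholesky paths into the 4x4 covariance of
#' `(twin1 var1, twin1 var2, twin2 var1, twin2 var2)`. The within-twin block
#' is \eqn{L_A L_A' + L_C L_C' + L_E L_E'}; the cross-twin block is
#' \eqn{k L_A L_A' + L_C L_C'} with the additive-genetic cross-twin
#' correlation k = 1 for MZ pairs and 0.5 for DZ pairs, the common
#' environment fully shared, and the unique environment uncorrelated
#' between twins.
#'
#' @param params a [cholesky_params()] object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A symmetric positive semi-definite 4x4 matrix.
#' @export
implied_covariance <- function(params, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  k <- if (zygosity == "MZ") 1 else 0.5
  A <- tcrossprod(path_matrix(params$a))
  C <- tcrossprod(path_matrix(params$c))
  E <- tcrossprod(path_matrix(params$e))
  within <- A + C + E
  cross <- k * A + C
  rbind(cbind(within, cross), cbind(cross, within))
}

# Flip latent-factor column signs so that the reported solution satisfies
# x11 >= 0 and x22 >= 0 for each source (removes reflection
# non-identifiability; leaves L L' unchanged).
normalize_paths <- function(x) {
  if (x[1] < 0) x[1:2] <- -x[1:2]
  if (x[3] < 0) x[3] <- -x[3]
  x
}
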
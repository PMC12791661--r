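# Gaussian MI/CMI from covariance determinants. Shared helpers keep the
# skeleton algorithm and the standalone estimators on the same arithmetic.

# clamp tiny numerical negatives to 0; anything clearly negative signals a
# covariance bug and raises
clamp_info <- function(value) {
  if (is.na(value)) abort("information estimate is NA")
  if (value < -1e-9) {
    abort(paste0("negative information estimate (", format(value),
                 "); covariance computation is inconsistent"))
  }
  max(value, 0)
}

check_info_vec <- function(x, name) {
  if (!is.numeric(x)) abort(paste0(name, " must be numeric"))
  if (anyNA(x)) abort(paste0(name, " contains missing values"))
  if (var(x) == 0) abort(paste0("constant input vector: ", name))
  invisible(x)
}

#' Gaussian mutual information between two vectors
#'
#' Closed-form MI under a bivariate Gaussian model,
#' \eqn{MI(X,Y) = \frac{1}{2}\log\frac{\sigma_X^2 \sigma_Y^2}{|C(X,Y)|}}
#' with `C(X, Y)` the 2x2 sample covariance matrix (denominator n - 1),
#' equal to \eqn{-\frac{1}{2}\log(1-\rho^2)} for the sample correlation
#' \eqn{\rho}. Natural logarithm; units are nats. MI is 0 iff the sample
#' correlation is 0.
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @param cap Value returned (with a warning) when the covariance matrix is
#'   singular (`y` a perfect affine function of `x`), where MI diverges.
#'   Default 10 nats.
#' @return A single nonnegative number (nats). Values in `(-1e-9, 0)` from
#'   floating-point noise are clamped to 0.
#' @export
mi_gaussian <- function(x, y, cap = 10) {
  check_info_vec(x, "x"); check_info_vec(y, "y")
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("at least 3 observations required")
  C <- cov(cbind(x, y))
  d <- C[1, 1] * C[2, 2] - C[1, 2] * C[2, 1]
  if (d <= 0) {
    warn("singular covariance (perfect linear dependence); capping MI")
    return(cap)
  }
  clamp_info(0.5 * log(C[1, 1] * C[2, 2] / d))
}

# determinant helper on a (ridged) covariance matrix subset
subdet <- function(C, idx) {
  if (length(idx) == 0) return(1)
  det(C[idx, idx, drop = FALSE])
}

# CMI from the joint covariance of (x, y, z...); x index 1, y index 2
cmi_from_cov <- function(C, cap = 10) {
  k <- nrow(C)
  ridge <- 1e-10 * sum(diag(C)) / k
  C <- C + diag(ridge, k)
  zi <- seq_len(k)[-(1:2)]
  num <- subdet(C, c(1, zi)) * subdet(C, c(2, zi))
  den <- subdet(C, zi) * subdet(C, seq_len(k))
  if (den <= 0 || num <= 0) {
    if (subdet(C, seq_len(k)) <= 0) {
      abort("singular conditioned covariance after regularization")
    }
    warn("degenerate covariance in CMI; capping")
    return(cap)
  }
  clamp_info(0.5 * log(num / den))
}

#' Gaussian conditional mutual information
#'
#' Closed-form CMI of `x` and `y` given the conditioning columns `z`, under a
#' joint Gaussian model:
#' \eqn{CMI(X,Y|Z) = \frac{1}{2}\log
#'   \frac{|C(X,Z)|\,|C(Y,Z)|}{|C(Z)|\,|C(X,Y,Z)|}},
#' where `|.|` is the determinant of the sample covariance matrix. With a
#' single conditioning column this equals
#' \eqn{-\frac{1}{2}\log(1-\rho^2_{XY\cdot Z})} for the sample partial
#' correlation. CMI near 0 signals conditional independence, i.e. an
#' association explained away by `z`. A small ridge
#' (`1e-10 * trace/dim`) is added to the joint covariance before taking
#' determinants to guard near-singularity.
#'
#' @param x,y Numeric vectors, equal length, neither constant.
#' @param z Numeric vector or matrix of conditioning columns; `NULL` or
#'   zero-column delegates to [mi_gaussian()].
#' @param cap Cap for divergent estimates, in nats. Default 10.
#' @return A single nonnegative number (nats).
#' @export
cmi_gaussian <- function(x, y, z = NULL, cap = 10) {
  if (is.null(z) || NCOL(z) == 0 || length(z) == 0) return(mi_gaussian(x, y, cap = cap))
  check_info_vec(x, "x"); check_info_vec(y, "y")
  z <- as.matrix(z)
  if (nrow(z) != length(x) || length(x) != length(y)) {
    abort("x, y and z must have the same number of observations")
  }
  for (j in seq_len(ncol(z))) {
    if (var(z[, j]) == 0) {
      abort(paste0("constant conditioning column: ",
                   if (!is.null(colnames(z))) colnames(z)[j] else j))
    }
  }
  cmi_from_cov(cov(cbind(x, y, z)), cap = cap)
}
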
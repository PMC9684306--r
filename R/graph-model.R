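#' Validate a precision matrix
#'
#' Checks that `omega` is a square numeric matrix, symmetric to `tol`,
#' with strictly positive diagonal and smallest eigenvalue greater than zero.
#'
#' @param omega numeric p x p matrix.
#' @param tol symmetry tolerance (maximum allowed |omega[j,k] - omega[k,j]|).
#' @return `omega`, invisibly, with dimnames preserved.
#' @keywords internal
check_precision <- function(omega, tol = 1e-10) {
  if (!is.matrix(omega) || !is.numeric(omega) || nrow(omega) != ncol(omega))
    stop("precision matrix must be a square numeric matrix")
  if (max(abs(omega - t(omega))) >= tol)
    stop("precision matrix is not symmetric (tolerance ", format(tol), ")")
  if (any(diag(omega) <= 0))
    stop("precision matrix must have strictly positive diagonal")
  ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop("precision matrix is not positive definite (smallest eigenvalue ",
         format(ev), ")")
  invisible(omega)
}

#' Conditional autoregressive parameters of a Gaussian graphical model
#'
#' Converts a precision matrix Omega into the parameters of the equivalent
#' conditional autoregressive (CAR) specification: each variable given the
#' rest is Gaussian with mean `sum_k beta[j,k] x_k` and variance `sigma2[j]`,
#' where `beta[j,k] = -omega[j,k]/omega[j,j]` and `sigma2[j] = 1/omega[j,j]`.
#' When the diagonal of Omega is constant, `beta` is symmetric.
#'
#' @param omega symmetric positive-definite precision matrix.
#' @return A list of class `"car_parameters"` with components `beta`
#'   (p x p, zero diagonal) and `sigma2` (length-p conditional variances).
#' @examples
#' om <- diag(3); om[1, 2] <- om[2, 1] <- 0.3
#' precision_to_car(om)$beta
#' @export
precision_to_car <- function(omega) {
  check_precision(omega)
  d <- diag(omega)
  beta <- -omega / d            # row j divided by omega[j,j]
  diag(beta) <- 0
  out <- list(beta = beta, sigma2 = 1 / d)
  dimnames(out$beta) <- dimnames(omega)
  names(out$sigma2) <- colnames(omega)
  class(out) <- "car_parameters"
  out
}

#' Partial correlations implied by a precision matrix
#'
#' `rho[j,k] = -omega[j,k] / sqrt(omega[j,j] * omega[k,k])`, with unit
#' diagonal. Zero entries of Omega map to zero partial correlation, i.e.
#' conditional independence and no edge.
#'
#' @inheritParams precision_to_car
#' @return p x p partial correlation matrix.
#' @export
precision_to_partial_corr <- function(omega) {
  check_precision(omega)
  s <- sqrt(diag(omega))
  rho <- -omega / outer(s, s)
  diag(rho) <- 1
  dimnames(rho) <- dimnames(omega)
  rho
}

#' Draw multivariate normal samples from a precision matrix
#'
#' Samples n observations from MVN(0, Omega^-1) using the Cholesky factor of
#' the precision matrix, so no explicit inversion is performed.
#'
#' @inheritParams precision_to_car
#' @param n number of samples (rows), at least 2.
#' @param seed optional integer seed; when supplied the draw is reproducible.
#' @return n x p numeric matrix; column names follow `omega`'s dimnames or
#'   default to `g1..gp`.
#' @export
sample_mvn <- function(omega, n, seed = NULL) {
  check_precision(omega)
  if (n < 2) stop("n must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(omega)
  R <- tryCatch(chol(omega),
                error = function(e) stop("Cholesky factorization failed: ",
                                         "precision matrix not positive definite"))
  z <- matrix(stats::rnorm(n * p), n, p)
  # If omega = R'R then x = R^{-1} z has covariance (R'R)^{-1} = omega^{-1}
  x <- t(backsolve(R, t(z)))
  colnames(x) <- if (!is.null(colnames(omega))) colnames(omega) else
    paste0("g", seq_len(p))
  rownames(x) <- paste0("s", seq_len(n))
  x
}

#' Standardize an expression matrix
#'
#' Centers each gene (column) to mean zero and scales to unit sample
#' variance (n - 1 denominator). Idempotent up to floating-point error.
#'
#' @param x numeric n x p matrix, samples in rows, genes in columns.
#' @return The standardized matrix with attribute `standardized = TRUE`.
#' @export
standardize_expression <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("expression matrix needs at least 2 samples and 2 genes")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    bad <- colnames(x)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("constant column(s): ", paste(bad, collapse = ", "))
  }
  out <- scale(x)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "standardized") <- TRUE
  out
}

#' @keywords internal
is_standardized <- function(x, tol = 1e-8) {
  all(abs(colMeans(x)) < tol) && all(abs(apply(x, 2, stats::var) - 1) < tol)
}

#' Log pseudo-likelihood of the CAR specification
#'
#' Sum over genes j and samples i of the log density of
#' `N(x[i,j]; sum_{k != j} beta[j,k] x[i,k], sigma2[j])`. This is the
#' product-of-conditionals objective the sampler targets; with a symmetric
#' `beta` each unordered pair contributes through both of its rows.
#'
#' @param x standardized expression matrix.
#' @param car a `"car_parameters"` object (or list with `beta`, `sigma2`).
#' @return scalar log pseudo-likelihood.
#' @export
log_pseudo_likelihood <- function(x, car) {
  beta <- car$beta
  sigma2 <- car$sigma2
  if (any(sigma2 <= 0)) stop("sigma2 must be strictly positive")
  n <- nrow(x)
  mu <- x %*% t(beta)                    # mu[i,j] = sum_k beta[j,k] x[i,k]
  rss <- colSums((x - mu)^2)
  val <- sum(-0.5 * n * log(2 * pi * sigma2) - rss / (2 * sigma2))
  if (!is.finite(val)) stop("non-finite pseudo-likelihood")
  val
}
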
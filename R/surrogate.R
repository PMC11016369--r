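#' Gaussian-process surrogate over rotation matrices
#'
#' The Bayesian-optimization acquisition function is the kriging mean of a
#' zero-mean Gaussian process over SO(3) with the squared-exponential
#' covariance on the Frobenius embedding of rotation matrices into R^9:
#' \deqn{k(R_1, R_2) = \sigma^2 \exp(-\|R_1 - R_2\|_F^2 / (2 \ell^2)).}
#' Given observed candidates \code{R_i} with loss values \code{y_i}, the
#' interpolant is \code{m(R) = k_n(R)' (K + eps I)^{-1} y}, where the small
#' nugget \code{eps} keeps the factorization stable when candidates
#' cluster.  The marginal variance \code{sigma2} cancels out of the
#' interpolant and is kept only for documentation fidelity (default 1).
#' The Euclidean gradient of \code{m} is available in closed form, which
#' is what makes the surrogate cheap to minimize on the manifold.
#'
#' @name surrogate
NULL

.check_hyper <- function(sigma2, lengthscale) {
  if (!is.numeric(lengthscale) || length(lengthscale) != 1L ||
      !is.finite(lengthscale) || lengthscale <= 0) {
    stop("'lengthscale' must be a positive number", call. = FALSE)
  }
  if (!is.numeric(sigma2) || length(sigma2) != 1L ||
      !is.finite(sigma2) || sigma2 <= 0) {
    stop("'sigma2' must be a positive number", call. = FALSE)
  }
}

#' Squared-exponential kernel on the Frobenius embedding
#'
#' @param R1,R2 3x3 rotation (or orthogonal) matrices.
#' @param sigma2 marginal variance (> 0).
#' @param lengthscale correlation lengthscale (> 0) in Frobenius units.
#' @return numeric scalar; equals \code{sigma2} at \code{R1 = R2}.
#' @export
se_kernel <- function(R1, R2, sigma2 = 1, lengthscale = 0.75) {
  .check_hyper(sigma2, lengthscale)
  d2 <- sum((R1 - R2)^2)
  sigma2 * exp(-d2 / (2 * lengthscale^2))
}

# candidates as an m x 9 matrix of vectorized rotations
.stack_candidates <- function(candidates) {
  if (is.matrix(candidates) && all(dim(candidates) == c(3L, 3L))) {
    candidates <- list(candidates)
  }
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  t(vapply(candidates, as.numeric, numeric(9L)))
}

#' Kernel matrix of a candidate list
#'
#' @param candidates list of 3x3 rotation matrices.
#' @param sigma2,lengthscale kernel hyperparameters.
#' @return symmetric positive semidefinite matrix with diagonal
#'   \code{sigma2}.
#' @export
kernel_matrix <- function(candidates, sigma2 = 1, lengthscale = 0.75) {
  .check_hyper(sigma2, lengthscale)
  C <- .stack_candidates(candidates)
  sq <- rowSums(C^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(C)
  D2[D2 < 0] <- 0
  K <- sigma2 * exp(-D2 / (2 * lengthscale^2))
  (K + t(K)) / 2
}

#' Fit the nugget-regularized Gaussian-process interpolant
#'
#' Factorizes \code{K + eps I} by Cholesky and solves for the interpolation
#' weights \code{w = (K + eps I)^{-1} y}.  With \code{nugget = 0} and
#' distinct candidates the surrogate mean reproduces every observation;
#' duplicated candidates with a zero nugget make the system singular and
#' raise an error.
#'
#' @param candidates list of 3x3 rotation matrices.
#' @param values numeric loss observations, one per candidate.
#' @param lengthscale kernel lengthscale.
#' @param nugget nonnegative diagonal regularizer.
#' @param sigma2 marginal variance (kept at 1; the interpolant does not
#'   depend on it when the nugget is 0 and only weakly otherwise).
#' @return an object of class \code{gp_surrogate}.
#' @export
fit_interpolant <- function(candidates, values, lengthscale = 0.75,
                            nugget = 1e-4, sigma2 = 1) {
  if (is.matrix(candidates) && all(dim(candidates) == c(3L, 3L))) {
    candidates <- list(candidates)
  }
  stopifnot(length(candidates) == length(values), nugget >= 0)
  K <- kernel_matrix(candidates, sigma2 = sigma2, lengthscale = lengthscale)
  Kr <- K + diag(nugget, nrow(K))
  fac <- tryCatch(chol(Kr), error = function(e) {
    stop("kernel system is not positive definite ",
         "(duplicated candidates with zero nugget?)", call. = FALSE)
  })
  w <- backsolve(fac, backsolve(fac, values, transpose = TRUE))
  structure(list(lengthscale = lengthscale, sigma2 = sigma2,
                 nugget = nugget,
                 C = .stack_candidates(candidates),
                 candidates = candidates,
                 values = as.numeric(values),
                 factor = fac, weights = as.numeric(w)),
            class = "gp_surrogate")
}

#' @export
print.gp_surrogate <- function(x, ...) {
  cat(sprintf(
    "gp_surrogate: %d candidates, lengthscale %.3g, nugget %.3g\n",
    length(x$values), x$lengthscale, x$nugget))
  invisible(x)
}

# cross-kernel vector k_n(R) against the stored candidates
.cross_kernel <- function(state, R) {
  r <- as.numeric(R)
  d2 <- rowSums(state$C^2) - 2 * drop(state$C %*% r) + sum(r^2)
  d2[d2 < 0] <- 0
  state$sigma2 * exp(-d2 / (2 * state$lengthscale^2))
}

#' Surrogate (kriging) mean at a rotation
#'
#' @param state a fitted \code{gp_surrogate}.
#' @param R 3x3 rotation matrix.
#' @return numeric scalar \code{k_n(R)' w}.
#' @export
surrogate_mean <- function(state, R) {
  stopifnot(inherits(state, "gp_surrogate"))
  sum(.cross_kernel(state, R) * state$weights)
}

#' Euclidean gradient of the surrogate mean
#'
#' The gradient with respect to the nine matrix entries,
#' \deqn{\nabla m(R) = \sum_i w_i k(R, R_i) (R_i - R) / \ell^2,}
#' returned as a 3x3 array.  Consistent with central finite differences.
#'
#' @inheritParams surrogate_mean
#' @return 3x3 numeric matrix.
#' @export
surrogate_grad <- function(state, R) {
  stopifnot(inherits(state, "gp_surrogate"))
  kv <- .cross_kernel(state, R) * state$weights
  g <- drop(crossprod(state$C, kv)) - as.numeric(R) * sum(kv)
  matrix(g / state$lengthscale^2, 3L, 3L)
}
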
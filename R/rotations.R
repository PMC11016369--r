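#' Rotation-group utilities
#'
#' Helpers for working with 3x3 rotation matrices (the group SO(3)) and,
#' for handedness searches, reflection-composed orthogonal matrices in O(3).
#' Rotations are represented as plain 3x3 numeric matrices throughout; the
#' functions here validate, sample, compare, parametrize and project them.
#'
#' @name rotations
NULL

.ROT_TOL <- 1e-10

#' Test whether a matrix is a valid rotation
#'
#' A valid rotation is a 3x3 real matrix with \code{t(R) \%*\% R = I} (max
#' absolute deviation below \code{tol}) and determinant +1.  Orthogonal
#' matrices with determinant -1 (reflections) are accepted only when
#' \code{allow_reflection = TRUE}.
#'
#' @param R matrix to test.
#' @param tol tolerance on orthogonality and determinant.
#' @param allow_reflection accept determinant -1 as well.
#' @return logical scalar.
#' @export
is_rotation <- function(R, tol = 1e-8, allow_reflection = FALSE) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || !is.numeric(R) ||
      anyNA(R) || any(!is.finite(R))) {
    return(FALSE)
  }
  if (max(abs(crossprod(R) - diag(3))) > tol) return(FALSE)
  d <- det(R)
  if (allow_reflection) abs(abs(d) - 1) <= tol else abs(d - 1) <= tol
}

.check_rotation <- function(R, allow_reflection = FALSE,
                            arg = deparse(substitute(R))) {
  if (!is_rotation(R, allow_reflection = allow_reflection)) {
    stop("'", arg, "' is not a valid ",
         if (allow_reflection) "orthogonal matrix" else "rotation matrix",
         call. = FALSE)
  }
  invisible(R)
}

#' Sample rotations uniformly (Haar measure) on SO(3)
#'
#' Draws rotation matrices from the Haar (uniform) distribution by
#' normalizing a 4-dimensional standard Gaussian to a unit quaternion and
#' converting it to a matrix.  The construction is exactly uniform and
#' reproducible under \code{set.seed}.
#'
#' @param n number of rotations to draw.
#' @param seed optional integer; when supplied, the function seeds R's RNG
#'   locally (restoring the previous state on exit) so a given seed always
#'   yields the same sample.
#' @return a 3x3 matrix if \code{n = 1}, otherwise a list of matrices.
#' @export
random_rotation <- function(n = 1L, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    out[[i]] <- quat_to_matrix(q)
  }
  if (n == 1L) out[[1L]] else out
}

# unit quaternion (w, x, y, z) -> rotation matrix
quat_to_matrix <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3L, 3L, byrow = TRUE)
}

#' Relative angle between two rotations
#'
#' The geodesic distance on SO(3):
#' \code{acos((trace(t(R1) \%*\% R2) - 1) / 2)}, reported in degrees in
#' [0, 180].  The arccos argument is clamped to [-1, 1] so that float
#' drift near 0 and 180 degrees cannot produce NaN.
#'
#' @param R1,R2 rotation matrices.
#' @return angle in degrees.
#' @export
relative_angle_deg <- function(R1, R2) {
  .check_rotation(R1, allow_reflection = TRUE)
  .check_rotation(R2, allow_reflection = TRUE)
  cosang <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Axis-angle (rotation-vector) exponential and logarithm
#'
#' \code{exp_rotvec} maps a rotation vector \code{v} (axis times angle in
#' radians) to a rotation matrix via the Rodrigues formula;
#' \code{log_rotvec} is its inverse with the canonical branch angle in
#' [0, pi].  At exactly 180 degrees the axis is only defined up to sign and
#' either of the two antipodal vectors may be returned.
#'
#' @param v numeric length-3 rotation vector.
#' @return \code{exp_rotvec}: a 3x3 rotation matrix.
#' @export
exp_rotvec <- function(v) {
  stopifnot(is.numeric(v), length(v) == 3L, all(is.finite(v)))
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3L], k[2L],
                k[3L], 0, -k[1L],
                -k[2L], k[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname exp_rotvec
#' @param R a rotation matrix (determinant +1).
#' @return \code{log_rotvec}: a length-3 rotation vector with norm <= pi.
#' @export
log_rotvec <- function(R) {
  .check_rotation(R)
  cosang <- (sum(diag(R)) - 1) / 2
  th <- acos(min(1, max(-1, cosang)))
  if (th < 1e-10) return(c(0, 0, 0))
  if (pi - th < 1e-6) {
    # angle ~ pi: axis from the symmetric part, R = I + 2 K^2 => kk' = (R + I)/2
    B <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(B), 0))
    i <- which.max(k)
    # fix relative signs from off-diagonal entries
    if (k[i] > 0) {
      s <- B[i, ] / k[i]
      k <- s
      k <- k / sqrt(sum(k^2))
    }
    # canonical tie-break: first nonzero component positive
    j <- which(abs(k) > 1e-12)[1L]
    if (k[j] < 0) k <- -k
    return(th * k)
  }
  ax <- c(R[3L, 2L] - R[2L, 3L],
          R[1L, 3L] - R[3L, 1L],
          R[2L, 1L] - R[1L, 2L]) / (2 * sin(th))
  th * ax
}

#' Project a matrix to the nearest rotation
#'
#' Returns the special-orthogonal matrix closest in Frobenius norm to
#' \code{M}, computed from the polar factor of the SVD with a determinant
#' sign correction.
#'
#' @param M nonsingular 3x3 matrix.
#' @return a rotation matrix (determinant +1).
#' @export
project_to_rotation <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == c(3L, 3L)), all(is.finite(M)))
  s <- svd(M)
  if (min(s$d) <= 1e-12 * max(s$d)) {
    stop("matrix is singular; nearest rotation is not unique", call. = FALSE)
  }
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    # flip the singular vector of the smallest singular value
    u <- s$u
    u[, 3L] <- -u[, 3L]
    R <- u %*% t(s$v)
  }
  R
}

#' Compose a rotation with a coordinate reflection
#'
#' Multiplies on the right by \code{diag(-1, 1, 1)}, producing an
#' orthogonal matrix with determinant -1.  Used for handedness searches
#' over O(3).  Applying it twice restores the input.
#'
#' @param R rotation matrix (determinant +1), or a previously reflected one.
#' @return orthogonal 3x3 matrix with the opposite determinant sign.
#' @export
reflect_rotation <- function(R) {
  .check_rotation(R, allow_reflection = TRUE)
  R %*% diag(c(-1, 1, 1))
}
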
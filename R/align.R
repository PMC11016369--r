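#' Alignment configuration
#'
#' Collects the tunable parameters of the alignment pipeline.  Defaults
#' follow the published settings of the method: kernel lengthscale 0.75
#' for the WEMD loss and 1.0 for the L2 loss, identity initial candidate,
#' early stopping of the surrogate minimization when both the Riemannian
#' gradient norm and the step size fall below 0.1, sym3 wavelet, and
#' refinement at downsampling level 32 in Euclidean loss.
#'
#' @param iterations total number of loss evaluations N of the Bayesian
#'   optimization loop (default 200).
#' @param downsample grid size to Fourier-crop the maps to before
#'   optimization (default 32); clipped to the input size.
#' @param loss \code{"wemd"} (default), \code{"l2"}, or \code{"custom"}.
#' @param lengthscale GP kernel lengthscale; default 0.75 for WEMD and
#'   1.0 for L2.
#' @param nugget kernel diagonal regularizer (default 1e-4).
#' @param grad_tol,step_tol early-stopping thresholds of the surrogate
#'   minimization (default 0.1 each).
#' @param max_inner iteration cap of the surrogate minimization
#'   (default 100).
#' @param restarts random initializations per surrogate minimization
#'   (default 1).
#' @param refine run the Nelder-Mead L2 refinement (default TRUE).
#' @param refine_downsample grid size for the refinement stage
#'   (default 32).
#' @param handedness also align against the reflected moving map and keep
#'   the better branch (default FALSE).
#' @param seed integer seed making the whole run reproducible.
#' @param backend rotation backend, \code{"fourier"} or
#'   \code{"trilinear"}.
#' @param wavelet,depth WEMD signature parameters; the depth is clamped
#'   at run time to the maximum the working grid supports.
#' @param contour threshold for the centering step (NULL = heuristic, see
#'   \code{\link{center_map}}).
#' @param custom_loss distance function for \code{loss = "custom"}.
#' @return an object of class \code{align_config}.
#' @export
align_config <- function(iterations = 200L, downsample = 32L,
                         loss = c("wemd", "l2", "custom"),
                         lengthscale = NULL, nugget = 1e-4,
                         grad_tol = 0.1, step_tol = 0.1,
                         max_inner = 100L, restarts = 1L,
                         refine = TRUE, refine_downsample = 32L,
                         handedness = FALSE, seed = NULL,
                         backend = c("fourier", "trilinear"),
                         wavelet = "sym3", depth = 6L, contour = NULL,
                         custom_loss = NULL) {
  loss <- match.arg(loss)
  backend <- match.arg(backend)
  if (is.null(lengthscale)) {
    lengthscale <- if (loss == "l2") 1.0 else 0.75
  }
  stopifnot(iterations >= 1L, grad_tol > 0, step_tol > 0, nugget >= 0,
            max_inner >= 1L, restarts >= 1L)
  structure(list(iterations = as.integer(iterations),
                 downsample = as.integer(downsample),
                 loss = loss, lengthscale = lengthscale, nugget = nugget,
                 grad_tol = grad_tol, step_tol = step_tol,
                 max_inner = as.integer(max_inner),
                 restarts = as.integer(restarts),
                 refine = isTRUE(refine),
                 refine_downsample = as.integer(refine_downsample),
                 handedness = isTRUE(handedness), seed = seed,
                 backend = backend, wavelet = wavelet,
                 depth = as.integer(depth), contour = contour,
                 custom_loss = custom_loss),
            class = "align_config")
}

# skew-symmetric part
.skew <- function(A) (A - t(A)) / 2

# QR-based retraction onto SO(3) with positive-diagonal convention
.retract <- function(M) {
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

#' Minimize the surrogate over SO(3) by Riemannian steepest descent
#'
#' Starting from a Haar-random rotation (or a supplied start), descends
#' the surrogate mean along the negative Riemannian gradient (the
#' Euclidean gradient projected onto the tangent space), stepping by a
#' QR retraction with backtracking line search.  Stops early when both
#' the Riemannian gradient norm and the last step size fall below their
#' thresholds, or at the iteration cap; the best iterate found is
#' returned, so the surrogate value at the output never exceeds the value
#' at the initialization.
#'
#' @param state a fitted \code{gp_surrogate}.
#' @param start optional 3x3 rotation to start from; default Haar-random
#'   (drawn from R's current RNG stream).
#' @param grad_tol,step_tol early-stopping thresholds.
#' @param max_iter iteration cap.
#' @return a 3x3 rotation matrix.
#' @export
minimize_surrogate <- function(state, start = NULL, grad_tol = 0.1,
                               step_tol = 0.1, max_iter = 100L) {
  stopifnot(inherits(state, "gp_surrogate"))
  R <- if (is.null(start)) random_rotation() else start
  val <- surrogate_mean(state, R)
  best_R <- R
  best_val <- val
  t_step <- 1
  for (it in seq_len(max_iter)) {
    G <- surrogate_grad(state, R)
    xi <- R %*% .skew(crossprod(R, G))   # Riemannian gradient at R
    gn <- sqrt(sum(xi^2))
    if (gn < 1e-14) break
    # backtracking line search on the surrogate mean
    t_try <- min(max(t_step * 2, 1e-3), 1e3)
    accepted <- FALSE
    step_len <- 0
    for (bt in seq_len(40L)) {
      R_new <- .retract(R - t_try * xi)
      v_new <- surrogate_mean(state, R_new)
      if (v_new <= val - 1e-4 * t_try * gn^2) {
        accepted <- TRUE
        break
      }
      t_try <- t_try / 2
    }
    if (!accepted) break
    step_len <- sqrt(sum((R_new - R)^2))
    R <- R_new
    val <- v_new
    t_step <- t_try
    if (val < best_val) {
      best_val <- val
      best_R <- R
    }
    if (gn < grad_tol && step_len < step_tol) break
  }
  best_R
}

#' Bayesian-optimization rotation search
#'
#' Runs the surrogate-minimization loop over SO(3): the candidate list
#' starts with the identity matrix; each iteration fits the
#' Gaussian-process interpolant on the history, minimizes it by Riemannian
#' steepest descent from a random start, evaluates the alignment loss at
#' the proposed candidate and appends the observation.  After
#' \code{cfg$iterations} loss evaluations the candidate with the smallest
#' observed loss (first occurrence on ties) is returned.  The loss is
#' \code{d(f1, rotate_map(f2, R))}: the returned rotation applies to the
#' second (moving) map.
#'
#' @param f1,f2 \code{\link{density_map}}s of equal size, already
#'   centered.
#' @param cfg an \code{\link{align_config}}.
#' @param loss optionally a prebuilt \code{\link{make_loss}} functional
#'   (used by the pipeline to share signatures); default built from
#'   \code{cfg}.
#' @return an object of class \code{alignment_result} with fields
#'   \code{rotation_bo}, \code{best_loss}, \code{loss_trace} (data frame
#'   of candidate index and loss), \code{evaluations}, and
#'   \code{candidates}.
#' @export
bo_align <- function(f1, f2, cfg = align_config(), loss = NULL) {
  if (is.null(loss)) {
    f1 <- .as_map(f1); f2 <- .as_map(f2)
    if (f1$n != f2$n) stop("maps have different sizes", call. = FALSE)
    # clamp the decomposition depth to what the working grid supports
    depth <- min(cfg$depth, floor(log2(f1$n)) + 1L)
    loss <- make_loss(f1, f2, kind = cfg$loss, wavelet = cfg$wavelet,
                      depth = depth, backend = cfg$backend,
                      custom = cfg$custom_loss)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  N <- cfg$iterations
  candidates <- vector("list", N)
  values <- numeric(N)
  candidates[[1L]] <- diag(3)
  values[1L] <- loss(diag(3))
  if (N > 1L) {
    C_hist <- matrix(as.numeric(diag(3)), nrow = 1L)
    for (i in 2L:N) {
      state <- fit_interpolant(candidates[seq_len(i - 1L)],
                               values[seq_len(i - 1L)],
                               lengthscale = cfg$lengthscale,
                               nugget = cfg$nugget)
      prop <- NULL
      prop_val <- Inf
      for (r in seq_len(cfg$restarts)) {
        cand <- minimize_surrogate(state, grad_tol = cfg$grad_tol,
                                   step_tol = cfg$step_tol,
                                   max_iter = cfg$max_inner)
        cv <- surrogate_mean(state, cand)
        if (cv < prop_val) {
          prop <- cand
          prop_val <- cv
        }
      }
      # duplicate guard: keep the kernel system well-conditioned
      d2min <- min(rowSums(sweep(C_hist, 2L, as.numeric(prop))^2))
      if (sqrt(d2min) < 1e-6) {
        prop <- prop %*% exp_rotvec(stats::rnorm(3) *
                                      (pi / 180) / sqrt(3))
      }
      candidates[[i]] <- prop
      values[i] <- loss(prop)
      C_hist <- rbind(C_hist, as.numeric(prop))
    }
  }
  best <- which.min(values)  # first occurrence on ties
  structure(list(rotation_bo = candidates[[best]],
                 best_loss = values[best],
                 best_index = best,
                 loss_trace = data.frame(candidate = seq_len(N),
                                         loss = values),
                 evaluations = loss_evaluations(loss),
                 candidates = candidates),
            class = "alignment_result")
}

#' Nelder-Mead refinement in Euclidean loss
#'
#' Polishes a rotation estimate by minimizing
#' \code{l2_distance(f1, rotate_map(f2, exp_rotvec(delta) \%*\% R_init))}
#' over the 3-dimensional rotation-vector perturbation \code{delta} with
#' the Nelder-Mead simplex method started at \code{delta = 0}.  The final
#' loss never exceeds the loss at \code{R_init} (best-vertex return).
#'
#' @param f1,f2 centered \code{\link{density_map}}s of equal size.
#' @param R_init rotation to refine (moving-map convention, as returned
#'   by \code{\link{bo_align}}).
#' @param cfg an \code{\link{align_config}} (backend is honored).
#' @param maxit Nelder-Mead iteration cap.
#' @return list with \code{rotation} (refined 3x3 matrix), \code{loss}
#'   (final L2 loss) and \code{evaluations}.
#' @export
refine_nelder_mead <- function(f1, f2, R_init, cfg = align_config(),
                               maxit = 200L) {
  .check_rotation(R_init, allow_reflection = TRUE)
  loss <- make_loss(f1, f2, kind = "l2", backend = cfg$backend)
  obj <- function(delta) loss(exp_rotvec(delta) %*% R_init)
  opt <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  list(rotation = exp_rotvec(opt$par) %*% R_init,
       loss = opt$value,
       evaluations = loss_evaluations(loss))
}

#' Align two density maps end to end
#'
#' Full pipeline: both maps are centered at their thresholded centers of
#' mass at full resolution, Fourier-downsampled, and the rotation is
#' estimated with \code{\link{bo_align}}; optionally the estimate is
#' polished by \code{\link{refine_nelder_mead}} in Euclidean loss at the
#' refinement downsampling level.  With \code{handedness = TRUE} the whole
#' procedure is repeated against the reflected moving map and the branch
#' with the smaller final loss is returned with the \code{reflected} flag
#' set.
#'
#' Conventions: the moving map is modelled as
#' \code{f2 = shift(rotate_map(f1, rotation), shift)} (for a reflected
#' result, with \code{reflect_map(f2)} in place of \code{f2}).
#' \code{rotation} is the forward estimate; \code{rotation_bo} and
#' \code{rotation_refined} are kept in the internal moving-map convention
#' (their transpose).  The shift is reported in full-resolution voxels
#' and is recovered at centering time from the two centers of mass; it is
#' not re-estimated after refinement.
#'
#' @param f1 fixed \code{\link{density_map}}.
#' @param f2 moving \code{\link{density_map}} of the same size.
#' @param cfg an \code{\link{align_config}}.
#' @return an \code{alignment_result} with fields \code{rotation},
#'   \code{rotation_bo}, \code{rotation_refined} (or NULL), \code{shift},
#'   \code{reflected}, \code{best_loss}, \code{final_loss},
#'   \code{loss_trace}, \code{evaluations},
#'   \code{refine_evaluations}.
#' @export
align_volumes <- function(f1, f2, cfg = align_config()) {
  f1 <- .as_map(f1); f2 <- .as_map(f2)
  if (f1$n != f2$n) stop("maps have different sizes", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  c1 <- center_map(f1, contour = cfg$contour)
  run_branch <- function(f2_branch) {
    c2 <- center_map(f2_branch, contour = cfg$contour)
    n <- f1$n
    m <- min(cfg$downsample, n)
    f1d <- downsample_fourier(c1$map, m)
    f2d <- downsample_fourier(c2$map, m)
    cfg_bo <- cfg
    cfg_bo$seed <- NULL  # RNG stream already set once for the whole run
    res <- bo_align(f1d, f2d, cfg_bo)
    R_hat <- res$rotation_bo
    res$rotation_refined <- NULL
    res$refine_evaluations <- 0L
    if (cfg$refine) {
      mr <- min(cfg$refine_downsample, n)
      f1r <- downsample_fourier(c1$map, mr)
      f2r <- downsample_fourier(c2$map, mr)
      ref <- refine_nelder_mead(f1r, f2r, res$rotation_bo, cfg)
      res$rotation_refined <- ref$rotation
      res$refine_evaluations <- ref$evaluations
      res$final_loss <- ref$loss
      R_hat <- ref$rotation
    } else {
      res$final_loss <- res$best_loss
    }
    # forward model: f2 ~ shift(rotate(f1, R_fwd), t);
    # bo/refined rotations live in the moving-map convention (f2 -> f1)
    res$rotation <- t(R_hat)
    res$shift <- (-c2$shift) - drop(res$rotation %*% (-c1$shift))
    res
  }
  res <- run_branch(f2)
  res$reflected <- FALSE
  if (cfg$handedness) {
    res_ref <- run_branch(reflect_map(f2))
    res_ref$reflected <- TRUE
    if (res_ref$final_loss < res$final_loss) res <- res_ref
  }
  res$config <- cfg
  class(res) <- "alignment_result"
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("alignment_result\n")
  if (!is.null(x$rotation)) {
    cat("  rotation (forward, f1 -> f2):\n")
    m <- format(round(x$rotation, 5), nsmall = 5)
    for (i in 1:3) cat("    ", m[i, 1], m[i, 2], m[i, 3], "\n")
  }
  if (!is.null(x$shift)) {
    cat(sprintf("  shift (voxels): %s\n",
                paste(sprintf("%.3f", x$shift), collapse = ", ")))
  }
  if (!is.null(x$reflected)) cat("  reflected:", x$reflected, "\n")
  cat(sprintf("  best BO loss: %.6g after %d evaluations\n",
              x$best_loss, x$evaluations))
  if (!is.null(x$final_loss) && !is.null(x$rotation_refined)) {
    cat(sprintf("  refined L2 loss: %.6g (%d extra evaluations)\n",
                x$final_loss, x$refine_evaluations))
  }
  invisible(x)
}

#' Rotation recovery error in degrees
#'
#' The relative angle between the estimated and the true rotation - the
#' geodesic distance on SO(3).  Invariant under simultaneous
#' left-multiplication of both arguments.
#'
#' @param R_est,R_true rotation matrices.
#' @return angle in degrees.
#' @export
recovery_error <- function(R_est, R_true) relative_angle_deg(R_est, R_true)
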
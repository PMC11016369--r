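#' Wavelet earth mover's distance (WEMD)
#'
#' The 1-Wasserstein (earth mover's) distance between two densities can be
#' approximated, up to metric equivalence, by a weighted L1 distance
#' between their multiscale wavelet coefficients: writing the difference
#' \code{f - g} in a 3D wavelet basis with coefficients \code{w_{j,k}} at
#' dyadic scale \code{j} (larger = finer, following the convention
#' \code{psi_{j,k}(x) = 2^{jd/2} psi(2^j x - k)}),
#' \deqn{WEMD(f, g) = \sum_{j,k} 2^{-j(1 + d/2)} |w_{j,k}|, \quad d = 3.}
#' Coarse scales therefore carry geometrically larger weights - moving
#' mass far costs more - which is what makes the quantity transport-like.
#' Unlike the exact Wasserstein distance it is defined for maps with
#' negative values or unequal mass, and costs O(n^3) per evaluation.
#'
#' Here the finest resolvable scale of the voxel grid is indexed j = 0, so
#' the decomposition level \code{l = 1..J} (1 = finest) has scale
#' \code{j = -(l - 1)} and weight \code{2^{(l-1)(1+d/2)}}.  The coarsest
#' approximation (scaling) band is kept with the coarsest-level weight so
#' the distance stays sensitive to bulk mass displacement.
#'
#' @name wemd
NULL

# sym3 analysis filters (equal to db3 at this order)
.SYM3_DEC_LO <- c(0.035226291882100656, -0.08544127388224149,
                  -0.13501102001039084, 0.4598775021193313,
                  0.8068915093133388, 0.3326705529509569)
.SYM3_DEC_HI <- c(-0.3326705529509569, 0.8068915093133388,
                  -0.4598775021193313, -0.13501102001039084,
                  0.08544127388224149, 0.035226291882100656)

.wavelet_filters <- function(wavelet) {
  if (!identical(wavelet, "sym3")) {
    stop("unsupported wavelet '", wavelet, "' (available: sym3)",
         call. = FALSE)
  }
  list(lo = .SYM3_DEC_LO, hi = .SYM3_DEC_HI)
}

# single-level 1D analysis matrix for signals of length n with zero-padding
# boundary extension: full convolution with the filter, keeping every
# second sample (even 1-based positions); output length floor((n+L-1)/2)
.dwt_matrix <- function(n, filt) {
  L <- length(filt)
  m <- (n + L - 1L) %/% 2L
  A <- matrix(0, m, n)
  for (r in seq_len(m)) {
    p <- 2L * r               # position in the full convolution (1-based)
    for (q in seq_len(L)) {
      cidx <- p - q + 1L      # conv: y[p] = sum_q filt[q] * x[p - q + 1]
      if (cidx >= 1L && cidx <= n) A[r, cidx] <- filt[q]
    }
  }
  A
}

# apply a matrix along the first axis of a 3D array
.apply_axis1 <- function(A, arr) {
  d <- dim(arr)
  out <- A %*% matrix(arr, nrow = d[1L])
  array(out, dim = c(nrow(A), d[2L], d[3L]))
}

# one separable 3D analysis level; returns the approximation band and the
# 7 detail subbands
.dwt3_level <- function(arr, lo_mat, hi_mat) {
  rot <- function(a) aperm(a, c(2L, 3L, 1L))
  lx <- rot(.apply_axis1(lo_mat, arr)); hx <- rot(.apply_axis1(hi_mat, arr))
  lxly <- rot(.apply_axis1(lo_mat, lx)); lxhy <- rot(.apply_axis1(hi_mat, lx))
  hxly <- rot(.apply_axis1(lo_mat, hx)); hxhy <- rot(.apply_axis1(hi_mat, hx))
  list(
    approx  = rot(.apply_axis1(lo_mat, lxly)),
    details = list(
      rot(.apply_axis1(hi_mat, lxly)),   # LLH
      rot(.apply_axis1(lo_mat, lxhy)),   # LHL
      rot(.apply_axis1(hi_mat, lxhy)),   # LHH
      rot(.apply_axis1(lo_mat, hxly)),   # HLL
      rot(.apply_axis1(hi_mat, hxly)),   # HLH
      rot(.apply_axis1(lo_mat, hxhy)),   # HHL
      rot(.apply_axis1(hi_mat, hxhy))    # HHH
    )
  )
}

#' Weighted multiscale wavelet signature of a map
#'
#' Computes a separable 3D discrete wavelet decomposition to depth
#' \code{depth} with zero-padding boundary extension and multiplies every
#' coefficient by its scale weight \code{2^{(l-1)(1+d/2)}} (level
#' \code{l = 1} finest, \code{d = 3}); the coarsest approximation band is
#' included at the coarsest-level weight.  The WEMD between two maps is
#' then the plain L1 distance between their signatures
#' (\code{\link{wemd_distance}}).  Map mass is used as-is - the
#' approximation is well defined for maps with negative values - unless
#' \code{normalize = TRUE} divides by the total mass first.
#'
#' @param map a \code{\link{density_map}}.
#' @param wavelet wavelet family name (currently \code{"sym3"}).
#' @param depth decomposition depth J >= 1.  Depths with
#'   \code{2^(depth-1) > n} are refused as coarser than the box.
#' @param normalize divide the map by its total mass first (default off).
#' @return an object of class \code{wemd_signature}: a list with
#'   \code{coefficients} (flat numeric vector of weighted coefficients)
#'   and \code{meta} (wavelet, depth, n).
#' @export
wavelet_signature <- function(map, wavelet = "sym3", depth = 6L,
                              normalize = FALSE) {
  map <- .as_map(map)
  depth <- as.integer(depth)
  if (depth < 1L) stop("'depth' must be >= 1", call. = FALSE)
  if (2^(depth - 1L) > map$n) {
    stop("depth ", depth, " too large for grid size ", map$n, call. = FALSE)
  }
  f <- .wavelet_filters(wavelet)
  arr <- map$data
  if (normalize) {
    tot <- sum(arr)
    if (tot == 0) stop("cannot normalize a zero-mass map", call. = FALSE)
    arr <- arr / tot
  }
  w_step <- 2^(1 + 3 / 2)   # per-level weight ratio 2^(1+d/2), d = 3
  pieces <- vector("list", depth + 1L)
  weight <- 1
  for (l in seq_len(depth)) {
    nn <- dim(arr)[1L]
    lo_mat <- .dwt_matrix(nn, f$lo)
    hi_mat <- .dwt_matrix(nn, f$hi)
    lev <- .dwt3_level(arr, lo_mat, hi_mat)
    pieces[[l]] <- weight * unlist(lapply(lev$details, as.numeric),
                                   use.names = FALSE)
    arr <- lev$approx
    if (l < depth) weight <- weight * w_step
  }
  pieces[[depth + 1L]] <- weight * as.numeric(arr)  # coarsest approx band
  structure(list(coefficients = unlist(pieces, use.names = FALSE),
                 meta = list(wavelet = wavelet, depth = depth, n = map$n)),
            class = "wemd_signature")
}

#' @export
print.wemd_signature <- function(x, ...) {
  cat(sprintf("wemd_signature: %d coefficients (%s, depth %d, n = %d)\n",
              length(x$coefficients), x$meta$wavelet, x$meta$depth,
              x$meta$n))
  invisible(x)
}

#' WEMD between two wavelet signatures
#'
#' The L1 distance between the weighted coefficient vectors.  Signatures
#' are comparable only when computed with the same wavelet, depth and grid
#' size.
#'
#' @param a,b \code{wemd_signature} objects with matching meta fields.
#' @return nonnegative numeric scalar.
#' @export
wemd_distance <- function(a, b) {
  stopifnot(inherits(a, "wemd_signature"), inherits(b, "wemd_signature"))
  if (!identical(a$meta, b$meta)) {
    stop("signature meta mismatch: signatures are not comparable",
         call. = FALSE)
  }
  sum(abs(a$coefficients - b$coefficients))
}

#' Euclidean (L2) distance between two maps
#'
#' @param f,g \code{\link{density_map}}s of equal size.
#' @return nonnegative numeric scalar.
#' @export
l2_distance <- function(f, g) {
  f <- .as_map(f); g <- .as_map(g)
  if (f$n != g$n) stop("maps have different sizes", call. = FALSE)
  sqrt(sum((f$data - g$data)^2))
}

#' Build an alignment loss functional over rotations
#'
#' Returns a function \code{loss(R)} evaluating the chosen distance
#' between \code{f1} and \code{rotate_map(f2, R)}.  For the WEMD loss the
#' signature of \code{f1} is computed once at construction.  The number of
#' evaluations performed so far is observable via
#' \code{\link{loss_evaluations}} for budget accounting.
#'
#' @param f1,f2 \code{\link{density_map}}s of equal size.
#' @param kind \code{"wemd"}, \code{"l2"}, or \code{"custom"}.
#' @param wavelet,depth signature parameters for the WEMD loss, fixed at
#'   construction.
#' @param backend rotation backend passed to \code{\link{rotate_map}}.
#' @param custom for \code{kind = "custom"}: a function
#'   \code{d(f1, f2_rotated)} returning a numeric scalar.
#' @return a function of class \code{alignment_loss}.
#' @export
make_loss <- function(f1, f2, kind = c("wemd", "l2", "custom"),
                      wavelet = "sym3", depth = 6L,
                      backend = "fourier", custom = NULL) {
  f1 <- .as_map(f1); f2 <- .as_map(f2)
  if (f1$n != f2$n) stop("maps have different sizes", call. = FALSE)
  kind <- match.arg(kind)
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  rot2 <- .map_rotator(f2, backend = backend)  # shared upsample cache
  fn <- switch(kind,
    wemd = {
      sig1 <- wavelet_signature(f1, wavelet = wavelet, depth = depth)
      function(R) {
        env$count <- env$count + 1L
        wemd_distance(sig1, wavelet_signature(rot2(R), wavelet = wavelet,
                                              depth = depth))
      }
    },
    l2 = function(R) {
      env$count <- env$count + 1L
      l2_distance(f1, rot2(R))
    },
    custom = {
      if (!is.function(custom)) {
        stop("kind = 'custom' requires a 'custom' distance function",
             call. = FALSE)
      }
      function(R) {
        env$count <- env$count + 1L
        custom(f1, rot2(R))
      }
    }
  )
  structure(fn, class = c("alignment_loss", "function"),
            counter = env, kind = kind)
}

#' Number of evaluations performed by an alignment loss
#' @param loss a loss built by \code{\link{make_loss}}.
#' @return integer count.
#' @export
loss_evaluations <- function(loss) {
  stopifnot(inherits(loss, "alignment_loss"))
  attr(loss, "counter")$count
}

#' Loss-landscape diagnostic scan
#'
#' Evaluates the self-alignment loss of a map against itself rotated by a
#' two-axis composed rotation \code{R_axis2(b) \%*\% R_axis1(a)} on a grid
#' of angle pairs - the flat-basin diagnostic for comparing WEMD against
#' the Euclidean loss.
#'
#' @param map a \code{\link{density_map}}.
#' @param kind loss kind for \code{\link{make_loss}}.
#' @param angles two-column matrix (degrees) of angle pairs (a, b).
#' @param axes integer axes (1, 2, or 3) of the two rotations.
#' @param ... further arguments passed to \code{\link{make_loss}}.
#' @return numeric vector of losses, one per row of \code{angles}.
#' @export
landscape_scan <- function(map, kind = "wemd", angles,
                           axes = c(3L, 1L), ...) {
  map <- .as_map(map)
  angles <- as.matrix(angles)
  stopifnot(ncol(angles) == 2L, length(axes) == 2L)
  loss <- make_loss(map, map, kind = kind, ...)
  axis_rot <- function(axis, deg) {
    v <- c(0, 0, 0); v[axis] <- deg * pi / 180
    exp_rotvec(v)
  }
  vapply(seq_len(nrow(angles)), function(i) {
    R <- axis_rot(axes[2L], angles[i, 2L]) %*% axis_rot(axes[1L], angles[i, 1L])
    loss(R)
  }, numeric(1))
}
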
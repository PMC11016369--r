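#' Voxel-grid operations on density maps
#'
#' Downsampling, thresholding, centering, shifting, rotation, and
#' reflection of cubic density maps.  All geometric operations are taken
#' about the grid center (0-based voxel index \code{n \%/\% 2}) and the
#' Fourier-based ones use zero-frequency-centered transforms.  Shifts use
#' the periodic convention; wrap-around is acceptable because maps are
#' assumed compactly supported inside the box.
#'
#' @name volume-ops
NULL

# centered voxel coordinates along one axis (0-based index minus n %/% 2)
.grid_coords <- function(n) seq_len(n) - 1 - n %/% 2

# centered integer frequencies in FFT output order is (k %% n); here we
# enumerate the centered set -floor(n/2) .. ceil(n/2)-1
.centered_freqs <- function(n) seq.int(-(n %/% 2), n - n %/% 2 - 1)

.map_data <- function(map) .as_map(map)$data

#' Total mass (sum of voxel values) of a map
#' @param map a \code{\link{density_map}}.
#' @return numeric scalar.
#' @export
map_mass <- function(map) sum(.map_data(map))

#' Downsample a map by Fourier cropping
#'
#' Retains the central \code{m^3} block of the zero-frequency-centered
#' discrete Fourier transform and inverse-transforms, scaled so the mean
#' voxel value is preserved.  \code{m = n} returns the input unchanged
#' (within float round-off).
#'
#' @param map a \code{\link{density_map}}.
#' @param m target grid size, \code{2 <= m <= n}.
#' @return a \code{\link{density_map}} of size \code{m^3}.  The voxel size
#'   is rescaled by \code{n/m} so the box keeps its physical extent.
#' @export
downsample_fourier <- function(map, m) {
  map <- .as_map(map)
  n <- map$n
  m <- as.integer(m)
  if (m < 2L || m > n) stop("'m' must satisfy 2 <= m <= n", call. = FALSE)
  if (m == n) return(map)
  F <- stats::fft(map$data)
  ks <- .centered_freqs(m)
  ii <- (ks %% n) + 1L
  oo <- (ks %% m) + 1L
  G <- array(0 + 0i, dim = c(m, m, m))
  G[oo, oo, oo] <- F[ii, ii, ii]
  g <- Re(stats::fft(G, inverse = TRUE)) / n^3
  density_map(g, voxel_size = map$voxel_size * n / m)
}

#' Threshold a map at a contour level
#'
#' Voxels below \code{level} are set to zero; the rest are unchanged.
#'
#' @param map a \code{\link{density_map}}.
#' @param level contour level.
#' @return thresholded \code{\link{density_map}}.
#' @export
threshold_map <- function(map, level) {
  map <- .as_map(map)
  d <- map$data
  d[d < level] <- 0
  density_map(d, voxel_size = map$voxel_size)
}

#' Center of mass of a map
#'
#' Intensity-weighted mean voxel coordinate, in voxels relative to the
#' grid center.  The total mass must be positive; threshold the map first
#' if it contains negative values.
#'
#' @param map a \code{\link{density_map}}.
#' @return numeric length-3 vector (voxels).
#' @export
center_of_mass <- function(map) {
  map <- .as_map(map)
  n <- map$n
  tot <- sum(map$data)
  if (!is.finite(tot) || tot <= 0) {
    stop("nonpositive total mass; threshold the map before centering",
         call. = FALSE)
  }
  co <- .grid_coords(n)
  # axis marginals
  mx <- apply(map$data, 1L, sum)
  my <- apply(map$data, 2L, sum)
  mz <- apply(map$data, 3L, sum)
  c(sum(mx * co), sum(my * co), sum(mz * co)) / tot
}

#' Translate a map by a (possibly fractional) voxel shift
#'
#' Fourier phase-shift translation \code{g(x) = f(x - v)} under the
#' periodic convention.  Integer shifts agree with a cyclic array roll to
#' within float precision; shifting by \code{v} then \code{-v} restores
#' the input.
#'
#' @param map a \code{\link{density_map}}.
#' @param v numeric length-3 shift in voxels.
#' @return shifted \code{\link{density_map}}.
#' @export
shift_map <- function(map, v) {
  map <- .as_map(map)
  stopifnot(is.numeric(v), length(v) == 3L, all(is.finite(v)))
  if (all(v == 0)) return(map)
  n <- map$n
  k <- .centered_freqs(n)
  k <- k[order((k %% n))]  # reorder to FFT output order 0,1,...,-1
  ph <- function(vj) exp(-2i * pi * k * vj / n)
  F <- stats::fft(map$data)
  px <- ph(v[1L]); py <- ph(v[2L]); pz <- ph(v[3L])
  F <- F * outer(outer(px, py), pz)
  g <- Re(stats::fft(F, inverse = TRUE)) / n^3
  density_map(g, voxel_size = map$voxel_size)
}

#' Center a map at its (thresholded) center of mass
#'
#' The center of mass is estimated on a thresholded copy of the map and
#' the resulting shift is applied to the original, unthresholded map, so
#' negative background values do not bias the estimate but are preserved
#' in the output.
#'
#' @param map a \code{\link{density_map}}.
#' @param contour threshold level below which voxels are ignored for the
#'   center-of-mass estimate.  Default \code{NULL} uses the 80th
#'   percentile of the positive voxel values, a heuristic stand-in for a
#'   recommended display contour when none is supplied.
#' @return a list with elements \code{map} (the centered map) and
#'   \code{shift} (the length-3 shift that was applied, in voxels).
#' @export
center_map <- function(map, contour = NULL) {
  map <- .as_map(map)
  if (is.null(contour)) {
    pos <- map$data[map$data > 0]
    if (length(pos) == 0L) {
      stop("map has no positive voxels; supply an explicit contour",
           call. = FALSE)
    }
    contour <- stats::quantile(pos, 0.8, names = FALSE)
  }
  com <- center_of_mass(threshold_map(map, contour))
  list(map = shift_map(map, -com), shift = -com)
}

#' Rotate (or reflect) a map about the grid center
#'
#' Implements \code{f_R(x) = f(t(R) \%*\% x)}: the output at grid point
#' \code{x} is the input sampled at the back-rotated point.  With the
#' \code{"fourier"} backend the map is first interpolated onto a 2x
#' Fourier-upsampled grid (trigonometric interpolation by zero-padding the
#' centered spectrum) and then sampled trilinearly, which closely
#' approximates nonuniform Fourier evaluation on the rotated grid; the
#' \code{"trilinear"} backend samples the original grid directly.  Points
#' that fall outside the box evaluate to zero.
#'
#' @param map a \code{\link{density_map}}.
#' @param R 3x3 orthogonal matrix; determinant -1 is allowed so that
#'   reflection-composed elements can be applied for handedness work.
#' @param backend \code{"fourier"} (default) or \code{"trilinear"}.
#' @return rotated \code{\link{density_map}}.
#' @export
rotate_map <- function(map, R, backend = c("fourier", "trilinear")) {
  map <- .as_map(map)
  backend <- match.arg(backend)
  if (!is_rotation(R, tol = 1e-6, allow_reflection = TRUE)) {
    stop("'R' must be an orthogonal 3x3 matrix", call. = FALSE)
  }
  n <- map$n
  co <- .grid_coords(n)
  xx <- rep(co, times = n * n)
  yy <- rep(rep(co, each = n), times = n)
  zz <- rep(co, each = n * n)
  # p = t(R) x, computed componentwise
  px <- xx * R[1L, 1L] + yy * R[2L, 1L] + zz * R[3L, 1L]
  py <- xx * R[1L, 2L] + yy * R[2L, 2L] + zz * R[3L, 2L]
  pz <- xx * R[1L, 3L] + yy * R[2L, 3L] + zz * R[3L, 3L]
  g <- switch(backend,
    trilinear = .interp_trilinear(map$data, px, py, pz, step = 1),
    fourier = .interp_tricubic(.fourier_upsample2(map$data),
                               px, py, pz, step = 0.5,
                               center = 2L * (n %/% 2) + 1L)
  )
  density_map(array(g, dim = c(n, n, n)), voxel_size = map$voxel_size)
}

# closure that rotates one fixed map repeatedly; for the fourier backend
# the upsampled grid is computed once and reused across evaluations
.map_rotator <- function(map, backend = "fourier") {
  map <- .as_map(map)
  n <- map$n
  co <- .grid_coords(n)
  xx <- rep(co, times = n * n)
  yy <- rep(rep(co, each = n), times = n)
  zz <- rep(co, each = n * n)
  if (backend == "fourier") {
    up <- .fourier_upsample2(map$data)
    ctr <- 2L * (n %/% 2) + 1L
  }
  function(R) {
    px <- xx * R[1L, 1L] + yy * R[2L, 1L] + zz * R[3L, 1L]
    py <- xx * R[1L, 2L] + yy * R[2L, 2L] + zz * R[3L, 2L]
    pz <- xx * R[1L, 3L] + yy * R[2L, 3L] + zz * R[3L, 3L]
    g <- if (backend == "fourier") {
      .interp_tricubic(up, px, py, pz, step = 0.5, center = ctr)
    } else {
      .interp_trilinear(map$data, px, py, pz, step = 1)
    }
    density_map(array(g, dim = c(n, n, n)), voxel_size = map$voxel_size)
  }
}

# trigonometric interpolation of a real cubic array onto the 2x finer grid
.fourier_upsample2 <- function(a) {
  n <- dim(a)[1L]
  m <- 2L * n
  F <- stats::fft(a)
  ks <- .centered_freqs(n)
  ii <- (ks %% n) + 1L
  oo <- (ks %% m) + 1L
  G <- array(0 + 0i, dim = c(m, m, m))
  G[oo, oo, oo] <- F[ii, ii, ii]
  Re(stats::fft(G, inverse = TRUE)) / n^3
}

# vectorized trilinear sampling of array `a` at center-origin coordinates
# (px, py, pz); `step` is the grid spacing of `a` relative to the unit
# voxel of the query coordinates (0.5 for the 2x upsampled grid)
.interp_trilinear <- function(a, px, py, pz, step = 1,
                              center = dim(a)[1L] %/% 2 + 1L) {
  n <- dim(a)[1L]
  fx <- px / step + center
  fy <- py / step + center
  fz <- pz / step + center
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
  ok <- i0 >= 1 & i0 <= n - 1 & j0 >= 1 & j0 <= n - 1 & k0 >= 1 & k0 <= n - 1
  out <- numeric(length(px))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  tx <- tx[ok]; ty <- ty[ok]; tz <- tz[ok]
  base <- i0 + (j0 - 1) * n + (k0 - 1) * n * n
  v000 <- a[base];               v100 <- a[base + 1]
  v010 <- a[base + n];           v110 <- a[base + n + 1]
  v001 <- a[base + n * n];       v101 <- a[base + n * n + 1]
  v011 <- a[base + n * n + n];   v111 <- a[base + n * n + n + 1]
  c00 <- v000 * (1 - tx) + v100 * tx
  c10 <- v010 * (1 - tx) + v110 * tx
  c01 <- v001 * (1 - tx) + v101 * tx
  c11 <- v011 * (1 - tx) + v111 * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  out[ok] <- c0 * (1 - tz) + c1 * tz
  out
}

# vectorized tricubic (Catmull-Rom) sampling; interpolating, C^1, with
# O(h^4) error on smooth data - used on the Fourier-upsampled grid where
# the extra accuracy makes rotations of well-sampled maps near-exact
.interp_tricubic <- function(a, px, py, pz, step = 1,
                             center = dim(a)[1L] %/% 2 + 1L) {
  n <- dim(a)[1L]
  fx <- px / step + center
  fy <- py / step + center
  fz <- pz / step + center
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  ok <- i0 >= 2 & i0 <= n - 2 & j0 >= 2 & j0 <= n - 2 & k0 >= 2 & k0 <= n - 2
  # boundary shell: fall back to trilinear there (stencil always fits)
  out <- .interp_trilinear(a, px, py, pz, step = step, center = center)
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  tx <- fx[ok] - i0; ty <- fy[ok] - j0; tz <- fz[ok] - k0
  cr_w <- function(t) {
    t2 <- t * t; t3 <- t2 * t
    list(0.5 * (-t + 2 * t2 - t3),
         0.5 * (2 - 5 * t2 + 3 * t3),
         0.5 * (t + 4 * t2 - 3 * t3),
         0.5 * (-t2 + t3))
  }
  wx <- cr_w(tx); wy <- cr_w(ty); wz <- cr_w(tz)
  base <- i0 + (j0 - 1) * n + (k0 - 1) * n * n
  acc <- numeric(length(base))
  for (c in 0:3) {
    offc <- (c - 1) * n * n
    for (b in 0:3) {
      wyz <- wy[[b + 1]] * wz[[c + 1]]
      offbc <- offc + (b - 1) * n
      for (aa in 0:3) {
        acc <- acc + wx[[aa + 1]] * wyz * a[base + offbc + (aa - 1)]
      }
    }
  }
  out[ok] <- acc
  out
}

#' Reflect a map through the grid center
#'
#' Coordinate flip \code{x -> -x} along the first axis about the grid
#' center, i.e. the voxel action of \code{diag(-1, 1, 1)}, using the
#' center-preserving periodic index convention so that a double reflection
#' restores the input exactly for both even and odd \code{n}.
#'
#' @param map a \code{\link{density_map}}.
#' @return reflected \code{\link{density_map}}.
#' @export
reflect_map <- function(map) {
  map <- .as_map(map)
  n <- map$n
  h <- n %/% 2
  idx <- ((2L * h - (seq_len(n) - 1L)) %% n) + 1L
  density_map(map$data[idx, , , drop = FALSE], voxel_size = map$voxel_size)
}
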
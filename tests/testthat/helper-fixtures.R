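# programmatic fixtures shared across test files

# isotropic (or axis-aligned anisotropic) Gaussian blob, unit peak
gauss_blob <- function(n, sigma, center = c(0, 0, 0)) {
  sigma <- rep_len(sigma, 3L)
  co <- seq_len(n) - 1 - n %/% 2
  xx <- rep(co, times = n * n)
  yy <- rep(rep(co, each = n), times = n)
  zz <- rep(co, each = n * n)
  q <- (xx - center[1])^2 / (2 * sigma[1]^2) +
       (yy - center[2])^2 / (2 * sigma[2]^2) +
       (zz - center[3])^2 / (2 * sigma[3]^2)
  density_map(array(exp(-q), dim = c(n, n, n)))
}

rel_l2 <- function(x, y) {
  if (inherits(x, "density_map")) x <- x$data
  if (inherits(y, "density_map")) y <- y$data
  sqrt(sum((x - y)^2)) / sqrt(sum(y^2))
}

# axis rotation matrix (degrees)
axis_rot <- function(axis, deg) {
  v <- c(0, 0, 0)
  v[axis] <- deg * pi / 180
  exp_rotvec(v)
}

# the shared 4-lobe phantom at a given size
phantom <- function(n = 32L) gaussian_mixture_map(synthetic_spec(n))
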
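# independent reference transform: plain-loop convolution + downsampling,
# axis by axis, structurally unrelated to the package's matrix-based path
ref_conv_down <- function(x, f) {
  nx <- length(x); nf <- length(f)
  full <- numeric(nx + nf - 1)
  for (i in seq_len(nx)) {
    full[i:(i + nf - 1)] <- full[i:(i + nf - 1)] + x[i] * f
  }
  full[seq(2, length(full), by = 2)]
}

ref_apply_axis <- function(arr, f, axis) {
  out <- apply(arr, setdiff(1:3, axis), ref_conv_down, f = f)
  # apply puts the transformed axis first; restore its place
  aperm(out, order(c(axis, setdiff(1:3, axis))))
}

ref_signature <- function(map, depth) {
  lo <- wembo:::.SYM3_DEC_LO; hi <- wembo:::.SYM3_DEC_HI
  arr <- map$data
  coefs <- list()
  weight <- 1
  for (l in seq_len(depth)) {
    bands <- list(arr)
    for (ax in 1:3) {
      bands <- unlist(lapply(bands, function(b) {
        list(ref_apply_axis(b, lo, ax), ref_apply_axis(b, hi, ax))
      }), recursive = FALSE)
    }
    # bands[[1]] is LLL; the other 7 are detail bands
    coefs[[l]] <- weight * unlist(lapply(bands[-1], as.numeric))
    arr <- bands[[1]]
    if (l < depth) weight <- weight * 2^(1 + 3 / 2)
  }
  coefs[[depth + 1]] <- weight * as.numeric(arr)
  unlist(coefs)
}

test_that("wavelet signatures are linear and vanish on the zero map", {
  z <- density_map(array(0, dim = c(16, 16, 16)))
  expect_true(all(wavelet_signature(z, depth = 4)$coefficients == 0))
  set.seed(8)
  f <- density_map(array(stats::rnorm(16^3), dim = c(16, 16, 16)))
  g <- density_map(array(stats::rnorm(16^3), dim = c(16, 16, 16)))
  sf <- wavelet_signature(f, depth = 4)$coefficients
  sg <- wavelet_signature(g, depth = 4)$coefficients
  comb <- wavelet_signature(density_map(2 * f$data - 3 * g$data),
                            depth = 4)$coefficients
  expect_lt(max(abs(comb - (2 * sf - 3 * sg))), 1e-10)
})

test_that("signature equals the directly computed weighted transform", {
  n <- 16; h <- n %/% 2
  a <- array(0, dim = c(n, n, n)); a[h + 1, h + 1, h + 1] <- 1
  m <- density_map(a)
  sig <- wavelet_signature(m, depth = 3)$coefficients
  ref <- ref_signature(m, depth = 3)
  expect_equal(length(sig), length(ref))
  expect_lt(max(abs(sort(sig) - sort(ref))), 1e-12)
  # and on a generic random map
  set.seed(9)
  r <- density_map(array(stats::rnorm(8^3), dim = c(8, 8, 8)))
  expect_lt(max(abs(sort(wavelet_signature(r, depth = 2)$coefficients) -
                    sort(ref_signature(r, depth = 2)))), 1e-10)
})

test_that("infeasible depths and meta mismatches are refused", {
  f <- gauss_blob(16, 2)
  expect_error(wavelet_signature(f, depth = 0), "depth")
  expect_error(wavelet_signature(f, depth = 6), "too large")
  a <- wavelet_signature(f, depth = 3)
  b <- wavelet_signature(f, depth = 4)
  expect_error(wemd_distance(a, b), "mismatch")
})

test_that("WEMD is a metric on signatures", {
  f <- gauss_blob(16, 2)
  s <- wavelet_signature(f, depth = 4)
  expect_identical(wemd_distance(s, s), 0)
  set.seed(10)
  for (i in 1:30) {
    maps <- lapply(1:3, function(j) {
      density_map(array(stats::rnorm(16^3), dim = c(16, 16, 16)))
    })
    sg <- lapply(maps, wavelet_signature, depth = 4)
    d12 <- wemd_distance(sg[[1]], sg[[2]])
    expect_identical(d12, wemd_distance(sg[[2]], sg[[1]]))
    expect_gte(d12, 0)
    expect_lte(wemd_distance(sg[[1]], sg[[3]]),
               d12 + wemd_distance(sg[[2]], sg[[3]]) + 1e-9)
  }
})

test_that("WEMD grows monotonically with shift length", {
  f <- gauss_blob(32, 2.5)
  s0 <- wavelet_signature(f, depth = 6)
  d <- vapply(1:8, function(v) {
    wemd_distance(s0, wavelet_signature(shift_map(f, c(v, 0, 0)), depth = 6))
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("the L2 distance matches direct summation", {
  set.seed(11)
  for (i in 1:5) {
    a <- array(stats::rnorm(8^3), dim = c(8, 8, 8))
    b <- array(stats::rnorm(8^3), dim = c(8, 8, 8))
    expect_equal(l2_distance(density_map(a), density_map(b)),
                 sqrt(sum((a - b)^2)), tolerance = 1e-12)
  }
  f <- gauss_blob(8, 1.5)
  g <- f$data; g[2, 3, 4] <- g[2, 3, 4] + 0.7
  expect_equal(l2_distance(f, density_map(g)), 0.7, tolerance = 1e-12)
  expect_identical(l2_distance(f, f), 0)
  expect_error(l2_distance(f, gauss_blob(16, 2)), "size")
})

test_that("loss functionals evaluate the declared distance and count calls", {
  f <- phantom(16)
  R <- random_rotation(seed = 14)
  lw <- make_loss(f, f, "wemd", depth = 4)
  expect_lt(lw(diag(3)), 1e-3 * sum(abs(wavelet_signature(f, depth = 4)$coefficients)))
  l2 <- make_loss(f, f, "l2")
  expect_equal(l2(R), l2_distance(f, rotate_map(f, R)))
  expect_identical(loss_evaluations(l2), 1L)
  lc <- make_loss(f, f, "custom", custom = function(a, b) 0)
  expect_identical(lc(R), 0)
  expect_error(make_loss(f, f, "nope"), "arg")
  expect_error(make_loss(f, f, "custom"), "custom")
})

test_that("landscape scan has its minimum at zero and respects symmetry", {
  f <- phantom(24)
  grid <- cbind(seq(-30, 30, by = 10), 0)
  vals <- landscape_scan(f, "wemd", grid, depth = 5)
  expect_equal(which.min(vals), 4L)   # the (0, 0) row
  # two-blob map on an odd grid is symmetric under angle negation: the
  # Euclidean loss exactly, WEMD up to the (slight) asymmetry of the sym3
  # analysis filters under grid reversal
  n <- 25
  two <- density_map(gauss_blob(n, 3, c(3, 0, 0))$data +
                     gauss_blob(n, 3, c(-3, 0, 0))$data)
  grid <- cbind(seq(-40, 40, by = 10), 5)
  s_l2 <- landscape_scan(two, "l2", grid, axes = c(3L, 1L))
  expect_lt(max(abs(s_l2 - rev(s_l2))) / max(s_l2), 1e-6)
  s <- landscape_scan(two, "wemd", grid, axes = c(3L, 1L), depth = 5)
  expect_lt(max(abs(s - rev(s))) / max(s), 0.02)
})
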
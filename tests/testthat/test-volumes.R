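test_that("MRC mode-2 volumes round-trip exactly", {
  set.seed(1)
  path <- withr::local_tempfile(fileext = ".mrc")
  m0 <- density_map(array(stats::rnorm(16^3), dim = c(16, 16, 16)),
                    voxel_size = 1.34)
  write_mrc(m0, path)
  m1 <- read_mrc(path)        # float32 quantization happens here
  expect_equal(m1$voxel_size, 1.34, tolerance = 1e-6)
  expect_lt(max(abs(m1$data - m0$data)), 1e-6)
  path2 <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m1, path2)
  m2 <- read_mrc(path2)
  expect_identical(m2$data, m1$data)   # bit-exact once in float32
  expect_identical(m2$voxel_size, m1$voxel_size)
})

test_that("invalid MRC inputs are rejected", {
  expect_error(read_mrc(file.path(tempdir(), "no-such-file.mrc")),
               "not found")
  expect_error(density_map(array(0, dim = c(16, 16, 8))), "cubic")
  # patch the NZ header word of a valid file to make it non-cubic
  path <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(density_map(array(1, dim = c(8, 8, 8))), path)
  con <- file(path, "r+b")
  seek(con, 8L, rw = "write")
  writeBin(4L, con, size = 4L, endian = "little")
  close(con)
  expect_error(read_mrc(path), "cubic")
})

test_that("Fourier downsampling preserves DC and matches analytic resampling", {
  cm <- density_map(array(3.7, dim = c(16, 16, 16)))
  expect_lt(max(abs(downsample_fourier(cm, 8)$data - 3.7)), 1e-10)
  f <- phantom(16)
  expect_lt(rel_l2(downsample_fourier(f, 16), f), 1e-10)
  expect_error(downsample_fourier(f, 17), "m")
  # broad Gaussian 64 -> 32 vs direct evaluation on the coarse grid
  g64 <- gauss_blob(64, 8)
  g32 <- downsample_fourier(g64, 32)
  ana <- gauss_blob(32, 4)   # same physical blob on the coarse grid
  ana <- density_map(ana$data * mean(g32$data) / mean(ana$data))
  expect_lt(rel_l2(g32, ana), 0.02)
  # mean (hence mass density) is preserved
  expect_equal(mean(g32$data), mean(g64$data), tolerance = 1e-10)
})

test_that("thresholding zeroes values below the level only", {
  m <- density_map(array(c(-1, 0.5, 2, rep(0, 5)), dim = c(2, 2, 2)))
  thr <- threshold_map(m, 0)
  expect_identical(as.numeric(thr$data)[1:3], c(0, 0.5, 2))
  expect_identical(threshold_map(m, -Inf)$data, m$data)
  expect_true(all(threshold_map(m, 3)$data == 0))
})

test_that("center of mass uses grid-center-origin voxel coordinates", {
  n <- 16; h <- n %/% 2
  a <- array(0, dim = c(n, n, n)); a[h + 1, h + 1, h + 1] <- 2
  expect_equal(center_of_mass(density_map(a)), c(0, 0, 0))
  a <- array(0, dim = c(n, n, n)); a[h + 4, h + 1, h + 1] <- 1
  expect_equal(center_of_mass(density_map(a)), c(3, 0, 0))
  a <- array(0, dim = c(n, n, n))
  a[h + 3, h + 1, h + 1] <- 1; a[h - 1, h + 1, h + 1] <- 1
  expect_equal(center_of_mass(density_map(a)), c(0, 0, 0))
  expect_error(center_of_mass(density_map(array(-1, dim = c(4, 4, 4)))),
               "mass")
})

test_that("Fourier shifts match cyclic rolls and invert cleanly", {
  n <- 16; h <- n %/% 2
  a <- array(0, dim = c(n, n, n)); a[h + 1, h + 1, h + 1] <- 1
  d <- density_map(a)
  s <- shift_map(d, c(1, 0, 0))
  expected <- array(0, dim = c(n, n, n)); expected[h + 2, h + 1, h + 1] <- 1
  expect_lt(max(abs(s$data - expected)), 1e-8)
  expect_identical(shift_map(d, c(0, 0, 0))$data, d$data)
  f <- gauss_blob(32, 2.5)
  v <- c(1.3, -0.7, 2.2)
  expect_lt(max(abs(shift_map(shift_map(f, v), -v)$data - f$data)), 1e-8)
  # integer shift equals an array roll
  rolled <- f$data[c(32, 1:31), , ]
  expect_lt(max(abs(shift_map(f, c(1, 0, 0))$data - rolled)), 1e-8)
  # exact linearity in the map
  expect_equal(shift_map(density_map(3 * f$data), v)$data,
               3 * shift_map(f, v)$data)
})

test_that("centering recovers sub-voxel displacements", {
  f <- gauss_blob(32, 3)
  cc <- center_map(f, contour = 1e-6)
  expect_lt(max(abs(cc$shift)), 0.05)
  moved <- shift_map(f, c(2.5, -1, 0))
  cc <- center_map(moved, contour = 1e-6)
  expect_lt(max(abs(cc$shift + c(2.5, -1, 0))), 0.25)
  expect_lt(max(abs(center_of_mass(threshold_map(cc$map, 1e-6)))), 0.25)
  expect_error(center_map(density_map(array(-2, dim = c(8, 8, 8))),
                          contour = 5), "positive|mass")
})

test_that("centering inverts shifts up to 5 voxels on clean blobs", {
  set.seed(44)
  f <- gauss_blob(32, 2.5)
  for (i in 1:5) {
    v <- stats::runif(3, -5, 5)
    cc <- center_map(shift_map(f, v), contour = 1e-6)
    expect_lt(sqrt(sum((cc$shift + v)^2)), 0.25)
  }
})

test_that("rotation is exact at identity and spherically invariant", {
  f <- phantom(32)
  expect_lt(rel_l2(rotate_map(f, diag(3)), f), 1e-6)
  iso <- gauss_blob(32, 4)
  R <- random_rotation(seed = 3)
  expect_lt(rel_l2(rotate_map(iso, R), iso), 1e-3)
  expect_error(rotate_map(f, matrix(1, 3, 3)), "orthogonal")
})

test_that("rotations compose, agree across backends, and preserve mass", {
  f <- gauss_blob(32, c(5, 3, 2.5))
  R1 <- random_rotation(seed = 4); R2 <- random_rotation(seed = 5)
  c1 <- rotate_map(rotate_map(f, R1), R2)
  c2 <- rotate_map(f, R2 %*% R1)
  expect_lt(rel_l2(c1, c2), 0.01)
  expect_lt(rel_l2(rotate_map(f, R1, backend = "trilinear"),
                   rotate_map(f, R1)), 0.02)
  expect_lt(abs(map_mass(rotate_map(f, R1)) - map_mass(f)) / map_mass(f),
            0.005)
  # commutes with intensity scaling exactly
  expect_equal(rotate_map(density_map(2.5 * f$data), R1)$data,
               2.5 * rotate_map(f, R1)$data)
})

test_that("the loss is continuous in the rotation (1-degree perturbations)", {
  f <- phantom(32)
  nrm <- sqrt(sum(f$data^2))
  for (ax in 1:3) {
    d <- l2_distance(f, rotate_map(f, axis_rot(ax, 1)))
    expect_lt(d / nrm, 0.05)
  }
})

test_that("reflection flips the first axis about the grid center", {
  f <- phantom(16)
  expect_identical(reflect_map(reflect_map(f))$data, f$data)
  iso <- gauss_blob(17, 3)   # odd grid: exact centrosymmetry
  expect_lt(rel_l2(reflect_map(iso), iso), 1e-12)
  n <- 16; h <- n %/% 2
  a <- array(0, dim = c(n, n, n)); a[h + 4, h + 1, h + 1] <- 1
  r <- reflect_map(density_map(a))
  expect_equal(r$data[h - 2, h + 1, h + 1], 1)
  expect_equal(sum(r$data), 1)
})
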
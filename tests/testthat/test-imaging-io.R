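test_that("voxel volume converts anisotropic nm grids to um^3", {
  expect_equal(voxel_volume(c(200, 47, 47)), 0.2 * 0.047 * 0.047)
  expect_equal(voxel_volume(c(1000, 1000, 1000)), 1)
  # the 50-voxel minimal gamma-H2AX size corresponds to 0.022 um^3
  expect_equal(signif(50 * voxel_volume(c(200, 47, 47)), 2), 0.022)
  expect_error(voxel_volume(c(0, 47, 47)))
})

test_that("gaussian PSF kernel is normalised, symmetric and anisotropic", {
  psf <- make_gaussian_psf(0.1, 0.3, c(200, 47, 47))
  k <- psf$kernel
  expect_equal(sum(k), 1, tolerance = 1e-9)
  expect_equal(k, k[rev(seq_len(dim(k)[1])), , ], tolerance = 1e-12)
  expect_equal(k, k[, rev(seq_len(dim(k)[2])), ], tolerance = 1e-12)

  # second moments reflect sigma_z / sigma_xy (in physical units)
  d <- dim(k)
  zc <- ((seq_len(d[1])) - (d[1] + 1) / 2) * 0.2   # um
  yc <- ((seq_len(d[2])) - (d[2] + 1) / 2) * 0.047
  mz <- sqrt(sum(apply(k, 1, sum) * zc^2))
  my <- sqrt(sum(apply(k, 2, sum) * yc^2))
  # truncation at 3 sigma shrinks both slightly; the ratio survives
  expect_equal(mz / my, 3, tolerance = 0.05)

  # sigma -> 0 limit: exact single-voxel delta
  d0 <- make_gaussian_psf(1e-9, 1e-9, c(200, 100, 100))
  expect_identical(dim(d0$kernel), c(1L, 1L, 1L))
  expect_equal(d0$kernel[1, 1, 1], 1)
})

test_that("richardson_lucy restores contrast, conserves flux, stays non-negative", {
  psf <- make_gaussian_psf(0.15, 0.35, c(300, 150, 150))
  blob <- array(0, c(16, 48, 48)); blob[8, 24, 24] <- 100
  pad <- c(2, 4, 4)
  blurred <- fociquant3d:::fft_convolve3(
    fociquant3d:::pad_reflect3(blob, pad), psf$kernel)
  blurred <- blurred[pad[1] + 1:16, pad[2] + 1:48, pad[3] + 1:48]
  dim(blurred) <- dim(blob)
  blurred <- pmax(blurred, 0)

  out <- richardson_lucy(blurred, psf, max_iter = 40)
  expect_true(all(out >= 0))
  expect_gt(max(out), max(blurred))                      # contrast restored
  expect_lt(abs(sum(out) - sum(blurred)) / sum(blurred), 0.01)  # flux
  expect_lte(attr(out, "iterations"), 40)

  # delta PSF: identity deconvolution
  dpsf <- make_gaussian_psf(1e-9, 1e-9, c(300, 150, 150))
  x <- array(runif(4 * 6 * 6), c(4, 6, 6))
  expect_equal(richardson_lucy(x, dpsf, max_iter = 5), x,
               ignore_attr = TRUE)

  # oversized PSF rejected
  expect_error(richardson_lucy(array(1, c(2, 2, 2)), psf), "larger")
})

test_that("a single RL update matches the brute-force reference", {
  set.seed(41)
  psf <- make_gaussian_psf(0.1, 0.1, c(300, 150, 150))  # 3 x 5 x 5 kernel
  x <- array(runif(5 * 5 * 5, 0.1, 1), c(5, 5, 5))
  got <- richardson_lucy(x, psf, max_iter = 1)

  pad <- pmin((dim(psf$kernel) - 1L) %/% 2L, dim(x) - 1L)
  obs <- pad_reflect_oracle(x, pad)
  ref <- rl_update_brute(obs, pmax(obs, .Machine$double.eps), psf$kernel)
  ref <- ref[pad[1] + 1:5, pad[2] + 1:5, pad[3] + 1:5]
  expect_equal(as.vector(got), as.vector(ref), tolerance = 1e-10)
})

test_that("KL divergence to the re-blurred image is non-increasing", {
  psf <- make_gaussian_psf(0.15, 0.3, c(300, 150, 150))
  blob <- array(0.01, c(12, 24, 24))
  blob[6, 12, 12] <- 50; blob[7, 15, 9] <- 30
  pad <- c(2, 3, 3)
  obs <- fociquant3d:::fft_convolve3(
    fociquant3d:::pad_reflect3(blob, pad), psf$kernel)
  obs <- pmax(obs[pad[1] + 1:12, pad[2] + 1:24, pad[3] + 1:24], 1e-9)
  dim(obs) <- dim(blob)

  kl <- vapply(c(1, 3, 6, 10, 15), function(it) {
    est <- richardson_lucy(obs, psf, max_iter = it)
    reproj <- fociquant3d:::fft_convolve3(
      fociquant3d:::pad_reflect3(pmax(est, 1e-12), pad), psf$kernel)
    reproj <- pmax(reproj[pad[1] + 1:12, pad[2] + 1:24, pad[3] + 1:24], 1e-12)
    sum(obs * log(obs / reproj) - obs + reproj)
  }, 0)
  expect_true(all(diff(kl) <= 1e-8))
})

test_that("TIFF write/read round trip preserves data and metadata", {
  p <- coarse_phantom(seed = 5, n_nuclei = 1L, n_gh2ax = 3L,
                      stack_shape = c(14L, 60L, 60L))
  st <- gen_foci_stack(p)$stack
  path <- tempfile(fileext = ".tif")
  on.exit(unlink(c(path, paste0(path, ".json"))), add = TRUE)
  write_stack(st, path)

  rt <- read_stack(path)
  expect_identical(names(rt$channels), names(st$channels))
  expect_equal(rt$voxel_size_nm, st$voxel_size_nm)
  # float32 storage: lossless up to single precision
  expect_equal(rt$channels$gh2ax, st$channels$gh2ax, tolerance = 1e-6)

  # override wins over sidecar metadata
  rt2 <- read_stack(path, voxel_size_override = c(100, 50, 50))
  expect_equal(rt2$voxel_size_nm, c(100, 50, 50))

  # plain TIFF without sidecar and without override: voxel size error
  path2 <- tempfile(fileext = ".tif")
  on.exit(unlink(path2), add = TRUE)
  tiff::writeTIFF(list(matrix(0.5, 8, 8)), path2)
  expect_error(read_stack(path2), "voxel size")
  # ... but an override makes a 1-page stack readable
  one <- read_stack(path2, voxel_size_override = c(200, 100, 100))
  expect_identical(one$dim, c(1L, 8L, 8L))
})
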
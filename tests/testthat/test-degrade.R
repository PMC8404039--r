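test_that("noise SD scales with the noise-free voxel value", {
  # Monte-Carlo oracle: many realisations of a single voxel
  n <- 50000
  m <- suvr_map(array(2, c(n, 1, 1)))
  noisy <- add_noise(m, 0.20, seed = 1)
  added <- noisy$values - m$values
  # clipping at 0 is negligible for value 2 (5 sigma away)
  expect_lt(abs(sd(added) - 0.4), 0.01)
  expect_lt(abs(mean(added)), 0.01)
})

test_that("zero voxels are unchanged and support is preserved", {
  v <- array(c(0, 1, 0, 2, 0, 3, 0, 0), c(8, 1, 1))
  out <- add_noise(v, 0.2, seed = 3)
  expect_identical(out$values[v == 0], v[v == 0])
  expect_true(all(out$values >= 0))
})

test_that("noise degradation is seeded and validates input", {
  v <- array(runif(64), c(4, 4, 4))
  expect_identical(add_noise(v, 0.2, seed = 5)$values,
                   add_noise(v, 0.2, seed = 5)$values)
  bad <- v; bad[1] <- NA
  expect_error(add_noise(bad, 0.2), "finite")
  expect_error(add_noise(v, 0), "noise_fraction")
  expect_error(add_noise(v, 1.5), "noise_fraction")
})

test_that("identity rigid transform returns the map voxelwise", {
  v <- array(runif(20 * 22 * 20), c(20, 22, 20))
  out <- apply_rigid(v, c(0, 0, 0), c(0, 0, 0))
  expect_equal(out$values, v, tolerance = 1e-7)
})

test_that("a 10 mm translation on a 2 mm grid shifts content 5 voxels", {
  sh <- c(21L, 21L, 21L)
  v <- array(0, sh)
  v[11, 11, 11] <- 1
  out <- apply_rigid(suvr_map(v, voxel_size_mm = 2), c(10, 0, 0), c(0, 0, 0))
  expect_equal(out$values[16, 11, 11], 1, tolerance = 1e-6)
  expect_equal(sum(out$values > 0.5), 1)
  expect_identical(out$space, "native/misaligned")
})

test_that("rigid transforms invert to interpolation error", {
  m <- synth_suvr_map(coarse_spec(rigid_jitter_mm = 0, rigid_jitter_deg = 0),
                      seed = 21)
  th <- 9 * pi / 180
  t1 <- c(6, -4, 3)
  fwd <- apply_rigid(m, t1, c(0, 0, 9))
  # inverse of (Rz(th), t): rotation -th, translation -Rz(-th) t
  Rz <- matrix(c(cos(-th), sin(-th), 0, -sin(-th), cos(-th), 0, 0, 0, 1), 3, 3)
  back <- apply_rigid(fwd, -as.vector(Rz %*% t1), c(0, 0, -9))
  mad <- mean(abs(back$values - m$values))
  expect_lt(mad, 0.02 * max(m$values))
})

test_that("misalignment approximately preserves the image sum in the field of view", {
  m <- synth_suvr_map(coarse_spec(), seed = 22)
  out <- apply_rigid(m, c(8, 5, -6), c(3, -4, 5))
  expect_lt(abs(sum(out$values) - sum(m$values)) / sum(m$values), 0.05)
})

test_that("rigid transform rejects non-finite parameters", {
  v <- array(0, c(4, 4, 4))
  expect_error(apply_rigid(v, c(NA, 0, 0), c(0, 0, 0)), "finite")
  expect_error(apply_rigid(v, c(0, 0, 0), c(NaN, 0, 0)), "finite")
})

test_that("sampled misalignments always violate the 8 mm criterion", {
  mags <- vapply(1:1000, function(i) {
    s <- sample_misalignment(seed = i)
    sqrt(sum(s$translation_mm^2))
  }, numeric(1))
  expect_true(all(mags >= 8))
  expect_true(all(mags <= 25))
  rots <- sample_misalignment(seed = 4)$rotation_deg
  expect_true(all(abs(rots) <= 10))
  expect_identical(sample_misalignment(seed = 77), sample_misalignment(seed = 77))
  expect_error(sample_misalignment(seed = 1, mag_range_mm = c(4, 10)), "criterion")
})

test_that("noise lowers the brain SNR statistic on matched phantom pairs", {
  masks <- coarse_masks()
  spec <- coarse_spec()
  lower <- vapply(1:50, function(i) {
    m <- synth_suvr_map(spec, seed = 300 + i)
    n <- add_noise(m, 0.20, seed = 900 + i)
    snr_statistic(n, masks$brain) < snr_statistic(m, masks$brain)
  }, logical(1))
  expect_true(all(lower))
})
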
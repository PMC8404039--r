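test_that("template masks are nested, disjoint and reproduce brute-force ellipsoid counts", {
  masks <- make_template_masks()
  expect_gt(sum(masks$striatal), 0)
  expect_true(all(masks$brain[masks$striatal]))
  expect_true(all(masks$brain[masks$cerebellar]))
  expect_false(any(masks$striatal & masks$cerebellar))

  # independent oracle: enumerate every lattice point against the two
  # striatal ellipsoid inequalities (explicit world coordinates per voxel)
  origin <- c(46, 64, 37)
  g <- expand.grid(i = 1:91, j = 1:109, k = 1:91)
  w <- sweep(as.matrix(g), 2, origin) * 2
  count <- 0L
  for (side in c(-1, 1)) {
    ctr <- c(side * 22, 4, 4)
    ax <- c(10, 17, 12)
    q <- ((w[, 1] - ctr[1]) / ax[1])^2 + ((w[, 2] - ctr[2]) / ax[2])^2 +
      ((w[, 3] - ctr[3]) / ax[3])^2
    count <- count + sum(q <= 1)
  }
  expect_identical(sum(masks$striatal), as.integer(count))
})

test_that("degenerate grids are rejected", {
  expect_error(make_template_masks(c(4, 4, 4)), "too small")
})

test_that("clean phantoms satisfy the physiological SUVr regime", {
  masks <- make_template_masks()
  m <- synth_suvr_map(seed = 7)
  expect_s3_class(m, "suvr_map")
  expect_identical(dim(m$values), c(91L, 109L, 91L))
  expect_identical(m$space, "template-aligned")
  expect_gt(mean(m$values[masks$striatal]), 1.5)
  # background stays essentially zero (smoothing bleeds a little at edges)
  expect_lt(mean(m$values[!masks$brain]), 0.05)

  # cerebellar mean within +/- 0.2 of 1.0 before jitter
  spec0 <- phantom_spec(intensity_jitter = 0, rigid_jitter_mm = 0,
                        rigid_jitter_deg = 0)
  m0 <- synth_suvr_map(spec0, seed = 7)
  expect_lt(abs(mean(m0$values[masks$cerebellar]) - 1.0), 0.2)
})

test_that("identical seeds give bit-identical phantoms; different seeds differ", {
  spec <- coarse_spec()
  a <- synth_suvr_map(spec, seed = 11)
  b <- synth_suvr_map(spec, seed = 11)
  c <- synth_suvr_map(spec, seed = 12)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
})

test_that("the smoothing kernel realises the nominal 4.5 mm FWHM", {
  # insert a point source and measure the width of the smoothed profile at
  # half maximum by linear interpolation
  sh <- c(41L, 41L, 41L)
  vol <- array(0, sh)
  vol[21, 21, 21] <- 1
  fwhm_mm <- 4.5
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / 2
  sm <- array(fdopaqc:::cpp_gauss_smooth(vol, sh, sigma_vox), sh)
  pr <- sm[, 21, 21]
  hm <- max(pr) / 2
  above <- which(pr >= hm)
  lo <- min(above); hi <- max(above)
  f1 <- lo - 1 + (hm - pr[lo - 1]) / (pr[lo] - pr[lo - 1])
  f2 <- hi + (pr[hi] - hm) / (pr[hi] - pr[hi + 1])
  measured <- (f2 - f1) * 2
  expect_lt(abs(measured - fwhm_mm) / fwhm_mm, 0.10)
})

test_that("synthetic datasets honour the requested composition", {
  spec <- coarse_spec()
  ds <- synth_dataset(c(good = 6, misaligned = 5, noisy = 4), spec, seed = 3)
  expect_equal(nrow(ds$entries), 15)
  expect_equal(as.vector(table(ds$entries$class)[c("good", "misaligned", "noisy")]),
               c(6, 5, 4))
  expect_false(any(duplicated(ds$entries$id)))
  # degraded entries record their parameters
  mis <- ds$entries[ds$entries$class == "misaligned", ]
  expect_true(all(sqrt(mis$tx_mm^2 + mis$ty_mm^2 + mis$tz_mm^2) >= 8))
  expect_true(all(ds$entries$noise_fraction[ds$entries$class == "noisy"] == 0.20))

  # a Dataset-2-style composition
  ds2 <- synth_dataset(c(good = 13, misaligned = 4), spec, seed = 5)
  expect_equal(nrow(ds2$entries), 17)

  # edge cases
  expect_equal(nrow(synth_dataset(c(good = 0, misaligned = 0, noisy = 0))$entries), 0)
  expect_error(synth_dataset(c(good = -1, misaligned = 0, noisy = 0)), ">= 0")
})

test_that("datasets are reproducible and round-trip through NIfTI + CSV", {
  spec <- coarse_spec()
  d1 <- synth_dataset(c(good = 2, misaligned = 1, noisy = 1), spec, seed = 9)
  d2 <- synth_dataset(c(good = 2, misaligned = 1, noisy = 1), spec, seed = 9)
  expect_identical(d1$entries, d2$entries)
  expect_identical(d1$maps, d2$maps)

  dir <- withr::local_tempdir()
  d3 <- synth_dataset(c(good = 2, misaligned = 1), spec, seed = 9, dir = dir)
  expect_true(all(file.exists(d3$entries$path)))
  rt <- read_suvr_map(d3$entries$path[1])
  expect_equal(rt$values, d1$maps[[d3$entries$id[1]]]$values,
               tolerance = 1e-6)
  csv <- file.path(dir, "manifest.csv")
  write_manifest(d3, csv)
  back <- read_manifest(csv)
  expect_equal(back$entries$class, d3$entries$class)
  m <- fdopaqc:::manifest_map(back, 1)
  expect_s3_class(m, "suvr_map")
})

test_that("clean phantoms pass the automated QC rules", {
  masks <- make_template_masks()
  pass <- vapply(1:15, function(i) {
    m <- synth_suvr_map(seed = 200 + i)
    qc_verdict(m, masks)$verdict == "pass"
  }, logical(1))
  expect_gte(mean(pass), 0.99)
})

test_that("phantom specification validates its invariants", {
  expect_error(phantom_spec(striatal_suvr_range = c(1.2, 2)), "criterion 4")
  expect_error(phantom_spec(smoothing_fwhm_mm = 0), "positive")
  expect_error(phantom_spec(striatal_suvr_range = c(3, 2)), "interval")
})
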
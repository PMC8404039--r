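test_that("channel bookkeeping follows k0 + k x (n - 1)", {
  cfg <- densenet_config(dims = 1)
  ch <- densenet_channels(cfg)
  expect_identical(ch$layer_inputs[[1]], c(24L, 36L, 48L, 60L))
  expect_identical(ch$block_output[1], 72L)           # 24 + 4 * 12
  expect_identical(ch$layer_inputs[[1]][1], 24L)      # n = 1 boundary: k0
  expect_identical(ch$layer_inputs[[1]][4], 24L + 12L * 3L)  # n = 4 -> 60
  for (b in seq_along(ch$layer_inputs)) {
    k0 <- ch$layer_inputs[[b]][1]
    expect_identical(ch$layer_inputs[[b]],
                     k0 + cfg$growth_rate * (seq_len(cfg$layers_per_block) - 1L))
  }
})

test_that("transitions compress by floor(theta c) and pool by floor division", {
  expect_identical(densenet_channels(densenet_config(dims = 1))$transition_output[1],
                   72L)  # theta = 1: no compression
  expect_identical(densenet_channels(densenet_config(dims = 1,
                                                     compression = 0.5))$transition_output[1],
                   36L)
  m <- densenet_init(densenet_config(dims = 1), 91L, seed = 1)
  expect_identical(vapply(m$spatial, `[`, integer(1), 1), c(91L, 45L, 22L))
  m3 <- densenet_init(densenet_config(dims = 3), c(12L, 14L, 12L), seed = 1)
  expect_identical(m3$spatial[[2]], c(6L, 7L, 6L))
  expect_identical(m3$spatial[[3]], c(3L, 3L, 3L))
  # pooling a fully degenerate grid is refused
  expect_error(densenet_init(densenet_config(dims = 1, n_blocks = 3), 2L),
               "cannot pool")
})

test_that("parameter counts match an independent hand enumeration", {
  cfg <- densenet_config(dims = 1)
  # longhand: initial conv + per-layer BN (2c) + conv (4 c k) per block,
  # transition BN + 1-conv, head BN + linear
  kd <- 4
  k <- 12
  ins <- list(c(24, 36, 48, 60), c(72, 84, 96, 108), c(120, 132, 144, 156))
  hand <- kd * 1 * 24
  for (b in 1:3) {
    for (cin in ins[[b]]) hand <- hand + 2 * cin + kd * cin * k
    if (b < 3) {
      cb <- ins[[b]][4] + k
      hand <- hand + 2 * cb + cb * cb  # theta = 1 transition conv
    }
  }
  cf <- ins[[3]][4] + k
  hand <- hand + 2 * cf + cf * 2 + 2
  expect_identical(count_params(cfg), as.integer(hand))

  # dimensionality only changes the kernel volume
  expect_identical(count_params(densenet_config(dims = 3)) -
                     count_params(densenet_config(dims = 1)),
                   as.integer((4^3 - 4) * (1 * 24 + sum(unlist(ins)) * 12)))

  # monotonicity in the initial channel count
  expect_gt(count_params(densenet_config(dims = 1, init_channels = 48)),
            count_params(densenet_config(dims = 1)))
})

test_that("the same configuration shares its channel schedule across 1D/2D/3D", {
  chs <- lapply(1:3, function(d) densenet_channels(densenet_config(dims = d)))
  expect_identical(chs[[1]], chs[[2]])
  expect_identical(chs[[2]], chs[[3]])
})

test_that("a dense layer emits k feature maps at unchanged spatial size", {
  cfg <- densenet_config(dims = 1)
  m <- densenet_init(cfg, 91L, seed = 2)
  A <- array(rnorm(91 * 72 * 3), c(91, 72, 3))
  lc <- fdopaqc:::dense_layer_forward(m, 1, 1, A, 24L, training = TRUE)
  expect_identical(dim(lc$z), c(91L, 12L, 3L))
})

test_that("ReLU and batch normalisation honour their contracts", {
  expect_identical(fdopaqc:::relu(c(-2, -0.1, 0, 0.3)), c(0, 0, 0, 0.3))
  set.seed(9)
  x <- array(rnorm(50 * 3 * 8, mean = 4, sd = 3), c(50, 3, 8))
  st <- fdopaqc:::bn_stats(x)
  # normalised values have batch mean ~0 and SD ~1 per channel
  for (c in 1:3) {
    xh <- (x[, c, ] - st$mean[c]) / sqrt(st$var[c] + 1e-5)
    expect_lt(abs(mean(xh)), 1e-10)
    expect_lt(abs(sd(xh) - 1), 1e-2)
  }
})

test_that("forward emits a probability vector summing to one", {
  cfg <- tiny_config()
  m <- densenet_init(cfg, 32L, seed = 3)
  x <- array(rnorm(32 * 5), c(32, 5))
  p <- predict(m, x, type = "prob")
  expect_identical(dim(p), c(5L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)

  # equal pre-softmax scores give (0.5, 0.5)
  m0 <- m
  m0$params$fc_w[] <- 0
  m0$params$fc_b[] <- 0
  p0 <- predict(m0, x)
  expect_equal(as.vector(p0), rep(0.5, 10))

  expect_error(predict(m, array(rnorm(31 * 2), c(31, 2))), "does not match")
})

test_that("inference is deterministic with fixed weights", {
  m <- densenet_init(tiny_config(), 32L, seed = 4)
  x <- array(rnorm(32 * 4), c(32, 4))
  expect_identical(predict(m, x), predict(m, x))
})

test_that("the bottleneck inserts a 1-wide convolution to 4k channels", {
  cfg <- tiny_config(bottleneck = TRUE)
  m <- densenet_init(cfg, 32L, seed = 5)
  expect_identical(dim(m$params$b1_l1_bconv_w), c(1L, 8L, 16L))   # cin -> 4k
  expect_identical(dim(m$params$b1_l1_conv_w), c(4L, 16L, 4L))    # 4k -> k
  # forward still works and counts agree with the formula
  x <- array(rnorm(32 * 3), c(32, 3))
  expect_equal(rowSums(predict(m, x)), rep(1, 3), tolerance = 1e-6)
  expect_identical(count_params(cfg),
                   as.integer(sum(vapply(m$params, length, numeric(1)))))
})

test_that("configuration invariants are validated", {
  expect_error(densenet_config(compression = 0), "theta")
  expect_error(densenet_config(compression = 1.2), "theta")
  expect_error(densenet_config(dropout_rate = 1), "dropout")
  expect_error(densenet_config(dims = 4), "dims")
})
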
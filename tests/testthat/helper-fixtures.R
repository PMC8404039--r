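# Shared fixtures.  Tests that only need the generator's structure (not the
# full MNI grid) use a coarse 31 x 37 x 31 grid at 6 mm voxels, which keeps
# the same anatomy in millimetre terms at ~3% of the voxel count.

coarse_spec <- function(...) {
  phantom_spec(shape = c(31L, 37L, 31L), voxel_size_mm = 6, ...)
}

coarse_masks <- function() {
  make_template_masks(c(31L, 37L, 31L), 6)
}

# Tiny 1D DenseNet for training-mechanics tests.
tiny_config <- function(...) {
  defaults <- list(dims = 1, n_blocks = 2, layers_per_block = 2,
                   growth_rate = 4, init_channels = 8, dropout_rate = 0,
                   l2_weight = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(densenet_config, args)
}

# Two well-separated classes of 1D profiles: a Gaussian bump centred left
# (class "good") or right (class "failed") of the midline.
separable_profiles <- function(n_per_class, len = 32, shift = 6, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    mk <- function(s) sapply(seq_len(n_per_class), function(i) {
      c0 <- len / 2 + s + rnorm(1, 0, 0.8)
      exp(-(seq_len(len) - c0)^2 / 18) * runif(1, 2, 3) + rnorm(len, 0, 0.02)
    })
    x <- cbind(mk(-shift), mk(shift))
    y <- factor(rep(c("good", "failed"), each = n_per_class),
                levels = c("good", "failed"))
    list(x = array(x, c(len, 2 * n_per_class)), y = y)
  })
}
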
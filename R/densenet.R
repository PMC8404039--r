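#' DenseNet architecture configuration
#'
#' Hyperparameters of the dimension-generic DenseNet classifier.  The
#' defaults are the QC architecture: three dense blocks of four layers each,
#' growth rate `k = 12`, 4-wide convolution kernels, no bottleneck, no
#' compression (`theta = 1`), dropout 0.2 and L2 weight decay.  Each dense
#' layer applies batch normalisation, ReLU and a same-size convolution
#' producing `k` new feature maps; layer `n` of a block receives the
#' concatenation of the block input and all previous layer outputs, hence
#' `k0 + k * (n - 1)` input channels.  Transition layers between blocks apply
#' BN-ReLU, a 1-wide convolution to `floor(theta * c)` channels, and average
#' pooling with stride 2.  The head is BN-ReLU, global average pooling and a
#' single linear layer with softmax.
#'
#' @param dims spatial dimensionality of the inputs: 1, 2 or 3.
#' @param n_blocks number of dense blocks.
#' @param layers_per_block dense layers per block.
#' @param growth_rate `k`, feature maps added by each dense layer.
#' @param init_channels `k0`, channels produced by the initial convolution
#'   (the DenseNet convention `2 * k` by default).
#' @param kernel_size convolution kernel width per spatial axis.  Even
#'   kernels keep spatial size by padding `floor((K-1)/2)` low and
#'   `ceil((K-1)/2)` high.
#' @param bottleneck if `TRUE`, a 1-wide convolution to `4 * k` channels
#'   (with its own BN-ReLU) precedes each layer's main convolution.
#' @param compression `theta` in (0, 1]; transition channel count is
#'   `floor(theta * c)`.  `theta = 1` means no compression.
#' @param dropout_rate dropout probability applied after each dense layer's
#'   convolution during training.
#' @param l2_weight L2 regularisation weight; the training loss is the data
#'   loss plus `l2_weight * sum(w^2)` over convolution and linear weights.
#' @param n_classes number of output classes.
#' @return An object of class `densenet_config`.
#' @examples
#' cfg <- densenet_config(dims = 1)
#' densenet_channels(cfg)$block_output[1]  # 24 + 4 * 12 = 72
#' @export
densenet_config <- function(dims = 3, n_blocks = 3, layers_per_block = 4,
                            growth_rate = 12, init_channels = 2 * growth_rate,
                            kernel_size = 4, bottleneck = FALSE,
                            compression = 1, dropout_rate = 0.2,
                            l2_weight = 1e-4, n_classes = 2) {
  if (!dims %in% 1:3) stop("dims must be 1, 2 or 3")
  if (compression <= 0 || compression > 1)
    stop("compression theta must lie in (0, 1]")
  if (growth_rate < 1 || layers_per_block < 1 || n_blocks < 1)
    stop("growth_rate, layers_per_block and n_blocks must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (l2_weight < 0) stop("l2_weight must be >= 0")
  structure(list(dims = as.integer(dims), n_blocks = as.integer(n_blocks),
                 layers_per_block = as.integer(layers_per_block),
                 growth_rate = as.integer(growth_rate),
                 init_channels = as.integer(init_channels),
                 kernel_size = as.integer(kernel_size),
                 bottleneck = isTRUE(bottleneck),
                 compression = compression,
                 dropout_rate = dropout_rate, l2_weight = l2_weight,
                 n_classes = as.integer(n_classes)),
            class = "densenet_config")
}

#' Channel schedule of a DenseNet configuration
#'
#' Returns the channel bookkeeping implied by a configuration: the input
#' channel count of every dense layer (`k0 + k * (n - 1)` within each block),
#' each block's output count (`k0 + k * layers_per_block`), the transition
#' outputs (`floor(theta * c)`), and the feature count entering the final
#' linear layer.  The schedule depends only on channel hyperparameters, so
#' the same configuration built for 1D, 2D or 3D inputs shares it.
#'
#' @param config a [densenet_config()].
#' @return A list with `layer_inputs` (a list per block), `block_output`,
#'   `transition_output` and `final_features`.
#' @export
densenet_channels <- function(config) {
  stopifnot(inherits(config, "densenet_config"))
  k <- config$growth_rate
  cin <- config$init_channels
  layer_inputs <- vector("list", config$n_blocks)
  block_output <- integer(config$n_blocks)
  transition_output <- integer(max(config$n_blocks - 1L, 0L))
  for (b in seq_len(config$n_blocks)) {
    layer_inputs[[b]] <- cin + k * (seq_len(config$layers_per_block) - 1L)
    block_output[b] <- cin + k * config$layers_per_block
    if (b < config$n_blocks) {
      transition_output[b] <- as.integer(config$compression * block_output[b])
      cin <- transition_output[b]
    }
  }
  list(layer_inputs = layer_inputs, block_output = block_output,
       transition_output = transition_output,
       final_features = block_output[config$n_blocks])
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars in the model a configuration describes:
#' convolution kernels (bias-free, as every convolution is followed by batch
#' normalisation), the affine scale and shift of each BN, and the final
#' linear layer's weights and bias.  The count is independent of input size.
#'
#' @param config a [densenet_config()].
#' @return An integer.
#' @export
count_params <- function(config) {
  ch <- densenet_channels(config)
  kd <- config$kernel_size^config$dims
  k <- config$growth_rate
  total <- kd * 1 * config$init_channels       # initial convolution
  for (b in seq_len(config$n_blocks)) {
    for (cin in ch$layer_inputs[[b]]) {
      total <- total + 2 * cin                 # BN affine
      if (config$bottleneck) {
        total <- total + cin * 4 * k           # 1-wide bottleneck conv
        total <- total + 2 * (4 * k)           # its BN
        total <- total + kd * 4 * k * k        # main conv
      } else {
        total <- total + kd * cin * k          # main conv
      }
    }
    if (b < config$n_blocks) {
      cb <- ch$block_output[b]
      total <- total + 2 * cb                  # transition BN
      total <- total + cb * ch$transition_output[b]  # 1-wide conv
    }
  }
  cf <- ch$final_features
  total <- total + 2 * cf                      # head BN
  total <- total + cf * config$n_classes + config$n_classes
  as.integer(total)
}

# ---- internal geometry -----------------------------------------------------

net_kernel <- function(config) {
  k <- rep(1L, 3L)
  k[seq_len(config$dims)] <- config$kernel_size
  k
}

pool_shape <- function(shape) {
  ifelse(shape > 1L, shape %/% 2L, 1L)
}

# ---- initialisation --------------------------------------------------------

#' Initialise a DenseNet model
#'
#' Builds an untrained model: variance-scaling (He) normal initialisation for
#' convolution and linear weights, and unit scale / zero shift for batch
#' normalisation.
#'
#' @param config a [densenet_config()].
#' @param input_shape integer vector of length `config$dims`, the spatial
#'   grid of the inputs (e.g. `c(91, 109, 91)` for 3D, `91` for 1D).
#' @param seed integer seed for the weight initialisation.
#' @return An object of class `fdopa_densenet` (untrained).
#' @export
densenet_init <- function(config, input_shape, seed = NULL) {
  stopifnot(inherits(config, "densenet_config"))
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != config$dims)
    stop("input_shape must have length dims = ", config$dims)
  if (any(input_shape < 2L))
    stop("input spatial size too small for the network")
  shape3 <- c(input_shape, rep(1L, 3L - config$dims))
  kern <- net_kernel(config)
  pad_lo <- (kern - 1L) %/% 2L

  spatial <- vector("list", config$n_blocks)
  spatial[[1]] <- shape3
  for (b in seq_len(config$n_blocks - 1L)) {
    if (all(spatial[[b]] == 1L))
      stop("spatial size 1 in every axis: cannot pool further")
    spatial[[b + 1]] <- pool_shape(spatial[[b]])
  }
  ch <- densenet_channels(config)
  k <- config$growth_rate
  kd <- prod(kern)
  params <- list()
  buffers <- list()
  he_conv <- function(kd, cin, cout)
    array(rnorm(kd * cin * cout, sd = sqrt(2 / (kd * cin))),
          c(kd, cin, cout))
  add_bn <- function(name, c) {
    params[[paste0(name, "_gamma")]] <<- rep(1, c)
    params[[paste0(name, "_beta")]] <<- rep(0, c)
    buffers[[paste0(name, "_mean")]] <<- rep(0, c)
    buffers[[paste0(name, "_var")]] <<- rep(1, c)
  }
  with_seed(seed, {
    params$conv0_w <- he_conv(kd, 1L, config$init_channels)
    for (b in seq_len(config$n_blocks)) {
      for (l in seq_len(config$layers_per_block)) {
        cin <- ch$layer_inputs[[b]][l]
        stopifnot(cin == ch$layer_inputs[[b]][1] + k * (l - 1))  # k0 + k(n-1)
        p <- sprintf("b%d_l%d", b, l)
        add_bn(paste0(p, "_bn"), cin)
        if (config$bottleneck) {
          params[[paste0(p, "_bconv_w")]] <- he_conv(1L, cin, 4L * k)
          add_bn(paste0(p, "_bn2"), 4L * k)
          params[[paste0(p, "_conv_w")]] <- he_conv(kd, 4L * k, k)
        } else {
          params[[paste0(p, "_conv_w")]] <- he_conv(kd, cin, k)
        }
      }
      if (b < config$n_blocks) {
        cb <- ch$block_output[b]
        p <- sprintf("t%d", b)
        add_bn(paste0(p, "_bn"), cb)
        params[[paste0(p, "_conv_w")]] <- he_conv(1L, cb,
                                                  ch$transition_output[b])
      }
    }
    cf <- ch$final_features
    add_bn("final_bn", cf)
    params$fc_w <- matrix(rnorm(cf * config$n_classes, sd = sqrt(2 / cf)),
                          cf, config$n_classes)
    params$fc_b <- rep(0, config$n_classes)
  })
  structure(list(config = config, input_shape = input_shape,
                 spatial = spatial, kernel = kern, pad_lo = pad_lo,
                 channels = ch, params = params, buffers = buffers,
                 classes = NULL, history = NULL),
            class = "fdopa_densenet")
}

# ---- primitive layers ------------------------------------------------------

# Convolution wrappers around the padded shift-offset GEMM kernels.
# x is (V, cin, B); w is (Kd, cin, cout); shape is the 3-padded spatial grid.
conv_fwd_r <- function(x, w, shape, kernel, pad_lo) {
  d <- dim(x)
  y <- cpp_conv_fwd(x, w, shape, kernel, pad_lo, dim(w)[2], dim(w)[3], d[3])
  array(y, c(d[1], dim(w)[3], d[3]))
}

conv_bwd_r <- function(x, w, dy, shape, kernel, pad_lo, need_dx = TRUE) {
  d <- dim(x)
  r <- cpp_conv_bwd(x, w, dy, shape, kernel, pad_lo, dim(w)[2], dim(w)[3],
                    d[3], need_dx)
  r$dw <- array(r$dw, dim(w))
  if (need_dx) r$dx <- array(r$dx, d)
  r
}

KERNEL1 <- c(1L, 1L, 1L)
PAD0 <- c(0L, 0L, 0L)

# Batch statistics (mean, biased variance) of the first n_channels channels
# of a (V, C, B) tensor.  Channel-prefix access lets dense layers read their
# inputs directly from the growing block concatenation without copying.
bn_stats <- function(x, n_channels = dim(x)[2]) {
  d <- dim(x)
  s <- cpp_bn_stats(x, d[1], n_channels, d[3], d[2])
  list(mean = s[, 1], var = s[, 2])
}

# Fused BN + ReLU.  mu/invsd are either batch statistics (training) or
# running statistics (inference); the same kernel serves both modes.
bn_relu <- function(x, gamma, beta, mu, invsd, n_channels = dim(x)[2]) {
  d <- dim(x)
  array(cpp_bn_relu_fwd(x, d[1], n_channels, d[3], gamma, beta, mu, invsd,
                        d[2]),
        c(d[1], n_channels, d[3]))
}

bn_relu_bwd <- function(x, da, gamma, beta, mu, invsd,
                        n_channels = dim(x)[2]) {
  d <- dim(x)
  r <- cpp_bn_relu_bwd(x, da, d[1], n_channels, d[3], gamma, beta, mu,
                       invsd, d[2])
  r$dx <- array(r$dx, c(d[1], n_channels, d[3]))
  r
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_cols <- function(z) {
  z <- exp(sweep(z, 2, apply(z, 2, max)))
  sweep(z, 2, colSums(z), `/`)
}

# ---- forward / backward ----------------------------------------------------
#
# Backward recomputes the cheap elementwise activations (BN-ReLU outputs)
# from the stored block concatenations and cached batch statistics instead
# of caching every intermediate tensor, which keeps the training memory
# footprint at roughly one concatenation array per block.

# BN statistics (or running statistics) for one named BN, plus the fused
# activation on the first n_channels channels of x.
bn_act <- function(model, name, x, training, n_channels = dim(x)[2]) {
  pr <- model$params
  if (training) {
    st <- bn_stats(x, n_channels)
    mu <- st$mean
    invsd <- 1 / sqrt(st$var + BN_EPS)
  } else {
    mu <- model$buffers[[paste0(name, "_mean")]]
    invsd <- 1 / sqrt(model$buffers[[paste0(name, "_var")]] + BN_EPS)
    st <- NULL
  }
  a <- bn_relu(x, pr[[paste0(name, "_gamma")]], pr[[paste0(name, "_beta")]],
               mu, invsd, n_channels)
  list(a = a, mu = mu, invsd = invsd, stats = st)
}

roll_stats <- function(buffers, name, stats) {
  buffers[[paste0(name, "_mean")]] <-
    (1 - BN_MOMENTUM) * buffers[[paste0(name, "_mean")]] +
    BN_MOMENTUM * stats$mean
  buffers[[paste0(name, "_var")]] <-
    (1 - BN_MOMENTUM) * buffers[[paste0(name, "_var")]] +
    BN_MOMENTUM * stats$var
  buffers
}

# One dense layer: BN-ReLU(-bottleneck)-conv(-dropout), producing k new
# feature maps at unchanged spatial size.  A is the block concatenation; the
# layer reads its first cl channels in place.
dense_layer_forward <- function(model, b, l, A, cl, training) {
  cfg <- model$config
  p <- sprintf("b%d_l%d", b, l)
  pr <- model$params
  sp <- model$spatial[[b]]
  act <- bn_act(model, paste0(p, "_bn"), A, training, cl)
  cache <- list(mu = act$mu, invsd = act$invsd, stats = act$stats)
  if (cfg$bottleneck) {
    zb <- conv_fwd_r(act$a, pr[[paste0(p, "_bconv_w")]], sp, KERNEL1, PAD0)
    act2 <- bn_act(model, paste0(p, "_bn2"), zb, training)
    z <- conv_fwd_r(act2$a, pr[[paste0(p, "_conv_w")]], sp, model$kernel,
                    model$pad_lo)
    cache$mu2 <- act2$mu
    cache$invsd2 <- act2$invsd
    cache$stats2 <- act2$stats
  } else {
    z <- conv_fwd_r(act$a, pr[[paste0(p, "_conv_w")]], sp, model$kernel,
                    model$pad_lo)
  }
  if (training && cfg$dropout_rate > 0) {
    cache$drop_seed <- sample.int(.Machine$integer.max, 1)
    z <- array(cpp_dropout_mul(z, cfg$dropout_rate, cache$drop_seed), dim(z))
  }
  cache$z <- z
  cache
}

# Full forward pass.  x is (V, 1, B) at the input resolution.  Returns class
# probabilities and, when keep_cache, what backward needs.  In training mode
# the updated BN running statistics are returned as well.
net_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  pr <- model$params
  k <- cfg$growth_rate
  L <- cfg$layers_per_block
  buffers <- model$buffers
  caches <- vector("list", cfg$n_blocks)
  h <- conv_fwd_r(x, pr$conv0_w, model$spatial[[1]], model$kernel,
                  model$pad_lo)
  for (b in seq_len(cfg$n_blocks)) {
    V <- dim(h)[1]; B <- dim(h)[3]
    cin <- dim(h)[2]
    stopifnot(cin == model$channels$layer_inputs[[b]][1])
    A <- array(0, c(V, cin + k * L, B))
    A[, seq_len(cin), ] <- h
    layer_caches <- vector("list", L)
    for (l in seq_len(L)) {
      cl <- cin + k * (l - 1)  # layer n sees k0 + k (n - 1) channels
      stopifnot(cl == model$channels$layer_inputs[[b]][l])
      lc <- dense_layer_forward(model, b, l, A, cl, training)
      stopifnot(dim(lc$z)[2] == k)
      A[, cl + seq_len(k), ] <- lc$z
      lc$z <- NULL
      if (training) {
        p <- sprintf("b%d_l%d", b, l)
        buffers <- roll_stats(buffers, paste0(p, "_bn"), lc$stats)
        if (cfg$bottleneck)
          buffers <- roll_stats(buffers, paste0(p, "_bn2"), lc$stats2)
      }
      layer_caches[[l]] <- if (keep_cache) lc else NULL
    }
    h <- A
    block_cache <- list(layers = layer_caches)
    if (keep_cache) block_cache$A <- A
    if (b < cfg$n_blocks) {
      p <- sprintf("t%d", b)
      sp <- model$spatial[[b]]
      act <- bn_act(model, paste0(p, "_bn"), h, training)
      z <- conv_fwd_r(act$a, pr[[paste0(p, "_conv_w")]], sp, KERNEL1, PAD0)
      hp <- cpp_avgpool_fwd(z, sp, dim(z)[2], dim(z)[3])
      h <- array(hp, c(prod(pool_shape(sp)), dim(z)[2], dim(z)[3]))
      if (training) buffers <- roll_stats(buffers, paste0(p, "_bn"),
                                          act$stats)
      if (keep_cache)
        block_cache$transition <- list(mu = act$mu, invsd = act$invsd,
                                       stats = act$stats, zdim = dim(z))
    }
    caches[[b]] <- block_cache
  }
  actf <- bn_act(model, "final_bn", h, training)
  Vf <- dim(actf$a)[1]
  feat <- matrix(.colSums(actf$a, Vf, dim(actf$a)[2] * dim(actf$a)[3]) / Vf,
                 dim(actf$a)[2], dim(actf$a)[3])
  logits <- crossprod(pr$fc_w, feat) + pr$fc_b
  probs <- softmax_cols(logits)
  if (training) {
    buffers <- roll_stats(buffers, "final_bn", actf$stats)
  }
  out <- list(probs = probs, logits = logits)
  if (training) out$buffers <- buffers
  if (keep_cache)
    out$cache <- list(x = x, blocks = caches, head_in = h,
                      final_mu = actf$mu, final_invsd = actf$invsd,
                      final_stats = actf$stats, feat = feat)
  out
}

# Precise-BN recalibration: replace the momentum-based running statistics
# with exact aggregated batch statistics over a reference set (one forward
# pass).  With few gradient updates the exponential running averages still
# carry their initialisation, which corrupts inference-mode normalisation;
# aggregating E[x] and E[x^2] per BN over the whole training set removes
# that bias.
refresh_bn_stats <- function(model, x, batch_size = 32L) {
  # statistics describe the inference-time network: dropout off
  drop_rate <- model$config$dropout_rate
  model$config$dropout_rate <- 0
  n <- dim(x)[3]
  acc <- list()
  wt <- 0
  add <- function(name, stats, w) {
    key_m <- paste0(name, "_mean")
    key_v <- paste0(name, "_var")
    if (is.null(acc[[key_m]])) {
      acc[[key_m]] <<- w * stats$mean
      acc[[key_v]] <<- w * (stats$var + stats$mean^2)
    } else {
      acc[[key_m]] <<- acc[[key_m]] + w * stats$mean
      acc[[key_v]] <<- acc[[key_v]] + w * (stats$var + stats$mean^2)
    }
  }
  for (i0 in seq(1, n, by = batch_size)) {
    ii <- i0:min(i0 + batch_size - 1, n)
    fw <- net_forward(model, x[, , ii, drop = FALSE], training = TRUE,
                      keep_cache = TRUE)
    w <- length(ii)
    wt <- wt + w
    cfg <- model$config
    for (b in seq_len(cfg$n_blocks)) {
      bc <- fw$cache$blocks[[b]]
      for (l in seq_len(cfg$layers_per_block)) {
        p <- sprintf("b%d_l%d", b, l)
        add(paste0(p, "_bn"), bc$layers[[l]]$stats, w)
        if (cfg$bottleneck) add(paste0(p, "_bn2"), bc$layers[[l]]$stats2, w)
      }
      if (b < cfg$n_blocks) add(sprintf("t%d_bn", b), bc$transition$stats, w)
    }
    add("final_bn", fw$cache$final_stats, w)
  }
  for (nm in names(acc)) {
    if (endsWith(nm, "_mean")) {
      model$buffers[[nm]] <- acc[[nm]] / wt
    } else {
      base <- sub("_var$", "", nm)
      mu <- acc[[paste0(base, "_mean")]] / wt
      model$buffers[[nm]] <- pmax(acc[[nm]] / wt - mu^2, 0)
    }
  }
  model$config$dropout_rate <- drop_rate
  model
}

dense_layer_backward <- function(model, b, l, A, cl, dz, lc, grads) {
  cfg <- model$config
  p <- sprintf("b%d_l%d", b, l)
  pr <- model$params
  sp <- model$spatial[[b]]
  if (!is.null(lc$drop_seed))
    dz <- array(cpp_dropout_mul(dz, cfg$dropout_rate, lc$drop_seed), dim(dz))
  # recompute the BN-ReLU activation from the cached statistics
  a <- bn_relu(A, pr[[paste0(p, "_bn_gamma")]],
               pr[[paste0(p, "_bn_beta")]], lc$mu, lc$invsd, cl)
  if (cfg$bottleneck) {
    zb <- conv_fwd_r(a, pr[[paste0(p, "_bconv_w")]], sp, KERNEL1, PAD0)
    a2 <- bn_relu(zb, pr[[paste0(p, "_bn2_gamma")]],
                  pr[[paste0(p, "_bn2_beta")]], lc$mu2, lc$invsd2)
    cb <- conv_bwd_r(a2, pr[[paste0(p, "_conv_w")]], dz, sp, model$kernel,
                     model$pad_lo)
    grads[[paste0(p, "_conv_w")]] <- cb$dw
    bb2 <- bn_relu_bwd(zb, cb$dx, pr[[paste0(p, "_bn2_gamma")]],
                       pr[[paste0(p, "_bn2_beta")]], lc$mu2, lc$invsd2)
    grads[[paste0(p, "_bn2_gamma")]] <- bb2$dgamma
    grads[[paste0(p, "_bn2_beta")]] <- bb2$dbeta
    cb1 <- conv_bwd_r(a, pr[[paste0(p, "_bconv_w")]], bb2$dx, sp, KERNEL1,
                      PAD0)
    grads[[paste0(p, "_bconv_w")]] <- cb1$dw
    da <- cb1$dx
  } else {
    cb <- conv_bwd_r(a, pr[[paste0(p, "_conv_w")]], dz, sp, model$kernel,
                     model$pad_lo)
    grads[[paste0(p, "_conv_w")]] <- cb$dw
    da <- cb$dx
  }
  bb <- bn_relu_bwd(A, da, pr[[paste0(p, "_bn_gamma")]],
                    pr[[paste0(p, "_bn_beta")]], lc$mu, lc$invsd, cl)
  grads[[paste0(p, "_bn_gamma")]] <- bb$dgamma
  grads[[paste0(p, "_bn_beta")]] <- bb$dbeta
  list(dxin = bb$dx, grads = grads)
}

# Backward pass from dlogits; returns gradients named like params.
net_backward <- function(model, fw, dlogits) {
  cfg <- model$config
  pr <- model$params
  k <- cfg$growth_rate
  L <- cfg$layers_per_block
  cache <- fw$cache
  grads <- list()
  grads$fc_w <- cache$feat %*% t(dlogits)
  grads$fc_b <- rowSums(dlogits)
  dfeat <- pr$fc_w %*% dlogits
  d <- dim(cache$head_in); Vf <- d[1]
  daf <- array(rep(as.vector(dfeat), each = Vf) / Vf, d)
  bbf <- bn_relu_bwd(cache$head_in, daf, pr$final_bn_gamma,
                     pr$final_bn_beta, cache$final_mu, cache$final_invsd)
  grads$final_bn_gamma <- bbf$dgamma
  grads$final_bn_beta <- bbf$dbeta
  dh <- bbf$dx
  for (b in rev(seq_len(cfg$n_blocks))) {
    bc <- cache$blocks[[b]]
    if (b < cfg$n_blocks) {
      tc <- bc$transition
      p <- sprintf("t%d", b)
      sp <- model$spatial[[b]]
      dz <- array(cpp_avgpool_bwd(dh, sp, tc$zdim[2], tc$zdim[3]), tc$zdim)
      a <- bn_relu(bc$A, pr[[paste0(p, "_bn_gamma")]],
                   pr[[paste0(p, "_bn_beta")]], tc$mu, tc$invsd)
      cb <- conv_bwd_r(a, pr[[paste0(p, "_conv_w")]], dz, sp, KERNEL1, PAD0)
      grads[[paste0(p, "_conv_w")]] <- cb$dw
      bb <- bn_relu_bwd(bc$A, cb$dx, pr[[paste0(p, "_bn_gamma")]],
                        pr[[paste0(p, "_bn_beta")]], tc$mu, tc$invsd)
      grads[[paste0(p, "_bn_gamma")]] <- bb$dgamma
      grads[[paste0(p, "_bn_beta")]] <- bb$dbeta
      dh <- bb$dx
    }
    cin <- model$channels$layer_inputs[[b]][1]
    for (l in rev(seq_len(L))) {
      cl <- cin + k * (l - 1)
      dz <- dh[, cl + seq_len(k), , drop = FALSE]
      r <- dense_layer_backward(model, b, l, bc$A, cl, dz, bc$layers[[l]],
                                grads)
      grads <- r$grads
      # dh is owned by this pass; accumulate the input gradient in place
      cpp_add_slice(dh, r$dxin, dim(dh)[1], cl, dim(dh)[3], dim(dh)[2])
    }
    dh <- dh[, seq_len(cin), , drop = FALSE]
  }
  cb0 <- conv_bwd_r(cache$x, pr$conv0_w, dh, model$spatial[[1]],
                    model$kernel, model$pad_lo, need_dx = FALSE)
  grads$conv0_w <- cb0$dw
  grads
}

#' @export
print.fdopa_densenet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("DenseNet %dD classifier: %d blocks x %d layers, k = %d, k0 = %d\n",
              cfg$dims, cfg$n_blocks, cfg$layers_per_block, cfg$growth_rate,
              cfg$init_channels))
  cat(sprintf("  input %s | %d trainable parameters | %s\n",
              paste(x$input_shape, collapse = " x "), count_params(cfg),
              if (is.null(x$history)) "untrained"
              else sprintf("trained %d epochs", nrow(x$history))))
  if (!is.null(x$history)) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  final training loss %.4f, accuracy %.3f\n",
                h$loss, h$accuracy))
    if (!is.na(h$val_accuracy))
      cat(sprintf("  final validation loss %.4f, accuracy %.3f\n",
                  h$val_loss, h$val_accuracy))
  }
  invisible(x)
}

#' @export
summary.fdopa_densenet <- function(object, ...) {
  print(object)
  ch <- object$channels
  cat("Channel schedule:\n")
  for (b in seq_along(ch$layer_inputs))
    cat(sprintf("  block %d: inputs %s -> %d channels\n", b,
                paste(ch$layer_inputs[[b]], collapse = ", "),
                ch$block_output[b]))
  invisible(object)
}

#' Predict from a trained DenseNet
#'
#' Runs the network in inference mode (batch normalisation uses running
#' statistics; dropout is off), producing softmax class probabilities --
#' entries in `[0, 1]` summing to 1 -- or the argmax class.
#'
#' @param object a trained `fdopa_densenet`.
#' @param x array of inputs, sample index last (a single map's worth of
#'   dimensions is also accepted).
#' @param type `"prob"` for the probability matrix (samples x classes) or
#'   `"class"` for predicted labels.
#' @param batch_size samples per forward pass.
#' @param ... unused.
#' @return A matrix of probabilities or a vector of labels.
#' @export
predict.fdopa_densenet <- function(object, x, type = c("prob", "class"),
                                   batch_size = 64L, ...) {
  type <- match.arg(type)
  x <- prep_inputs(object, x)
  n <- dim(x)[3]
  probs <- matrix(NA_real_, n, object$config$n_classes)
  for (i0 in seq(1, n, by = batch_size)) {
    ii <- i0:min(i0 + batch_size - 1, n)
    fw <- net_forward(object, x[, , ii, drop = FALSE])
    probs[ii, ] <- t(fw$probs)
  }
  cls <- object$classes
  if (!is.null(cls)) colnames(probs) <- cls
  if (type == "prob") return(probs)
  idx <- max.col(probs, ties.method = "first")
  if (is.null(cls)) idx else factor(cls[idx], levels = cls)
}

# Flatten user input (spatial dims ..., N) to the internal (V, 1, B) layout,
# checking the spatial grid against the model.
prep_inputs <- function(model, x) {
  if (inherits(x, "suvr_map")) x <- x$values
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  ds <- model$input_shape
  if (length(d) == length(ds) && all(d == ds)) {
    x <- array(x, c(d, 1L))
    d <- dim(x)
  }
  # tolerate degenerate trailing spatial dims (e.g. 91 x 109 x 1 slices)
  dd <- d[-length(d)]
  dd <- dd[dd > 1 | seq_along(dd) <= length(ds)]
  if (length(dd) != length(ds) || !all(dd[seq_along(ds)] == ds))
    stop("input shape (", paste(d[-length(d)], collapse = " x "),
         ") does not match model input ", paste(ds, collapse = " x "))
  array(as.double(x), c(prod(ds), 1L, d[length(d)]))
}
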
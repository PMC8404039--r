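#' Training configuration
#'
#' Optimisation settings for [densenet_train()].  The defaults are the QC
#' training protocol: stochastic gradient descent with learning rate 1e-3,
#' momentum 0.9 and Nesterov acceleration, batch size 32, and an epoch cap
#' of 300 (the point beyond which classification performance changes by
#' less than 1%).  Adam is available with its published defaults
#' (beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8).
#'
#' @param optimizer `"sgd"` or `"adam"`.
#' @param learning_rate step size.
#' @param momentum SGD momentum coefficient.
#' @param nesterov use Nesterov momentum (SGD only).
#' @param batch_size training samples per gradient update.
#' @param max_epochs number of passes over the training data.
#' @param seed integer seed controlling weight initialisation, shuffling and
#'   dropout; identical seeds give identical training runs.
#' @param shuffle reshuffle the training order every epoch.
#' @param verbose print a line per epoch.
#' @return An object of class `train_control`.
#' @export
train_control <- function(optimizer = c("sgd", "adam"), learning_rate = 1e-3,
                          momentum = 0.9, nesterov = TRUE, batch_size = 32L,
                          max_epochs = 300L, seed = NULL, shuffle = TRUE,
                          verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (max_epochs < 1L) stop("max_epochs must be >= 1")
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 momentum = momentum, nesterov = isTRUE(nesterov),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = seed, shuffle = isTRUE(shuffle),
                 verbose = isTRUE(verbose)),
            class = "train_control")
}

# One optimizer step; returns updated params and state.
optim_step <- function(params, grads, state, control) {
  lr <- control$learning_rate
  if (control$optimizer == "sgd") {
    mu <- control$momentum
    for (nm in names(grads)) {
      g <- grads[[nm]]
      v <- if (is.null(state$v[[nm]])) g * 0 else state$v[[nm]]
      v <- mu * v + g
      step <- if (control$nesterov) g + mu * v else v
      params[[nm]] <- params[[nm]] - lr * step
      state$v[[nm]] <- v
    }
  } else {
    state$t <- (if (is.null(state$t)) 0L else state$t) + 1L
    bc1 <- 1 - ADAM_BETA1^state$t
    bc2 <- 1 - ADAM_BETA2^state$t
    for (nm in names(grads)) {
      g <- grads[[nm]]
      m <- if (is.null(state$m[[nm]])) g * 0 else state$m[[nm]]
      v <- if (is.null(state$v[[nm]])) g * 0 else state$v[[nm]]
      m <- ADAM_BETA1 * m + (1 - ADAM_BETA1) * g
      v <- ADAM_BETA2 * v + (1 - ADAM_BETA2) * g * g
      params[[nm]] <- params[[nm]] -
        lr * (m / bc1) / (sqrt(v / bc2) + ADAM_EPS)
      state$m[[nm]] <- m
      state$v[[nm]] <- v
    }
  }
  list(params = params, state = state)
}

# Softmax cross-entropy data loss and gradient for integer labels (1-based).
softmax_loss <- function(logits, y_idx) {
  probs <- softmax_cols(logits)
  B <- ncol(probs)
  picked <- probs[cbind(y_idx, seq_len(B))]
  loss <- -mean(log(pmax(picked, CE_EPS)))
  dlogits <- probs
  dlogits[cbind(y_idx, seq_len(B))] <-
    dlogits[cbind(y_idx, seq_len(B))] - 1
  list(loss = loss, dlogits = dlogits / B, probs = probs)
}

# L2 penalty over convolution and linear weights (not BN affine terms).
l2_penalty <- function(params, l2) {
  if (l2 <= 0) return(0)
  l2 * sum(vapply(names(params)[endsWith(names(params), "_w")],
                  function(nm) sum(params[[nm]]^2), numeric(1)))
}

add_l2_grads <- function(grads, params, l2) {
  if (l2 <= 0) return(grads)
  for (nm in names(grads))
    if (endsWith(nm, "_w")) grads[[nm]] <- grads[[nm]] + 2 * l2 * params[[nm]]
  grads
}

# Total training loss of a model on a batch: data cross-entropy plus the L2
# penalty.  Exposed internally so tests can assert the decomposition.
training_loss <- function(model, x, y_idx) {
  fw <- net_forward(model, x, training = FALSE)
  sl <- softmax_loss(fw$logits, y_idx)
  sl$loss + l2_penalty(model$params, model$config$l2_weight)
}

#' Train a DenseNet QC classifier
#'
#' Fits the dimension-generic DenseNet by mini-batch gradient descent on the
#' softmax cross-entropy plus the configured L2 penalty.  Training is
#' deterministic given `control$seed` (weight initialisation, shuffling and
#' dropout all draw from one seeded stream).
#'
#' @param x numeric array of training maps, sample index last; the leading
#'   dimensions are the spatial grid and must match `config$dims`.
#' @param y class labels (factor or coercible); at least two classes must be
#'   present.  By convention the QC-failed class is the second level.
#' @param config a [densenet_config()].
#' @param control a [train_control()].
#' @param validation optional `list(x, y)` evaluated after every epoch.
#' @param model optionally, a previously initialised or trained
#'   `fdopa_densenet` to continue training.
#' @return A trained `fdopa_densenet`; `$history` holds one row per epoch
#'   with training loss (cross-entropy + L2 penalty), training accuracy and,
#'   when `validation` is given, validation cross-entropy and accuracy.
#' @examples
#' \donttest{
#' x <- array(rnorm(16 * 20), c(16, 20))
#' x[1:8, 1:10] <- x[1:8, 1:10] + 3
#' y <- factor(rep(c("good", "failed"), each = 10),
#'             levels = c("good", "failed"))
#' cfg <- densenet_config(dims = 1, n_blocks = 2, layers_per_block = 2,
#'                        growth_rate = 4, init_channels = 8)
#' fit <- densenet_train(x, y, cfg,
#'                       train_control(learning_rate = 0.05, max_epochs = 30,
#'                                     seed = 1))
#' fit
#' }
#' @export
densenet_train <- function(x, y, config = densenet_config(),
                           control = train_control(), validation = NULL,
                           model = NULL) {
  y <- as.factor(y)
  present <- table(y)
  if (sum(present > 0) < 2L)
    stop("training data must contain at least 2 classes")
  if (nlevels(y) != config$n_classes)
    stop("number of factor levels must equal config$n_classes")
  y_idx <- as.integer(y)
  if (is.null(model))
    model <- densenet_init(config, head(dim(x), config$dims),
                           seed = control$seed)
  x <- prep_inputs(model, x)
  n <- dim(x)[3]
  if (length(y_idx) != n) stop("x and y disagree in sample count")

  val <- NULL
  if (!is.null(validation))
    val <- list(x = validation$x,
                y_idx = as.integer(factor(validation$y, levels = levels(y))))

  state <- list()
  history <- vector("list", control$max_epochs)
  prev_epochs <- if (is.null(model$history)) 0L else nrow(model$history)
  with_seed(if (is.null(control$seed)) NULL else control$seed + 1L, {
    for (epoch in seq_len(control$max_epochs)) {
      ord <- if (control$shuffle) sample.int(n) else seq_len(n)
      ep_loss <- 0
      ep_correct <- 0L
      for (i0 in seq(1, n, by = control$batch_size)) {
        ii <- ord[i0:min(i0 + control$batch_size - 1, n)]
        xb <- x[, , ii, drop = FALSE]
        yb <- y_idx[ii]
        fw <- net_forward(model, xb, training = TRUE, keep_cache = TRUE)
        model$buffers <- fw$buffers
        sl <- softmax_loss(fw$logits, yb)
        grads <- net_backward(model, fw, sl$dlogits)
        grads <- add_l2_grads(grads, model$params, config$l2_weight)
        st <- optim_step(model$params, grads, state, control)
        model$params <- st$params
        state <- st$state
        ep_loss <- ep_loss + (sl$loss +
          l2_penalty(model$params, config$l2_weight)) * length(ii)
        ep_correct <- ep_correct + sum(max.col(t(sl$probs)) == yb)
      }
      row <- data.frame(epoch = prev_epochs + epoch, loss = ep_loss / n,
                        accuracy = ep_correct / n,
                        val_loss = NA_real_, val_accuracy = NA_real_)
      if (!is.null(val)) {
        ev <- net_evaluate(model, val$x, val$y_idx)
        row$val_loss <- ev$loss
        row$val_accuracy <- ev$accuracy
      }
      history[[epoch]] <- row
      if (control$verbose)
        cat(sprintf("epoch %3d  loss %.4f  acc %.3f%s\n", row$epoch,
                    row$loss, row$accuracy,
                    if (is.null(val)) "" else
                      sprintf("  val_loss %.4f  val_acc %.3f",
                              row$val_loss, row$val_accuracy)))
    }
  })
  # precise-BN: replace momentum running statistics with exact aggregated
  # statistics over the training set before the model is used for inference
  model <- refresh_bn_stats(model, x, control$batch_size)
  model$history <- rbind(model$history, do.call(rbind, history))
  model$classes <- levels(y)
  model$control <- control
  model
}

# Inference-mode evaluation: multiclass cross-entropy and accuracy.
net_evaluate <- function(model, x, y_idx, batch_size = 64L) {
  if (is.factor(y_idx)) y_idx <- as.integer(y_idx)
  x <- prep_inputs(model, x)
  n <- dim(x)[3]
  loss <- 0
  correct <- 0L
  probs <- matrix(NA_real_, n, model$config$n_classes)
  for (i0 in seq(1, n, by = batch_size)) {
    ii <- i0:min(i0 + batch_size - 1, n)
    fw <- net_forward(model, x[, , ii, drop = FALSE])
    picked <- fw$probs[cbind(y_idx[ii], seq_along(ii))]
    loss <- loss - sum(log(pmax(picked, CE_EPS)))
    correct <- correct + sum(max.col(t(fw$probs)) == y_idx[ii])
    probs[ii, ] <- t(fw$probs)
  }
  list(loss = loss / n, accuracy = correct / n, probs = probs)
}

#' Plot training history
#'
#' Loss and accuracy per epoch for the training set and, when recorded, the
#' validation set.
#'
#' @param x a trained `fdopa_densenet`.
#' @param ... passed to [plot()].
#' @export
plot.fdopa_densenet <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  has_val <- !all(is.na(h$val_loss))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
       ylim = range(c(h$loss, h$val_loss), na.rm = TRUE), ...)
  if (has_val) lines(h$epoch, h$val_loss, lty = 2)
  plot(h$epoch, h$accuracy, type = "l", xlab = "epoch", ylab = "accuracy",
       ylim = c(0, 1), ...)
  if (has_val) {
    lines(h$epoch, h$val_accuracy, lty = 2)
    legend("bottomright", c("training", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

# Subset an array along its last (sample) dimension.
slice_samples <- function(x, idx) {
  d <- dim(x)
  m <- matrix(x, prod(d[-length(d)]), d[length(d)])[, idx, drop = FALSE]
  array(m, c(d[-length(d)], length(idx)))
}

# Class-stratified disjoint folds: within each class, shuffled indices are
# dealt round-robin, so balanced data yield balanced validation folds.
stratified_folds <- function(y, n_folds, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' Cross-validate a DenseNet QC classifier
#'
#' Stratified `n_folds`-fold cross-validation: each validation fold holds
#' `1/n_folds` of the data with equal class counts (for balanced data), a
#' fresh model is trained on the remainder, and the five evaluation metrics
#' -- accuracy, precision, recall, AUC and validation cross-entropy -- are
#' computed on the held-out fold and aggregated as mean and SD.  The
#' `"random_splits"` scheme instead draws independent stratified 80/20
#' splits per repetition.
#'
#' @param x training array, sample index last.
#' @param y class labels; every class needs at least `n_folds` members.  The
#'   second factor level is treated as the positive (QC-failed) class.
#' @param config a [densenet_config()].
#' @param control a [train_control()]; fold `f` trains with seed
#'   `control$seed + f` so runs are reproducible yet folds differ.
#' @param n_folds number of folds.
#' @param scheme `"stratified"` (disjoint folds, the default) or
#'   `"random_splits"`.
#' @param keep_models keep the per-fold trained models (needed for
#'   out-of-sample prediction with [predict.densenet_cv()]).
#' @return An object of class `densenet_cv` with elements `folds` (per-fold
#'   metric data frame, including the final training loss), `summary`
#'   (mean and SD per metric), `models`, and `fold_id`.
#' @export
cross_validate <- function(x, y, config = densenet_config(),
                           control = train_control(), n_folds = 5L,
                           scheme = c("stratified", "random_splits"),
                           keep_models = TRUE) {
  scheme <- match.arg(scheme)
  y <- droplevels(as.factor(y))
  if (any(table(y) < n_folds))
    stop("every class needs at least n_folds = ", n_folds, " members")
  n <- length(y)
  fold_id <- if (scheme == "stratified")
    stratified_folds(y, n_folds, seed = control$seed)
  else NULL

  folds <- vector("list", n_folds)
  models <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    val_idx <- if (scheme == "stratified") which(fold_id == f)
    else with_seed(if (is.null(control$seed)) NULL else control$seed + 100L + f,
                   unlist(lapply(levels(y), function(cl) {
                     i <- which(y == cl)
                     sample(i, round(length(i) / n_folds))
                   })))
    tr_idx <- setdiff(seq_len(n), val_idx)
    ctl <- control
    if (!is.null(ctl$seed)) ctl$seed <- ctl$seed + f
    fit <- densenet_train(slice_samples(x, tr_idx), y[tr_idx], config, ctl)
    ev <- net_evaluate(fit, slice_samples(x, val_idx),
                       as.integer(y[val_idx]))
    scores <- ev$probs[, 2]
    pred <- max.col(ev$probs, ties.method = "first")
    m <- eval_metrics(as.integer(y[val_idx]) == 2L, pred == 2L, scores)
    folds[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                             precision = m$precision, recall = m$recall,
                             auc = m$auc, loss = m$loss,
                             train_loss = fit$history$loss[nrow(fit$history)],
                             n_val = length(val_idx))
    models[[f]] <- if (keep_models) fit else NULL
  }
  folds <- do.call(rbind, folds)
  metrics <- c("accuracy", "precision", "recall", "auc", "loss",
               "train_loss")
  summ <- data.frame(metric = metrics,
                     mean = vapply(metrics, function(m) mean(folds[[m]]),
                                   numeric(1)),
                     sd = vapply(metrics, function(m) sd(folds[[m]]),
                                 numeric(1)),
                     row.names = NULL)
  structure(list(folds = folds, summary = summ, models = models,
                 fold_id = fold_id, classes = levels(y), scheme = scheme,
                 config = config, control = control),
            class = "densenet_cv")
}

#' @export
print.densenet_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated DenseNet (%s folds)\n",
              nrow(x$folds), x$scheme))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-10s %.3f +/- %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}

#' Predict with an ensemble of cross-validated models
#'
#' Applies every fold's model to new data.  `"vote"` takes the majority
#' class over fold models (ties broken by mean probability); `"mean_prob"`
#' averages the fold probabilities and takes the argmax.
#'
#' @param object a `densenet_cv` fitted with `keep_models = TRUE`.
#' @param x array of inputs, sample index last.
#' @param method `"vote"` or `"mean_prob"`.
#' @param ... unused.
#' @return A factor of predicted labels with attribute `"prob"` holding the
#'   mean probability matrix.
#' @export
predict.densenet_cv <- function(object, x, method = c("vote", "mean_prob"),
                                ...) {
  method <- match.arg(method)
  if (!length(object$models) || is.null(object$models[[1]]))
    stop("cross-validation was run with keep_models = FALSE")
  probs <- lapply(object$models, function(m) predict(m, x, type = "prob"))
  mean_prob <- Reduce(`+`, probs) / length(probs)
  if (method == "vote") {
    votes <- vapply(probs, function(p) max.col(p, ties.method = "first"),
                    integer(nrow(mean_prob)))
    votes <- matrix(votes, nrow = nrow(mean_prob))
    pick <- apply(votes, 1, function(v) {
      tb <- tabulate(v, nbins = ncol(mean_prob))
      w <- which(tb == max(tb))
      if (length(w) == 1L) w else NA_integer_
    })
    tie <- is.na(pick)
    pick[tie] <- max.col(mean_prob[tie, , drop = FALSE],
                         ties.method = "first")
  } else {
    pick <- max.col(mean_prob, ties.method = "first")
  }
  out <- factor(object$classes[pick], levels = object$classes)
  attr(out, "prob") <- mean_prob
  out
}

#' Save or load a DenseNet model
#'
#' Models (or cross-validation ensembles) are serialised with their full
#' configuration embedded, so a loaded checkpoint predicts identically.
#'
#' @param model a `fdopa_densenet` or `densenet_cv`.
#' @param path file path (conventionally `.rds`).
#' @return `load_densenet` returns the deserialised object.
#' @export
save_densenet <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_densenet
#' @export
load_densenet <- function(path) readRDS(path)
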
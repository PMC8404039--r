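test_that("zero learning rate leaves the weights unchanged", {
  d <- separable_profiles(6)
  cfg <- tiny_config()
  m0 <- densenet_init(cfg, 32L, seed = 10)
  fit <- densenet_train(d$x, d$y, cfg,
                        train_control(learning_rate = 0, max_epochs = 3,
                                      seed = 10))
  expect_equal(fit$params, m0$params)
})

test_that("training is deterministic given the seed", {
  d <- separable_profiles(6)
  ctl <- train_control(learning_rate = 0.05, max_epochs = 5, seed = 2)
  f1 <- densenet_train(d$x, d$y, tiny_config(), ctl)
  f2 <- densenet_train(d$x, d$y, tiny_config(), ctl)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$params, f2$params)
  ctl2 <- train_control(learning_rate = 0.05, max_epochs = 5, seed = 3)
  f3 <- densenet_train(d$x, d$y, tiny_config(), ctl2)
  expect_false(identical(f1$history$loss, f3$history$loss))
})

test_that("single-class training data are rejected", {
  d <- separable_profiles(6)
  keep <- d$y == "good"
  expect_error(densenet_train(fdopaqc:::slice_samples(d$x, which(keep)),
                              d$y[keep], tiny_config(), train_control()),
               "at least 2 classes")
})

test_that("the model overfits trivially separable inputs to perfect accuracy", {
  d <- separable_profiles(10)
  fit <- densenet_train(d$x, d$y, tiny_config(),
                        train_control(optimizer = "adam",
                                      learning_rate = 1e-3,
                                      max_epochs = 60, seed = 6))
  expect_equal(mean(predict(fit, d$x, type = "class") == d$y), 1)
  expect_equal(tail(fit$history$accuracy, 1), 1)
})

test_that("the training loss decomposes into data loss plus the L2 penalty", {
  d <- separable_profiles(6)
  cfg <- tiny_config(l2_weight = 0.01)
  m <- densenet_init(cfg, 32L, seed = 11)
  x <- fdopaqc:::prep_inputs(m, d$x)
  y_idx <- as.integer(d$y)
  total <- fdopaqc:::training_loss(m, x, y_idx)
  fw <- fdopaqc:::net_forward(m, x)
  data_loss <- fdopaqc:::softmax_loss(fw$logits, y_idx)$loss
  w_sq <- sum(vapply(names(m$params)[endsWith(names(m$params), "_w")],
                     function(nm) sum(m$params[[nm]]^2), numeric(1)))
  expect_equal(total, data_loss + 0.01 * w_sq, tolerance = 1e-12)
})

test_that("SGD and Adam both reduce the training loss", {
  d <- separable_profiles(10)
  for (opt in c("sgd", "adam")) {
    fit <- densenet_train(d$x, d$y, tiny_config(),
                          train_control(optimizer = opt,
                                        learning_rate = if (opt == "sgd") 0.1 else 1e-3,
                                        max_epochs = 30, seed = 8))
    expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  }
})

test_that("stratified folds partition the data with balanced validation sets", {
  d <- separable_profiles(20)  # 40 samples, 20/20
  cv <- cross_validate(d$x, d$y, tiny_config(),
                       train_control(learning_rate = 0.05, max_epochs = 2,
                                     seed = 4))
  expect_identical(nrow(cv$folds), 5L)
  expect_true(all(cv$folds$n_val == 8))            # 20% of the data
  for (f in 1:5) {
    val <- which(cv$fold_id == f)
    expect_identical(as.vector(table(d$y[val])), c(4L, 4L))  # balanced
  }
  # union of validation folds covers every sample exactly once
  expect_identical(sort(unlist(lapply(1:5, function(f) which(cv$fold_id == f)))),
                   1:40)
  expect_error(cross_validate(fdopaqc:::slice_samples(d$x, 1:24),
                              d$y[1:24], tiny_config(), train_control()),
               "at least n_folds")
})

test_that("a constant classifier scores chance accuracy on balanced data", {
  y <- rep(c(0, 1), each = 50)
  expect_equal(metric_accuracy(y, rep(1, 100)), 0.5)
  expect_equal(metric_auc(y, rep(0.7, 100)), 0.5)
})

test_that("the random-splits scheme draws balanced 20% validation sets", {
  d <- separable_profiles(15)  # 30 samples
  cv <- cross_validate(d$x, d$y, tiny_config(),
                       train_control(learning_rate = 0.05, max_epochs = 2,
                                     seed = 4),
                       scheme = "random_splits")
  expect_true(all(cv$folds$n_val == 6))
})

test_that("the cross-validated ensemble predicts by majority vote", {
  d <- separable_profiles(10)
  cv <- cross_validate(d$x, d$y, tiny_config(),
                       train_control(optimizer = "adam", learning_rate = 1e-3,
                                     max_epochs = 40, seed = 9))
  pred <- predict(cv, d$x)
  expect_s3_class(pred, "factor")
  expect_identical(levels(pred), c("good", "failed"))
  expect_gt(mean(pred == d$y), 0.9)
  expect_identical(dim(attr(pred, "prob")), c(20L, 2L))
})

test_that("models survive a save/load round trip", {
  d <- separable_profiles(6)
  fit <- densenet_train(d$x, d$y, tiny_config(),
                        train_control(learning_rate = 0.05, max_epochs = 3,
                                      seed = 12))
  path <- withr::local_tempfile(fileext = ".rds")
  save_densenet(fit, path)
  back <- load_densenet(path)
  expect_identical(predict(back, d$x), predict(fit, d$x))
})

test_that("training control validates its arguments", {
  expect_error(train_control(batch_size = 0), "batch_size")
  expect_error(train_control(max_epochs = 0), "max_epochs")
  expect_error(train_control(optimizer = "rmsprop"))
})
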
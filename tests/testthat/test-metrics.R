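# Independent oracle: metrics from an explicitly counted confusion table.
oracle_confusion <- function(y, p) {
  tp <- sum(y == 1 & p == 1); tn <- sum(y == 0 & p == 0)
  fp <- sum(y == 0 & p == 1); fn <- sum(y == 1 & p == 0)
  list(acc = (tp + tn) / length(y),
       prec = if (tp + fp > 0) tp / (tp + fp) else NaN,
       rec = if (tp + fn > 0) tp / (tp + fn) else NaN)
}

# O(n^2) Mann-Whitney oracle with half-weight ties.
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

test_that("metrics reproduce their closed-form values", {
  expect_equal(metric_accuracy(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  # TP=3, TN=5, N=10
  y <- c(rep(1, 5), rep(0, 5))
  p <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(metric_accuracy(y, p), 0.8)
  expect_equal(metric_precision(c(1, 1, 1, 1), c(1, 1, 1, 1)), 1)
  expect_equal(metric_precision(c(1, 1, 1, 1, 0, 0, 0, 0), rep(1, 8)), 0.5)
  expect_equal(metric_recall(c(1, 1, 1, 1), c(1, 1, 1, 1)), 1)
  expect_equal(metric_recall(c(1, 1, 1, 1), c(1, 0, 0, 0)), 0.25)
  expect_equal(metric_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(metric_auc(c(1, 1, 0, 0), rep(0.5, 4)), 0.5)
  expect_equal(metric_cross_entropy(1, 1), 0, tolerance = 1e-6)
  expect_equal(metric_cross_entropy(1, 0.5), log(2))
  expect_equal(metric_cross_entropy(0, 0.1), -log(0.9))
})

test_that("metrics agree with brute-force oracles on random instances", {
  set.seed(42)
  got <- matrix(NA_real_, 200, 5)
  want <- matrix(NA_real_, 200, 5)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    y <- rbinom(n, 1, 0.5)
    if (all(y == 1)) y[1] <- 0
    if (all(y == 0)) y[1] <- 1
    p <- rbinom(n, 1, 0.5)
    s <- round(runif(n), 2)  # rounding forces ties
    pr <- pmin(pmax(runif(n), 1e-6), 1 - 1e-6)
    o <- oracle_confusion(y, p)
    got[rep, ] <- suppressWarnings(c(
      metric_accuracy(y, p), metric_precision(y, p), metric_recall(y, p),
      metric_auc(y, s), metric_cross_entropy(y, pr)))
    want[rep, ] <- c(o$acc, o$prec, o$rec, oracle_auc(y, s),
                     -mean(y * log(pr) + (1 - y) * log(1 - pr)))
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("class relabelling fixes accuracy and mirrors AUC", {
  set.seed(7)
  y <- rbinom(30, 1, 0.5); y[1:2] <- c(0, 1)
  p <- rbinom(30, 1, 0.5)
  s <- runif(30)
  expect_equal(metric_accuracy(1 - y, 1 - p), metric_accuracy(y, p))
  expect_equal(metric_auc(1 - y, s), 1 - metric_auc(y, s))
})

test_that("the AUC matches an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (rep in 1:20) {
    y <- rbinom(25, 1, 0.5); y[1:2] <- c(0, 1)
    s <- round(runif(25), 1)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(metric_auc(y, s), ref)
  }
})

test_that("degenerate inputs raise errors or flagged sentinels", {
  expect_error(metric_accuracy(numeric(), numeric()), "empty")
  expect_error(metric_accuracy(c(1, 0), 1), "length")
  expect_error(metric_auc(c(1, 1), c(0.1, 0.2)), "both classes")
  expect_warning(v <- metric_precision(c(1, 0), c(0, 0)), "no predicted")
  expect_true(is.nan(v))
  expect_warning(v2 <- metric_recall(c(0, 0), c(1, 0)), "no actual")
  expect_true(is.nan(v2))
  expect_error(metric_cross_entropy(c(1, 0), c(0.5, 1.2)), "probabilities")
  expect_error(metric_cross_entropy(c(2, 0), c(0.5, 0.5)), "binary")
})

test_that("factor labels use the QC-failed (last) level as positive", {
  y <- factor(c("good", "failed", "failed"), levels = c("good", "failed"))
  p <- factor(c("good", "failed", "good"), levels = c("good", "failed"))
  expect_equal(metric_recall(y, p), 0.5)
  expect_equal(metric_precision(y, p), 1)
})
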
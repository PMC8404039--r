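# Binary classification metrics.  Convention: the QC-failed class
# (misaligned / poor SNR) is the positive class.  Labels and predictions may
# be given as 0/1, logicals, or factors (whose last level is positive unless
# `positive` says otherwise).

as_binary <- function(x, positive = NULL) {
  if (is.factor(x) || is.character(x)) {
    x <- as.factor(x)
    pos <- if (is.null(positive)) levels(x)[nlevels(x)] else positive
    return(as.integer(x == pos))
  }
  x <- as.integer(as.logical(x) | x > 0)
  x
}

check_pair <- function(labels, predictions) {
  if (length(labels) == 0) stop("empty input")
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
}

#' Classification metrics
#'
#' The five evaluation metrics used to score a QC classifier: accuracy
#' `(TP + TN) / N`, precision `TP / (TP + FP)`, recall `TP / (TP + FN)`, the
#' area under the ROC curve, and the mean binary cross-entropy
#' `-(y log p + (1 - y) log(1 - p))`.  The QC-failed class is the positive
#' class.  `metric_auc` equals the Mann-Whitney probability that a random
#' positive outscores a random negative, ties counting 1/2.
#'
#' @param labels true classes (0/1, logical, or factor).
#' @param predictions predicted classes, same encoding.
#' @param scores numeric scores (e.g. predicted probability of the positive
#'   class) for `metric_auc`.
#' @param p predicted probabilities in (0, 1) for `metric_cross_entropy`;
#'   values are clamped to `[eps, 1 - eps]`.
#' @param positive for factor input, the positive-class level (defaults to
#'   the last level).
#' @param eps probability clamp.
#' @return A scalar.  `metric_precision` and `metric_recall` return `NaN`
#'   with a warning when undefined (no predicted / no actual positives).
#' @examples
#' metric_accuracy(c(1, 0, 1, 0), c(1, 0, 0, 0))  # 0.75
#' metric_cross_entropy(1, 0.5)                   # log(2)
#' @name metrics
NULL

#' @rdname metrics
#' @export
metric_accuracy <- function(labels, predictions, positive = NULL) {
  check_pair(labels, predictions)
  mean(as_binary(labels, positive) == as_binary(predictions, positive))
}

#' @rdname metrics
#' @export
metric_precision <- function(labels, predictions, positive = NULL) {
  check_pair(labels, predictions)
  y <- as_binary(labels, positive); p <- as_binary(predictions, positive)
  tp <- sum(y == 1 & p == 1)
  if (tp + sum(y == 0 & p == 1) == 0) {
    warning("precision undefined: no predicted positives")
    return(NaN)
  }
  tp / sum(p == 1)
}

#' @rdname metrics
#' @export
metric_recall <- function(labels, predictions, positive = NULL) {
  check_pair(labels, predictions)
  y <- as_binary(labels, positive); p <- as_binary(predictions, positive)
  if (sum(y == 1) == 0) {
    warning("recall undefined: no actual positives")
    return(NaN)
  }
  sum(y == 1 & p == 1) / sum(y == 1)
}

#' @rdname metrics
#' @export
metric_auc <- function(labels, scores, positive = NULL) {
  check_pair(labels, scores)
  y <- as_binary(labels, positive)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname metrics
#' @export
metric_cross_entropy <- function(labels, p, positive = NULL, eps = CE_EPS) {
  check_pair(labels, p)
  if (is.numeric(labels) && !all(labels %in% c(0, 1)))
    stop("labels must be binary")
  y <- as_binary(labels, positive)
  if (!all(is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# All five metrics for one validation set.
eval_metrics <- function(labels, predictions, scores) {
  y <- as_binary(labels)
  list(accuracy = metric_accuracy(y, predictions),
       precision = suppressWarnings(metric_precision(y, predictions)),
       recall = suppressWarnings(metric_recall(y, predictions)),
       auc = metric_auc(y, scores),
       loss = metric_cross_entropy(y, scores))
}
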
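# Labels, classification metrics and confidence intervals.

#' Derive the binary skill label from two rubric item scores
#'
#' Two structured-rubric items are scored on a 2-5 scale; a video is
#' labeled expert (1) if at least one item scores 5 and the other scores
#' at least 4, else novice (0).
#'
#' @param item1,item2 integer scores in 2..5 (vectorized).
#' @return integer vector of 0/1 labels.
#' @export
derive_skill_label <- function(item1, item2) {
  ok <- function(x) all(!is.na(x)) && all(x %in% 2:5)
  if (!ok(item1) || !ok(item2)) {
    stop("rubric item scores must be integers in 2..5")
  }
  as.integer(pmax(item1, item2) == 5 & pmin(item1, item2) >= 4)
}

# Wilson score 95% interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

# AUC as the probability that a random positive outranks a random
# negative (ties count 1/2); rank formulation
auc_estimate <- function(labels, probs) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics with 95% confidence intervals
#'
#' Sensitivity (`TP/(TP+FN)`) and specificity (`TN/(TN+FP)`) at
#' probability threshold 0.5 with Wilson score intervals, and AUC (the
#' probability that a random positive is ranked above a random negative,
#' ties counting one half) with a DeLong interval.  AUC is reported as
#' `NA` (undefined) when only one class is present.
#'
#' @param labels 0/1 truth vector.
#' @param probs predicted probabilities.
#' @param arm `"internal"` or `"external"` validation arm tag.
#' @param threshold hard-label threshold (default 0.5).
#' @return a `metrics_report` list: `sensitivity`, `specificity`, `auc`
#'   (each `c(estimate, lo, hi)`), `arm`, `n`.
#' @export
compute_metrics <- function(labels, probs, arm = "internal",
                            threshold = 0.5) {
  stopifnot(length(labels) == length(probs), all(labels %in% c(0, 1)))
  pred <- as.integer(probs > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  auc <- auc_estimate(labels, probs)
  auc_ci <- c(NA_real_, NA_real_)
  if (!is.na(auc) && stats::var(probs) > 0) {
    ci <- tryCatch(suppressWarnings(suppressMessages(
      pROC::ci.auc(pROC::roc(labels, probs, quiet = TRUE,
                             direction = "<", levels = c(0, 1)),
                   method = "delong"))),
      error = function(e) NULL)
    if (!is.null(ci)) auc_ci <- pmin(pmax(as.numeric(ci[c(1, 3)]), 0), 1)
  }
  structure(list(
    sensitivity = c(estimate = sens, wilson_ci(tp, tp + fn)),
    specificity = c(estimate = spec, wilson_ci(tn, tn + fp)),
    auc = c(estimate = auc, auc_ci),
    arm = arm,
    n = length(labels)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) {
    if (is.na(v[1])) return("undefined")
    sprintf("%.2f (%.2f to %.2f)", v[1], v[2], v[3])
  }
  cat("<metrics_report> arm: ", x$arm, ", n = ", x$n, "\n",
      "  sensitivity: ", fmt(x$sensitivity), "\n",
      "  specificity: ", fmt(x$specificity), "\n",
      "  AUC:         ", fmt(x$auc), "\n", sep = "")
  invisible(x)
}

#' Stratified fold assignment
#'
#' Partitions videos into `k` folds so that per-fold label counts differ
#' by at most one within each class.
#'
#' @param labels 0/1 vector (one per video).
#' @param k number of folds (default 5).
#' @return integer fold assignment in 1..k.
#' @export
stratified_folds <- function(labels, k = 5) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
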
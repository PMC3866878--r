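#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' The probability that a random class-1 sample scores above a random
#' class-0 sample, with tied scores counted one half — computed from average
#' ranks, which equals the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric classifier scores, higher = more class-1.
#' @param labels 0/1 outcome vector aligned with `scores`.
#' @return A one-row tibble with `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    stop("scores must be finite numeric values", call. = FALSE)
  }
  labels <- check_labels(labels, length(scores), require_both = FALSE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos < 1L) stop("cannot compute AUC: no class-1 (positive) samples", call. = FALSE)
  if (n_neg < 1L) stop("cannot compute AUC: no class-0 (negative) samples", call. = FALSE)
  r <- rank(scores)  # average ranks handle ties as 1/2
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  tibble::tibble(auc = auc, n_pos = n_pos, n_neg = n_neg)
}

#' Accuracy, sensitivity and specificity of hard class predictions
#'
#' Class 1 is the event class: sensitivity is the fraction of class-1
#' samples predicted 1, specificity the fraction of class-0 samples
#' predicted 0.
#'
#' @param predicted 0/1 predicted classes.
#' @param labels 0/1 true classes, same length.
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(predicted, labels) {
  predicted <- check_labels(predicted, require_both = FALSE)
  labels <- check_labels(labels, require_both = FALSE)
  if (length(predicted) != length(labels)) {
    stop("predicted and labels must have equal length", call. = FALSE)
  }
  tp <- sum(predicted == 1L & labels == 1L)
  tn <- sum(predicted == 0L & labels == 0L)
  tibble::tibble(
    accuracy = (tp + tn) / length(labels),
    sensitivity = tp / sum(labels == 1L),
    specificity = tn / sum(labels == 0L)
  )
}

#' Percentile confidence interval over repeated-CV statistics
#'
#' The empirical `(1-level)/2` and `1-(1-level)/2` quantiles (linear
#' interpolation between order statistics) of a set of per-iteration values,
#' e.g. the 100 AUCs of repeated cross-validation.
#'
#' @param values Numeric vector (length >= 2).
#' @param level Coverage level in (0, 1); default 0.95.
#' @return A one-row tibble with `lower`, `upper`, `level`.
#' @export
percentile_ci <- function(values, level = 0.95) {
  if (!is.numeric(values) || length(values) < 2L || any(!is.finite(values))) {
    stop("need at least 2 finite values for a percentile interval", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be a single number in (0, 1)", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  q <- unname(quantile(values, c(alpha, 1 - alpha), type = 7))
  tibble::tibble(lower = q[1], upper = q[2], level = level)
}
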
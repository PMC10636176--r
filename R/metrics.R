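#' Two-class confusion matrix
#'
#' Tallies true/false positives and negatives for a declared positive class.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param positive The label counted as positive.
#' @return An object of class `"confusion_matrix"`: a list with integer
#'   counts `TP`, `TN`, `FP`, `FN` and the `positive` label.
#' @export
#' @examples
#' cm <- confusion_matrix(c("+", "+", "-", "-"), c("+", "-", "+", "-"), "+")
#' derive_metrics(cm)
confusion_matrix <- function(y_true, y_pred, positive) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (!positive %in% c(y_true, y_pred)) {
    stop(sprintf("positive label '%s' not present in the labels", positive),
         call. = FALSE)
  }
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn, positive = positive),
            class = "confusion_matrix")
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/total`, and F1 = 2 P R / (P + R), all
#' expressed as percentages. A zero denominator yields 0 for that metric
#' with a warning (such cases are never scored in the benchmarks).
#'
#' @param cm A [confusion_matrix()].
#' @return A one-row tibble: `sensitivity`, `specificity`, `precision`,
#'   `accuracy`, `f1` (percent).
#' @export
derive_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("zero denominator for %s; returning 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  sens <- safe_div(cm$TP, cm$TP + cm$FN, "sensitivity")
  spec <- safe_div(cm$TN, cm$TN + cm$FP, "specificity")
  prec <- safe_div(cm$TP, cm$TP + cm$FP, "precision")
  acc <- safe_div(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN, "accuracy")
  f1 <- f1_score(100 * prec, 100 * sens)
  tibble::tibble(sensitivity = 100 * sens, specificity = 100 * spec,
                 precision = 100 * prec, accuracy = 100 * acc, f1 = f1)
}

#' F1 score from precision and sensitivity
#'
#' Harmonic mean of precision and sensitivity (both as percentages), e.g.
#' for checking published F1 cells against their printed precision and
#' sensitivity columns.
#'
#' @param precision,sensitivity Percent values.
#' @return F1 as a percent.
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(precision + sensitivity == 0, 0,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' Macro average across datasets
#'
#' The unweighted arithmetic mean of a per-dataset metric — the headline
#' cross-dataset aggregate.
#'
#' @param values Non-empty numeric vector.
#' @return The mean.
#' @export
macro_average <- function(values) {
  if (length(values) == 0L) stop("empty metric list", call. = FALSE)
  mean(values)
}

#' Macro-average summary of a benchmark metrics table
#'
#' @param metrics A tibble like [leaf_benchmark_metrics()] with columns
#'   `model` and `accuracy` (plus any other metric columns).
#' @param metric Column to aggregate (default `"accuracy"`).
#' @return A tibble with one row per model: `model`, `macro_<metric>`.
#' @export
macro_summary <- function(metrics, metric = "accuracy") {
  stopifnot(metric %in% names(metrics))
  metrics |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise("macro_{metric}" := macro_average(.data[[metric]]),
                     .groups = "drop")
}
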
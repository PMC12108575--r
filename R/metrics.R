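## Independently implemented binary-classification metric suite:
## confusion counts, the five derived metrics (accuracy, sensitivity,
## specificity, F1, AUC), and fold-level aggregation with t-interval
## confidence bounds.

#' Confusion counts for a binary split
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels (same length, same label alphabet).
#' @param positive_class The label counted as positive.
#' @return A `confusion_counts` list with integer fields `tp`, `fp`,
#'   `tn`, `fn` (summing to `length(y_true)`).
#' @export
confusion_counts <- function(y_true, y_pred, positive_class) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    abort(sprintf("Length mismatch: %d true vs %d predicted labels.",
                  length(y_true), length(y_pred)))
  }
  known <- unique(y_true)
  if (!positive_class %in% known) {
    abort(sprintf("positive_class '%s' does not occur in y_true.", positive_class))
  }
  bad <- setdiff(unique(y_pred), known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown predicted label(s): %s", paste(bad, collapse = ", ")))
  }
  pos <- y_true == positive_class
  pred_pos <- y_pred == positive_class
  structure(list(
    tp = sum(pos & pred_pos), fp = sum(!pos & pred_pos),
    tn = sum(!pos & !pred_pos), fn = sum(pos & !pred_pos)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Classification metric set from confusion counts
#'
#' Computes accuracy = (TP+TN)/total, sensitivity (recall, true
#' positive rate) = TP/(TP+FN), specificity = TN/(TN+FP), precision =
#' TP/(TP+FP), F1 = 2*precision*recall/(precision+recall), and — when
#' continuous scores are supplied — AUC via [auc_score()]. Empty
#' denominators yield 0 by convention and are flagged in the
#' `degenerate` column.
#'
#' @param counts A [confusion_counts()] object.
#' @param scores Optional per-sample continuous scores (for AUC).
#' @param y_true Labels aligned with `scores` (required with them).
#' @param positive_class Positive label for the AUC (required with
#'   `scores`).
#' @return A one-row tibble: `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `auc` (NA without scores) and
#'   `degenerate` (comma-separated list of zero-denominator metrics,
#'   empty string when none).
#' @export
metric_set <- function(counts, scores = NULL, y_true = NULL, positive_class = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  degenerate <- character(0)
  flag <- function(metric, den) {
    if (den == 0) degenerate <<- c(degenerate, metric)
    invisible(NULL)
  }
  flag("sensitivity", counts$tp + counts$fn)
  flag("specificity", counts$tn + counts$fp)
  flag("precision", counts$tp + counts$fp)
  sens <- safe_ratio(counts$tp, counts$tp + counts$fn)
  spec <- safe_ratio(counts$tn, counts$tn + counts$fp)
  prec <- safe_ratio(counts$tp, counts$tp + counts$fp)
  f1 <- if (prec + sens == 0) {
    flag("f1", 0)
    0
  } else 2 * prec * sens / (prec + sens)
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.null(y_true) || is.null(positive_class)) {
      abort("`y_true` and `positive_class` are required with `scores`.")
    }
    auc <- auc_score(scores, y_true, positive_class)
  }
  tibble::tibble(
    accuracy = safe_ratio(counts$tp + counts$tn, total),
    sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
    auc = auc, degenerate = paste(degenerate, collapse = ",")
  )
}

#' Area under the ROC curve
#'
#' Computed through the Mann–Whitney rank identity: the AUC equals
#' the probability that a randomly chosen positive sample outscores a
#' randomly chosen negative one, with ties counted one half. This is
#' exactly the area obtained by trapezoidal integration of the ROC
#' curve over all score thresholds.
#'
#' @param scores Per-sample continuous scores (higher = more
#'   positive).
#' @param y_true Labels aligned with `scores`; both classes must be
#'   present.
#' @param positive_class The positive label (defaults through the
#'   [sample_labels()] conventions).
#' @return The AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_score(c(0.9, 0.8, 0.2, 0.1), c("case", "case", "control", "control"), "case")
auc_score <- function(scores, y_true, positive_class = NULL) {
  by <- binary_y(y_true, positive = positive_class)
  if (length(scores) != length(by$y01)) abort("scores/labels length mismatch.")
  n1 <- sum(by$y01 == 1)
  n0 <- sum(by$y01 == 0)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present to compute an AUC.")
  r <- rank(scores)  # midranks handle ties at one-half weight
  (sum(r[by$y01 == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Aggregate per-fold metrics into mean, sd, and 95% CI
#'
#' For each metric column: mean, sample standard deviation (n-1
#' denominator; 0 for a single fold), and a Student-t 95% confidence
#' interval `mean +/- t(0.975, n-1) * sd / sqrt(n)` truncated to
#' `[0, 1]`. With a single fold the interval degenerates to the point
#' value and is flagged.
#'
#' @param evals Data frame of per-fold evaluations; every numeric
#'   column except `fold` is treated as a metric.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble: `metric`, `mean`, `sd`, `ci_lo`, `ci_hi`, `n`,
#'   `degenerate_ci`.
#' @export
aggregate_metrics <- function(evals, conf_level = 0.95) {
  evals <- as.data.frame(evals)
  if (nrow(evals) < 1) abort("At least one evaluation is required.")
  is_metric <- vapply(evals, is.numeric, logical(1)) &
    !(names(evals) %in% c("fold", "outer_fold", "inner_fold", "n_validation"))
  cols <- names(evals)[is_metric]
  purrr::map_dfr(cols, function(col) {
    v <- evals[[col]]
    v <- v[!is.na(v)]
    n <- length(v)
    m <- mean(v)
    s <- if (n > 1) sd(v) else 0
    half <- if (n > 1) qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n) else 0
    tibble::tibble(
      metric = col, mean = m, sd = s,
      ci_lo = max(0, m - half), ci_hi = min(1, m + half),
      n = n, degenerate_ci = n < 2
    )
  })
}
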
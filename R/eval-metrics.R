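#' Mann-Whitney estimate of the area under the ROC curve
#'
#' AUC is estimated as the probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties given half credit:
#' `P(s_pos > s_neg) + 0.5 * P(s_pos == s_neg)`. Computed via mid-ranks, it
#' equals the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric prediction scores.
#' @param truth Binary truth vector (0/1).
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when truth has a
#'   single class.
#' @examples
#' auc_mann_whitney(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
#' @export
auc_mann_whitney <- function(scores, truth) {
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]; truth <- truth[keep]
  if (!all(truth %in% c(0, 1))) abort("truth must be binary 0/1")
  npos <- sum(truth == 1)
  nneg <- sum(truth == 0)
  if (npos == 0L || nneg == 0L) {
    warn("AUC undefined: truth has a single class")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Confusion-table metrics at a fixed threshold
#'
#' Predictions are positive iff `score >= threshold`. Sensitivity is `NA`
#' without positives in truth; specificity is `NA` without negatives.
#'
#' @param scores Numeric scores.
#' @param truth Binary truth (0/1).
#' @param threshold Decision threshold.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`, `f1`.
#' @export
confusion_metrics <- function(scores, truth, threshold) {
  if (!is.finite(threshold)) abort("threshold must be finite")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  tn <- sum(pred == 0 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tibble(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  )
}

#' F1-maximizing decision threshold
#'
#' Scans every distinct score value as a candidate threshold (decision rule
#' `score >= t`) and returns the one with the largest F1; ties on F1 break
#' toward the smallest threshold.
#'
#' @param scores Numeric scores.
#' @param truth Binary truth with at least one positive.
#' @return List with `threshold` and `f1`.
#' @examples
#' f1_max_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
f1_max_threshold <- function(scores, truth) {
  if (!all(truth %in% c(0, 1))) abort("truth must be binary 0/1")
  if (sum(truth == 1) == 0L) abort("cannot choose an F1 threshold without positives")
  cand <- sort(unique(scores))
  f1s <- vapply(cand, function(t) {
    pred <- scores >= t
    tp <- sum(pred & truth == 1)
    fp <- sum(pred & truth == 0)
    fn <- sum(!pred & truth == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  best <- which.max(f1s) # which.max takes the first (smallest threshold) on ties
  list(threshold = cand[best], f1 = f1s[best])
}

#' Single-operating-point AUC for a binary rater
#'
#' A rater that only issues binary reads traces a one-point ROC curve; the
#' trapezoidal area under it is `(sensitivity + specificity) / 2`.
#'
#' @param reads Binary reads (0/1).
#' @param truth Binary truth (0/1).
#' @return AUC value, `NA` when truth has a single class.
#' @export
radiologist_auc <- function(reads, truth) {
  if (!all(reads %in% c(0, 1))) abort("reads must be binary 0/1")
  if (length(unique(truth)) < 2L) {
    warn("AUC undefined: truth has a single class")
    return(NA_real_)
  }
  sens <- sum(reads == 1 & truth == 1) / sum(truth == 1)
  spec <- sum(reads == 0 & truth == 0) / sum(truth == 0)
  (sens + spec) / 2
}

#' Mean and SD of per-label metrics
#'
#' Summarizes a per-label metric table as arithmetic mean and sample SD per
#' metric, excluding (and counting) undefined labels.
#'
#' @param metrics Per-label metric tibble, e.g. from [evaluate_labels()];
#'   must have a `label` column, all other numeric columns are summarized.
#' @return Tibble: `metric`, `mean`, `sd`, `n_labels`, `n_na`.
#' @export
summarize_labels <- function(metrics) {
  num <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  purrr::map_dfr(num, function(m) {
    v <- metrics[[m]]
    ok <- !is.na(v)
    tibble(
      metric = m,
      mean = if (any(ok)) mean(v[ok]) else NA_real_,
      sd = if (sum(ok) > 1L) sd(v[ok]) else if (sum(ok) == 1L) 0 else NA_real_,
      n_labels = sum(ok),
      n_na = sum(!ok)
    )
  })
}
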
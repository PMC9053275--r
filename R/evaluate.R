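#' Per-label diagnostic evaluation of a score matrix
#'
#' For every label: Mann-Whitney AUC; the F1-maximizing decision threshold
#' on the supplied scores; accuracy, sensitivity, specificity and F1 at
#' that threshold; and subsample/bootstrap confidence intervals for all
#' five metrics (default 100 iterations of 95% subsamples, shared across
#' metrics within a label). Labels with a single truth class get `NA`
#' metrics.
#'
#' @param scores Score matrix (`subject_id` + per-label probability
#'   columns).
#' @param truth Label matrix with the same subjects and labels.
#' @param iterations,subsample,replace,seed Resampling controls passed to
#'   the CI machinery; see [bootstrap_ci()].
#' @return Tibble of class `metric_result`, one row per label: `label`,
#'   `n_pos`, `threshold`, then `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `f1` each with `_low`/`_high` CI columns.
#' @export
evaluate_labels <- function(scores, truth, iterations = 100, subsample = 0.95,
                            replace = FALSE, seed = 1) {
  scores <- as_tibble(scores)
  truth <- as_tibble(truth)
  if (!identical(as.character(scores$subject_id), as.character(truth$subject_id))) {
    abort("scores and truth must cover the same subjects in the same order")
  }
  labs <- setdiff(names(scores), "subject_id")
  if (!setequal(labs, setdiff(names(truth), "subject_id"))) {
    abort("scores and truth must share the same label set")
  }
  metrics <- c("auc", "accuracy", "sensitivity", "specificity", "f1")
  out <- purrr::map_dfr(seq_along(labs), function(li) {
    lab <- labs[li]
    s <- scores[[lab]]
    y <- truth[[lab]]
    row <- tibble(label = lab, n_pos = sum(y == 1), threshold = NA_real_)
    for (m in metrics) {
      row[[m]] <- NA_real_
      row[[paste0(m, "_low")]] <- NA_real_
      row[[paste0(m, "_high")]] <- NA_real_
    }
    if (length(unique(y)) < 2L) return(row)
    thr <- f1_max_threshold(s, y)
    point <- c(
      auc = suppressWarnings(auc_mann_whitney(s, y)),
      unlist(confusion_metrics(s, y, thr$threshold))
    )
    row$threshold <- thr$threshold
    reps <- matrix(NA_real_, iterations, length(metrics),
                   dimnames = list(NULL, metrics))
    n <- length(s)
    msub <- max(1L, round(subsample * n))
    with_seed_local(seed + li, {
      for (i in seq_len(iterations)) {
        idx <- sample.int(n, msub, replace = replace)
        yi <- y[idx]; si <- s[idx]
        if (length(unique(yi)) < 2L) next
        cm <- confusion_metrics(si, yi, thr$threshold)
        reps[i, ] <- c(suppressWarnings(auc_mann_whitney(si, yi)), unlist(cm))
      }
    })
    for (m in metrics) {
      row[[m]] <- unname(point[[m]])
      v <- reps[, m]
      if (sum(!is.na(v)) >= iterations / 2) {
        qs <- quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
        row[[paste0(m, "_low")]] <- qs[1]
        row[[paste0(m, "_high")]] <- qs[2]
      }
    }
    row
  })
  class(out) <- c("metric_result", class(out))
  out
}

#' @export
glance.metric_result <- function(x, ...) {
  s <- summarize_labels(select(
    x, all_of(c("auc", "accuracy", "sensitivity", "specificity", "f1"))
  ) %>% mutate(label = x$label))
  tidyr::pivot_wider(
    s, names_from = "metric",
    values_from = c("mean", "sd"), names_glue = "{metric}_{.value}"
  )
}

#' Compare per-label AUCs of two prediction sources
#'
#' Runs DeLong's test label by label between two score matrices on a shared
#' truth. The second source may be binary reads (e.g. a radiologist): a
#' binary read vector is a valid score vector for the Mann-Whitney
#' statistic, and its AUC equals the single-operating-point value
#' `(sensitivity + specificity) / 2`. Per-label p-values are reported
#' without multiplicity correction by default, with `p_adjust` available.
#'
#' @param scores_a Score matrix of source A.
#' @param scores_b Score (or binary read) matrix of source B.
#' @param truth Label matrix on the same subjects.
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return Tibble: `label`, `auc_a`, `auc_b`, `delta`, `statistic`,
#'   `p.value` (and `p.adjusted` when requested); `NA` rows for
#'   single-class labels.
#' @export
compare_auc <- function(scores_a, scores_b, truth, p_adjust = "none") {
  scores_a <- as_tibble(scores_a); scores_b <- as_tibble(scores_b)
  truth <- as_tibble(truth)
  if (!identical(as.character(scores_a$subject_id), as.character(truth$subject_id)) ||
      !identical(as.character(scores_b$subject_id), as.character(truth$subject_id))) {
    abort("all matrices must cover the same subjects in the same order")
  }
  labs <- setdiff(names(truth), "subject_id")
  out <- purrr::map_dfr(labs, function(lab) {
    y <- truth[[lab]]
    if (length(unique(y)) < 2L) {
      return(tibble(
        label = lab, auc_a = NA_real_, auc_b = NA_real_, delta = NA_real_,
        statistic = NA_real_, p.value = NA_real_
      ))
    }
    d <- delong_test(scores_a[[lab]], scores_b[[lab]], y)
    tibble(
      label = lab, auc_a = d$auc_a, auc_b = d$auc_b, delta = d$delta,
      statistic = d$z, p.value = d$p_value
    )
  })
  if (!identical(p_adjust, "none")) {
    out$p.adjusted <- stats::p.adjust(out$p.value, method = p_adjust)
  }
  out
}

#' Points of the empirical ROC curve
#'
#' @param scores Numeric scores.
#' @param truth Binary truth (0/1).
#' @return Tibble with `fpr`, `tpr` sorted for plotting/trapezoidal
#'   integration, including the (0,0) and (1,1) endpoints.
#' @export
roc_curve_points <- function(scores, truth) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  npos <- sum(truth == 1); nneg <- sum(truth == 0)
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble(
      fpr = if (nneg > 0) sum(pred & truth == 0) / nneg else NA_real_,
      tpr = if (npos > 0) sum(pred & truth == 1) / npos else NA_real_
    )
  })
  bind_rows(pts, tibble(fpr = 1, tpr = 1)) %>% distinct()
}
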
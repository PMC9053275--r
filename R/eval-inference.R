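#' Subsample/bootstrap confidence interval for a metric
#'
#' Resamples subjects `iterations` times and takes the 2.5th/97.5th
#' percentiles of the replicate metric values. The default draws a fraction
#' `subsample` of the subjects *without* replacement per replicate
#' (95% subsampling, 100 iterations); `replace = TRUE` switches to a
#' conventional bootstrap that resamples with replacement at the same
#' replicate size. Replicates where the metric is undefined (`NA`) are
#' skipped with a warning; if more than half are undefined the CI is `NA`.
#'
#' @param metric_fn Function of `(scores, truth)` (or of one data vector if
#'   `truth` is `NULL`) returning a scalar.
#' @param scores,truth Subject-level data passed to `metric_fn`.
#' @param iterations Number of replicates (default 100).
#' @param subsample Fraction of subjects per replicate (default 0.95).
#' @param replace Resample with replacement? Default `FALSE` (plain
#'   subsampling).
#' @param seed Integer seed; the CI is deterministic given it.
#' @param level Confidence level (default 0.95).
#' @return List with `low`, `high`, and `replicates` (the replicate values).
#' @export
bootstrap_ci <- function(metric_fn, scores, truth = NULL, iterations = 100,
                         subsample = 0.95, replace = FALSE, seed = 1,
                         level = 0.95) {
  n <- length(scores)
  m <- max(1L, round(subsample * n))
  reps <- with_seed_local(seed, {
    vapply(seq_len(iterations), function(i) {
      idx <- sample.int(n, m, replace = replace)
      val <- if (is.null(truth)) {
        suppressWarnings(metric_fn(scores[idx]))
      } else {
        suppressWarnings(metric_fn(scores[idx], truth[idx]))
      }
      if (length(val) != 1L) NA_real_ else as.numeric(val)
    }, numeric(1))
  })
  n_bad <- sum(is.na(reps))
  if (n_bad > 0L) {
    warn(paste0(n_bad, " of ", iterations, " replicates were undefined and skipped"))
  }
  if (n_bad > iterations / 2) {
    return(list(low = NA_real_, high = NA_real_, replicates = reps))
  }
  alpha <- (1 - level) / 2
  qs <- quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(low = qs[1], high = qs[2], replicates = reps)
}

# per-subject structural components of the Mann-Whitney AUC:
# V10 over positives, V01 over negatives
delong_components <- function(scores, truth) {
  xs <- scores[truth == 1]
  ys <- scores[truth == 0]
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same subjects
#' and truth, using the per-subject structural components of the
#' Mann-Whitney statistic to estimate the variance of the AUC difference,
#' with a two-sided normal reference for `z = delta / sqrt(var)`.
#'
#' @param scores_a,scores_b Numeric score vectors on the same subjects.
#' @param truth Binary truth (0/1) with both classes present.
#' @return Object of class `delong_result`: `auc_a`, `auc_b`, `delta`,
#'   `var_delta`, `z`, `p_value`, `degenerate` flag.
#' @examples
#' set.seed(1)
#' y <- rbinom(100, 1, 0.4)
#' a <- y + rnorm(100); b <- rnorm(100)
#' delong_test(a, b, y)
#' @export
delong_test <- function(scores_a, scores_b, truth) {
  if (length(scores_a) != length(truth) || length(scores_b) != length(truth)) {
    abort("score vectors and truth must be the same length (same subjects)")
  }
  if (!all(truth %in% c(0, 1)) || length(unique(truth)) < 2L) {
    abort("truth must be binary with both classes present")
  }
  ca <- delong_components(scores_a, truth)
  cb <- delong_components(scores_b, truth)
  m <- sum(truth == 1)
  n <- sum(truth == 0)
  # a class with a single member contributes no estimable variance
  s10 <- if (m >= 2) stats::cov(cbind(ca$v10, cb$v10)) else matrix(0, 2, 2)
  s01 <- if (n >= 2) stats::cov(cbind(ca$v01, cb$v01)) else matrix(0, 2, 2)
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- ca$auc - cb$auc
  degenerate <- FALSE
  if (var_delta <= 0) {
    if (abs(delta) < .Machine$double.eps^0.5) {
      z <- 0; p <- 1
    } else {
      z <- sign(delta) * Inf; p <- 0; degenerate <- TRUE
      warn("zero variance with nonzero AUC difference; p degenerate")
    }
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    list(
      auc_a = ca$auc, auc_b = cb$auc, delta = delta,
      var_delta = var_delta, z = z, p_value = p, degenerate = degenerate,
      n_pos = m, n_neg = n
    ),
    class = "delong_result"
  )
}

#' @export
print.delong_result <- function(x, ...) {
  cat("DeLong's test for two correlated AUCs\n")
  cat(sprintf("  AUC A: %.4f   AUC B: %.4f   delta: %+.4f\n", x$auc_a, x$auc_b, x$delta))
  cat(sprintf("  z = %.3f, two-sided p = %.4g\n", x$z, x$p_value))
  invisible(x)
}

#' @export
tidy.delong_result <- function(x, ...) {
  tibble(
    auc_a = x$auc_a, auc_b = x$auc_b, delta = x$delta,
    var_delta = x$var_delta, statistic = x$z, p.value = x$p_value
  )
}

#' @export
glance.delong_result <- function(x, ...) {
  tibble(statistic = x$z, p.value = x$p_value, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Per-subject concordance between two label matrices
#'
#' Counts, for every subject, on how many of the labels the two sources
#' agree (a Hamming-style agreement count), the histogram over those
#' counts, and the fraction of subjects agreeing on at least
#' `min_concordant` labels. Labels absent in both sources count as
#' agreement on a negative finding.
#'
#' @param labels_a,labels_b Label matrices over the same subjects and
#'   labels (e.g. classifier reads vs consensus reference).
#' @param min_concordant Agreement-count threshold for the summary fraction
#'   (default 22 of 25).
#' @return Object of class `concordance_result`: `per_subject` (tibble
#'   `subject_id`, `n_agree`), `histogram` (tibble `n_agree`, `n`),
#'   `fraction_at_least`, `min_concordant`, `n_labels`.
#' @export
concordance <- function(labels_a, labels_b, min_concordant = 22) {
  a <- as_tibble(labels_a)
  b <- as_tibble(labels_b)
  if (!identical(as.character(a$subject_id), as.character(b$subject_id))) {
    abort("label matrices must cover the same subjects in the same order")
  }
  cols <- setdiff(names(a), "subject_id")
  if (!setequal(cols, setdiff(names(b), "subject_id"))) {
    abort("label matrices must share the same label set")
  }
  va <- as.matrix(a[cols])
  vb <- as.matrix(b[cols])
  agree <- rowSums(va == vb)
  lvls <- 0:length(cols)
  structure(
    list(
      per_subject = tibble(subject_id = as.character(a$subject_id), n_agree = as.integer(agree)),
      histogram = tibble(
        n_agree = lvls,
        n = as.integer(table(factor(agree, levels = lvls)))
      ),
      fraction_at_least = mean(agree >= min_concordant),
      min_concordant = min_concordant,
      n_labels = length(cols)
    ),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result>\n")
  cat(sprintf("  %d subjects, %d labels\n", nrow(x$per_subject), x$n_labels))
  cat(sprintf(
    "  fraction with >= %d concordant labels: %.3f\n",
    x$min_concordant, x$fraction_at_least
  ))
  invisible(x)
}

#' @export
tidy.concordance_result <- function(x, ...) x$histogram

#' @export
glance.concordance_result <- function(x, ...) {
  tibble(
    n_subjects = nrow(x$per_subject),
    n_labels = x$n_labels,
    min_concordant = x$min_concordant,
    fraction_at_least = x$fraction_at_least,
    mean_agree = mean(x$per_subject$n_agree)
  )
}
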
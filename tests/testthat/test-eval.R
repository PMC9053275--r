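test_that("Mann-Whitney AUC matches worked examples and edge cases", {
  expect_equal(auc_mann_whitney(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_mann_whitney(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc_mann_whitney(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_warning(out <- auc_mann_whitney(runif(5), rep(1, 5)), "single class")
  expect_true(is.na(out))
})

test_that("rank AUC agrees with pair counting and trapezoidal ROC area", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    truth <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    a <- auc_mann_whitney(scores, truth)
    expect_equal(a, auc_pair_count(scores, truth), tolerance = 1e-12)
    expect_equal(a, auc_trapezoid(scores, truth), tolerance = 1e-12)
  }
})

test_that("F1-max threshold matches the exhaustive scan oracle", {
  got <- f1_max_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(got$threshold, 0.35)
  expect_equal(got$f1, 0.8)

  expect_equal(f1_max_threshold(c(0.1, 0.2, 0.9, 0.95), c(0, 0, 1, 1))$f1, 1)

  # all scores equal, prevalence pi: everyone predicted positive
  y <- c(rep(1, 3), rep(0, 7))
  got2 <- f1_max_threshold(rep(0.4, 10), y)
  pi <- 0.3
  expect_equal(got2$f1, 2 * pi / (pi + 1))

  expect_error(f1_max_threshold(runif(4), rep(0, 4)), "positives")

  # never below any scanned threshold; ties break to the smallest threshold
  set.seed(7)
  for (i in 1:50) {
    n <- sample(8:25, 1)
    y <- c(1, rbinom(n - 1, 1, 0.4))
    s <- round(runif(n), 2)
    got <- f1_max_threshold(s, y)
    f1_at <- function(t) {
      pred <- s >= t
      tp <- sum(pred & y == 1); fp <- sum(pred & y == 0); fn <- sum(!pred & y == 1)
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }
    all_f1 <- vapply(sort(unique(s)), f1_at, numeric(1))
    expect_gte(got$f1 + 1e-12, max(all_f1))
    expect_equal(got$threshold, min(sort(unique(s))[all_f1 == max(all_f1)]))
  }
})

test_that("confusion metrics follow the 2x2 table definitions", {
  # TP=2, FP=1, TN=1, FN=0 at threshold 0.35
  cm <- confusion_metrics(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), 0.35)
  expect_equal(cm$accuracy, 0.75)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 0.5)
  expect_equal(cm$f1, 0.8)

  perfect <- confusion_metrics(c(0.1, 0.9), c(0, 1), 0.5)
  expect_true(all(unlist(perfect) == 1))

  allneg <- confusion_metrics(c(0.1, 0.2, 0.3), c(0, 1, 1), 0.9)
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)
  expect_error(confusion_metrics(0.5, 1, Inf), "finite")
})

test_that("subsample CIs are deterministic, degenerate on constants, NA-safe", {
  set.seed(2)
  y <- rbinom(200, 1, 0.4)
  s <- plogis(rnorm(200) + y)
  ci1 <- bootstrap_ci(auc_mann_whitney, s, y, seed = 5)
  ci2 <- bootstrap_ci(auc_mann_whitney, s, y, seed = 5)
  expect_identical(ci1[c("low", "high")], ci2[c("low", "high")])
  expect_lte(ci1$low, auc_mann_whitney(s, y))
  expect_gte(ci1$high, auc_mann_whitney(s, y))

  const <- bootstrap_ci(function(x) mean(x), rep(0.7, 100), seed = 1)
  expect_equal(const$low, 0.7)
  expect_equal(const$high, 0.7)

  # all-positive truth: every replicate undefined -> NA CI with warning
  expect_warning(
    bad <- bootstrap_ci(auc_mann_whitney, runif(30), rep(1, 30), seed = 1),
    "undefined"
  )
  expect_true(is.na(bad$low))
})

test_that("DeLong test is exact on self-comparison and antisymmetric", {
  set.seed(9)
  y <- rbinom(150, 1, 0.4)
  a <- rnorm(150) + 0.8 * y
  b <- rnorm(150) + 0.4 * y
  self <- delong_test(a, a, y)
  expect_equal(self$delta, 0)
  expect_equal(self$p_value, 1)

  ab <- delong_test(a, b, y)
  ba <- delong_test(b, a, y)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$auc_a, auc_mann_whitney(a, y))

  td <- tidy(ab)
  expect_equal(td$p.value, ab$p_value)
  expect_error(delong_test(a, b, rep(1, 150)), "both classes")
})

test_that("DeLong agrees with pROC and with a paired permutation oracle", {
  set.seed(31)
  y <- rbinom(200, 1, 0.4)
  a <- rnorm(200) + 0.9 * y
  b <- rnorm(200) + 0.5 * y
  ours <- delong_test(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(ours$p_value, as.numeric(ref$p.value), tolerance = 1e-10)

  # paired sign-flip permutation of the source assignment
  obs <- abs(ours$delta)
  set.seed(77)
  perm <- vapply(1:10000, function(i) {
    flip <- runif(200) < 0.5
    pa <- ifelse(flip, b, a)
    pb <- ifelse(flip, a, b)
    abs(auc_mann_whitney(pa, y) - auc_mann_whitney(pb, y))
  }, numeric(1))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(ours$p_value - p_perm), 0.02)
})

test_that("binary-rater AUC equals (sensitivity + specificity) / 2", {
  y <- c(0, 0, 0, 1, 1)
  expect_equal(radiologist_auc(y, y), 1)
  expect_equal(radiologist_auc(1 - y, y), 0)
  # sens 0.8, spec 0.9 case
  truth <- c(rep(1, 10), rep(0, 10))
  reads <- c(rep(1, 8), 0, 0, rep(0, 9), 1)
  expect_equal(radiologist_auc(reads, truth), 0.85)
  # equals the Mann-Whitney AUC of the binary reads
  expect_equal(radiologist_auc(reads, truth), auc_mann_whitney(reads, truth))
  expect_warning(out <- radiologist_auc(c(1, 0), c(1, 1)), "single class")
  expect_true(is.na(out))
})

test_that("concordance counts agree with a per-row Hamming oracle", {
  a <- random_label_matrix(100, p = 0.2, seed = 31)
  b <- random_label_matrix(100, p = 0.2, seed = 32)
  b$subject_id <- a$subject_id
  res <- concordance(a, b)
  ham <- 25 - rowSums(abs(as.matrix(a[, -1]) - as.matrix(b[, -1])))
  expect_equal(res$per_subject$n_agree, as.integer(ham))
  for (k in 0:25) {
    expect_equal(res$histogram$n[res$histogram$n_agree == k], sum(ham == k))
  }
  expect_equal(res$fraction_at_least, mean(ham >= 22))
  expect_equal(sum(res$histogram$n), 100L)

  same <- concordance(a, a)
  expect_true(all(same$per_subject$n_agree == 25L))
  expect_equal(same$fraction_at_least, 1)

  flipped <- a
  flipped$nodule[1] <- 1L - flipped$nodule[1]
  one <- concordance(a, flipped)
  expect_equal(one$per_subject$n_agree[1], 24L)
  expect_true(all(one$per_subject$n_agree[-1] == 25L))

  expect_error(concordance(a, b[1:50, ]), "same subjects")
})

test_that("per-label summaries report mean, SD and NA bookkeeping", {
  m <- tibble::tibble(label = c("a", "b"), auc = c(0.8, 1.0))
  s <- summarize_labels(m)
  expect_equal(s$mean[s$metric == "auc"], 0.9)
  expect_equal(s$sd[s$metric == "auc"], sqrt(0.02))

  one <- summarize_labels(tibble::tibble(label = "a", auc = 0.7))
  expect_equal(one$sd, 0)
  expect_equal(one$n_labels, 1L)

  none <- summarize_labels(tibble::tibble(label = c("a", "b"), auc = c(NA_real_, NA_real_)))
  expect_true(is.na(none$mean))
  expect_equal(none$n_na, 2L)
})

test_that("evaluate_labels assembles per-label metrics with CIs", {
  gen <- generate_reports(pkg_graph, 150, grammar_config(prevalence = 0.3), seed = 12)
  scores <- generate_scores(gen$truth, auc = 0.9, seed = 13)
  res <- evaluate_labels(scores, gen$truth, iterations = 50, seed = 1)
  expect_s3_class(res, "metric_result")
  expect_equal(nrow(res), 25L)
  ok <- !is.na(res$auc)
  expect_true(all(res$auc_low[ok] <= res$auc[ok] + 1e-12))
  expect_true(all(res$auc_high[ok] >= res$auc[ok] - 1e-12))
  # point metrics recompute from the underlying primitives
  lab <- res$label[ok][1]
  thr <- f1_max_threshold(scores[[lab]], gen$truth[[lab]])
  expect_equal(res$threshold[res$label == lab], thr$threshold)
  expect_equal(res$f1[res$label == lab], thr$f1)
  expect_equal(res$auc[res$label == lab],
               auc_mann_whitney(scores[[lab]], gen$truth[[lab]]))
  g <- glance(res)
  expect_true(g$auc_mean > 0.8)
})

test_that("compare_auc runs label-wise DeLong tests with optional adjustment", {
  gen <- generate_reports(pkg_graph, 200, grammar_config(prevalence = 0.3), seed = 14)
  sa <- generate_scores(gen$truth, auc = 0.9, seed = 15)
  sb <- generate_scores(gen$truth, auc = 0.7, seed = 16)
  cmp <- compare_auc(sa, sb, gen$truth, p_adjust = "BH")
  expect_equal(nrow(cmp), 25L)
  ok <- !is.na(cmp$p.value)
  expect_true(mean(cmp$delta[ok] > 0) > 0.8)
  expect_true(all(cmp$p.adjusted[ok] >= cmp$p.value[ok] - 1e-12))
  lab <- cmp$label[ok][1]
  d <- delong_test(sa[[lab]], sb[[lab]], gen$truth[[lab]])
  expect_equal(cmp$p.value[cmp$label == lab], d$p_value)
})
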
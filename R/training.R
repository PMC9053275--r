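# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed_local <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Class-weighted binary cross-entropy
#'
#' `loss = -(w_pos * y * log(p) + w_neg * (1 - y) * log(1 - p))`, with `p`
#' clipped to `[eps, 1 - eps]`. With unit weights this is the standard
#' binary cross-entropy (the Bernoulli negative log-likelihood); unequal
#' weights place greater weight on the infrequent class.
#'
#' @param y Binary truth vector (0/1).
#' @param p Predicted probability vector.
#' @param w_pos,w_neg Positive/negative class weights (> 0).
#' @param eps Clipping constant (default 1e-12).
#' @return Numeric vector of per-observation losses.
#' @examples
#' weighted_bce(1, 0.5, w_pos = 2) # 2 * log(2)
#' @export
weighted_bce <- function(y, p, w_pos = 1, w_neg = 1, eps = 1e-12) {
  if (any(c(w_pos, w_neg) <= 0)) abort("class weights must be positive")
  if (!all(y %in% c(0, 1))) abort("y must be binary 0/1")
  p <- pmin(pmax(p, eps), 1 - eps)
  -(w_pos * y * log(p) + w_neg * (1 - y) * log(1 - p))
}

#' Balanced class weights for one label column
#'
#' `w_pos = N / (2 * N_pos)` and `w_neg = N / (2 * N_neg)`, so a balanced
#' column gets unit weights and the rarer class is up-weighted in
#' proportion to its scarcity.
#'
#' @param y Binary truth vector with at least one positive and one negative.
#' @return List with `w_pos` and `w_neg`.
#' @export
default_weights <- function(y) {
  if (!all(y %in% c(0, 1))) abort("y must be binary 0/1")
  n <- length(y)
  npos <- sum(y == 1)
  if (npos == 0L || npos == n) {
    abort("label column has a single class; drop this label before training")
  }
  list(w_pos = n / (2 * npos), w_neg = n / (2 * (n - npos)))
}

#' Multi-label stratified k-fold assignment
#'
#' Iterative stratification: labels are processed rarest-first and each
#' positive subject is placed in the fold with the greatest remaining demand
#' for that label (ties broken by overall remaining fold capacity, then by
#' a seeded draw), so every fold carries close to the same per-label
#' positive fraction. With `k = n` this reduces to leave-one-out.
#'
#' @param matrix A label matrix from [build_label_matrix()] (or any tibble
#'   `subject_id` + binary columns).
#' @param k Number of folds (default 5).
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return Tibble of class `fold_assignment`: `subject_id`, `fold` (1..k).
#' @export
stratified_kfold <- function(matrix, k = 5, seed = 1) {
  vals <- matrix_values(matrix)
  n <- nrow(vals)
  if (k < 2L) abort("k must be at least 2")
  if (n < k) abort("need at least k subjects")
  with_seed_local(seed, {
    capacity <- diff(round(seq(0, n, length.out = k + 1))) # fold sizes
    desired <- outer(colSums(vals), rep(1 / k, k))         # labels x folds
    fold <- rep(NA_integer_, n)
    npos_left <- function() {
      colSums(vals[is.na(fold), , drop = FALSE] * 1)
    }
    repeat {
      left <- npos_left()
      left[left == 0] <- NA
      if (all(is.na(left))) break
      lab <- which.min(left) # rarest label with remaining positives
      subj <- which(is.na(fold) & vals[, lab] == 1)
      if (length(subj) == 0L) break
      subj <- subj[sample.int(length(subj))]
      for (s in subj) {
        f <- pick_fold(desired[lab, ], capacity)
        fold[s] <- f
        pos_labels <- which(vals[s, ] == 1)
        desired[pos_labels, f] <- desired[pos_labels, f] - 1
        capacity[f] <- capacity[f] - 1L
      }
    }
    for (s in which(is.na(fold))) {
      f <- pick_fold(capacity, capacity)
      fold[s] <- f
      capacity[f] <- capacity[f] - 1L
    }
  })
  if (any(colSums(vals) > 0 & colSums(vals) < k)) {
    warn("some labels have fewer positives than folds; spread is best-effort")
  }
  out <- tibble(subject_id = as.character(matrix$subject_id), fold = fold)
  class(out) <- c("fold_assignment", class(out))
  out
}

# fold with max primary criterion, ties by max capacity, then seeded draw
pick_fold <- function(primary, capacity) {
  cand <- which(primary == max(primary))
  if (length(cand) > 1L) cand <- cand[capacity[cand] == max(capacity[cand])]
  if (length(cand) > 1L) cand <- cand[sample.int(length(cand), 1L)]
  cand
}

#' Construct a score matrix
#'
#' @param subject_ids Character vector.
#' @param values Numeric matrix (subjects x labels, in `[0, 1]`) with label
#'   column names.
#' @return Tibble of class `score_matrix`.
#' @export
score_matrix <- function(subject_ids, values) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) abort("score values need label column names")
  if (any(values < 0 | values > 1, na.rm = TRUE)) {
    abort("scores must lie in [0, 1]")
  }
  out <- bind_cols(tibble(subject_id = as.character(subject_ids)), as_tibble(values))
  class(out) <- c("score_matrix", class(out))
  out
}

#' Average several score matrices element-wise
#'
#' The final prediction of a k-fold model committee is the arithmetic mean
#' of the per-model predicted probabilities.
#'
#' @param scores List of score matrices sharing subjects and labels.
#' @return A single `score_matrix` of the element-wise means.
#' @export
ensemble_mean <- function(scores) {
  if (!is.list(scores) || length(scores) == 0L) abort("need a non-empty list of score matrices")
  ref <- scores[[1]]
  for (s in scores[-1]) {
    if (!identical(dim(s), dim(ref)) ||
        !identical(names(s), names(ref)) ||
        !identical(s$subject_id, ref$subject_id)) {
      abort("score matrices must share subjects and labels")
    }
  }
  vals <- Reduce(`+`, lapply(scores, matrix_values)) / length(scores)
  score_matrix(ref$subject_id, vals)
}

#' Reference classifiers satisfying the fit/predict contract
#'
#' A classifier is a list with elements `fit(x, y, weights)` returning a
#' model object and `predict_prob(model, x)` returning probabilities in
#' `[0, 1]`. `logistic_classifier()` wraps a weighted logistic regression
#' (falling back to the training prevalence when a fold is single-class);
#' `constant_classifier()` always predicts `p`.
#'
#' @param p Constant probability for `constant_classifier()`.
#' @return A classifier contract list.
#' @export
logistic_classifier <- function() {
  list(
    fit = function(x, y, weights = NULL) {
      if (length(unique(y)) < 2L) {
        return(list(const = mean(y)))
      }
      df <- as.data.frame(x)
      df$.y <- y
      fit <- suppressWarnings(
        glm(.y ~ ., data = df, family = binomial(), weights = weights)
      )
      list(fit = fit)
    },
    predict_prob = function(model, x) {
      if (!is.null(model$const)) return(rep(model$const, nrow(as.data.frame(x))))
      p <- suppressWarnings(predict(model$fit, newdata = as.data.frame(x), type = "response"))
      pmin(pmax(as.numeric(p), 0), 1)
    }
  )
}

#' @rdname logistic_classifier
#' @export
constant_classifier <- function(p = 0.5) {
  list(
    fit = function(x, y, weights = NULL) list(p = p),
    predict_prob = function(model, x) rep(model$p, nrow(as.data.frame(x)))
  )
}

#' Train one two-way model per label per fold
#'
#' For each of the labels a separate binary ("two-way") model is fit on
#' each cross-validation training split, with class weights from
#' [default_weights()] handed to the classifier. Out-of-fold predictions
#' are assembled into a score matrix; when `newdata` is supplied, the k
#' per-fold models also score it and their mean (the committee prediction)
#' is returned alongside.
#'
#' @param matrix Label matrix (truth) from [build_label_matrix()].
#' @param features Data frame: `subject_id` + numeric feature columns,
#'   covering every subject in `matrix`.
#' @param classifier A classifier contract, e.g. [logistic_classifier()].
#' @param folds A [stratified_kfold()] assignment for the same subjects.
#' @param newdata Optional feature data frame for held-out subjects.
#' @return List with `oof` (out-of-fold `score_matrix`) and, when `newdata`
#'   is given, `test` (mean-of-folds `score_matrix` for `newdata`).
#' @export
train_two_way_models <- function(matrix, features, classifier, folds, newdata = NULL) {
  if (!all(c("fit", "predict_prob") %in% names(classifier)) ||
      !is.function(classifier$fit) || !is.function(classifier$predict_prob)) {
    abort("classifier must provide fit() and predict_prob() functions")
  }
  features <- as_tibble(features)
  idx <- match(matrix$subject_id, features$subject_id)
  if (anyNA(idx)) abort("features missing for some subjects")
  x <- as.matrix(features[idx, setdiff(names(features), "subject_id")])
  vals <- matrix_values(matrix)
  fold <- folds$fold[match(matrix$subject_id, folds$subject_id)]
  if (anyNA(fold)) abort("fold assignment missing for some subjects")
  k <- max(fold)
  labs <- colnames(vals)
  oof <- matrix(NA_real_, nrow(vals), length(labs), dimnames = list(NULL, labs))
  xnew <- NULL
  if (!is.null(newdata)) {
    newdata <- as_tibble(newdata)
    xnew <- as.matrix(newdata[setdiff(names(newdata), "subject_id")])
  }
  test_acc <- if (!is.null(xnew)) {
    matrix(0, nrow(xnew), length(labs), dimnames = list(NULL, labs))
  }
  for (lab in labs) {
    y <- vals[, lab]
    for (f in seq_len(k)) {
      tr <- fold != f
      w <- if (length(unique(y[tr])) == 2L) {
        cfg <- default_weights(y[tr])
        ifelse(y[tr] == 1, cfg$w_pos, cfg$w_neg)
      }
      model <- classifier$fit(x[tr, , drop = FALSE], y[tr], w)
      oof[!tr, lab] <- classifier$predict_prob(model, x[!tr, , drop = FALSE])
      if (!is.null(xnew)) {
        test_acc[, lab] <- test_acc[, lab] + classifier$predict_prob(model, xnew) / k
      }
    }
  }
  out <- list(oof = score_matrix(matrix$subject_id, oof))
  if (!is.null(xnew)) {
    out$test <- score_matrix(as.character(newdata$subject_id), test_acc)
  }
  out
}
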
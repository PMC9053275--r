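#' Keep only the earliest examination per subject
#'
#' When a subject has multiple examinations, only the earliest report is
#' included; ties on the date keep the first-seen record (stable order).
#'
#' @param reports Data frame of reports with `subject_id` and `exam_date`
#'   (Date or ISO-8601 string).
#' @return Tibble with one row per subject.
#' @export
deduplicate_earliest <- function(reports) {
  reports <- as_tibble(reports)
  dates <- as.Date(as.character(reports$exam_date), format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))
    abort(paste0(
      "unparseable exam_date for subject(s): ",
      paste(reports$subject_id[bad], collapse = ", ")
    ))
  }
  reports %>%
    mutate(.date = dates, .ord = row_number()) %>%
    group_by(subject_id) %>%
    slice(which.min(.data$.date)) %>%  # which.min is stable on ties
    ungroup() %>%
    arrange(.data$.ord) %>%
    select(-".date", -".ord")
}

#' Partition reports into kept and excluded
#'
#' Applies the cohort exclusion criteria carried as quality flags on each
#' report (mobile radiograph, insufficient image quality, incomplete
#' report). A report with several flags is excluded once with all reasons
#' recorded.
#'
#' @param reports Data frame of reports with an optional `quality_flags`
#'   column (character, semicolon-separated, or list-column).
#' @return List with elements `kept` (tibble of unflagged reports) and
#'   `excluded` (tibble `subject_id`, `reasons`).
#' @export
apply_exclusions <- function(reports) {
  reports <- as_tibble(reports)
  flags <- report_flags(reports)
  excluded <- vapply(flags, length, integer(1)) > 0L
  list(
    kept = reports[!excluded, , drop = FALSE],
    excluded = tibble(
      subject_id = as.character(reports$subject_id[excluded]),
      reasons = vapply(flags[excluded], paste, "", collapse = ";")
    )
  )
}

#' Assemble label vectors into a subjects-by-labels matrix table
#'
#' @param vectors Data frame of label vectors (`subject_id` + one 0/1 column
#'   per label), e.g. from [label_reports()].
#' @param graph Optional [knowledge_graph()]; when given, the columns are
#'   checked against (and ordered as) the graph's leaf labels.
#' @return Tibble of class `label_matrix`: `subject_id` plus binary label
#'   columns.
#' @export
build_label_matrix <- function(vectors, graph = NULL) {
  vectors <- as_tibble(vectors)
  if (!"subject_id" %in% names(vectors)) abort("vectors must have subject_id")
  if (anyDuplicated(vectors$subject_id)) {
    abort("duplicate subject_id; deduplicate first")
  }
  cols <- setdiff(names(vectors), "subject_id")
  if (!is.null(graph)) {
    ids <- label_ids(graph)
    missing <- setdiff(ids, cols)
    if (length(missing) > 0L) {
      abort(paste0("missing label column(s): ", paste(missing, collapse = ", ")))
    }
    cols <- ids
  }
  vals <- vectors[cols]
  if (!all(vapply(vals, function(v) all(v %in% c(0L, 1L)), logical(1)))) {
    abort("label values must be binary 0/1")
  }
  out <- bind_cols(tibble(subject_id = as.character(vectors$subject_id)), vals)
  class(out) <- c("label_matrix", class(out))
  out
}

# numeric matrix view of a label/score matrix tibble
matrix_values <- function(m) {
  as.matrix(m[setdiff(names(m), "subject_id")])
}

#' Summarize a cohort label matrix
#'
#' Counts subjects by number of positive signs (bins 0,1,...,5,>5), the
#' number of subjects with at least one abnormal sign, and per-label subject
#' counts. The per-label counts are per subject (one row each), which is
#' what the low-frequency merge policy consumes.
#'
#' @param matrix A label matrix from [build_label_matrix()].
#' @return List of class `cohort_summary`: `n_total`,
#'   `n_positive_subjects`, `per_label` (tibble `concept_id`, `n_subjects`),
#'   `sign_count_histogram` (tibble `n_signs`, `n`).
#' @export
summarize_cohort <- function(matrix) {
  vals <- matrix_values(matrix)
  n <- nrow(vals)
  rs <- rowSums(vals)
  bins <- c(as.character(0:5), ">5")
  binned <- ifelse(rs > 5, ">5", as.character(rs))
  hist <- tibble(
    n_signs = factor(bins, levels = bins),
    n = as.integer(table(factor(binned, levels = bins)))
  )
  structure(
    list(
      n_total = n,
      n_positive_subjects = sum(rs >= 1),
      per_label = tibble(
        concept_id = colnames(vals),
        n_subjects = as.integer(colSums(vals))
      ),
      sign_count_histogram = hist
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf(
    "  subjects: %d (%d with >=1 abnormal sign, %.1f%%)\n",
    x$n_total, x$n_positive_subjects,
    if (x$n_total > 0) 100 * x$n_positive_subjects / x$n_total else 0
  ))
  cat("  signs per subject:\n")
  for (i in seq_len(nrow(x$sign_count_histogram))) {
    cat(sprintf(
      "    %3s: %d\n",
      as.character(x$sign_count_histogram$n_signs[i]), x$sign_count_histogram$n[i]
    ))
  }
  invisible(x)
}

#' @export
tidy.cohort_summary <- function(x, ...) x$per_label

#' @export
glance.cohort_summary <- function(x, ...) {
  tibble(
    n_total = x$n_total,
    n_positive_subjects = x$n_positive_subjects,
    frac_positive = ifelse(x$n_total > 0, x$n_positive_subjects / x$n_total, NA_real_)
  )
}
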
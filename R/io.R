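#' Read and write report tables
#'
#' Reports travel as JSONL (one UTF-8 JSON object per line) or CSV with
#' columns `subject_id`, `exam_date` (ISO-8601), `findings`, `impression`,
#' `quality_flags` (semicolon-separated).
#'
#' @param path File path.
#' @return `read_reports()`: tibble of reports.
#' @export
read_reports <- function(path) {
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    out <- purrr::map_dfr(lines, function(l) {
      rec <- jsonlite::fromJSON(l)
      tibble(
        subject_id = as.character(rec$subject_id),
        exam_date = as.character(rec$exam_date %||% NA_character_),
        findings = as.character(rec$findings %||% ""),
        impression = as.character(rec$impression %||% ""),
        quality_flags = paste(unlist(rec$quality_flags), collapse = ";")
      )
    })
  } else {
    out <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
    if (!"quality_flags" %in% names(out)) out$quality_flags <- ""
    out$quality_flags[is.na(out$quality_flags)] <- ""
    out$findings[is.na(out$findings)] <- ""
    out$impression[is.na(out$impression)] <- ""
  }
  out
}

#' @rdname read_reports
#' @param reports Report tibble.
#' @export
write_reports_jsonl <- function(reports, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(reports))) {
    flags <- parse_flags(reports$quality_flags[i] %||% character())
    writeLines(jsonlite::toJSON(
      list(
        subject_id = reports$subject_id[i],
        exam_date = as.character(reports$exam_date[i]),
        findings = reports$findings[i],
        impression = reports$impression[i],
        quality_flags = as.list(flags)
      ),
      auto_unbox = TRUE
    ), con)
  }
  invisible(path)
}

#' @rdname read_reports
#' @export
write_reports_csv <- function(reports, path) {
  out <- mutate(as_tibble(reports), exam_date = as.character(exam_date))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a label or score matrix from CSV
#'
#' @param path CSV with a `subject_id` column and one numeric column per
#'   label.
#' @param graph Optional [knowledge_graph()] to validate/order label
#'   columns against.
#' @return `read_label_matrix()`: a `label_matrix`; `read_score_matrix()`:
#'   a `score_matrix`.
#' @export
read_label_matrix <- function(path, graph = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), .default = readr::col_double()
  ))
  build_label_matrix(df, graph)
}

#' @rdname read_label_matrix
#' @export
read_score_matrix <- function(path, graph = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), .default = readr::col_double()
  ))
  cols <- setdiff(names(df), "subject_id")
  if (!is.null(graph)) {
    ids <- label_ids(graph)
    missing <- setdiff(ids, cols)
    if (length(missing) > 0L) {
      abort(paste0("missing label column(s): ", paste(missing, collapse = ", ")))
    }
    cols <- ids
  }
  score_matrix(df$subject_id, as.matrix(df[cols]))
}
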
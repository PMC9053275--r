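#' Default negation and uncertainty cue lists
#'
#' Polarity of a finding mention is decided from cue words in the same
#' comma/conjunction-delimited segment of the sentence. Uncertainty cues
#' take precedence over negation cues, so hedges such as "not excluded"
#' (which contains the token "not") classify as uncertain rather than
#' negative. Cue matching is case-insensitive on word boundaries.
#'
#' @return List with character vectors `negation` and `uncertainty`.
#' @export
default_cues <- function() {
  list(
    negation = c(
      "no", "without", "absent", "not seen", "free of", "clear of",
      "negative for", "disappeared", "resolved", "denies"
    ),
    uncertainty = c(
      "possible", "possibly", "probable", "likely", "suspected",
      "suspicious", "questionable", "may be", "may represent",
      "not excluded", "cannot be excluded", "not ruled out",
      "cannot rule out"
    )
  )
}

#' Labeling configuration
#'
#' @param uncertain_as How hedged ("positive with uncertainty") findings map
#'   to binary labels: `"positive"` (default, screening-oriented: possible
#'   findings become weak positives) or `"negative"`.
#' @param delimiters Sentence-terminating characters used by
#'   [combine_and_segment()].
#' @param cues Cue lists as from [default_cues()].
#' @param skip_flagged Skip reports carrying quality flags (mobile
#'   radiograph, insufficient quality, incomplete report)?
#' @return List of class `labeler_config`.
#' @export
labeler_config <- function(uncertain_as = c("positive", "negative"),
                           delimiters = c(".", "?", ";", "\n"),
                           cues = default_cues(),
                           skip_flagged = TRUE) {
  uncertain_as <- arg_match(uncertain_as)
  structure(
    list(
      uncertain_as = uncertain_as, delimiters = delimiters,
      cues = cues, skip_flagged = skip_flagged
    ),
    class = "labeler_config"
  )
}

#' Combine findings and impression and split into sentences
#'
#' The free-text image description (findings) and conclusion (impression)
#' are concatenated, findings first, into one source and split on the
#' configured sentence delimiters. Empty fragments are dropped.
#'
#' @param report One report: a list or one-row data frame with `findings`
#'   and `impression` character fields.
#' @param delimiters Characters that terminate a sentence.
#' @return Tibble with columns `sentence_index` (1-based) and `sentence`.
#' @examples
#' combine_and_segment(list(findings = "No abnormal sign.", impression = "Normal chest."))
#' @export
combine_and_segment <- function(report, delimiters = c(".", "?", ";", "\n")) {
  findings <- as.character(report$findings %||% "")[1]
  impression <- as.character(report$impression %||% "")[1]
  if (is.na(findings)) findings <- ""
  if (is.na(impression)) impression <- ""
  combined <- trimws(paste(findings, impression))
  sentences <- split_sentences(combined, delimiters)
  tibble(sentence_index = seq_along(sentences), sentence = sentences)
}

split_sentences <- function(text, delimiters = c(".", "?", ";", "\n")) {
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  rx <- paste0("[", paste(vapply(delimiters, rx_escape, ""), collapse = ""), "]")
  parts <- trimws(strsplit(text, rx, perl = TRUE)[[1]])
  parts[nzchar(parts)]
}

rx_escape <- function(x) gsub("([.\\\\|()\\[\\]{}^$*+?])", "\\\\\\1", x, perl = TRUE)

#' Recognize lexicon entities in sentences
#'
#' The default recognizer is deterministic longest-match lexicon lookup:
#' case-insensitive, on word boundaries, with overlapping candidates
#' resolved in favor of the longest (then leftmost) match so that e.g.
#' "pleural thickening" wins over "pleura". A learned recognizer can replace
#' this step as long as it emits the same mention table.
#'
#' @param sentence Character vector of one or more sentences.
#' @param graph A [knowledge_graph()] supplying the lexicon.
#' @return Tibble of mentions: `sentence_index`, `surface_form`, `category`,
#'   `concept_id`, `start`, `end` (0-based, half-open character offsets).
#' @examples
#' g <- load_ontology()
#' recognize_entities("consolidation in the inferior lobe of the right lung", g)
#' @export
recognize_entities <- function(sentence, graph) {
  stopifnot(inherits(graph, "knowledge_graph"))
  lex <- graph$lexicon
  if (nrow(lex) == 0L) abort("lexicon is empty")
  low <- tolower(sentence)
  hits <- vector("list", nrow(lex))
  for (i in seq_len(nrow(lex))) {
    rx <- paste0("\\b", rx_escape(lex$surface_form[i]), "\\b")
    m <- gregexpr(rx, low, perl = TRUE)
    starts <- unlist(m, use.names = FALSE)
    sidx <- rep.int(seq_along(m), lengths(m))
    keep <- starts != -1L
    if (!any(keep)) next
    lens <- unlist(lapply(m, attr, "match.length"), use.names = FALSE)
    hits[[i]] <- data.frame(
      sentence_index = sidx[keep],
      surface_form = lex$surface_form[i],
      category = lex$category[i],
      concept_id = lex$concept_id[i],
      start = starts[keep] - 1L,
      end = starts[keep] - 1L + lens[keep]
    )
  }
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits) || nrow(hits) == 0L) {
    return(tibble(
      sentence_index = integer(), surface_form = character(),
      category = character(), concept_id = character(),
      start = integer(), end = integer()
    ))
  }
  # longest-match overlap resolution within each sentence
  hits <- hits[order(hits$sentence_index, -(hits$end - hits$start), hits$start), ]
  parts <- split(seq_len(nrow(hits)), hits$sentence_index)
  keep_rows <- unlist(lapply(parts, function(rows) {
    if (length(rows) == 1L) return(rows)
    s <- hits$start[rows]; e <- hits$end[rows]
    keep <- logical(length(rows))
    for (i in seq_along(rows)) {
      keep[i] <- !any(s[keep] < e[i] & s[i] < e[keep])
    }
    rows[keep]
  }), use.names = FALSE)
  hits <- hits[sort(keep_rows), ]
  out <- as_tibble(hits)
  arrange(out, sentence_index, start)
}

# segment spans (0-based half-open) after splitting on commas/conjunctions
segment_spans <- function(sentence) {
  rx <- "(,|;| and | but | while | whereas )"
  m <- gregexpr(rx, tolower(sentence), perl = TRUE)[[1]]
  n <- nchar(sentence)
  if (m[1] == -1L) return(matrix(c(0, n), ncol = 2))
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  cuts <- rbind(c(NA, 0L), cbind(starts, starts + lens))
  spans <- cbind(cuts[, 2], c(starts, n))
  spans[spans[, 1] <= spans[, 2], , drop = FALSE]
}

#' Classify the polarity of a mention within its sentence
#'
#' Mentions are classified as `negative` (e.g. "no abnormal sign"),
#' `positive` (e.g. "consolidation in the inferior lobe of the right lung")
#' or `uncertain` (e.g. "possible", "not excluded"). The decision is a pure
#' function of the sentence and the cue lists: cues are searched in the
#' comma/conjunction-delimited segment containing the mention, uncertainty
#' cues take precedence over negation cues, and the default is positive.
#'
#' @param sentence One sentence.
#' @param mention One mention row from [recognize_entities()] (or `NULL` to
#'   classify the sentence as a whole).
#' @param cues Cue lists as from [default_cues()].
#' @return One of `"negative"`, `"positive"`, `"uncertain"`.
#' @examples
#' classify_polarity("no abnormal sign", NULL)
#' classify_polarity("mass not excluded", NULL)
#' @export
classify_polarity <- function(sentence, mention = NULL, cues = default_cues()) {
  seg <- sentence
  if (!is.null(mention)) {
    spans <- segment_spans(sentence)
    pos <- mention$start[1]
    row <- which(spans[, 1] <= pos & pos < spans[, 2])
    if (length(row) >= 1L) {
      seg <- substr(sentence, spans[row[1], 1] + 1L, spans[row[1], 2])
    }
  }
  polarity_of_segment(seg, cues)
}

cue_regex <- function(cue_list) {
  paste0("\\b(", paste(vapply(cue_list, rx_escape, ""), collapse = "|"), ")\\b")
}

polarity_of_segment <- function(seg, cues) {
  if (grepl(cue_regex(cues$uncertainty), seg, ignore.case = TRUE, perl = TRUE)) "uncertain"
  else if (grepl(cue_regex(cues$negation), seg, ignore.case = TRUE, perl = TRUE)) "negative"
  else "positive"
}

# vectorized polarity for a mention table spanning many sentences
batch_polarity <- function(sentences, mentions, cues) {
  segs <- character(nrow(mentions))
  spl <- split(seq_len(nrow(mentions)), mentions$sentence_index)
  for (si in names(spl)) {
    s <- sentences[as.integer(si)]
    spans <- segment_spans(s)
    for (i in spl[[si]]) {
      pos <- mentions$start[i]
      row <- which(spans[, 1] <= pos & pos < spans[, 2])
      segs[i] <- if (length(row)) substr(s, spans[row[1], 1] + 1L, spans[row[1], 2]) else s
    }
  }
  out <- rep("positive", length(segs))
  out[grepl(cue_regex(cues$negation), segs, ignore.case = TRUE, perl = TRUE)] <- "negative"
  out[grepl(cue_regex(cues$uncertainty), segs, ignore.case = TRUE, perl = TRUE)] <- "uncertain"
  out
}

#' Extract rule-constrained relation tuples from one sentence's mentions
#'
#' Each image-feature mention anchors at most one tuple; mentions of other
#' categories in the same sentence join the tuple only if the category pair
#' is allowed by the relation rules (so "left-large-consolidation" links
#' location and adjective to the feature, while region-adjective pairs are
#' never linked). The tuple inherits the feature mention's polarity.
#'
#' @param mentions Mention tibble for a single sentence, with a `polarity`
#'   column (add one via [classify_polarity()]).
#' @param graph A [knowledge_graph()].
#' @return Tibble of tuples: `label_concept`, `polarity`, `members`
#'   (list-column of member mention tibbles).
#' @export
extract_relations <- function(mentions, graph) {
  stopifnot(inherits(graph, "knowledge_graph"))
  empty <- tibble(
    label_concept = character(), polarity = character(), members = list()
  )
  if (is.null(mentions) || nrow(mentions) == 0L) return(empty)
  if (!"polarity" %in% names(mentions)) {
    abort("mentions must carry a polarity column")
  }
  feats <- which(mentions$category == "feature_name")
  if (length(feats) == 0L) return(empty)
  purrr::map_dfr(feats, function(i) {
    ok <- vapply(seq_len(nrow(mentions)), function(j) {
      j != i && validate_relation(graph$rules, mentions$category[j], "feature_name")
    }, logical(1))
    tibble(
      label_concept = mentions$concept_id[i],
      polarity = mentions$polarity[i],
      members = list(mentions[c(i, which(ok)), , drop = FALSE])
    )
  })
}

#' Map relation tuples onto a binary sign-label vector
#'
#' Tuples are resolved up the concept hierarchy to the nearest leaf label.
#' Positive tuples set the label to 1; uncertain tuples follow
#' `uncertain_as`; negative tuples never set 1. When one report carries
#' conflicting polarities for the same label, any positive wins. Labels not
#' mentioned stay 0.
#'
#' @param tuples Tuple tibble from [extract_relations()] (rows from several
#'   sentences may be concatenated).
#' @param graph A [knowledge_graph()].
#' @param uncertain_as `"positive"` (default) or `"negative"`.
#' @return Named integer vector over the graph's leaf labels, values 0/1.
#' @export
map_to_label_vector <- function(tuples, graph, uncertain_as = c("positive", "negative")) {
  uncertain_as <- arg_match(uncertain_as)
  ids <- label_ids(graph)
  vec <- setNames(integer(length(ids)), ids)
  if (is.null(tuples) || nrow(tuples) == 0L) return(vec)
  for (i in seq_len(nrow(tuples))) {
    lab <- resolve_to_label(graph, tuples$label_concept[i])
    if (is.na(lab)) next
    pol <- tuples$polarity[i]
    on <- pol == "positive" || (pol == "uncertain" && uncertain_as == "positive")
    if (on) vec[[lab]] <- 1L
  }
  vec
}

#' Label one report
#'
#' Runs the full pipeline on a single report: segmentation, entity
#' recognition, polarity classification, relation extraction and label
#' mapping. Reports carrying quality flags raise a classed condition
#' (`radlabel_skip`) unless `config$skip_flagged` is `FALSE`.
#'
#' @param report A list or one-row data frame with `subject_id`, `findings`,
#'   `impression` and optionally `quality_flags` (character vector or
#'   semicolon-separated string).
#' @param graph A [knowledge_graph()].
#' @param config A [labeler_config()].
#' @return One-row tibble: `subject_id` plus one 0/1 column per leaf label.
#' @examples
#' g <- load_ontology()
#' label_report(list(subject_id = "s1", findings = "No abnormal sign.",
#'                   impression = ""), g)
#' @export
label_report <- function(report, graph, config = labeler_config()) {
  flags <- if (is.data.frame(report)) {
    report_flags(report)[[1]]
  } else {
    parse_flags(report$quality_flags %||% character())
  }
  if (config$skip_flagged && length(flags) > 0L) {
    abort(
      paste0("report ", report$subject_id[1], " excluded: ", paste(flags, collapse = ", ")),
      class = "radlabel_skip",
      subject_id = as.character(report$subject_id[1]),
      reasons = flags
    )
  }
  sent <- combine_and_segment(report, config$delimiters)
  tuples <- sentence_tuples(sent$sentence, graph, config)
  vec <- map_to_label_vector(tuples, graph, config$uncertain_as)
  bind_cols(
    tibble(subject_id = as.character(report$subject_id[1])),
    as_tibble(as.list(vec))
  )
}

# per-row quality flags of a report table (empty when the column is absent)
report_flags <- function(reports) {
  if (!"quality_flags" %in% names(reports)) {
    return(replicate(nrow(reports), character(), simplify = FALSE))
  }
  lapply(seq_len(nrow(reports)), function(i) parse_flags(reports$quality_flags[i]))
}

parse_flags <- function(x) {
  if (is.list(x)) x <- unlist(x)
  x <- as.character(x)
  x <- x[!is.na(x)]
  flags <- unlist(strsplit(x, ";", fixed = TRUE))
  trimws(flags[nzchar(trimws(flags))])
}

# tuples for a vector of sentences (single report or batch slice)
sentence_tuples <- function(sentences, graph, config) {
  men <- recognize_entities(sentences, graph)
  if (nrow(men) == 0L) {
    return(tibble(label_concept = character(), polarity = character(), members = list()))
  }
  men$polarity <- vapply(seq_len(nrow(men)), function(i) {
    classify_polarity(sentences[men$sentence_index[i]], men[i, ], config$cues)
  }, character(1))
  men %>%
    group_by(sentence_index) %>%
    group_modify(~ extract_relations(.x, graph)) %>%
    ungroup() %>%
    select(-sentence_index)
}

#' Label a table of reports
#'
#' Data-frame front end to [label_report()]: one row in, one row out, with
#' flagged reports partitioned off rather than raising.
#'
#' @param reports Data frame of reports (`subject_id`, `exam_date`,
#'   `findings`, `impression`, optional `quality_flags`).
#' @param graph A [knowledge_graph()].
#' @param config A [labeler_config()].
#' @return Tibble of label vectors (`subject_id` + 25 label columns) for the
#'   non-excluded reports, with attribute `"skipped"` holding a tibble
#'   (`subject_id`, `reasons`) of excluded reports.
#' @export
label_reports <- function(reports, graph, config = labeler_config()) {
  reports <- as_tibble(reports)
  flags <- report_flags(reports)
  skip <- config$skip_flagged & vapply(flags, length, integer(1)) > 0L
  skipped <- tibble(
    subject_id = as.character(reports$subject_id[skip]),
    reasons = vapply(flags[skip], paste, "", collapse = ";")
  )
  kept <- reports[!skip, , drop = FALSE]
  ids <- label_ids(graph)
  if (nrow(kept) == 0L) {
    out <- bind_cols(
      tibble(subject_id = character()),
      as_tibble(setNames(rep(list(integer()), length(ids)), ids))
    )
    attr(out, "skipped") <- skipped
    return(out)
  }

  # batch path: recognize over all sentences at once, then fold per report
  sent <- purrr::map_dfr(seq_len(nrow(kept)), function(i) {
    s <- combine_and_segment(kept[i, ], config$delimiters)
    mutate(s, .report = i)
  })
  vecs <- matrix(0L, nrow(kept), length(ids), dimnames = list(NULL, ids))
  if (nrow(sent) > 0L) {
    men <- recognize_entities(sent$sentence, graph)
    if (nrow(men) > 0L) {
      men$polarity <- batch_polarity(sent$sentence, men, config$cues)
      men$.report <- sent$.report[men$sentence_index]
      # a relation tuple is anchored by its feature mention and inherits its
      # polarity, so the label vector only needs the feature mentions
      feats <- men[men$category == "feature_name", , drop = FALSE]
      if (nrow(feats) > 0L) {
        resolve_map <- vapply(
          unique(feats$concept_id),
          function(id) resolve_to_label(graph, id) %||% NA_character_,
          character(1)
        )
        lab <- resolve_map[feats$concept_id]
        on <- feats$polarity == "positive" |
          (feats$polarity == "uncertain" & config$uncertain_as == "positive")
        sel <- !is.na(lab) & on
        vecs[cbind(feats$.report[sel], match(lab[sel], ids))] <- 1L
      }
    }
  }
  out <- bind_cols(
    tibble(subject_id = as.character(kept$subject_id)),
    as_tibble(vecs)
  )
  attr(out, "skipped") <- skipped
  out
}
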
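test_that("findings and impression combine, findings first, and split on delimiters", {
  s <- combine_and_segment(list(findings = "No abnormal sign.",
                                impression = "Normal chest."))
  expect_equal(nrow(s), 2L)
  expect_equal(s$sentence, c("No abnormal sign", "Normal chest"))

  expect_equal(nrow(combine_and_segment(list(findings = "", impression = ""))), 0L)
  expect_equal(
    combine_and_segment(list(findings = "A. B? C", impression = ""))$sentence,
    c("A", "B", "C")
  )
  # custom delimiter set
  s2 <- combine_and_segment(list(findings = "A|B", impression = ""),
                            delimiters = "|")
  expect_equal(s2$sentence, c("A", "B"))
})

test_that("entity recognition is longest-match, case-insensitive and non-overlapping", {
  m <- recognize_entities("consolidation in the inferior lobe of the right lung", pkg_graph)
  expect_true("consolidation" %in% m$surface_form)
  expect_equal(m$concept_id[m$surface_form == "consolidation"], "consolidation")
  expect_true(all(c("location", "anatomical_region") %in% m$category))

  m2 <- recognize_entities("Pleural Thickening", pkg_graph)
  expect_equal(m2$surface_form, "pleural thickening")
  expect_equal(nrow(m2), 1L)

  expect_equal(nrow(recognize_entities("entirely unremarkable text", pkg_graph)), 0L)

  # spans are 0-based half-open within bounds and non-overlapping
  m3 <- recognize_entities("no small consolidation and large mass", pkg_graph)
  expect_true(all(m3$start < m3$end))
  ord <- order(m3$start)
  expect_true(all(diff(m3$start[ord]) >= 0))
  expect_true(all(head(m3$end[ord], -1) <= m3$start[ord][-1]))
  expect_equal(m3$concept_id[m3$category == "feature_name"],
               c("small_consolidation", "mass"))
})

test_that("polarity classification follows cue precedence and segment scope", {
  expect_equal(classify_polarity("no abnormal sign", NULL), "negative")
  expect_equal(
    classify_polarity("consolidation in the inferior lobe of the right lung", NULL),
    "positive"
  )
  expect_equal(classify_polarity("mass not excluded", NULL), "uncertain")
  expect_equal(classify_polarity("possible nodule", NULL), "uncertain")
  # uncertainty outranks negation in the same segment
  expect_equal(classify_polarity("no definite mass, lesion not excluded", NULL), "uncertain")
  # negation is scoped to the mention's comma-delimited segment
  sent <- "no consolidation, large mass"
  men <- recognize_entities(sent, pkg_graph)
  pol <- vapply(seq_len(nrow(men)), function(i) {
    classify_polarity(sent, men[i, ])
  }, character(1))
  expect_equal(pol[men$surface_form == "consolidation"], "negative")
  expect_equal(pol[men$surface_form == "mass"], "positive")
  # pure function of (sentence, cues): other sentences are irrelevant
  expect_equal(classify_polarity("large mass", men[2, ]), "positive")
})

test_that("relation extraction links only rule-allowed pairs to the feature anchor", {
  sent <- "left large consolidation"
  men <- recognize_entities(sent, pkg_graph)
  men$polarity <- "positive"
  tup <- extract_relations(men, pkg_graph)
  expect_equal(nrow(tup), 1L)
  expect_equal(tup$label_concept, "consolidation")
  members <- tup$members[[1]]
  expect_setequal(members$category, c("feature_name", "location", "feature_adjective"))

  # region + adjective with no feature anchor yields nothing
  men2 <- recognize_entities("blurred lung", pkg_graph)
  men2$polarity <- "positive"
  expect_equal(nrow(extract_relations(men2, pkg_graph)), 0L)

  expect_equal(nrow(extract_relations(NULL, pkg_graph)), 0L)
})

test_that("label mapping applies polarity, hierarchy resolution and any-positive rule", {
  g <- pkg_graph
  one <- tibble::tibble(label_concept = "pneumothorax", polarity = "positive",
                        members = list(NULL))
  v <- map_to_label_vector(one, g)
  expect_equal(unname(v[["pneumothorax"]]), 1L)
  expect_equal(sum(v), 1L)

  expect_equal(sum(map_to_label_vector(NULL, g)), 0L)

  # non-label concept resolves to its nearest labeled ancestor
  sub <- tibble::tibble(label_concept = "aortic_arch_calcification",
                        polarity = "positive", members = list(NULL))
  expect_equal(unname(map_to_label_vector(sub, g)[["aortic_arteriosclerosis"]]), 1L)

  # full polarity-pair resolution table under the any-positive rule
  pols <- c("negative", "positive", "uncertain")
  expect_on <- function(p1, p2, uncertain_as) {
    on1 <- p1 == "positive" | (p1 == "uncertain" & uncertain_as == "positive")
    on2 <- p2 == "positive" | (p2 == "uncertain" & uncertain_as == "positive")
    as.integer(on1 | on2)
  }
  for (ua in c("positive", "negative")) {
    for (p1 in pols) for (p2 in pols) {
      tup <- tibble::tibble(
        label_concept = "nodule", polarity = c(p1, p2), members = list(NULL, NULL)
      )
      expect_equal(
        unname(map_to_label_vector(tup, g, ua)[["nodule"]]),
        expect_on(p1, p2, ua),
        info = paste(p1, p2, ua)
      )
      # invariant to tuple ordering
      expect_equal(
        map_to_label_vector(tup, g, ua),
        map_to_label_vector(tup[2:1, ], g, ua)
      )
    }
  }
})

test_that("adding a positive tuple never turns a label off (monotonicity)", {
  g <- pkg_graph
  ids <- label_ids(g)
  set.seed(11)
  for (i in 1:20) {
    k <- sample(1:6, 1)
    tup <- tibble::tibble(
      label_concept = sample(ids, k, replace = TRUE),
      polarity = sample(c("negative", "positive", "uncertain"), k, replace = TRUE),
      members = replicate(k, NULL, simplify = FALSE)
    )
    base <- map_to_label_vector(tup, g)
    extra <- dplyr::bind_rows(tup, tibble::tibble(
      label_concept = sample(ids, 1), polarity = "positive", members = list(NULL)
    ))
    expect_true(all(map_to_label_vector(extra, g) >= base))
  }
})

test_that("label_report composes the pipeline and honors exclusion flags", {
  out <- label_report(
    list(subject_id = "s1", findings = "No abnormal sign.", impression = ""),
    pkg_graph
  )
  expect_equal(sum(out[, -1]), 0)

  out2 <- label_report(
    list(subject_id = "s2",
         findings = "Left large consolidation. Mass not excluded.",
         impression = "No pleural effusion."),
    pkg_graph
  )
  expect_equal(out2$consolidation, 1L)
  expect_equal(out2$mass, 1L)  # uncertain_as = positive default
  expect_equal(out2$pleural_effusion, 0L)

  cfg_neg <- labeler_config(uncertain_as = "negative")
  out3 <- label_report(
    list(subject_id = "s2", findings = "Mass not excluded.", impression = ""),
    pkg_graph, cfg_neg
  )
  expect_equal(out3$mass, 0L)

  expect_error(
    label_report(
      list(subject_id = "s3", findings = "x", impression = "",
           quality_flags = "mobile_cxr"),
      pkg_graph
    ),
    class = "radlabel_skip"
  )
})

test_that("label_reports matches per-report labeling and partitions skips", {
  gen <- generate_reports(pkg_graph, 25, seed = 5)
  reports <- gen$reports
  reports$quality_flags[3] <- "mobile_cxr;incomplete_report"
  out <- label_reports(reports, pkg_graph)
  expect_equal(nrow(out), 24L)
  skipped <- attr(out, "skipped")
  expect_equal(skipped$subject_id, reports$subject_id[3])
  expect_match(skipped$reasons, "mobile_cxr")
  # batch path agrees with the one-report path
  for (i in c(1, 2, 10)) {
    expect_equal(
      out[out$subject_id == reports$subject_id[i], ],
      label_report(reports[i, ], pkg_graph),
      ignore_attr = TRUE
    )
  }
})

test_that("grammar-generated reports round-trip to their exact truth", {
  gen <- generate_reports(pkg_graph, 200, seed = 17)
  lab <- label_reports(gen$reports, pkg_graph)
  expect_equal(as.matrix(lab[, -1]), as.matrix(gen$truth[, -1]),
               ignore_attr = TRUE)
})
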
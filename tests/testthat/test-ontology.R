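test_that("packaged ontology reproduces the published label structure", {
  labs <- graph_labels(pkg_graph)
  expect_equal(nrow(labs), 25L)
  counts <- table(labs$region)
  expect_equal(unname(counts[["lung_parenchyma"]]), 12L)
  expect_equal(unname(counts[["mediastinum"]]), 4L)
  expect_equal(unname(counts[["pleura"]]), 6L)
  expect_equal(unname(counts[["thoracic_wall"]]), 3L)
  # every lexicon feature term resolves to a node
  expect_true(all(
    pkg_graph$lexicon$concept_id[pkg_graph$lexicon$category == "feature_name"] %in%
      pkg_graph$nodes$concept_id
  ))
})

test_that("ontology validation rejects malformed configurations", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    nodes = list(
      list(concept_id = "pleura", display_name = "Pleura", region = "pleura",
           is_label = FALSE),
      list(concept_id = "child", display_name = "Child", region = "pleura",
           parent_id = "missing", is_label = TRUE)
    ),
    lexicon = list(
      list(surface_form = "child", category = "feature_name", concept_id = "child")
    )
  ), path)
  expect_error(load_ontology(path), "validation error.*missing")
  expect_error(load_ontology(tempfile("nope")), "not found")

  # duplicate surface form within a category
  nodes <- pkg_graph$nodes
  lex <- dplyr::bind_rows(
    pkg_graph$lexicon,
    tibble::tibble(surface_form = "nodule", category = "feature_name",
                   concept_id = "mass")
  )
  expect_error(knowledge_graph(nodes, lex), "duplicate surface form")
})

test_that("relation rules allow region-feature links but not region-adjective", {
  rules <- pkg_graph$rules
  expect_true(validate_relation(rules, "anatomical_region", "feature_name"))
  expect_false(validate_relation(rules, "anatomical_region", "feature_adjective"))
  expect_false(validate_relation(rules, "feature_name", "feature_name"))
  expect_true(validate_relation(rules, "location", "anatomical_region"))
  expect_true(validate_relation(rules, "feature_adjective", "feature_name"))
  expect_error(validate_relation(rules, "bogus", "feature_name"), "unknown")
  # table is total over ordered pairs and the default is symmetric
  expect_equal(nrow(rules), 16L)
  sym <- dplyr::inner_join(
    rules,
    dplyr::rename(rules,
      source_category = "target_category", target_category = "source_category",
      allowed2 = "allowed"
    ),
    by = c("source_category", "target_category")
  )
  expect_true(all(sym$allowed == sym$allowed2))
})

test_that("region_of_label returns the region ancestor for leaf labels only", {
  expect_equal(region_of_label(pkg_graph, "pneumothorax"), "pleura")
  expect_equal(region_of_label(pkg_graph, "cardiomegaly"), "mediastinum")
  expect_equal(region_of_label(pkg_graph, "scoliosis"), "thoracic_wall")
  expect_equal(region_of_label(pkg_graph, "nodule"), "lung_parenchyma")
  expect_error(region_of_label(pkg_graph, "mediastinum"), "not a leaf")
})

test_that("low-frequency labels merge upward with counts accruing", {
  g <- toy_merge_graph()
  counts <- c(
    aortic_arch_calcification = 30, aortic_knob_calcification = 28,
    aortic_arteriosclerosis = 400
  )
  merged <- merge_low_frequency(g, counts, merge_policy(50))
  expect_setequal(merged$merge_log$concept_id,
                  c("aortic_arch_calcification", "aortic_knob_calcification"))
  expect_true(all(merged$merge_log$merged_into == "aortic_arteriosclerosis"))
  retained <- merged$nodes$concept_id[merged$nodes$is_label]
  expect_false("aortic_arch_calcification" %in% retained)
  # counts conserve under accrual
  expect_equal(
    merged$counts$n_subjects[merged$counts$concept_id == "aortic_arteriosclerosis"],
    458
  )
  expect_equal(sum(merged$counts$n_subjects), sum(counts))
  # lexicon entries re-point to the surviving ancestor
  lex <- merged$lexicon
  expect_equal(
    lex$concept_id[lex$surface_form == "aortic arch calcification"],
    "aortic_arteriosclerosis"
  )
})

test_that("cavity is retained at any count via the exception set", {
  g <- toy_merge_graph()
  merged <- merge_low_frequency(g, c(cavity = 20), merge_policy(50, "cavity"))
  expect_true("cavity" %in% merged$nodes$concept_id[merged$nodes$is_label])
  expect_equal(nrow(merged$merge_log), 0L)
})

test_that("the merge threshold is a strict greater-than", {
  g <- toy_merge_graph()
  counts <- c(aortic_arch_calcification = 51, aortic_knob_calcification = 50,
              aortic_arteriosclerosis = 400)
  merged <- merge_low_frequency(g, counts, merge_policy(50, exceptions = character()))
  retained <- merged$nodes$concept_id[merged$nodes$is_label]
  expect_true("aortic_arch_calcification" %in% retained)   # 51 > 50
  expect_false("aortic_knob_calcification" %in% retained)  # 50 is not > 50
})

test_that("merging is idempotent and unmergeable roots are retained with warning", {
  g <- toy_merge_graph()
  counts <- c(aortic_arch_calcification = 30, aortic_knob_calcification = 28,
              aortic_arteriosclerosis = 400)
  once <- merge_low_frequency(g, counts, merge_policy(50))
  twice <- merge_low_frequency(once, counts, merge_policy(50))
  expect_equal(once$nodes, twice$nodes)
  expect_equal(once$lexicon, twice$lexicon)

  # nodule sits directly under the (unlabeled) region root
  expect_warning(
    out <- merge_low_frequency(g, c(nodule = 3), merge_policy(50)),
    "no labeled ancestor"
  )
  expect_true("nodule" %in% out$nodes$concept_id[out$nodes$is_label])
})

test_that("graph tables export round-trips through CSV", {
  dir <- withr::local_tempdir()
  paths <- export_graph_tables(pkg_graph, dir)
  nodes <- readr::read_csv(paths[["nodes"]], show_col_types = FALSE)
  expect_equal(nrow(nodes), nrow(pkg_graph$nodes))
  expect_equal(sum(nodes$is_label), 25)
})
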
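# shared fixtures built in code

pkg_graph <- load_ontology()

# minimal three-level toy graph used by the merge tests: a labeled parent
# ("aortic arteriosclerosis") with two labeled children, plus a rare
# stand-alone label ("cavity") and an unmergeable label under a region root
toy_merge_graph <- function() {
  nodes <- tibble::tribble(
    ~concept_id, ~display_name, ~region, ~parent_id, ~is_label,
    "mediastinum", "Mediastinum", "mediastinum", NA, FALSE,
    "lung_parenchyma", "Lung parenchyma", "lung_parenchyma", NA, FALSE,
    "aortic_arteriosclerosis", "Aortic arteriosclerosis", "mediastinum", "mediastinum", TRUE,
    "aortic_arch_calcification", "Aortic arch calcification", "mediastinum", "aortic_arteriosclerosis", TRUE,
    "aortic_knob_calcification", "Aortic knob calcification", "mediastinum", "aortic_arteriosclerosis", TRUE,
    "cavity", "Cavity", "lung_parenchyma", "lung_parenchyma", TRUE,
    "nodule", "Nodule", "lung_parenchyma", "lung_parenchyma", TRUE
  )
  lexicon <- tibble::tribble(
    ~surface_form, ~category, ~concept_id,
    "aortic arteriosclerosis", "feature_name", "aortic_arteriosclerosis",
    "aortic arch calcification", "feature_name", "aortic_arch_calcification",
    "aortic knob calcification", "feature_name", "aortic_knob_calcification",
    "cavity", "feature_name", "cavity",
    "nodule", "feature_name", "nodule"
  )
  knowledge_graph(nodes, lexicon)
}

# a named all-zero label vector over the packaged ontology
zero_vector <- function(graph = pkg_graph) {
  stats::setNames(rep(0L, length(label_ids(graph))), label_ids(graph))
}

# random binary label matrix tibble
random_label_matrix <- function(n, graph = pkg_graph, p = 0.3, seed = 1) {
  ids <- label_ids(graph)
  set.seed(seed)
  vals <- matrix(rbinom(n * length(ids), 1, p), n, dimnames = list(NULL, ids))
  build_label_matrix(
    dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("r%03d", seq_len(n))),
      tibble::as_tibble(vals)
    ),
    graph
  )
}

# brute-force AUC by pair enumeration (independent oracle)
auc_pair_count <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# trapezoidal area under the empirical ROC (second independent oracle)
auc_trapezoid <- function(scores, truth) {
  pts <- roc_curve_points(scores, truth)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}
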
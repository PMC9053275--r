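#' Entity categories of the report lexicon
#'
#' The labeling pipeline distinguishes exactly four categories of linguistic
#' entity in a radiology report: the anatomical region (e.g. "lung",
#' "aorta"), the location of a lesion (e.g. "left", "bilateral", "upper"),
#' the image feature name (e.g. "nodule", "consolidation"), and the image
#' feature adjective (e.g. "blur", "large").
#'
#' @return Character vector of the four category names.
#' @export
entity_categories <- function() {
  c("anatomical_region", "location", "feature_name", "feature_adjective")
}

#' Default relation-rule table
#'
#' Semantic relations between entity mentions are restricted by a rule table
#' over ordered category pairs. The default allows region--feature_name,
#' location--feature_name, feature_adjective--feature_name and
#' location--region links (symmetrically) and disallows everything else,
#' including all same-category pairs and region--adjective, which carries no
#' radiological meaning.
#'
#' @param allowed_pairs List of length-2 character vectors of category names;
#'   each pair is allowed in both orders. Defaults to the table above.
#' @return A tibble with columns `source_category`, `target_category`,
#'   `allowed`, total over all 16 ordered category pairs.
#' @export
default_relation_rules <- function(allowed_pairs = NULL) {
  cats <- entity_categories()
  if (is.null(allowed_pairs)) {
    allowed_pairs <- list(
      c("anatomical_region", "feature_name"),
      c("location", "feature_name"),
      c("feature_adjective", "feature_name"),
      c("location", "anatomical_region")
    )
  }
  rules <- tidyr::expand_grid(source_category = cats, target_category = cats)
  key <- function(a, b) paste(a, b, sep = "|")
  allowed_keys <- unlist(lapply(allowed_pairs, function(p) {
    if (length(p) != 2L || !all(p %in% cats)) {
      abort("each allowed pair must contain two valid entity categories")
    }
    c(key(p[1], p[2]), key(p[2], p[1]))
  }))
  rules$allowed <- key(rules$source_category, rules$target_category) %in% allowed_keys
  rules
}

#' Look up whether two entity categories may be semantically related
#'
#' @param rules Rule table from [default_relation_rules()] or a graph's
#'   `$rules` element.
#' @param a,b Entity category names.
#' @return Logical scalar.
#' @export
validate_relation <- function(rules, a, b) {
  cats <- entity_categories()
  if (!is.character(a) || !(a %in% cats)) abort(paste0("unknown entity category: ", a))
  if (!is.character(b) || !(b %in% cats)) abort(paste0("unknown entity category: ", b))
  hit <- rules$allowed[rules$source_category == a & rules$target_category == b]
  if (length(hit) != 1L) abort("rule table is not total over ordered category pairs")
  hit
}

#' Construct a knowledge graph of report concepts
#'
#' A knowledge graph bundles the hierarchical concept nodes (a forest rooted
#' at the four anatomical regions, whose labeled leaves are the binary
#' classification targets), the surface-form lexicon that normalizes report
#' terms onto concepts, and the relation-rule table. Location and adjective
#' lexicon entries normalize onto modifier concepts, which are tracked
#' separately from the anatomical node forest.
#'
#' @param nodes Data frame with columns `concept_id`, `display_name`,
#'   `region`, `parent_id` (NA for the four region roots) and `is_label`.
#' @param lexicon Data frame with columns `surface_form`, `category`,
#'   `concept_id`.
#' @param rules Rule table; defaults to [default_relation_rules()].
#' @return An object of class `knowledge_graph` (a list of tibbles `nodes`,
#'   `lexicon`, `rules`, `modifiers`).
#' @export
knowledge_graph <- function(nodes, lexicon, rules = default_relation_rules()) {
  nodes <- as_tibble(nodes)
  lexicon <- as_tibble(lexicon)
  need_n <- c("concept_id", "display_name", "region", "parent_id", "is_label")
  if (!all(need_n %in% names(nodes))) {
    abort(paste0("nodes must have columns: ", paste(need_n, collapse = ", ")))
  }
  need_l <- c("surface_form", "category", "concept_id")
  if (!all(need_l %in% names(lexicon))) {
    abort(paste0("lexicon must have columns: ", paste(need_l, collapse = ", ")))
  }
  regions <- c("pleura", "lung_parenchyma", "mediastinum", "thoracic_wall")
  if (!all(nodes$region %in% regions)) {
    abort("validation error: node region must be one of the four anatomical regions")
  }
  if (anyDuplicated(nodes$concept_id)) {
    abort("validation error: duplicate concept_id in nodes")
  }
  dangling <- setdiff(stats::na.omit(nodes$parent_id), nodes$concept_id)
  if (length(dangling) > 0) {
    abort(paste0(
      "validation error: parent_id does not resolve: ",
      paste(dangling, collapse = ", ")
    ))
  }
  if (!all(lexicon$category %in% entity_categories())) {
    abort("validation error: lexicon category outside the four entity categories")
  }
  dup <- lexicon %>%
    mutate(surface_form = tolower(surface_form)) %>%
    count(category, surface_form) %>%
    filter(n > 1L)
  if (nrow(dup) > 0) {
    abort(paste0(
      "validation error: duplicate surface form within category: ",
      paste(dup$surface_form, collapse = ", ")
    ))
  }
  anat <- lexicon$category %in% c("feature_name", "anatomical_region")
  unresolved <- setdiff(lexicon$concept_id[anat], nodes$concept_id)
  if (length(unresolved) > 0) {
    abort(paste0(
      "validation error: lexicon concept_id does not resolve: ",
      paste(unresolved, collapse = ", ")
    ))
  }
  modifiers <- lexicon %>%
    filter(category %in% c("location", "feature_adjective")) %>%
    distinct(concept_id, category)
  graph <- structure(
    list(
      nodes = nodes,
      lexicon = mutate(lexicon, surface_form = tolower(surface_form)),
      rules = as_tibble(rules),
      modifiers = modifiers
    ),
    class = "knowledge_graph"
  )
  # every root must be a region root and every label must sit under its region
  roots <- nodes$concept_id[is.na(nodes$parent_id)]
  for (id in nodes$concept_id) {
    root <- id
    seen <- character()
    repeat {
      p <- nodes$parent_id[nodes$concept_id == root]
      if (is.na(p)) break
      if (root %in% seen) abort("validation error: cycle in parent links")
      seen <- c(seen, root)
      root <- p
    }
    if (!(root %in% roots)) abort("validation error: unreachable root")
    if (nodes$region[nodes$concept_id == root] != nodes$region[nodes$concept_id == id]) {
      abort(paste0("validation error: node ", id, " disagrees with its root region"))
    }
  }
  graph
}

#' @export
print.knowledge_graph <- function(x, ...) {
  labs <- graph_labels(x)
  cat("<knowledge_graph>\n")
  cat("  nodes:  ", nrow(x$nodes), " (", nrow(labs), " leaf sign labels)\n", sep = "")
  tab <- table(labs$region)
  cat("  labels by region: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  lexicon:", nrow(x$lexicon), "surface forms\n")
  invisible(x)
}

#' Load a sign ontology from a YAML/JSON file
#'
#' With no arguments this returns the packaged default ontology: 25 leaf
#' sign labels partitioned over the four anatomical regions as 12 lung
#' parenchyma, 4 mediastinum, 6 pleura and 3 thoracic wall, together with
#' the surface-form lexicon and the default relation rules.
#'
#' @param path Path to an ontology file (YAML or JSON with top-level keys
#'   `nodes`, `lexicon` and optionally `rules$allowed_pairs`). `NULL` loads
#'   the packaged default.
#' @return A [knowledge_graph()].
#' @examples
#' g <- load_ontology()
#' dplyr::count(graph_labels(g), region)
#' @export
load_ontology <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ontology.yaml", package = "radlabel")
  }
  if (!file.exists(path)) abort(paste0("ontology file not found: ", path))
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(doc) || is.null(doc$nodes) || is.null(doc$lexicon)) {
    abort(paste0("parse error in ", path, ": expected top-level 'nodes' and 'lexicon'"))
  }
  nodes <- purrr::map_dfr(doc$nodes, function(nd) {
    tibble(
      concept_id = nd$concept_id,
      display_name = nd$display_name %||% nd$concept_id,
      region = nd$region,
      parent_id = nd$parent_id %||% NA_character_,
      is_label = isTRUE(nd$is_label)
    )
  })
  lexicon <- purrr::map_dfr(doc$lexicon, function(le) {
    tibble(
      surface_form = le$surface_form,
      category = le$category,
      concept_id = le$concept_id
    )
  })
  rules <- if (!is.null(doc$rules$allowed_pairs)) {
    default_relation_rules(lapply(doc$rules$allowed_pairs, unlist))
  } else {
    default_relation_rules()
  }
  knowledge_graph(nodes, lexicon, rules)
}

#' Leaf sign labels of a knowledge graph
#'
#' @param graph A [knowledge_graph()].
#' @return Tibble with one row per leaf label: `concept_id`, `display_name`,
#'   `region`, in node order.
#' @export
graph_labels <- function(graph) {
  stopifnot(inherits(graph, "knowledge_graph"))
  graph$nodes %>%
    filter(is_label) %>%
    select(concept_id, display_name, region)
}

#' @rdname graph_labels
#' @return `label_ids()`: character vector of leaf-label concept ids.
#' @export
label_ids <- function(graph) graph_labels(graph)$concept_id

#' Anatomical region of a leaf sign label
#'
#' @param graph A [knowledge_graph()].
#' @param concept_id Leaf-label concept id (vectorized).
#' @return Character vector of regions (`pleura`, `lung_parenchyma`,
#'   `mediastinum`, `thoracic_wall`).
#' @export
region_of_label <- function(graph, concept_id) {
  labs <- graph_labels(graph)
  idx <- match(concept_id, labs$concept_id)
  if (anyNA(idx)) {
    abort(paste0(
      "not a leaf sign label: ",
      paste(concept_id[is.na(idx)], collapse = ", ")
    ))
  }
  labs$region[idx]
}

# climb the node forest to the nearest labeled concept at or above `id`;
# NA if no labeled ancestor exists
resolve_to_label <- function(graph, id) {
  nodes <- graph$nodes
  cur <- id
  while (!is.na(cur)) {
    row <- match(cur, nodes$concept_id)
    if (is.na(row)) return(NA_character_)
    if (nodes$is_label[row]) return(cur)
    cur <- nodes$parent_id[row]
  }
  NA_character_
}

#' Merge policy for low-frequency sign labels
#'
#' Labels observed in too few subjects are folded into their nearest labeled
#' ancestor so that every retained classification target has enough positive
#' subjects to train on. The retention rule is strictly "more than"
#' `min_subject_count` subjects; concepts in `exceptions` are retained at any
#' count (by default `cavity`, rare but clinically important).
#'
#' @param min_subject_count Retention threshold (default 50, strict `>`).
#' @param exceptions Character vector of concept ids exempt from merging.
#' @return A list of class `merge_policy`.
#' @export
merge_policy <- function(min_subject_count = 50, exceptions = "cavity") {
  if (!is.numeric(min_subject_count) || min_subject_count < 0) {
    abort("min_subject_count must be a non-negative number")
  }
  structure(
    list(min_subject_count = min_subject_count, exceptions = as.character(exceptions)),
    class = "merge_policy"
  )
}

#' Fold low-frequency labels into their labeled ancestors
#'
#' Labels whose per-subject count does not exceed the policy threshold are
#' merged upward: their subject counts accrue to the nearest labeled
#' ancestor, their lexicon entries re-point to that ancestor, and the node
#' stops being a classification label. Counts are per subject, not per
#' mention. A low-frequency label with no labeled ancestor is retained with
#' a warning. Labels absent from `counts` are left untouched.
#'
#' @param graph A [knowledge_graph()].
#' @param counts Named numeric vector or two-column data frame
#'   (`concept_id`, `n_subjects`) of per-label subject counts.
#' @param policy A [merge_policy()].
#' @return The merged `knowledge_graph`, with two extra elements: `counts`
#'   (tibble of post-merge counts for retained labels) and `merge_log`
#'   (tibble `concept_id`, `merged_into`).
#' @examples
#' g <- load_ontology()
#' cnt <- c(small_consolidation = 30, patchy_consolidation = 28, consolidation = 400)
#' merged <- merge_low_frequency(g, cnt, merge_policy())
#' merged$merge_log
#' @export
merge_low_frequency <- function(graph, counts, policy = merge_policy()) {
  stopifnot(inherits(graph, "knowledge_graph"), inherits(policy, "merge_policy"))
  if (is.data.frame(counts)) {
    counts <- setNames(counts$n_subjects, counts$concept_id)
  }
  if (is.null(names(counts)) || anyNA(names(counts))) {
    abort("counts must be named by concept_id")
  }
  unknown <- setdiff(names(counts), graph$nodes$concept_id)
  if (length(unknown) > 0) {
    abort(paste0("counts name unknown concepts: ", paste(unknown, collapse = ", ")))
  }
  bad_exc <- setdiff(policy$exceptions, graph$nodes$concept_id)
  if (length(bad_exc) > 0) {
    abort(paste0("merge exceptions do not resolve: ", paste(bad_exc, collapse = ", ")))
  }

  nodes <- graph$nodes
  lexicon <- graph$lexicon
  cnt <- counts
  log <- tibble(concept_id = character(), merged_into = character())

  depth_of <- function(id) {
    d <- 0L
    cur <- id
    repeat {
      p <- nodes$parent_id[nodes$concept_id == cur]
      if (is.na(p)) return(d)
      d <- d + 1L
      cur <- p
    }
  }

  repeat {
    cand <- names(cnt)[
      names(cnt) %in% nodes$concept_id[nodes$is_label] &
        cnt <= policy$min_subject_count &
        !(names(cnt) %in% policy$exceptions)
    ]
    # skip candidates already reported unmergeable
    cand <- setdiff(cand, log$concept_id[is.na(log$merged_into)])
    if (length(cand) == 0L) break
    # deepest first so children accrue before their parent is judged
    cand <- cand[order(-vapply(cand, depth_of, integer(1)))]
    id <- cand[[1L]]
    parent <- nodes$parent_id[nodes$concept_id == id]
    target <- if (is.na(parent)) NA_character_ else resolve_to_label(graph_stub(nodes), parent)
    if (is.na(target)) {
      warn(paste0("label '", id, "' is low-frequency but has no labeled ancestor; retained"))
      log <- bind_rows(log, tibble(concept_id = id, merged_into = NA_character_))
      next
    }
    cnt[target] <- (if (target %in% names(cnt)) cnt[[target]] else 0) + cnt[[id]]
    cnt <- cnt[names(cnt) != id]
    nodes$is_label[nodes$concept_id == id] <- FALSE
    lexicon$concept_id[lexicon$concept_id == id] <- target
    log <- bind_rows(log, tibble(concept_id = id, merged_into = target))
  }

  out <- knowledge_graph(nodes, lexicon, graph$rules)
  retained <- intersect(names(cnt), out$nodes$concept_id[out$nodes$is_label])
  out$counts <- tibble(concept_id = retained, n_subjects = as.numeric(cnt[retained]))
  out$merge_log <- log
  out
}

# minimal graph-shaped wrapper so resolve_to_label can run on a working
# node table during merging
graph_stub <- function(nodes) structure(list(nodes = nodes), class = "knowledge_graph")

#' Export the node and lexicon tables of a graph as CSV
#'
#' @param graph A [knowledge_graph()].
#' @param dir Output directory (created if needed). Writes `nodes.csv` and
#'   `lexicon.csv`.
#' @return Invisibly, the paths written.
#' @export
export_graph_tables <- function(graph, dir) {
  stopifnot(inherits(graph, "knowledge_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    nodes = file.path(dir, "nodes.csv"),
    lexicon = file.path(dir, "lexicon.csv")
  )
  readr::write_csv(graph$nodes, paths[["nodes"]])
  readr::write_csv(graph$lexicon, paths[["lexicon"]])
  invisible(paths)
}
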
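#' Grammar configuration for synthetic report generation
#'
#' Controls the phrase grammar that writes synthetic radiology reports with
#' known ground truth: per-label prevalence, how often a true finding is
#' phrased as a hedge ("possible ...", "... not excluded"), how often an
#' absent finding is explicitly mentioned under a negation cue ("no ..."),
#' and an optional rate of hedged mentions of truly absent findings
#' (distractors for robustness testing; off by default so that hedges
#' always encode truth = 1 and the default `uncertain_as = "positive"`
#' mapping round-trips exactly).
#'
#' @param prevalence Per-label positive probability: scalar or named vector
#'   over leaf labels (default 0.15 for every label).
#' @param p_uncertain Probability a positive finding is phrased as
#'   uncertain (default 0.1).
#' @param p_negated_mention Probability an absent finding is explicitly
#'   negated in the text (default 0.3).
#' @param p_distractor Probability an absent finding appears as a hedged
#'   mention (default 0; breaks the exact round-trip by design when > 0).
#' @return List of class `grammar_config`.
#' @export
grammar_config <- function(prevalence = 0.15, p_uncertain = 0.1,
                           p_negated_mention = 0.3, p_distractor = 0) {
  probs <- c(p_uncertain, p_negated_mention, p_distractor, prevalence)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  structure(
    list(
      prevalence = prevalence, p_uncertain = p_uncertain,
      p_negated_mention = p_negated_mention, p_distractor = p_distractor
    ),
    class = "grammar_config"
  )
}

region_surface <- c(
  lung_parenchyma = "lung", mediastinum = "mediastinum",
  pleura = "pleural space", thoracic_wall = "chest wall"
)

#' Generate a synthetic report corpus with known ground truth
#'
#' Draws a binary truth matrix from the per-label prevalences and writes
#' one report per subject from sentence templates: positive findings use
#' rule-allowed phrasings (plain term, adjective + term, location +
#' adjective + term, or term + anatomical region), hedged positives use
#' uncertainty cues, and a configurable share of absent findings is
#' explicitly negated. Reports with no mentioned finding read "No abnormal
#' sign." Deterministic given the seed.
#'
#' @param graph A [knowledge_graph()] whose lexicon covers all leaf labels.
#' @param n Number of subjects.
#' @param config A [grammar_config()].
#' @param seed Integer seed.
#' @return List with `reports` (tibble `subject_id`, `exam_date`,
#'   `findings`, `impression`, `quality_flags`) and `truth` (label matrix).
#' @export
generate_reports <- function(graph, n, config = grammar_config(), seed = 1) {
  stopifnot(inherits(graph, "knowledge_graph"))
  ids <- label_ids(graph)
  prev <- config$prevalence
  if (length(prev) == 1L && is.null(names(prev))) {
    prev <- setNames(rep(prev, length(ids)), ids)
  }
  if (!all(ids %in% names(prev))) abort("prevalence must cover every leaf label")
  prev <- prev[ids]

  # surface forms usable for each label: feature terms resolving to it
  feat <- graph$lexicon %>% filter(category == "feature_name")
  feat$label <- vapply(feat$concept_id, function(id) {
    resolve_to_label(graph, id) %||% NA_character_
  }, character(1))
  surfaces <- split(feat$surface_form, feat$label)
  missing <- setdiff(ids, names(surfaces))
  if (length(missing) > 0L) {
    abort(paste0("lexicon does not cover label(s): ", paste(missing, collapse = ", ")))
  }
  locs <- c("left", "right", "bilateral", "upper", "lower")
  adjs <- c("large", "dense", "faint", "prominent", "scattered", "multiple", "extensive")
  cap <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))
  regions <- region_of_label(graph, ids)

  with_seed_local(seed, {
    truth <- matrix(
      rbinom(n * length(ids), 1L, rep(prev, each = n)),
      nrow = n, dimnames = list(NULL, ids)
    )
    pos_sentence <- function(lab) {
      term <- sample(surfaces[[lab]], 1L)
      switch(sample.int(4L, 1L),
        cap(term),
        cap(paste(sample(adjs, 1L), term)),
        cap(paste(sample(locs, 1L), sample(adjs, 1L), term)),
        cap(paste0(term, " in the ", sample(locs, 1L), " ",
                   region_surface[[regions[match(lab, ids)]]]))
      )
    }
    unc_sentence <- function(lab) {
      term <- sample(surfaces[[lab]], 1L)
      switch(sample.int(3L, 1L),
        cap(paste("possible", term)),
        cap(paste(term, "not excluded")),
        cap(paste("suspected", term))
      )
    }
    neg_sentence <- function(lab) cap(paste("no", sample(surfaces[[lab]], 1L)))

    findings <- character(n)
    for (i in seq_len(n)) {
      sent <- character()
      for (j in seq_along(ids)) {
        if (truth[i, j] == 1L) {
          sent <- c(sent, if (runif(1) < config$p_uncertain) {
            unc_sentence(ids[j])
          } else {
            pos_sentence(ids[j])
          })
        } else if (runif(1) < config$p_distractor) {
          sent <- c(sent, unc_sentence(ids[j]))
        } else if (runif(1) < config$p_negated_mention) {
          sent <- c(sent, neg_sentence(ids[j]))
        }
      }
      if (length(sent) == 0L) sent <- "No abnormal sign"
      findings[i] <- paste0(paste(sample(sent), collapse = ". "), ".")
    }
    reports <- tibble(
      subject_id = sprintf("s%04d", seq_len(n)),
      exam_date = as.Date("2014-01-01") + sample.int(1460, n, replace = TRUE) - 1L,
      findings = findings,
      impression = ifelse(
        rowSums(truth) > 0, "Abnormal chest radiograph.", "Normal chest radiograph."
      ),
      quality_flags = ""
    )
    truth_tbl <- build_label_matrix(
      bind_cols(tibble(subject_id = reports$subject_id), as_tibble(truth)),
      graph
    )
    list(reports = reports, truth = truth_tbl)
  })
}

#' Generate classifier scores with specified per-label AUC (binormal model)
#'
#' For each label, negatives draw from a standard normal and positives from
#' `N(mu, 1)` with `mu = sqrt(2) * qnorm(auc)`, so the expected
#' Mann-Whitney AUC equals the target. The latent scores are squashed to
#' `[0, 1]` by the logistic function, which preserves ranks and therefore
#' the AUC.
#'
#' @param truth Label matrix (ground truth) from [build_label_matrix()] or
#'   [generate_reports()].
#' @param auc Target AUC in `[0.5, 1)`: scalar or named per-label vector.
#' @param seed Integer seed.
#' @return A `score_matrix` aligned with `truth`.
#' @examples
#' g <- load_ontology()
#' rep <- generate_reports(g, 50, seed = 1)
#' sc <- generate_scores(rep$truth, auc = 0.9, seed = 2)
#' @export
generate_scores <- function(truth, auc = 0.866, seed = 1) {
  vals <- matrix_values(truth)
  labs <- colnames(vals)
  if (length(auc) == 1L && is.null(names(auc))) {
    auc <- setNames(rep(auc, length(labs)), labs)
  }
  if (!all(labs %in% names(auc))) abort("auc must cover every label")
  auc <- auc[labs]
  if (any(auc < 0.5 | auc >= 1)) abort("target AUC must lie in [0.5, 1)")
  n <- nrow(vals)
  with_seed_local(seed, {
    mu <- sqrt(2) * qnorm(auc)
    z <- matrix(rnorm(n * length(labs)), n) + sweep(vals, 2, mu, `*`)
    score_matrix(truth$subject_id, plogis(z))
  })
}

# relative frequency profile of the 25 signs used by the fixture scenarios;
# scaled so the fraction of subjects with >= 1 sign hits a target
fixture_weights <- function(ids) {
  w <- c(
    consolidation = 0.8, small_consolidation = 0.4, patchy_consolidation = 0.5,
    nodule = 0.8, calcification = 0.7, mass = 0.1, interstitial_disease = 0.25,
    cavity = 0.03, hilar_adenopathy = 0.2, emphysema = 0.25,
    pulmonary_edema = 0.05, thickened_bronchovascular_markings = 1.0,
    cardiomegaly = 0.5, abnormal_aorta = 0.3, aortic_unfolding = 0.4,
    aortic_arteriosclerosis = 0.5, pneumothorax = 0.08, pleural_effusion = 0.4,
    abnormal_pleura = 0.2, pleural_thickening = 0.4, pleural_adhesion = 0.3,
    pleural_calcification = 0.15, scoliosis = 0.3, picc_implant = 0.05,
    pacemaker_implant = 0.05
  )
  if (!setequal(ids, names(w))) {
    # custom graphs: fall back to a uniform profile
    w <- setNames(rep(1, length(ids)), ids)
  }
  w[ids]
}

# scale weights so that 1 - prod(1 - s*w) = target under independence
scale_prevalence <- function(w, target) {
  f <- function(s) 1 - prod(1 - s * w) - target
  upper <- 0.999 / max(w)
  if (f(upper) < 0) abort("target positive fraction is unattainable for this profile")
  s <- stats::uniroot(f, c(1e-9, upper), tol = 1e-12)$root
  s * w
}

#' Build a self-contained synthetic fixture on disk
#'
#' Generates a report corpus, its ground-truth label matrix and a binormal
#' score matrix for one of three scenarios, and writes them in the formats
#' the rest of the toolchain consumes (`reports.jsonl`, `reports.csv`,
#' `truth.csv`, `scores.csv`, `summary.json`).
#'
#' Scenarios mirror the study populations: `"screening"` (n = 2130, about
#' 9.7% of subjects with at least one abnormal sign), `"symptomatic"`
#' (n = 5996, about 44.8% positive subjects), and `"tiny"` (n = 20, about
#' 45% positive) for fast end-to-end runs. Per-label prevalences follow a
#' fixed relative-frequency profile scaled to the scenario's
#' positive-subject fraction.
#'
#' @param scenario One of `"tiny"`, `"screening"`, `"symptomatic"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param graph A [knowledge_graph()] (default packaged ontology).
#' @param n Number of subjects; `NULL` uses the scenario default.
#' @param auc Target per-label AUC for the simulated scores (default
#'   0.866).
#' @return List with the generated `reports`, `truth`, `scores`, the
#'   scenario parameters, and the `paths` written.
#' @export
make_fixture <- function(scenario = c("tiny", "screening", "symptomatic"),
                         seed = 1, dir = tempfile("fixture"),
                         graph = load_ontology(), n = NULL, auc = 0.866) {
  scenario <- arg_match(scenario)
  defaults <- list(
    tiny = list(n = 20L, target = 0.45),
    screening = list(n = 2130L, target = 0.097),
    symptomatic = list(n = 5996L, target = 0.448)
  )[[scenario]]
  n <- n %||% defaults$n
  ids <- label_ids(graph)
  prev <- scale_prevalence(fixture_weights(ids), defaults$target)
  cfg <- grammar_config(prevalence = prev)
  gen <- generate_reports(graph, n, cfg, seed = seed)
  scores <- generate_scores(gen$truth, auc = auc, seed = seed + 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    reports_jsonl = file.path(dir, "reports.jsonl"),
    reports_csv = file.path(dir, "reports.csv"),
    truth = file.path(dir, "truth.csv"),
    scores = file.path(dir, "scores.csv"),
    summary = file.path(dir, "summary.json")
  )
  write_reports_jsonl(gen$reports, paths[["reports_jsonl"]])
  write_reports_csv(gen$reports, paths[["reports_csv"]])
  readr::write_csv(gen$truth, paths[["truth"]])
  readr::write_csv(scores, paths[["scores"]])
  summ <- summarize_cohort(gen$truth)
  jsonlite::write_json(
    list(
      scenario = scenario, n = n, seed = seed, target_auc = auc,
      target_positive_fraction = defaults$target,
      positive_fraction = summ$n_positive_subjects / summ$n_total,
      per_label_prevalence = as.list(setNames(round(prev, 6), ids))
    ),
    paths[["summary"]], auto_unbox = TRUE, digits = NA
  )
  list(
    reports = gen$reports, truth = gen$truth, scores = scores,
    scenario = scenario, prevalence = prev, paths = paths
  )
}
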
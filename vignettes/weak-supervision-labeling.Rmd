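---
title: "Weakly supervised sign labeling of chest X-ray reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised sign labeling of chest X-ray reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radlabel)
library(dplyr)
```

## The problem

Training image classifiers for chest radiographs (CXR) at scale requires
labels for tens of thousands of studies, far beyond what expert annotation
can supply. Weak supervision sidesteps this by mining the free-text
radiology report that accompanies every study: if the report asserts a
finding, the image is labeled positive for it. `radlabel` implements such a
report-mining pipeline around a curated knowledge graph of radiological
concepts, along with the downstream machinery a study of this kind needs —
cohort assembly, a cross-validation harness, multi-label diagnostic
evaluation, and an anatomical color encoding for embedding plots — plus
synthetic report and score generators so the whole chain is testable
without any clinical data.

## The sign ontology

The packaged ontology defines 25 binary abnormal-sign labels partitioned
over four anatomical regions: 12 lung-parenchyma signs (consolidation,
small consolidation, patchy consolidation, nodule, calcification, mass,
interstitial disease, cavity, hilar adenopathy, emphysema, pulmonary edema,
thickened bronchovascular markings), 4 mediastinal signs (cardiomegaly,
abnormal aorta, aortic unfolding, aortic arteriosclerosis), 6 pleural signs
(pneumothorax, pleural effusion, abnormal pleura, pleural thickening,
pleural adhesion, pleural calcification) and 3 thoracic-wall signs
(scoliosis, PICC implant, pacemaker implant).

```{r}
g <- load_ontology()
count(graph_labels(g), region)
```

Concept nodes form a forest rooted at the four regions; labels may nest
(e.g. *small consolidation* under *consolidation*, the two aortic-arch
calcification variants under *aortic arteriosclerosis*). The lexicon maps
surface forms — synonyms, parasynonyms, descriptive phrases — onto
concepts, in one of exactly four linguistic entity categories: anatomical
region, lesion location, image feature name, image feature adjective. The
packaged synonym lists are this package's own curation; a study would
replace them with lexicon rows mined from its corpus. Relations between
entity mentions are restricted by a rule table over category pairs: a
region may relate to a feature name ("consolidation ... lung"), a location
or adjective may modify a feature name ("left large consolidation"), but a
region–adjective pair carries no radiological meaning and is never linked.
The table is total over ordered pairs and user-overridable in the ontology
file.

### Frequency-based merging

Rare labels cannot support a binary classifier, so labels observed in too
few subjects are folded into their nearest labeled ancestor:
`merge_low_frequency()` retains a label only when its per-subject count
strictly exceeds the policy threshold (default 50 — "more than 50
subjects"), merges its counts and lexicon entries upward otherwise, and
exempts the concepts in the policy's exception set (default `cavity`, rare
but clinically important). Counts are per subject, not per mention; merging
is idempotent and conserves total subject counts. A low-frequency label
with no labeled ancestor is retained with a warning rather than dropped.

## The labeling pipeline

`label_report()` composes five deterministic steps:

1. **Segmentation.** Findings and impression are concatenated (findings
   first) and split on a configurable delimiter set (default `.`, `?`, `;`,
   newline).
2. **Entity recognition.** The default recognizer is case-insensitive
   longest-match lexicon lookup on word boundaries, resolving overlaps in
   favor of the longest match so "pleural thickening" wins over "pleura".
   This is a pluggable contract: a learned (e.g. transformer-based) tagger
   can replace it as long as it emits the same mention table. We chose the
   deterministic matcher as the default because it needs no model weights
   and makes the pipeline's behavior exactly reproducible.
3. **Polarity.** Each mention is classified negative ("no abnormal sign"),
   positive, or uncertain ("possible", "not excluded") from cue words in
   the same comma/conjunction-delimited segment. Uncertainty cues outrank
   negation cues — "not excluded" contains the token "not" and must not
   read as a negation. The classifier is a pure function of the sentence
   and the cue lists.
4. **Relation extraction.** Each feature-name mention anchors at most one
   tuple; co-sentence mentions join it only when the category pair is
   rule-allowed. The tuple inherits the feature mention's polarity.
5. **Label mapping.** Tuples resolve up the hierarchy to the nearest leaf
   label. Positive tuples set the label; uncertain tuples follow
   `uncertain_as` (default `"positive"`, a screening-oriented choice that
   turns hedged findings into weak positive training labels — the mapping
   of hedges to binary labels is genuinely open, so it is a config switch);
   negatives never set a label; conflicting polarities within a report
   resolve to positive.

Reports flagged as mobile radiographs, insufficient quality or incomplete
are excluded (`apply_exclusions()`), and multiple exams per subject reduce
to the earliest (`deduplicate_earliest()`, stable on ties). The working
language of the packaged lexicon and grammar is English; the matcher is
encoding-agnostic, so a lexicon in another language can be supplied.

## Training harness

The original study trained deep image classifiers; that is out of scope
here. The harness keeps the statistical scaffolding and accepts any
classifier over tabular features through a two-function contract
(`fit(x, y, weights)` / `predict_prob(model, x)`), with a weighted logistic
regression as the reference implementation so tests run in seconds.

* **Loss.** `weighted_bce()` is the class-weighted binary cross-entropy;
  `default_weights()` supplies the balanced heuristic
  `w_pos = N / (2 N_pos)`, `w_neg = N / (2 N_neg)` (the exact weighting
  formula is unspecified in the source material, so the balanced form is
  the package default and overridable).
* **Folds.** `stratified_kfold()` implements iterative multi-label
  stratification, processing labels rarest-first and assigning each
  positive subject to the fold with the greatest remaining demand for that
  label. With k = 5 each fold's complement is the 80% training split. All
  randomness flows through one seed.
* **Models.** `train_two_way_models()` fits one independent binary model
  per label per fold (25 two-way models per fold); out-of-fold predictions
  assemble into a score matrix and, for held-out data, the per-fold models'
  mean probability (`ensemble_mean()`) is the committee prediction. A
  single multi-head model is a plausible alternative reading of the
  original design; independent two-way models were chosen because they
  match the stated "two-way classification models" and keep labels
  decoupled.

## Evaluation statistics

* **AUC** is the Mann–Whitney estimator with half-credit ties, which
  equals the trapezoidal area under the empirical ROC; both routes are
  tested against each other to 1e-12.
* **Thresholds.** `f1_max_threshold()` scans every distinct score value
  with the rule *positive iff score ≥ t* and returns the F1-maximizing
  threshold (ties to the smallest threshold); sensitivity/specificity/
  accuracy are reported at that threshold.
* **Confidence intervals.** `bootstrap_ci()` follows the literal recipe of
  100 iterations each resampling 95% of the subjects, percentile 2.5/97.5
  endpoints. Drawing 95% *without* replacement (the default, matching the
  recipe's wording) yields replicate spread governed by the finite-
  population correction, about 23% of the estimator's sampling SD, so
  these intervals are descriptive of resampling stability rather than
  calibrated frequentist CIs. The `replace = TRUE` mode is a conventional
  bootstrap at the same replicate size and attains nominal coverage
  (measured ≈ 0.94–0.95 for an AUC at n = 2000); calibration claims in the
  test suite are asserted on that mode.
* **DeLong's test** compares two correlated AUCs via per-subject
  structural components; it agrees with an independent implementation and
  with a paired permutation oracle, and its null rejection rate at
  α = 0.05 is ≈ 0.05. A single positive or negative contributes no
  estimable variance; a zero-variance difference returns p = 1 when the
  AUCs are equal and is flagged degenerate otherwise. Per-label tests are
  reported without multiplicity correction by default (mirroring common
  practice for descriptive per-label tables), with `p_adjust` available.
* **Binary raters** trace a one-point ROC; `radiologist_auc()` returns
  `(sensitivity + specificity)/2`, which equals the Mann–Whitney AUC of
  the binary reads, so a read vector can also enter DeLong directly.
* **Concordance.** `concordance()` counts per-subject label agreements
  (absent signs agree as negatives) and reports the fraction of subjects
  with at least 22 of 25 concordant labels, the 88% working definition of
  a correctly read study.

## Color-index encoding

For embedding plots, a subject's 25 signs collapse to four bits — any
abnormality in thoracic wall, mediastinum, lung parenchyma, pleura — and
the color index `CI = y_th·8 + y_me·4 + y_lp·2 + y_pl·1` ∈ [0, 15].
Normal subjects code as 0; single-region abnormalities as 8, 4, 2, 1; and
multi-region subjects as the sum:

```{r}
v <- setNames(rep(0L, 25), label_ids(g))
v[c("cardiomegaly", "nodule")] <- 1L   # mediastinum + lung parenchyma
color_index(region_onehot(v, g))
```

The encoding is bijective (`decode_color_index()`) and invariant to which
leaf within a region is positive. Dimensionality reduction itself (t-SNE,
UMAP) is delegated; `export_embedding_table()` prepares the input/output
table.

## Synthetic data: what it does and does not emulate

`generate_reports()` draws a truth matrix from per-label prevalences and
phrases it through a small grammar: positive findings as rule-allowed
patterns (plain term, adjective + term, location + adjective + term, term +
region), hedged positives under uncertainty cues, and a configurable share
of absent findings explicitly negated. Hedged phrasing encodes truth = 1 by
default, so extraction with `uncertain_as = "positive"` round-trips
exactly; `p_distractor > 0` adds hedged mentions of absent findings for
robustness testing. `generate_scores()` is a binormal ROC model — negatives
standard normal, positives shifted by `mu = sqrt(2) * qnorm(AUC)`, squashed
to [0, 1] by the logistic (rank-preserving, hence AUC-preserving).

`make_fixture()` bundles three scenarios: `tiny` (n = 20, for fast
end-to-end runs), `screening` (n = 2130, ≈ 9.7% of subjects with ≥ 1 sign)
and `symptomatic` (n = 5996, ≈ 44.8%), mirroring the screening and
symptomatic cohort compositions of the motivating study. Per-label
prevalences follow a fixed relative-frequency profile (common signs like
thickened bronchovascular markings and consolidation weighted high, rare
ones like cavity and edema low, reflecting their relative frequency in
routine CXR reporting) scaled so that independent Bernoulli draws hit the
scenario's positive-subject fraction.

The grammar emulates sentence-level structure, synonym variation, negation
and hedging. It does **not** emulate long-range discourse (anaphora,
comparisons to priors), misspellings, reporting templates that mix
languages, or label correlations (signs are drawn independently). A 100%
round-trip on synthetic corpora therefore demonstrates internal consistency
of the grammar–extractor pair, not extraction accuracy on real reports,
which depends on lexicon coverage of the local reporting style.

## Numerical choices and problem sizes

Probabilities entering the cross-entropy are clipped at 1e-12. Score ties
get half credit in the AUC and mid-rank treatment throughout. F1 threshold
ties break toward the smallest threshold; the decision rule is `≥`. Fold
assignment, report generation, score generation and resampling are all
deterministic given their seed arguments, and seeds are restored on exit so
library calls never disturb the caller's RNG stream. The test suite runs
its round-trip property at 1000 reports, oracle comparisons at 100 random
instances, DeLong calibration at 1000 null simulations of n = 200, and
parameter-recovery at n = 2000 with 50 replicate runs per target AUC —
sizes chosen to keep Monte-Carlo error well below the asserted tolerances
while completing in a few minutes on one CPU.

## Known limitations

* Entity recognition is exact lexicon matching; terms outside the lexicon
  are invisible, and there is no spelling correction.
* Negation/uncertainty scope is segment-based, not parse-based; unusual
  constructions ("no evidence of A but B is present" within one segment)
  can mis-scope.
* The merge policy assumes the concept forest encodes clinically sensible
  fallback labels; merging across regions is impossible by construction.
* The 95%-subsample CIs (default mode) understate sampling variability by
  design of the recipe they follow; use `replace = TRUE` when calibrated
  coverage matters.
* Real-cohort performance tables of the motivating study require its
  private images and external test data and are out of scope here.
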
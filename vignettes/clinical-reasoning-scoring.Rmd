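---
title: "Scoring clinical-reasoning documentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring clinical-reasoning documentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crscore)
```

## The scoring problem

Admission notes document a clinician's diagnostic reasoning. The
Revised-IDEA rubric grades that documentation; `crscore` automates two
of its components:

* **D (differential diagnosis), scored 0–2.** A note earns D2 when it
  names at least two *specific* diagnoses (not diagnostic categories
  such as "cardiac") and explicitly prioritizes among them; D0 when it
  has fewer than two unique diagnoses; D1 otherwise.
* **EA (explanation of reasoning), scored 0–2, modelled as the binary
  EA2-vs-not target.** EA2 means the reasoning for lead and
  alternative diagnoses is explained with supporting data.

Two model families implement the scoring:

1. **NER + logic.** A span-level recognizer tags five entity types —
   `Dx` (diagnosis), `DC` (diagnostic category), `Prior`
   (prioritization language), `Data` (supporting clinical data) and
   `Link` (linkage terms) — and a deterministic rule maps the entity
   counts to a D score:

   $$
   D = \begin{cases}
     0 & \#\{\text{unique Dx}\} < 2\\
     2 & \#\{\text{unique Dx}\} \ge 2 \;\wedge\; \#\text{Prior} \ge 1\\
     1 & \text{otherwise.}
   \end{cases}
   $$

2. **One-vs-rest classifiers.** Binary note classifiers for D0, D2 and
   EA2. The three-level D score is recovered by the ordered stepwise
   rule — if the D0 model fires, D = 0; else if the D2 model fires,
   D = 2; else D = 1 — because a direct D1 model is structurally weak:
   D1 is "everything else", not a positive concept. EA is collapsed to
   EA2-vs-not (EA0 and EA1 merge at training time) for the same reason.

Real admission notes are protected health information, so the package
ships a synthetic-note generator that produces gold-annotated
assessment-section prose; every pipeline, test and benchmark runs on
it.

## Dx uniqueness and other logic conventions

* **Uniqueness** of diagnoses is equality of *normalized surface
  forms*: Unicode case-folding, stripping of leading/trailing
  punctuation, collapsing of internal whitespace
  (`normalize_dx_form()`). No ontology merging is attempted — "CHF"
  and "congestive heart failure" count as two diagnoses. A
  `synonym_map` argument exposes merging for users who want it, off by
  default, because any fixed synonym table would silently change
  scores.
* The D2 condition is read as *at least* two unique diagnoses; a
  strict "exactly two" reading would leave three-diagnosis notes
  unscorable.
* **Explicit prioritization** means at least one `Prior` span anywhere
  in the note; no positional relationship to the `Dx` spans is
  required.
* `ea_score_from_entities()` encodes the package's **EA convention**:
  a `Dx` mention counts as *explained* when its sentence (delimited by
  `.`, `!`, `?`) contains at least one `Data` and one `Link` span; EA
  is the number of explained mentions capped at 2. This is a generator
  convention — the rubric's EA semantics operationalized on entities —
  not a validated clinical rule; it exists so that EA labels are
  well-defined, learnable and consistent between the generator and
  any scorer.

## The synthetic-note generator

`generate_corpus()` draws per-note (D, EA) targets from configurable
class proportions and realizes each target by construction:
evidence-bearing sentences (`Data` + `Link` + `Dx`), plain mention
sentences, prioritization sentences, diagnostic-category sentences and
distractor sentences assembled from packaged lexicons (about 100
diagnoses, 12 category words, 10 prioritization phrases, 40 data
phrases, 15 linkage phrases). Defaults:

* `d_proportions = c(109, 154, 437)/700` and
  `ea_proportions = c(73, 255, 372)/700` — the class mix of the
  retrospective development note set the generator emulates.
* `noise = 0` — the "easy" regime. Noise is character-level
  substitution/recasing at the given rate, outside gold spans by
  default; `noise_in_spans = TRUE` gives the "hard" regime in which
  entity surfaces themselves are corrupted and dictionary lookup
  degrades.
* Gold labels are *computed from the gold spans* by the same
  `d_score_from_entities()` / `ea_score_from_entities()` used at
  scoring time, so label/logic consistency holds by construction and
  is still checked exhaustively in the tests.

Key invariants of the easy regime: the five lexicons are pairwise
disjoint, no phrase is a word-boundary substring of another, and
template glue words never collide with lexicon words — so every gold
surface occurs in exactly one lexicon and a dictionary tagger is a
perfect oracle there.

What the generator does **not** emulate: clinically realistic prose,
negation and uncertainty ("no evidence of PE"), abbreviation ambiguity,
cross-sentence reasoning, site-specific templating, or de-identification
artifacts. Passing benchmarks on synthetic corpora therefore
demonstrates that the machinery is correct and learnable signal is
recovered — not that these accuracy levels transfer to real notes,
where reported performance is far from ceiling.

## Preprocessing

`truncate_assessment()` extracts the span from the first
assessment-section header ("assessment", "assessment and plan", "a/p",
"impression", case-insensitive at line start) to the first plan marker
("plan:" or a numbered-list start). Institutions template notes
differently, so header and plan vocabularies are per-site *dialects*
(`truncation_dialects()`), editable in configuration; the shipped
`nyu`/`uc` tables are plausible seeds to be revised against local
conventions, not faithful reconstructions of any institution's rules.
When nothing matches, the whole note is returned and flagged
(`fallback_whole_note`) — silent truncation failures would bias D
scores downward. The output is always a contiguous substring; offsets
are returned so downstream spans can be mapped back.

## The reference tagger

`train_tagger()` is a deliberately desk-scale recognizer: per-token
multinomial logistic regression (ridge, `glmnet`) over BIO-encoded
labels with window features — lowercased token, collapsed shape,
neighbours at distance 1–2, boundary bigrams, and gazetteer membership
flags derived from the packaged lexicon word lists. Spans decode from
maximal same-type tag runs; contiguous same-type runs merge (under
overlap-based Type matching this never hurts); overlapping spans are
resolved longest-first, ties to the earlier start. The recognizer
*contract* — train on gold spans, emit valid, non-overlapping, sorted
spans — is the stable surface; an embedding-based or transformer
tagger can replace the implementation without touching the pipeline.

Numerical notes: prediction uses the smallest fitted penalty
(`lambda = 0.01` by default); BIO classes observed on a single
training token are folded into `O` (they cannot be fit, let alone
cross-validated) with a warning; training is deterministic given the
seed.

## Classifiers

The reference backend (`bow_glmnet`) is elastic-net logistic
regression over a bag-of-words feature map: unigram and token-bigram
counts, binary presence indicators, and pooled gazetteer counts
(total, distinct and repeated lexicon-class tokens per entity class).
The pooled block exists because of a concrete failure mode: with ~100
diagnosis phrases and a few hundred training notes, each diagnosis
word occurs a handful of times, so no per-word weight can be estimated
reliably, and plain BoW cannot separate "one diagnosis repeated" from
"two distinct diagnoses" — the exact D0-vs-rest boundary. Pooling
turns "how many distinct diagnosis words" into a single dense feature.
Backends are registered by name (`register_backend()`), so heavier
models slot in behind the same `train_ovr()`/`predict()` surface.

Training options mirror a low-resource fine-tuning recipe:

* **Runtime augmentation** (`augment_params()`): synonym replacement,
  random insertion, random swap — 15 words each by default — then
  per-word deletion at 15%. The four operations apply in that fixed
  order (the recipe lists them without an order; fixing one keeps runs
  reproducible), counts cap at the number of eligible words, and
  synonyms come from the packaged table so no download is needed.
  Augmented text loses character offsets, so augmentation only ever
  touches classifier training text, never span-annotated text.
* **Oversampling** (`oversample_indices()`): draws with replacement,
  each example weighted by the inverse frequency of its class, which
  equalizes expected per-class mass exactly.
* **Operating points** (`select_threshold()`): exhaustive search over
  the unique observed scores for the threshold maximizing F1 of the
  positive class (Youden's J available via `criterion`), ties broken
  toward the higher threshold; predictions use `score >= threshold`.
  The threshold stored at training time is fit on training scores;
  `set_threshold()` refits it on held-out data, which is what an
  honest operating point requires.

## Evaluation harness

* **Type matching** (`match_type()`): a predicted span is credited
  when its type equals the gold type and the character intervals
  overlap by at least one character; the gold–prediction assignment is
  one-to-one. The assignment is computed as a *maximum* bipartite
  matching per type (augmenting paths seeded in left-to-right gold
  order with ties to the larger overlap). A purely greedy pass can
  strand a matchable pair — gold A overlapping predictions 1 and 2 can
  consume the only prediction that gold B overlaps — and the tests
  hold the matcher to an exhaustive-search oracle, so optimality is a
  requirement, not an optimization.
* **F1 conventions** (`ner_f1()`): P = correct/(correct+spurious),
  R = correct/(correct+missing). A type with neither gold nor
  predicted spans scores 1.0 (vacuous truth); the `support` column is
  always reported so such types are visible.
* **AUROC** is the midrank (Mann–Whitney) statistic — ties count 1/2 —
  hence invariant under strictly monotone transforms. **AUPRC** is
  step-wise average precision over descending unique thresholds, with
  no linear interpolation between PR points; tied scores enter as a
  block, making the result order-independent.
* **Cross-validation** (`cross_validate()`): stratified folds (within
  each class, shuffled items are dealt round-robin from a random
  starting fold, so per-fold class counts differ by at most 1); the
  trainer receives only the training folds by construction. Across-fold
  CIs are mean ± t(0.975, k−1)·SE; single-set CIs use a seeded
  percentile bootstrap (2,000 resamples by default). Both are provided
  because reported CIs in this literature rarely state which was used.
* **ICC** (`icc_consistency()`): single-rater, two-way mixed-effects
  consistency form, (MS_S − MS_E)/(MS_S + (k−1)MS_E), with the
  F-distribution CI; the absolute-agreement variant is available via
  `type = "agreement"`. A constant-subject matrix raises an error
  rather than returning a meaningless value.

## Problem sizes

The shipped tests and the acceptance script run at deliberate desk
scale: corpora of 600 notes (480/120 train/test splits) for the
end-to-end benchmarks, 1,000 notes for label-consistency and
distributional checks, 300 notes for the 10-fold CV demonstration, a
76-note two-rater matrix for ICC. These sizes give stable metrics for
a package demonstration while keeping the full suite fast on a single
CPU.

## Known limitations

* Synthetic prose is templated; none of the benchmark numbers are
  claims about real admission notes.
* The EA convention is the package's own operationalization; EA gold
  labels on real data would come from human raters.
* Truncation dialects are seeds, not reconstructions of institutional
  truncation rules.
* The D logic counts surface-normalized diagnoses; true synonym
  merging would need an ontology and is deliberately out of scope.
* The reference tagger and classifier backends are linear models; they
  are contracts plus honest baselines, not competitors to pretrained
  clinical language models.
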
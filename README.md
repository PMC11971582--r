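# crscore

Automated scoring of clinical-reasoning documentation quality in
hospital admission notes.

Medical educators rate how well trainees document diagnostic reasoning
using the Revised-IDEA rubric. `crscore` automates two of its
components for the assessment section of an admission note:

* **D score (0–2)** — does the note contain an explicitly prioritized
  differential with *specific* diagnoses? D0: fewer than 2 unique
  diagnoses; D2: ≥ 2 unique diagnoses plus prioritization language;
  D1: everything else. Diagnostic categories ("cardiac") never count.
* **EA score**, modelled as the binary **EA2 vs not-EA2** target —
  is the reasoning for lead and alternative diagnoses explained with
  supporting data?

Two routes are implemented end to end:

1. **NER + logic**: a trainable span recognizer for five rubric entity
   types — `Dx`, `DC`, `Prior`, `Data`, `Link` — followed by the
   deterministic rule
   `D = 0 if #unique(Dx) < 2; 2 if #unique(Dx) >= 2 and #Prior >= 1; 1 otherwise`.
2. **One-vs-rest classifiers** for D0, D2 and EA2 (pluggable backends;
   the reference backend is elastic-net logistic regression over
   bag-of-words features), with runtime text augmentation,
   inverse-class-frequency oversampling, F1-maximizing threshold
   selection, and the stepwise composition
   `D0 positive → 0; else D2 positive → 2; else 1`.

The evaluation harness covers SemEval-2013 Task 9 *Type* NER matching
(type equality + character overlap, one-to-one), per-class D F1,
AUROC/AUPRC with bootstrap or across-fold CIs, leakage-free stratified
k-fold cross-validation, and two-way mixed-effects intraclass
correlation for inter-rater reliability.

Real admission notes are protected health information, so the package
includes a seeded synthetic-note generator (`generate_corpus()`) that
emits assessment-section prose with gold entity spans and gold D/EA
labels; all tests and benchmarks run on it. See the vignette
(`vignettes/clinical-reasoning-scoring.Rmd`) for the full methods
account.

## Worked example

```r
library(crscore)

corpus <- generate_corpus(generator_config(200, seed = 42))
cat(corpus[[1]]$text)
#> this presentation appears endocrine in origin. exam and labs show
#> hyperbilirubinemia, attributable to melanoma. admitted overnight.
corpus[[1]]$spans
#>   start end etype            surface
#> 1    26  35    DC          endocrine
#> 2    66  84  Data hyperbilirubinemia
#> 3    86 101  Link    attributable to
#> 4   102 110    Dx           melanoma
d_score_from_entities(corpus[[1]]$spans)
#> D0 (1 unique dx, 0 prior, 1 category)
```

One diagnosis ("melanoma") plus a category word gives D0: categories
are not diagnoses, and a single diagnosis cannot form a differential.

Train the reference tagger and score the NER → logic pipeline on a
held-out split:

```r
tagger <- train_tagger(corpus[1:160], seed = 1)
test   <- corpus[161:200]
f1 <- ner_f1(lapply(test, function(n)
  match_type(n$spans, predict_entities(tagger, n$text))))
f1[, 1:4]
#>   etype precision recall f1
#> 1    Dx         1      1  1
#> ...
#> 6 micro         1      1  1

scored <- score_corpus_d(tagger, test)
d_class_f1(scored$d_score, scored$d_gold)
#>   class precision recall f1 support
#> 1    D0         1      1  1       4
#> 2    D1         1      1  1      10
#> 3    D2         1      1  1      26
#> 4 macro         1      1  1      40
```

In the default noise-free ("easy") regime the lexicons are disjoint
and the tagger reaches ceiling; the hard regime
(`generator_config(..., noise = 0.12, noise_in_spans = TRUE)`)
corrupts entity surfaces and separates the trained tagger from the
dictionary baseline.

Classifier route with stepwise D composition:

```r
m0 <- train_ovr(corpus[1:160], "D0", seed = 1)
m2 <- train_ovr(corpus[1:160], "D2", seed = 1)
head(predict_stepwise_d(m0, m2, test), 3)
#>      note_id     d0_score    d2_score d_pred
#> 1 note_00161 0.7175954323 0.002700211      0
#> 2 note_00162 0.1067143408 0.861574501      2
#> 3 note_00163 0.0006571299 0.999978715      2
```

Inter-rater reliability from a subjects × raters matrix:

```r
icc_consistency(cbind(c(0,1,2,1,0,2,1), c(0,1,2,2,0,2,1)))
#> ICC(consistency, single rater) = 0.903 [0.543, 0.983], 7 subjects x 2 raters
```

## Command line

A thin CLI over the same functions ships at `inst/cli/crscore`:

```sh
Rscript inst/cli/crscore generate --n 500 --seed 7 --out corpus.jsonl
Rscript inst/cli/crscore train-ner --in corpus.jsonl --seed 7 --out ner_model
Rscript inst/cli/crscore score-d --model ner_model --in corpus.jsonl --out scores.csv
Rscript inst/cli/crscore icc --ratings ratings.csv
```

Corpora are JSONL (one note per line, 0-based half-open span offsets);
reports are CSV. Every command accepts `--seed` and is byte-reproducible
given it.

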
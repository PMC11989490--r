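---
title: "From discharge reports to AF-onset predictor vectors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From discharge reports to AF-onset predictor vectors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afdebut)
```

## The problem

Predictive models of atrial-fibrillation (AF) recurrence are typically fed
from a hospital's structured coding system. Coded data are noisy in two
directions: a substantial fraction of instances coded as new-onset AF are
false positives (previous diagnoses, miscoding), a comparable fraction of
true onsets never get coded at all, and many predictor variables are simply
missing from the structured record even though they are written in the
free-text discharge report. `afdebut` implements the complementary
text-mining route: it turns unstructured discharge reports into
patient-level predictor vectors anchored on the AF debut date, and it
reconciles text-detected AF onsets with coded ones so that a classifier can
be trained on labels of controllable specificity.

The pipeline has six processing stages, each exposed as ordinary functions
and exercised end-to-end by `run_pipeline()`:

1. **Sectioning** (`segment()`) — every report is split into the nine
   standardized discharge-report sections (Header, Reason for Consultation,
   Personal History, Current Illness, General Exploration, Complementary
   Tests, Diagnosis, Treatment, Evolution) plus `Unknown`.
2. **Negation detection** (`is_negated()`) — NegEx-style trigger/scope
   rules decide whether a candidate mention is asserted absent.
3. **Extraction** (`extract_report()`) — per-variable regular expressions
   are applied only inside each variable's target sections; numerics are
   unit-normalized, medications mapped to ATC codes, and AF mentions
   resolved into independent *new-onset* and *prior-history* flags.
4. **Vector overlapping** (`merge_patient()`, `resolve_debut()`) — all of a
   patient's report vectors are merged into one debut-anchored vector
   under per-class temporal windows.
5. **Dataset reconciliation** (`link_coded_to_reports()`,
   `build_corpora()`) — coded AF-onset events are linked to reports within
   a 30-day window and combined with regex detections into *intersection*
   (detected by both) and *union* (detected by either) training corpora.
6. **Classification** (`tfidf_fit()`, `ff_train()`, `crossval_evaluate()`,
   `compare_corpora()`) — a tf-idf + feedforward network classifier for
   AF-onset reports, with paired t-tests comparing corpora.

A synthetic-corpus generator (`generate_corpus()`) with complete ground
truth makes every stage testable without access to protected clinical
data.

## Section segmentation

Production systems at the source of this design used a learned sequence
model for section identification. Here the segmenter is a deterministic
heading-lexicon matcher: a line whose trimmed, lower-cased, accent-folded
content (minus one trailing colon) equals a known heading surface form
opens a section, which extends to the next recognized heading. This is
reproducible, auditable, exact on template-like reports, and the module
boundary lets a learned segmenter be swapped in without touching the
extractor. Text before the first recognized heading is labeled `Unknown`
and excluded from extraction. Offsets are 0-based and half-open
everywhere; accent folding is strictly one-character-to-one-character
(`fold_text()`), so offsets into folded text are valid offsets into the
original.

## Negation

The negation module is a NegEx-style scope algorithm: a mention is negated
when a pre-trigger phrase ("no", "sin", "niega", "se descarta", ...) ends
within `scope_window` tokens before it, or a post-trigger ("descartada",
"ruled out", ...) starts within `scope_window` tokens after it, with no
scope-breaking terminator (adversative conjunctions, commas, periods,
colons) in between. Defaults: `scope_window = 5` tokens; punctuation
characters count as tokens; sentences are split on newlines and on periods
followed by whitespace and a capital, and negation never crosses a
sentence boundary. Hedging ("possible AF") is deliberately *not* treated
as negation. The exact semantics are frozen by an exhaustive brute-force
enumerator in the test suite; any divergence from the (unpublished) scope
behavior of clinical NER systems in production is accepted and documented
here.

## Extraction strategies

Variables are described declaratively in a YAML schema
(`load_schema()`); the bundled demonstrator covers 23 variables across all
value types, and the format scales to a full clinical pattern bank.
Strategies follow the variable class:

* **Demographics** are searched in Reason for Consultation and Current
  Illness.
* **Medical history** (boolean comorbidities) in Personal History and
  Diagnosis. AF itself is deliberately excluded from the history schema
  and routed exclusively through `detect_af_flags()`.
* **Lab and echocardiographic numerics** only in Complementary Tests, with
  a per-variable unit table (e.g. creatinine µmol/L ÷ 88.4 to mg/dL).
  Unparseable numeric captures drop the mention with a warning rather
  than failing the report.
* **Medications** in Treatment, mapped to ATC codes by longest-prefix
  lookup after folding, so dose suffixes are tolerated.
* **Procedures** in Treatment, Evolution and Diagnosis.

When one report contains both an affirmed and a negated mention of the
same variable, the affirmed mention wins; this is a heuristic (the
alternative — negated wins — would let a single boilerplate denial erase a
documented diagnosis). A boolean variable whose only mentions are negated
becomes an explicit `FALSE`, which is distinct from missing.

AF flags: `af_prior_history` is a non-negated AF mention in Personal
History; `af_new_onset` is a non-negated mention in Diagnosis or Current
Illness that is onset-qualified ("de novo", "primer episodio", "debut")
or bare with no prior-history mention in the same report. The precedence
of bare mentions was genuinely open; this resolution (bare counts as onset
only in the absence of same-report history) favors specificity and is the
one frozen by the tests.

## Vector overlapping

Merging uses per-class temporal windows relative to the debut date:
180 days before debut (and nothing after) for labs, a symmetric 90-day
window for echo parameters, and an unbounded pre-debut window for
history/demographics/medications/procedures. Month-based phrasings were
fixed as 180/90 days because calendar-month arithmetic is locale-ambiguous
and day counts are testable; both are configurable
(`overlap_config()`). Among in-window candidates the value closest to
debut wins; ties resolve to the earlier report (pre-treatment values are
clinically conservative) and then to the smaller report id. The debut
itself is the earliest report asserting a new onset with no
chronologically earlier prior-history assertion; a contradicted onset
claim resolves to "no debut" rather than guessing, mirroring the
intersection philosophy of preferring specificity. Later AF-flagged
reports are surfaced as recurrence candidates but not modelled.

## Intersection and union corpora

Coded AF-onset events (deduplicated per patient to the earliest coding
date) are linked to discharge reports within ±30 days; the candidate
closest to the coding date becomes that patient's coded-positive report.
Intersection positives are reports detected by both the coding system and
the regex flags; union positives by either. "Union" here includes the
intersection, with per-entry provenance (`both`, `coded_only`,
`regex_only`) kept so the symmetric-difference reading remains
recoverable. Negatives are drawn once, seed-deterministically and without
replacement, from reports of patients with no AF in either source, and
are shared between the two corpora.

## Classifier

Features are tf-idf vectors: unicode word tokens, lower-cased and
accent-folded; smoothed inverse document frequency
$\mathrm{idf}(t) = \ln\frac{1+N}{1+\mathrm{df}(t)} + 1$; optional
sublinear tf; document rows L2-normalized; vocabulary restricted by
minimum document frequency and an optional feature cap. The classifier is
a fully connected feedforward network (one hidden layer of 64 ReLU units
by default) with sigmoid output and cross-entropy loss, trained full-batch
with Adam (learning rate 0.01, L2 decay 1e-4, at most 300 epochs) and
early stopping on a stratified 10% validation split. The implementation
is in plain matrix form inside the package: the exact idf formula above
and the training-configuration surface (layer widths, learning rate,
epochs, early stopping, seeds) are part of the package's contract, and
both the tf-idf weights and the network's behavior are pinned by
independent oracles in the test suite (a two-pass count oracle; metric
identities on confusion matrices).

Evaluation is stratified k-fold (default k = 5; the evaluation split used
by the original clinical study is unstated, so this is a package default,
not a behavioral contract); tf-idf is fitted on training folds only.
`compare_corpora()` trains intersection- and union-derived models on
k leave-one-fold-out resamples and evaluates every model on the *same*
gold-labeled held-out reports, pairing the per-resample error rates in a
classic paired t-test. The held-out set is produced by a patient-level
split (default 25% of patients) of the same corpus, so training and
held-out reports never share a patient.

## The synthetic corpus generator

`generate_corpus()` emulates the study population at desk scale: a
configurable AF-onset prevalence (default 0.30), prior-AF patients
(default 10% of the remainder), one to three reports per patient, report
dates scattered 15–210 days around the debut/anchor date, and a coded
export corrupted with exact-count sampling so that the realized fractions
converge to the configured rates — by default 23% of coded-positive
patients lack a true onset and 26% of true onsets are uncoded, the audit
figures that motivate the reconciliation design. By default 90% of true
onsets are actually documented in a report (not every onset reaches a
discharge report), echo parameters are never present in the coded export
(they are not structured-coded in practice), and other coded values are
masked at 50%.

Noise dials: `negation_rate` renders absent conditions as explicit
negations, `synonym_rate` switches mentions to non-primary surface forms
and alternative units, `distractor_rate` injects out-of-section lab
mentions into Evolution. Alternative-unit values are rendered with enough
decimal precision that conversion back to the canonical unit round-trips
within the 1% numeric scoring tolerance — the generator tests the
extractor's unit handling, not floating-point rounding.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: paraphrases outside the pattern bank (every
synonym the generator emits is coverable by the bundled regexes, so
extraction accuracy on synthetic corpora is an upper bound; the original
study reports 0.97 accuracy / 0.93 precision on real reports), scanned or
malformed section structure, misspellings, family-history confounders,
and realistic clinical narrative. Report-length and section-frequency
distributions are not described in the source material; the generator's
choices (sections present with fixed probabilities, 1–3 reports) are
arbitrary defaults documented here. Sentence templates live in a data
file (`inst/extdata/templates.yaml`), not in code, so the pattern bank
can be stress-tested independently of the generator.

## Numerical and degenerate-input choices

* Paired t-test: identical vectors give t = 0, p = 1; a constant nonzero
  difference (zero variance) reports an infinite t with p = 0.
* Precision/recall with zero denominators are `NA` ("not applicable") and
  excluded from macro averages — never silently 0.
* A value present in both sources but mismatched counts as a false
  positive only (the extractor asserted a wrong value); a flag
  (`count_mismatch_as_fn`) also counts it as a miss for double-penalty
  accounting.
* Numeric gold comparison uses a relative tolerance (default 1%); a gold
  value of exactly zero requires exact equality.
* Empty text segments to zero spans; a report with no recognized heading
  is a single `Unknown` span; `n_patients = 0` yields empty outputs, not
  errors.

## Problem sizes

The test suite and the acceptance script run the generator at 100–320
patients (roughly 200–650 reports) and the classifier comparison over 10
seeds with 5 resamples each; these sizes were chosen so the stochastic
properties (corruption-rate convergence, the intersection-over-union
advantage, chance-level sanity) are measured with comfortable margins
while a full run stays in the minutes range on a single CPU.

## Known limitations

* The segmenter requires headings on their own lines; inline headings
  ("Diagnóstico: FA") are not split.
* Negation scope is token-distance based; long coordinated lists can
  escape a trigger's window.
* The bundled schema is a ~20-variable demonstrator, not a full clinical
  pattern bank.
* The union/intersection comparison direction is replicated as a
  stochastic property of the synthetic world; its magnitudes are not
  comparable to results on any real hospital corpus.
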
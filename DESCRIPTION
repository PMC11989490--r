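Package: afdebut
Title: Rule-Based Extraction of Atrial Fibrillation Onset and Predictor
    Variables from Hospital Discharge Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns unstructured hospital discharge reports into
    patient-level predictor vectors for atrial-fibrillation (AF) onset and
    recurrence modelling. Provides a heading-lexicon section segmenter for
    the nine standardized discharge-report sections, a NegEx-style negation
    detector, section-targeted regular-expression variable extraction with
    unit normalization and ATC medication mapping, temporal merging of
    per-report vectors into debut-anchored patient vectors, reconciliation
    of coded-system AF labels with text-detected onsets into intersection
    and union training corpora, and a tf-idf + feedforward classifier for
    AF-onset report detection with paired statistical comparison. A
    synthetic discharge-report generator with known ground truth makes the
    whole pipeline testable without access to protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    stringi,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
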
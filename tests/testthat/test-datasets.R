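mk_reports <- function(df) {
  out <- lapply(seq_len(nrow(df)), function(i) {
    list(report_id = df$report_id[i], patient_id = df$patient_id[i],
         date = as.Date(df$date[i]),
         text = if ("text" %in% names(df)) df$text[i] else "x")
  })
  names(out) <- df$report_id
  out
}

test_that("coded events link to reports within the 30-day window only", {
  coded <- data.frame(patient_id = "P1", coded_af = 1,
                      coding_date = "2019-03-01",
                      stringsAsFactors = FALSE)
  reports <- mk_reports(data.frame(
    report_id = c("P1-R1", "P1-R2", "P1-R3"),
    patient_id = "P1",
    date = c("2019-04-01", "2019-03-01", "2019-01-15"),  # +31, 0, -45
    stringsAsFactors = FALSE))
  links <- link_coded_to_reports(coded, reports)
  expect_equal(links$P1, "P1-R2")
  # wider window admits the +31-day report
  links45 <- link_coded_to_reports(coded, reports, window_days = 45)
  expect_setequal(links45$P1, c("P1-R1", "P1-R2", "P1-R3"))
})

test_that("duplicate coding rows collapse to the earliest event", {
  coded <- data.frame(patient_id = c("P1", "P1"), coded_af = 1,
                      coding_date = c("2019-06-01", "2019-03-01"),
                      stringsAsFactors = FALSE)
  reports <- mk_reports(data.frame(
    report_id = c("P1-R1", "P1-R2"), patient_id = "P1",
    date = c("2019-03-05", "2019-06-02"), stringsAsFactors = FALSE))
  links <- link_coded_to_reports(coded, reports)
  expect_equal(length(links), 1L)
  expect_equal(links$P1, "P1-R1")  # linked to the March event
  expect_equal(coded_positive_reports(coded, reports), "P1-R1")
})

test_that("intersection and union follow set semantics with shared
           negatives", {
  pool <- mk_reports(data.frame(
    report_id = sprintf("N%02d", 1:10), patient_id = sprintf("Q%02d", 1:10),
    date = "2019-01-01", text = sprintf("neg %d", 1:10),
    stringsAsFactors = FALSE))
  texts <- setNames(sprintf("pos %s", c("A", "B", "C")), c("A", "B", "C"))
  corp <- build_corpora(c("A", "B"), c("B", "C"), pool, 5, seed = 3,
                        texts = texts)
  ipos <- corp$intersection$report_id[corp$intersection$label == "af_onset"]
  upos <- corp$union$report_id[corp$union$label == "af_onset"]
  expect_equal(ipos, "B")
  expect_setequal(upos, c("A", "B", "C"))
  expect_true(all(ipos %in% upos))
  expect_gte(nrow(corp$union), nrow(corp$intersection))
  # provenance is recoverable
  expect_equal(
    corp$union$provenance[match(c("A", "B", "C"), corp$union$report_id)],
    c("coded_only", "both", "regex_only"))
  # negatives are shared between both corpora
  strip <- function(x) {
    attr(x, "name") <- NULL
    rownames(x) <- NULL
    class(x) <- "data.frame"
    x
  }
  expect_identical(
    strip(corp$intersection[corp$intersection$label == "negative", ]),
    strip(corp$union[corp$union$label == "negative", ]))
  # identical positive sets collapse the two corpora
  corp2 <- build_corpora(c("A", "B"), c("A", "B"), pool, 5, seed = 3,
                         texts = texts)
  expect_identical(strip(corp2$intersection), strip(corp2$union))
})

test_that("negative sampling is seed-deterministic and guarded", {
  pool <- mk_reports(data.frame(
    report_id = sprintf("N%02d", 1:20), patient_id = sprintf("Q%02d", 1:20),
    date = "2019-01-01", text = sprintf("neg %d", 1:20),
    stringsAsFactors = FALSE))
  texts <- c(A = "pos A")
  a <- build_corpora("A", "A", pool, 8, seed = 11, texts = texts)
  b <- build_corpora("A", "A", pool, 8, seed = 11, texts = texts)
  c_ <- build_corpora("A", "A", pool, 8, seed = 12, texts = texts)
  expect_identical(a$union$report_id, b$union$report_id)
  expect_false(identical(a$union$report_id, c_$union$report_id))
  # a report cannot be both positive and negative
  expect_error(build_corpora("N01", "A", pool, 5, seed = 1,
                             texts = c(N01 = "x", A = "pos")),
               "input error")
  expect_error(build_corpora("A", "A", pool, 99, seed = 1, texts = texts),
               "input error")
})

test_that("with coding noise and perfect regex, intersection is purer
           than the union", {
  corpus <- generate_corpus(generation_config(n_patients = 250, seed = 17))
  gold_onset <- names(corpus$gold$reports)[vapply(
    corpus$gold$reports, function(g) isTRUE(g$af_new_onset), logical(1))]
  coded_pos <- coded_positive_reports(corpus$coded, corpus$reports)
  pool <- negative_pool_reports(corpus)
  texts <- vapply(corpus$reports, `[[`, "", "text")
  corp <- build_corpora(coded_pos, gold_onset, pool, 50, seed = 17,
                        texts = texts)
  expect_gt(corpus_purity(corp$intersection, gold_onset),
            corpus_purity(corp$union, gold_onset))
})
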
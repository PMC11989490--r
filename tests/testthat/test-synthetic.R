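test_that("invalid rates are configuration errors and n=0 is empty", {
  expect_error(generation_config(af_prevalence = 1.4),
               "configuration error")
  expect_error(generation_config(coding_fp_rate = -0.1),
               "configuration error")
  empty <- generate_corpus(generation_config(n_patients = 0, seed = 1))
  expect_length(empty$reports, 0L)
  expect_equal(nrow(empty$coded), 0L)
  expect_length(empty$gold$reports, 0L)
})

test_that("the seed fully determines the corpus byte-for-byte", {
  cfg <- generation_config(n_patients = 15, seed = 123)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(vapply(a$reports, `[[`, "", "text"),
                   vapply(b$reports, `[[`, "", "text"))
  expect_identical(a$coded, b$coded)
  expect_identical(a$gold, b$gold)
  # a different seed changes the corpus
  c_ <- generate_corpus(generation_config(n_patients = 15, seed = 124))
  expect_false(identical(vapply(a$reports, `[[`, "", "text"),
                         vapply(c_$reports, `[[`, "", "text")))
})

test_that("render_report is deterministic in isolation", {
  cfg <- generation_config(n_patients = 5, seed = 9)
  corpus <- generate_corpus(cfg)
  p <- corpus$profiles[[1L]]
  r1 <- render_report(p, 1L, cfg)
  r2 <- render_report(p, 1L, cfg)
  expect_identical(r1$report$text, r2$report$text)
  expect_identical(r1$gold, r2$gold)
  expect_identical(r1$report$text, corpus$reports[[r1$report$report_id]]$text)
})

test_that("zero coding noise leaves coded AF labels identical to gold", {
  corpus <- generate_corpus(generation_config(
    n_patients = 100, seed = 7, coding_fp_rate = 0, coding_fn_rate = 0))
  truth <- vapply(corpus$gold$patients, `[[`, "", "status") == "debut"
  coded <- setNames(corpus$coded$coded_af == 1, corpus$coded$patient_id)
  expect_identical(unname(coded[names(truth)]), unname(truth))
})

test_that("coding corruption converges to the configured rates", {
  corpus <- generate_corpus(generation_config(n_patients = 600, seed = 7))
  truth <- vapply(corpus$gold$patients, `[[`, "", "status") == "debut"
  coded <- setNames(corpus$coded$coded_af == 1, corpus$coded$patient_id)
  coded <- coded[names(truth)]
  fp_frac <- sum(coded & !truth) / sum(coded)
  fn_frac <- sum(truth & !coded) / sum(truth)
  se <- function(p, n) sqrt(p * (1 - p) / n)
  expect_lt(abs(fp_frac - 0.23), 3 * se(0.23, sum(coded)) + 1 / sum(coded))
  expect_lt(abs(fn_frac - 0.26), 3 * se(0.26, sum(truth)) + 1 / sum(truth))
})

test_that("every report has a Header plus at least two other sections", {
  corpus <- generate_corpus(generation_config(n_patients = 30, seed = 31))
  for (g in corpus$gold$reports) {
    expect_true("Header" %in% g$sections$label)
    expect_gte(sum(g$sections$label != "Header"), 2L)
  }
})

test_that("prior-AF phrasing stays in Personal History and labs in
           Complementary Tests", {
  corpus <- generate_corpus(generation_config(n_patients = 60, seed = 41))
  lab_ids <- names(es_schema)[vapply(es_schema, function(s)
    s$class %in% c("lab", "echo"), logical(1))]
  for (g in corpus$gold$reports) {
    m <- g$mentions
    lab_m <- m[m$variable_id %in% lab_ids & !m$distractor, , drop = FALSE]
    if (nrow(lab_m)) {
      expect_true(all(lab_m$section == "ComplementaryTests"))
    }
  }
  # prior-AF patients mention AF only inside Personal History
  prior_pids <- names(which(vapply(corpus$gold$patients, `[[`, "",
                                   "status") == "prior"))
  n_prior_reports <- 0L
  for (rid in names(corpus$reports)) {
    r <- corpus$reports[[rid]]
    if (!(r$patient_id %in% prior_pids)) next
    spans <- segment(r$text, es_lex)
    folded <- fold_text(r$text)
    hits <- stringi::stri_locate_all_regex(
      folded, "fibrilacion auricular|\\bfa\\b")[[1]]
    if (all(is.na(hits[, 1]))) next
    n_prior_reports <- n_prior_reports + 1L
    for (k in seq_len(nrow(hits))) {
      sec <- spans$label[spans$start < hits[k, 1] &
                           spans$end >= hits[k, 2]]
      expect_equal(sec, "PersonalHistory", info = rid)
    }
  }
  expect_gt(n_prior_reports, 3L)
})

test_that("gold carries every injected value without re-parsing text", {
  corpus <- generate_corpus(generation_config(n_patients = 20, seed = 8))
  for (i in seq_along(corpus$profiles)) {
    p <- corpus$profiles[[i]]
    g <- corpus$gold$patients[[p$patient_id]]
    expect_identical(g$variables, lapply(p$variables, `[[`, "value"))
    # report-level gold values are consistent with the patient truth
    for (r in seq_len(p$n_reports)) {
      rid <- sprintf("%s-R%d", p$patient_id, r)
      vals <- gold_report_values(corpus$gold$reports[[rid]], es_schema)
      for (v in names(vals)) {
        expect_true(isTRUE(all.equal(vals[[v]], g$variables[[v]])),
                    info = paste(rid, v))
      }
    }
  }
})
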
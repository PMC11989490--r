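test_that("tf-idf closed forms: single document and all-document terms", {
  # one document "a a b": both terms share idf, weights proportional (2,1)
  ft <- tfidf_fit_transform("a a b", tfidf_config())
  m <- as.matrix(ft$matrix)
  expect_equal(unname(m[1, c("a", "b")]), c(2, 1) / sqrt(5))
  # a term in every one of N documents has idf = ln(1) + 1 = 1
  docs <- c("common alpha", "common beta", "common gamma")
  ft3 <- tfidf_fit(docs, tfidf_config())
  expect_equal(unname(ft3$idf[["common"]]), log(4 / 4) + 1)
  expect_equal(unname(ft3$idf[["alpha"]]), log(4 / 2) + 1)
})

test_that("tf-idf equals the two-pass count oracle on random corpora", {
  with_seed(99, {
    vocab <- c(letters[1:12], "fibrilacion", "auricular")
    texts <- vapply(1:50, function(i) {
      paste(sample(vocab, sample(3:15, 1), replace = TRUE),
            collapse = " ")
    }, "")
  })
  for (cfg in list(tfidf_config(),
                   tfidf_config(min_document_frequency = 3),
                   tfidf_config(sublinear_tf = TRUE),
                   tfidf_config(max_features = 6))) {
    ft <- tfidf_fit_transform(texts, cfg)
    want <- oracle_tfidf(texts, cfg)
    got <- as.matrix(ft$matrix)[, colnames(want), drop = FALSE]
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
    expect_identical(colnames(as.matrix(ft$matrix)), colnames(want))
  }
  # filtering everything out is a configuration error
  expect_error(tfidf_fit(c("a", "b"), tfidf_config(
    min_document_frequency = 3)), "configuration error")
})

test_that("confusion-matrix metric identities hold", {
  m <- confusion_metrics(2, 0, 0, 2)
  expect_equal(unname(m), c(1, 1, 1, 1))
  m <- confusion_metrics(3, 1, 2, 4)
  expect_equal(m[["accuracy"]], 7 / 10)
  expect_equal(m[["precision"]], 3 / 4)
  expect_equal(m[["recall"]], 3 / 5)
  expect_equal(m[["f1"]], 2 * (3 / 4) * (3 / 5) / (3 / 4 + 3 / 5))
  # zero denominators are NA, not zero
  m <- confusion_metrics(0, 0, 0, 5)
  expect_true(is.na(m[["precision"]]))
  expect_true(is.na(m[["recall"]]))
})

test_that("paired t-test matches the hand formula and its degenerate
           contracts", {
  a <- c(0.9, 0.8, 0.85, 0.95)
  b <- c(0.7, 0.75, 0.8, 0.7)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  p_hand <- 2 * pt(-abs(t_hand), df = 3)
  res <- paired_ttest(a, b)
  expect_equal(res$t, t_hand)
  expect_equal(res$p, p_hand)
  # agrees with the stats reference implementation
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  # identical samples
  res0 <- paired_ttest(a, a)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # constant nonzero difference: zero variance contract
  resc <- paired_ttest(c(2, 2, 2, 2), c(1, 1, 1, 1))
  expect_true(is.infinite(resc$t) && resc$t > 0)
  expect_equal(resc$p, 0)
})

test_that("a separable corpus reaches near-perfect cross-validated F1", {
  corp <- separable_corpus(400, seed = 21)
  res <- crossval_evaluate(corp, tfidf_config(), ff_config(),
                           k_folds = 5, seed = 21)
  expect_gte(mean(res$metrics$f1), 0.99)
  # metrics are recomputable from the stored confusion matrices
  for (f in seq_len(5)) {
    cm <- res$confusions[[f]]
    want <- confusion_metrics(cm[["tp"]], cm[["fp"]], cm[["fn"]],
                              cm[["tn"]])
    expect_equal(unlist(res$metrics[f, c("accuracy", "precision",
                                         "recall", "f1")]),
                 want, ignore_attr = TRUE)
  }
})

test_that("cross-validation is seed-deterministic and leak-guarded", {
  corp <- separable_corpus(120, seed = 4)
  r1 <- crossval_evaluate(corp, tfidf_config(), ff_config(), 4, seed = 2)
  r2 <- crossval_evaluate(corp, tfidf_config(), ff_config(), 4, seed = 2)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$folds, r2$folds)
  r3 <- crossval_evaluate(corp, tfidf_config(), ff_config(), 4, seed = 3)
  expect_false(identical(r1$folds, r3$folds))
  # single-class corpus is an input error
  corp1 <- corp[corp$label == "negative", ]
  attr(corp1, "name") <- "neg"
  expect_error(crossval_evaluate(corp1, tfidf_config(), ff_config(), 4, 1),
               "input error")
})

test_that("compare_corpora rejects held-out overlap and runs end-to-end", {
  corp <- separable_corpus(60, seed = 12)
  held <- separable_corpus(60, seed = 13)
  held$report_id <- sprintf("H%04d", seq_len(nrow(held)))
  overlap_held <- held
  overlap_held$report_id[1] <- corp$report_id[1]
  expect_error(compare_corpora(corp, corp, overlap_held,
                               k_folds = 2, seed = 1),
               "input error")
  cmp <- compare_corpora(corp, corp, held, tfidf_config(),
                         ff_config(max_epochs = 50), k_folds = 2,
                         seed = 1)
  expect_length(cmp$a$errors, 2L)
  expect_equal(cmp$paired$df, 1L)
})
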
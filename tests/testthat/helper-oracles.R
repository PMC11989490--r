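# Shared fixtures and independent brute-force oracles used across tests.

es_lex <- load_heading_lexicon("es")
es_rules <- load_negation_rules("es")
es_schema <- load_schema("es")
es_af <- load_af_patterns("es")
en_lex <- load_heading_lexicon("en")
en_rules <- load_negation_rules("en")

# run the sectioner + extractor over a whole synthetic corpus
extract_corpus <- function(corpus, language = corpus$config$language) {
  lex <- load_heading_lexicon(language)
  schema <- load_schema(language)
  rules <- load_negation_rules(language)
  afp <- load_af_patterns(language)
  vectors <- lapply(names(corpus$reports), function(rid) {
    r <- corpus$reports[[rid]]
    extract_report(segment(r$text, lex), r$text, schema, rules, afp,
                   report_id = rid, patient_id = r$patient_id,
                   report_date = r$date)
  })
  names(vectors) <- names(corpus$reports)
  vectors
}

gold_values_list <- function(corpus, schema = es_schema) {
  lapply(corpus$gold$reports, function(g) {
    list(report_id = g$report_id, values = gold_report_values(g, schema))
  })
}

# value-map equality up to numeric tolerance
values_equal <- function(a, b, tol = 1e-9) {
  if (!setequal(names(a), names(b))) return(FALSE)
  all(vapply(names(a), function(n) {
    isTRUE(all.equal(a[[n]], b[[n]], tolerance = tol))
  }, logical(1)))
}

# ---- negation: exhaustive scope enumerator -------------------------------
# Independent of is_negated(): enumerates every occurrence of every trigger
# phrase anywhere in the sentence and tests the distance/terminator
# conditions directly.
oracle_negated <- function(text, start, end, rules) {
  toks <- tokenize_spans(text)
  mention <- which(toks$end > start & toks$start < end)
  if (length(mention) == 0L) return(FALSE)
  first <- min(mention)
  last <- max(mention)
  n <- nrow(toks)
  occurs <- function(phr) {
    k <- length(phr)
    if (k > n) return(integer())
    Filter(function(i) all(toks$token[i:(i + k - 1L)] == phr),
           seq_len(n - k + 1L))
  }
  for (phr in rules$pre_tokens) {
    for (s in occurs(phr)) {
      e <- s + length(phr) - 1L
      if (e >= first) next
      if (first - e > rules$scope_window) next
      gap <- if (e + 1L <= first - 1L) toks$token[(e + 1L):(first - 1L)]
        else character()
      if (!any(gap %in% rules$terminators)) return(TRUE)
    }
  }
  for (phr in rules$post_tokens) {
    for (s in occurs(phr)) {
      if (s <= last) next
      if (s - last > rules$scope_window) next
      gap <- if (last + 1L <= s - 1L) toks$token[(last + 1L):(s - 1L)]
        else character()
      if (!any(gap %in% rules$terminators)) return(TRUE)
    }
  }
  FALSE
}

# ---- overlap: brute-force nearest-candidate scan -------------------------
# Pairwise comparison over all in-window candidates, no sorting tricks.
oracle_merge_value <- function(vectors, vid, debut, before, after) {
  best <- NULL
  for (v in vectors) {
    if (is.null(v$values[[vid]])) next
    delta <- as.numeric(as.Date(v$report_date) - as.Date(debut))
    if (delta < -before || delta > after) next
    cand <- list(value = v$values[[vid]], delta = delta,
                 id = v$report_id)
    if (is.null(best)) {
      best <- cand
    } else {
      better <- abs(cand$delta) < abs(best$delta) ||
        (abs(cand$delta) == abs(best$delta) && cand$delta < best$delta) ||
        (abs(cand$delta) == abs(best$delta) &&
           cand$delta == best$delta && cand$id < best$id)
      if (better) best <- cand
    }
  }
  best
}

# random single-patient timeline of minimal report vectors
random_timeline <- function(pid, n_reports, vars, seed) {
  with_seed(seed, {
    debut <- as.Date("2018-06-01")
    lapply(seq_len(n_reports), function(r) {
      values <- list()
      for (vid in vars) {
        if (runif(1) < 0.6) values[[vid]] <- round(runif(1, 1, 100), 1)
      }
      list(report_id = sprintf("%s-R%02d", pid, r), patient_id = pid,
           report_date = debut + sample(-400:400, 1), values = values,
           af_new_onset = NA, af_prior_history = NA)
    })
  })
}

# ---- tf-idf: two-pass count oracle ---------------------------------------
oracle_tfidf <- function(texts, config) {
  toks <- lapply(fold_text(texts),
                 function(x) unlist(stringi::stri_extract_all_regex(
                   x, "[\\p{L}\\p{N}]+", omit_no_match = TRUE)))
  n <- length(texts)
  df <- table(unlist(lapply(toks, unique)))
  df <- df[df >= config$min_document_frequency]
  if (!is.null(config$max_features) && length(df) > config$max_features) {
    ord <- order(-as.integer(df), names(df))
    df <- df[ord][seq_len(config$max_features)]
  }
  vocab <- sort(names(df))
  m <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (d in seq_len(n)) {
    for (term in vocab) {
      tf <- sum(toks[[d]] == term)
      if (tf == 0) next
      if (config$sublinear_tf) tf <- 1 + log(tf)
      idf <- log((1 + n) / (1 + as.integer(df[[term]]))) + 1
      m[d, term] <- tf * idf
    }
    nrm <- sqrt(sum(m[d, ]^2))
    if (nrm > 0) m[d, ] <- m[d, ] / nrm
  }
  m
}

# ---- classifier test corpora ---------------------------------------------
# linearly separable two-class corpus with per-class marker tokens
separable_corpus <- function(n, seed) {
  with_seed(seed, {
    filler <- c("paciente", "ingreso", "control", "alta", "servicio",
                "clinica", "estable", "seguimiento")
    mk <- function(marker) {
      paste(c(marker, sample(filler, sample(4:8, 1), replace = TRUE)),
            collapse = " ")
    }
    lab <- rep(c("af_onset", "negative"), length.out = n)
    txt <- vapply(lab, function(l) {
      mk(if (l == "af_onset") "fibrilacion" else "sinusal")
    }, "")
    structure(data.frame(report_id = sprintf("D%04d", seq_len(n)),
                         text = txt, label = lab,
                         provenance = "synthetic",
                         stringsAsFactors = FALSE),
              name = "separable", class = c("labeled_corpus", "data.frame"))
  })
}

# balanced corpus whose labels are randomly shuffled (no signal)
shuffled_corpus <- function(n, seed) {
  corp <- separable_corpus(n, seed)
  corp$label <- with_seed(seed + 1L, sample(corp$label))
  attr(corp, "name") <- "shuffled"
  corp
}

# gold truth patient-by-variable table (for missingness oracles)
gold_patient_df <- function(corpus, schema = es_schema) {
  vars <- names(schema)
  rows <- lapply(corpus$gold$patients, function(p) {
    vals <- lapply(vars, function(vid) {
      x <- p$variables[[vid]]
      if (is.null(x)) NA else x
    })
    names(vals) <- vars
    as.data.frame(c(list(patient_id = p$patient_id), vals),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
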
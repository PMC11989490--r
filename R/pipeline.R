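#' Pipeline configuration
#'
#' Bundles the stage configurations and a single global seed that
#' propagates to every stochastic stage (corpus generation, negative
#' sampling, fold assignment, network initialization). Either a
#' [generation_config()] (synthetic run) or paths to an existing corpus
#' (`corpus_path` JSONL, `coded_path` CSV) must be supplied; referenced
#' files are checked before any stage runs.
#'
#' @param generation a [generation_config()] or `NULL`.
#' @param corpus_path,coded_path input files for non-synthetic runs.
#' @param language heading/negation/schema language.
#' @param overlap an [overlap_config()].
#' @param tfidf a [tfidf_config()].
#' @param ff an [ff_config()].
#' @param k_folds folds for the classifier evaluation.
#' @param n_negatives negatives sampled for the training corpora.
#' @param holdout_fraction fraction of patients held out for the
#'   corpus-comparison evaluation.
#' @param seed global integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(generation = generation_config(),
                            corpus_path = NULL, coded_path = NULL,
                            language = NULL,
                            overlap = overlap_config(),
                            tfidf = tfidf_config(min_document_frequency = 2,
                                                 max_features = 2000L),
                            ff = ff_config(), k_folds = 5L,
                            n_negatives = 150L,
                            holdout_fraction = 0.25, seed = 1L) {
  if (is.null(generation) &&
      (is.null(corpus_path) || is.null(coded_path))) {
    stop("configuration error: either a generation config or corpus_path ",
         "+ coded_path must be given", call. = FALSE)
  }
  for (p in c(corpus_path, coded_path)) {
    if (!file.exists(p)) {
      stop("configuration error: input file does not exist: ", p,
           call. = FALSE)
    }
  }
  if (!is.null(generation)) generation$seed <- as.integer(seed)
  language <- language %||%
    (if (!is.null(generation)) generation$language else "es")
  structure(list(generation = generation, corpus_path = corpus_path,
                 coded_path = coded_path, language = language,
                 overlap = overlap, tfidf = tfidf, ff = ff,
                 k_folds = as.integer(k_folds),
                 n_negatives = as.integer(n_negatives),
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full extraction and comparison pipeline
#'
#' Stages: synth (optional) -> section -> extract -> overlap -> corpora ->
#' train/compare -> score. All intermediate artifacts are written as plain
#' JSONL/CSV files so every stage is independently inspectable, and a
#' machine-readable manifest records seeds, counts and headline metrics.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("afdebut")),
                   seed = config$seed, language = config$language,
                   stages = list())

  # --- synth ---
  corpus <- run_stage("synth", {
    if (!is.null(config$generation)) {
      cp <- generate_corpus(config$generation)
      write_corpus(cp, out_dir)
      cp
    } else {
      read_corpus_files(config$corpus_path, config$coded_path)
    }
  })
  manifest$stages$synth <- list(
    n_patients = length(unique(vapply(corpus$reports, `[[`, "",
                                      "patient_id"))),
    n_reports = length(corpus$reports))

  schema <- load_schema(config$language)
  lex <- load_heading_lexicon(config$language)
  rules <- load_negation_rules(config$language)
  afp <- load_af_patterns(config$language)

  # --- section ---
  sectioned <- run_stage("section", segment_corpus(corpus$reports, lex))
  run_stage("section", write_jsonl(lapply(names(sectioned), function(id) {
    list(report_id = id, spans = df_to_records(sectioned[[id]]))
  }), path("sectioned.jsonl")))
  manifest$stages$section <- list(n_reports = length(sectioned))

  # --- extract ---
  vectors <- run_stage("extract", {
    out <- lapply(names(corpus$reports), function(rid) {
      r <- corpus$reports[[rid]]
      extract_report(sectioned[[rid]], r$text, schema, rules, afp,
                     report_id = rid, patient_id = r$patient_id,
                     report_date = r$date)
    })
    names(out) <- names(corpus$reports)
    out
  })
  run_stage("extract", {
    write_jsonl(lapply(vectors, report_vector_record),
                path("vectors.jsonl"))
    write.csv(report_vectors_to_df(vectors, schema), path("vectors.csv"),
              row.names = FALSE)
  })
  manifest$stages$extract <- list(
    n_af_onset_reports = sum(vapply(vectors, function(v)
      isTRUE(v$af_new_onset), logical(1))))

  # --- overlap ---
  class_map <- variable_class_map(schema)
  patients <- run_stage("overlap", {
    by_pid <- split(vectors, vapply(vectors, `[[`, "", "patient_id"))
    out <- list()
    for (pid in names(by_pid)) {
      deb <- resolve_debut(by_pid[[pid]])
      if (is.na(deb$debut_date)) next
      pv <- merge_patient(by_pid[[pid]], deb$debut_date, config$overlap,
                          class_map)
      pv$af_onset_report_id <- deb$af_onset_report_id
      out[[pid]] <- pv
    }
    out
  })
  pat_df <- patient_vectors_to_df(patients, schema)
  run_stage("overlap", write.csv(pat_df, path("patients.csv"),
                                 row.names = FALSE))
  miss <- NULL
  if (nrow(pat_df) > 0L &&
      length(intersect(pat_df$patient_id, corpus$coded$patient_id))) {
    miss <- run_stage("overlap", missingness(pat_df, corpus$coded))
    write.csv(miss, path("missingness.csv"), row.names = FALSE)
  }
  manifest$stages$overlap <- list(
    n_debut_patients = length(patients),
    overall_missing_reduction = if (!is.null(miss))
      miss$reduction[miss$variable == "overall"] else NA)

  # --- corpora ---
  regex_pos <- names(Filter(function(v) isTRUE(v$af_new_onset), vectors))
  pids <- unique(vapply(corpus$reports, `[[`, "", "patient_id"))
  hold_pids <- with_seed(derive_seed(config$seed, "holdout"),
                         sample(pids, round(config$holdout_fraction *
                                              length(pids))))
  in_hold <- function(ids) {
    vapply(corpus$reports[ids], `[[`, "", "patient_id") %in% hold_pids
  }
  corpora <- run_stage("corpora", {
    coded_pos <- coded_positive_reports(corpus$coded, corpus$reports)
    coded_pos <- coded_pos[!in_hold(coded_pos)]
    regex_tr <- regex_pos[!in_hold(regex_pos)]
    pool <- Filter(function(r) !(r$patient_id %in% hold_pids),
                   negative_pool_reports(corpus))
    texts <- vapply(corpus$reports, `[[`, "", "text")
    build_corpora(coded_pos, regex_tr, pool,
                  min(config$n_negatives, length(pool)),
                  derive_seed(config$seed, "negatives"), texts)
  })
  for (nm in names(corpora)) {
    write_jsonl(df_to_records(corpora[[nm]]),
                path(paste0(nm, ".jsonl")))
  }
  manifest$stages$corpora <- list(
    intersection_positives =
      sum(corpora$intersection$label == "af_onset"),
    union_positives = sum(corpora$union$label == "af_onset"),
    n_negatives = sum(corpora$union$label == "negative"))

  # --- train / compare ---
  comparison <- run_stage("train", {
    lh <- if (!is.null(corpus$gold)) labeled_reports(corpus) else NULL
    heldout <- if (!is.null(lh)) lh[lh$patient_id %in% hold_pids, ] else
      NULL
    cv <- crossval_evaluate(corpora$intersection, config$tfidf, config$ff,
                            config$k_folds, config$seed)
    cmp <- if (!is.null(heldout) &&
               length(unique(heldout$label)) == 2L) {
      compare_corpora(corpora$intersection, corpora$union, heldout,
                      config$tfidf, config$ff, config$k_folds,
                      config$seed)
    } else NULL
    list(crossval = cv, comparison = cmp)
  })
  eval_out <- list(
    intersection_cv = df_to_records(comparison$crossval$metrics),
    comparison = if (!is.null(comparison$comparison)) list(
      intersection_error = comparison$comparison$a$mean_error,
      union_error = comparison$comparison$b$mean_error,
      paired_t = comparison$comparison$paired$t,
      paired_p = comparison$comparison$paired$p) else NULL)
  jsonlite::write_json(eval_out, path("evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  manifest$stages$train <- eval_out$comparison %||%
    list(note = "no gold labels; comparison skipped")

  # --- score (needs gold) ---
  if (!is.null(corpus$gold) && length(corpus$gold$reports)) {
    scores <- run_stage("score", {
      gold_vals <- lapply(corpus$gold$reports, function(g) {
        list(report_id = g$report_id,
             values = gold_report_values(g, schema))
      })
      score_vectors(vectors, gold_vals, names(schema))
    })
    write.csv(scores$per_variable, path("extraction_metrics.csv"),
              row.names = FALSE)
    manifest$stages$score <- as.list(round(scores$aggregate, 6))
  }

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(manifest)
}

# ---- plain-text IO helpers ----

df_to_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, , drop = FALSE])
    lapply(r, function(x) if (inherits(x, "Date")) as.character(x) else
      if (is.list(x)) x[[1L]] else x)
  })
}

report_vector_record <- function(v) {
  list(report_id = v$report_id, patient_id = v$patient_id,
       report_date = as.character(v$report_date), values = v$values,
       af_new_onset = v$af_new_onset,
       af_prior_history = v$af_prior_history)
}

#' Flatten report vectors to a wide data.frame
#'
#' @param vectors list of `report_vector` objects.
#' @param schema schema whose variable ids define the columns.
#' @return data.frame, one row per report.
#' @export
report_vectors_to_df <- function(vectors, schema) {
  vars <- names(schema)
  rows <- lapply(vectors, function(v) {
    vals <- lapply(vars, function(vid) {
      x <- v$values[[vid]]
      if (is.null(x)) NA else x
    })
    names(vals) <- vars
    as.data.frame(c(list(report_id = v$report_id,
                         patient_id = v$patient_id,
                         report_date = as.character(v$report_date),
                         af_new_onset = v$af_new_onset,
                         af_prior_history = v$af_prior_history), vals),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flatten patient vectors to a wide data.frame
#'
#' @param patients list of `patient_vector` objects.
#' @param schema schema whose variable ids define the columns.
#' @return data.frame, one row per patient.
#' @export
patient_vectors_to_df <- function(patients, schema) {
  vars <- names(schema)
  if (length(patients) == 0L) {
    cols <- c("patient_id", "debut_date", "missing_count", vars)
    return(as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                  cols), stringsAsFactors = FALSE))
  }
  rows <- lapply(patients, function(p) {
    vals <- lapply(vars, function(vid) {
      x <- p$values[[vid]]
      if (is.null(x)) NA else x
    })
    names(vals) <- vars
    as.data.frame(c(list(patient_id = p$patient_id,
                         debut_date = as.character(p$debut_date),
                         missing_count = p$missing_count), vals),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_corpus <- function(corpus, out_dir) {
  write_jsonl(lapply(corpus$reports, function(r) {
    list(id = r$report_id, patient_id = r$patient_id,
         date = as.character(r$date), text = r$text)
  }), file.path(out_dir, "corpus.jsonl"))
  write.csv(corpus$coded, file.path(out_dir, "coded.csv"),
            row.names = FALSE)
  write_jsonl(lapply(corpus$gold$reports, function(g) {
    list(report_id = g$report_id, patient_id = g$patient_id,
         date = as.character(g$date),
         sections = df_to_records(g$sections),
         mentions = df_to_records(g$mentions),
         af_new_onset = g$af_new_onset,
         af_prior_history = g$af_prior_history)
  }), file.path(out_dir, "gold.jsonl"))
  invisible(out_dir)
}

read_corpus_files <- function(corpus_path, coded_path) {
  recs <- read_jsonl(corpus_path)
  reports <- lapply(recs, function(r) {
    list(report_id = r$id %||% r$report_id, patient_id = r$patient_id,
         date = as.Date(r$date), text = r$text)
  })
  names(reports) <- vapply(reports, `[[`, "", "report_id")
  coded <- read.csv(coded_path, stringsAsFactors = FALSE)
  coded$coding_date <- as.Date(coded$coding_date)
  list(reports = reports, coded = coded, gold = NULL)
}
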
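#' Link coded AF-onset events to candidate discharge reports
#'
#' Duplicate coding rows per patient are collapsed to one event (the
#' earliest coding date). A report is a candidate for a patient's coding
#' event iff the absolute difference between report date and coding date
#' is at most `window_days`.
#'
#' @param coded_export data.frame with columns `patient_id`, `coded_af`
#'   (0/1) and `coding_date`.
#' @param reports list of reports (lists with `report_id`, `patient_id`,
#'   `date`).
#' @param window_days linkage window in days (default 30).
#' @return named list: patient id -> character vector of candidate report
#'   ids (date order, then id order).
#' @export
link_coded_to_reports <- function(coded_export, reports,
                                  window_days = 30) {
  pos <- coded_export[coded_export$coded_af == 1 &
                        !is.na(coded_export$coding_date), , drop = FALSE]
  if (nrow(pos) == 0L) return(structure(list(), names = character()))
  pos$coding_date <- as.Date(pos$coding_date)
  pos <- pos[order(pos$patient_id, pos$coding_date), , drop = FALSE]
  pos <- pos[!duplicated(pos$patient_id), , drop = FALSE]  # earliest event

  rep_df <- data.frame(
    report_id = vapply(reports, `[[`, "", "report_id"),
    patient_id = vapply(reports, `[[`, "", "patient_id"),
    date = as.Date(vapply(reports, function(r) as.character(r$date), "")),
    stringsAsFactors = FALSE)

  out <- lapply(seq_len(nrow(pos)), function(i) {
    r <- rep_df[rep_df$patient_id == pos$patient_id[i], , drop = FALSE]
    r <- r[abs(as.numeric(r$date - pos$coding_date[i])) <= window_days, ,
           drop = FALSE]
    r <- r[order(r$date, r$report_id), , drop = FALSE]
    r$report_id
  })
  names(out) <- pos$patient_id
  out
}

#' Pick one coded-positive report per patient
#'
#' Mirrors the construction of the coded positive report set: for each
#' coded AF-onset patient, the candidate report closest to the coding date
#' (ties toward the earlier report, then the smaller report id).
#'
#' @inheritParams link_coded_to_reports
#' @return character vector of report ids (one per linkable patient).
#' @export
coded_positive_reports <- function(coded_export, reports,
                                   window_days = 30) {
  links <- link_coded_to_reports(coded_export, reports, window_days)
  if (length(links) == 0L) return(character())
  pos <- coded_export[coded_export$coded_af == 1 &
                        !is.na(coded_export$coding_date), , drop = FALSE]
  pos$coding_date <- as.Date(pos$coding_date)
  pos <- pos[order(pos$patient_id, pos$coding_date), , drop = FALSE]
  pos <- pos[!duplicated(pos$patient_id), , drop = FALSE]
  cdate <- setNames(pos$coding_date, pos$patient_id)

  rep_date <- setNames(
    as.Date(vapply(reports, function(r) as.character(r$date), "")),
    vapply(reports, `[[`, "", "report_id"))

  out <- character()
  for (pid in names(links)) {
    ids <- links[[pid]]
    if (length(ids) == 0L) next
    delta <- as.numeric(rep_date[ids] - cdate[[pid]])
    ord <- order(abs(delta), delta, ids)
    out <- c(out, ids[ord[1L]])
  }
  out
}

#' Build the intersection and union training corpora
#'
#' Positives of the intersection corpus are reports detected by both the
#' coding system and the regex tool; positives of the union corpus are
#' reports detected by either. Negatives are sampled once, without
#' replacement and seed-deterministically, from the negative pool and
#' shared between the two corpora. Provenance (`coded_only`, `regex_only`,
#' `both`, `sampled_negative`) is kept per entry so either reading of
#' "union" stays recoverable.
#'
#' @param coded_positive_ids,regex_positive_ids character vectors of report
#'   ids.
#' @param negative_pool list of reports (lists with `report_id`, `text`)
#'   from patients with no AF.
#' @param n_negatives number of negatives to sample.
#' @param seed integer seed for the negative sampling.
#' @param texts named character vector mapping positive report ids to
#'   their texts.
#' @return list with elements `intersection` and `union`, each of class
#'   `labeled_corpus`: a data.frame with `report_id`, `text`, `label`
#'   (`af_onset`/`negative`) and `provenance`, plus a `name` attribute.
#' @export
build_corpora <- function(coded_positive_ids, regex_positive_ids,
                          negative_pool, n_negatives, seed, texts) {
  coded_positive_ids <- unique(coded_positive_ids)
  regex_positive_ids <- unique(regex_positive_ids)
  pool_ids <- vapply(negative_pool, `[[`, "", "report_id")
  all_pos <- union(coded_positive_ids, regex_positive_ids)
  if (length(intersect(all_pos, pool_ids)) > 0L) {
    stop("input error: reports appear both as positives and in the ",
         "negative pool", call. = FALSE)
  }
  if (n_negatives > length(negative_pool)) {
    stop("input error: n_negatives exceeds the negative pool size",
         call. = FALSE)
  }
  neg_idx <- with_seed(seed, sample.int(length(negative_pool), n_negatives))
  neg_idx <- neg_idx[order(neg_idx)]  # stable row order, sample unchanged
  negatives <- data.frame(
    report_id = pool_ids[neg_idx],
    text = vapply(negative_pool[neg_idx], `[[`, "", "text"),
    label = "negative", provenance = "sampled_negative",
    stringsAsFactors = FALSE)

  provenance <- function(ids) {
    ifelse(ids %in% coded_positive_ids & ids %in% regex_positive_ids,
           "both",
           ifelse(ids %in% coded_positive_ids, "coded_only", "regex_only"))
  }
  positives_df <- function(ids) {
    missing_txt <- setdiff(ids, names(texts))
    if (length(missing_txt)) {
      stop("input error: no text for positive report(s) ",
           paste(head(missing_txt, 3), collapse = ", "), call. = FALSE)
    }
    ids <- sort(ids)
    data.frame(report_id = ids, text = unname(texts[ids]),
               label = "af_onset", provenance = provenance(ids),
               stringsAsFactors = FALSE)
  }

  mk <- function(ids, name) {
    df <- rbind(positives_df(ids), negatives)
    stopifnot(!anyDuplicated(df$report_id))
    structure(df, name = name, class = c("labeled_corpus", "data.frame"))
  }
  list(intersection = mk(intersect(coded_positive_ids, regex_positive_ids),
                         "intersection"),
       union = mk(all_pos, "union"))
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat("<labeled_corpus '", attr(x, "name"), "'> ", nrow(x), " reports: ",
      sum(x$label == "af_onset"), " af_onset / ",
      sum(x$label == "negative"), " negative\n", sep = "")
  print(table(x$provenance))
  invisible(x)
}

#' Label purity of a corpus against gold labels
#'
#' Fraction of the corpus's positive entries whose gold label is truly an
#' AF-onset report.
#'
#' @param corpus a `labeled_corpus`.
#' @param gold_onset_ids character vector of report ids that truly carry a
#'   new AF onset.
#' @return fraction in `[0, 1]` (`NaN` for a corpus with no positives).
#' @export
corpus_purity <- function(corpus, gold_onset_ids) {
  pos <- corpus$report_id[corpus$label == "af_onset"]
  mean(pos %in% gold_onset_ids)
}
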
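#' Extract a report vector from a sectioned report
#'
#' Applies each variable's regex patterns only inside that variable's
#' target sections, passes every candidate mention through negation
#' detection, parses and unit-normalizes numeric captures, and maps
#' medication mentions to ATC codes. When a variable has both an affirmed
#' and a negated mention in the same report, the affirmed mention wins
#' (heuristic; the negated mention is kept in the provenance list). A
#' boolean variable whose only mentions are negated yields an explicit
#' `FALSE`; negated numeric/categorical/medication mentions yield no value.
#'
#' @param sectioned section span table from [segment()].
#' @param text the report text the spans refer to.
#' @param schema list of variable specs from [load_schema()].
#' @param rules a [negation_rules()] object.
#' @param af_patterns AF patterns from [load_af_patterns()]; `NULL` skips
#'   AF flag detection (flags are then `NA`).
#' @param report_id,patient_id,report_date provenance carried through.
#' @return object of class `report_vector`: a list with `report_id`,
#'   `patient_id`, `report_date`, `values` (named list), `af_new_onset`,
#'   `af_prior_history` and `mentions` (provenance data.frame).
#' @export
extract_report <- function(sectioned, text, schema, rules,
                           af_patterns = NULL, report_id = NA_character_,
                           patient_id = NA_character_, report_date = NA) {
  folded <- fold_text(text)
  sentences <- sentence_spans(text)

  mentions <- list()
  for (spec in schema) {
    mentions[[length(mentions) + 1L]] <-
      match_variable(spec, sectioned, text, folded, sentences, rules)
  }
  mentions <- do.call(rbind, mentions)
  if (is.null(mentions)) mentions <- empty_mentions()

  values <- resolve_values(mentions, schema)

  flags <- if (is.null(af_patterns)) {
    list(af_new_onset = NA, af_prior_history = NA)
  } else {
    detect_af_flags(sectioned, text, af_patterns, rules)
  }

  structure(
    list(report_id = report_id, patient_id = patient_id,
         report_date = report_date, values = values,
         af_new_onset = flags$af_new_onset,
         af_prior_history = flags$af_prior_history,
         mentions = mentions),
    class = "report_vector")
}

empty_mentions <- function() {
  data.frame(variable_id = character(), section = character(),
             start = integer(), end = integer(), matched_text = character(),
             value = I(list()), negated = logical(),
             stringsAsFactors = FALSE)
}

# all matches of one variable spec inside its target sections
match_variable <- function(spec, sectioned, text, folded, sentences, rules) {
  rows <- list()
  spans <- sectioned[sectioned$label %in% spec$target_sections, ,
                     drop = FALSE]
  if (nrow(spans) == 0L) return(NULL)
  for (i in seq_len(nrow(spans))) {
    sec_start <- spans$start[i]
    sec_text <- span_text(folded, sec_start, spans$end[i])
    for (pat in spec$patterns) {
      hits <- regex_capture_all(pat, sec_text)
      if (nrow(hits) == 0L) next
      for (j in seq_len(nrow(hits))) {
        m_start <- sec_start + hits$start[j]
        m_end <- sec_start + hits$end[j]
        val <- mention_value(spec, hits[j, , drop = FALSE],
                             span_text(text, m_start, m_end))
        if (is.null(val$ok)) next
        neg <- mention_negated(text, sentences, m_start, m_end, rules)
        rows[[length(rows) + 1L]] <- data.frame(
          variable_id = spec$variable_id, section = spans$label[i],
          start = m_start, end = m_end,
          matched_text = span_text(text, m_start, m_end),
          value = I(list(val$value)), negated = neg,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  out[!duplicated(out[, c("variable_id", "start", "end")]), , drop = FALSE]
}

# all matches of a regex (perl, case-insensitive) with named capture groups;
# offsets 0-based half-open into `subject`
regex_capture_all <- function(pattern, subject) {
  m <- gregexpr(pattern, subject, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  out <- data.frame(start = starts, end = starts + lens,
                    stringsAsFactors = FALSE)
  cs <- attr(m, "capture.start")
  if (!is.null(cs)) {
    cl <- attr(m, "capture.length")
    for (g in colnames(cs)) {
      if (!nzchar(g)) next
      gs <- cs[, g]
      gl <- cl[, g]
      out[[paste0("g_", g)]] <- ifelse(
        gs > 0L, substr(rep(subject, length(gs)), gs, gs + gl - 1L), NA)
    }
  }
  out
}

# typed value for a mention; list(ok=TRUE, value=...) or list(ok=NULL) to
# drop the mention
mention_value <- function(spec, hit, matched_text) {
  switch(spec$value_type,
    boolean = list(ok = TRUE, value = TRUE),
    numeric = {
      raw <- hit$g_value %||% NA
      num <- suppressWarnings(as.numeric(gsub(",", ".", raw)))
      if (is.na(num) || !is.finite(num)) {
        warning("dropping mention of '", spec$variable_id,
                "': unparseable numeric capture '", raw, "'",
                call. = FALSE)
        return(list(ok = NULL))
      }
      unit <- hit$g_unit %||% NA
      if (!is.null(spec$unit_factors) && !is.na(unit) && nzchar(unit)) {
        f <- spec$unit_factors[fold_text(unit)]
        if (is.na(f)) {
          warning("dropping mention of '", spec$variable_id,
                  "': unknown unit '", unit, "'", call. = FALSE)
          return(list(ok = NULL))
        }
        num <- num * unname(f)
      }
      list(ok = TRUE, value = num)
    },
    categorical = {
      v <- map_surface(matched_text, spec$value_map)
      if (is.na(v)) {
        warning("dropping mention of '", spec$variable_id,
                "': unmapped surface '", matched_text, "'", call. = FALSE)
        return(list(ok = NULL))
      }
      list(ok = TRUE, value = v)
    },
    medication = {
      code <- map_medication(matched_text, spec$atc_map)
      if (is.na(code)) return(list(ok = NULL))
      list(ok = TRUE, value = code)
    })
}

mention_negated <- function(text, sentences, start, end, rules) {
  si <- sentence_index_at(sentences, start)
  if (is.na(si)) return(FALSE)
  s0 <- sentences$start[si]
  s1 <- sentences$end[si]
  is_negated(span_text(text, s0, s1),
             start - s0, min(end, s1) - s0, rules)
}

# longest-prefix lookup after case/accent folding
map_surface <- function(surface, map) {
  key <- trimws(fold_text(surface))
  cand <- names(map)[order(-nchar(names(map)))]
  for (k in cand) {
    if (startsWith(key, fold_text(k))) return(map[[k]])
  }
  NA_character_
}

#' Map a medication surface form to an ATC code
#'
#' Longest-prefix lookup after case/accent folding, so dose suffixes
#' (`"Apixabán 5 mg"`) are tolerated. Unmapped surfaces return `NA` with a
#' warning.
#'
#' @param surface matched drug text.
#' @param atc_map named list/vector: drug surface form -> ATC code.
#' @return ATC code string, or `NA`.
#' @export
map_medication <- function(surface, atc_map) {
  if (length(atc_map) == 0L) {
    stop("configuration error: empty atc_map", call. = FALSE)
  }
  code <- map_surface(surface, atc_map)
  if (is.na(code)) {
    warning("unmapped medication surface '", surface, "'", call. = FALSE)
  }
  code
}

# affirmed mention wins over negated; first affirmed mention provides the
# value; boolean with only negated mentions -> explicit FALSE
resolve_values <- function(mentions, schema) {
  values <- list()
  for (spec in schema) {
    m <- mentions[mentions$variable_id == spec$variable_id, , drop = FALSE]
    if (nrow(m) == 0L) next
    aff <- m[!m$negated, , drop = FALSE]
    if (nrow(aff) > 0L) {
      values[[spec$variable_id]] <- aff$value[[1L]]
    } else if (spec$value_type == "boolean") {
      values[[spec$variable_id]] <- FALSE
    }
  }
  values
}

#' Detect new-onset and prior-history AF flags
#'
#' `af_prior_history` is set by a non-negated AF mention (bare or
#' onset-qualified) in Personal History. `af_new_onset` is set by a
#' non-negated mention in Diagnosis or Current Illness that is either
#' onset-qualified, or bare with no prior-history mention in the same
#' report. The two flags are independently assignable.
#'
#' @inheritParams extract_report
#' @param af_patterns list with `bare` and `onset` regex vectors.
#' @return list with logical `af_new_onset` and `af_prior_history`.
#' @export
detect_af_flags <- function(sectioned, text, af_patterns, rules) {
  folded <- fold_text(text)
  sentences <- sentence_spans(text)

  affirmed_in <- function(labels, patterns) {
    spans <- sectioned[sectioned$label %in% labels, , drop = FALSE]
    if (nrow(spans) == 0L) return(FALSE)
    for (i in seq_len(nrow(spans))) {
      sec_text <- span_text(folded, spans$start[i], spans$end[i])
      for (pat in patterns) {
        hits <- regex_capture_all(pat, sec_text)
        if (nrow(hits) == 0L) next
        for (j in seq_len(nrow(hits))) {
          m_start <- spans$start[i] + hits$start[j]
          m_end <- spans$start[i] + hits$end[j]
          if (!mention_negated(text, sentences, m_start, m_end, rules)) {
            return(TRUE)
          }
        }
      }
    }
    FALSE
  }

  all_pats <- c(af_patterns$onset, af_patterns$bare)
  prior <- affirmed_in("PersonalHistory", all_pats)
  onset_sections <- c("Diagnosis", "CurrentIllness")
  onset_qualified <- affirmed_in(onset_sections, af_patterns$onset)
  bare <- affirmed_in(onset_sections, af_patterns$bare)

  list(af_new_onset = onset_qualified || (bare && !prior),
       af_prior_history = prior)
}
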
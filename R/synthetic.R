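#' Configuration for the synthetic discharge-report generator
#'
#' The generator emulates the population the extraction pipeline targets:
#' multi-section cardiology discharge reports with the nine standardized
#' headings, variable mentions with synonym/negation/distractor noise, lab
#' numerics with units, ATC-mappable medication mentions, AF-onset versus
#' prior-AF phrasing, per-patient multi-report timelines, and a coded
#' export with injectable false-positive/false-negative coding errors.
#' The default coding error rates (23% false positives among coded
#' AF-onset instances, 26% of true onsets missed) reproduce the audit
#' figures that motivate reconciling coded with text-extracted data.
#'
#' @param n_patients number of patients.
#' @param af_prevalence fraction of patients with a true new AF onset.
#' @param negation_rate probability that an absent condition is rendered
#'   as an explicitly negated mention (also drives negated AF distractor
#'   sentences).
#' @param synonym_rate probability of choosing a non-primary surface form
#'   or an alternative measurement unit.
#' @param distractor_rate probability of injecting an out-of-section lab
#'   mention (e.g. an outpatient value in the Evolution section).
#' @param coding_fp_rate target fraction of coded AF-onset patients
#'   without a true onset.
#' @param coding_fn_rate target fraction of true-onset patients absent
#'   from the coded export.
#' @param coded_missing_rate probability that a coded variable value is
#'   masked (echo parameters are never coded, mirroring their absence from
#'   structured exports).
#' @param af_doc_rate fraction of true onsets actually documented in a
#'   discharge report (not every onset reaches a report).
#' @param prior_af_rate fraction of non-onset patients with prior AF
#'   history.
#' @param date_jitter_days uniform jitter (days) applied to coding dates
#'   around the anchor event.
#' @param min_reports,max_reports per-patient report count range.
#' @param seed integer; fully determines the corpus byte-for-byte.
#' @param language `"es"` (as in the source hospital) or `"en"`.
#' @return object of class `generation_config`.
#' @export
generation_config <- function(n_patients = 200L, af_prevalence = 0.3,
                              negation_rate = 0.2, synonym_rate = 0.3,
                              distractor_rate = 0.2,
                              coding_fp_rate = 0.23,
                              coding_fn_rate = 0.26,
                              coded_missing_rate = 0.5,
                              af_doc_rate = 0.9, prior_af_rate = 0.1,
                              date_jitter_days = 10L, min_reports = 1L,
                              max_reports = 3L, seed = 1L,
                              language = "es") {
  rates <- c(af_prevalence = af_prevalence, negation_rate = negation_rate,
             synonym_rate = synonym_rate, distractor_rate = distractor_rate,
             coding_fp_rate = coding_fp_rate,
             coding_fn_rate = coding_fn_rate,
             coded_missing_rate = coded_missing_rate,
             af_doc_rate = af_doc_rate, prior_af_rate = prior_af_rate)
  if (any(rates < 0 | rates > 1)) {
    bad <- names(rates)[rates < 0 | rates > 1]
    stop("configuration error: rates must lie in [0, 1]: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (n_patients < 0 || date_jitter_days < 0 || min_reports < 1 ||
      max_reports < min_reports) {
    stop("configuration error: invalid counts", call. = FALSE)
  }
  structure(c(as.list(rates),
              list(n_patients = as.integer(n_patients),
                   date_jitter_days = as.integer(date_jitter_days),
                   min_reports = as.integer(min_reports),
                   max_reports = as.integer(max_reports),
                   seed = as.integer(seed), language = language)),
            class = "generation_config")
}

# prevalence of each variable class in a profile
class_presence <- c(demographic = 0.95, history = 0.35, lab = 0.7,
                    echo = 0.55, medication = 0.45, procedure = 0.2)

sim_value <- function(spec) {
  s <- spec$sim
  if (!is.null(s$mean)) {
    v <- rnorm(1, s$mean, s$sd)
    v <- min(max(v, s$min), s$max)
  } else {
    v <- runif(1, s$min, s$max)
  }
  round(v, s$digits %||% 0L)
}

sample_profile <- function(i, config, schema, templates) {
  pid <- sprintf("P%05d", i)
  status <- if (runif(1) < config$af_prevalence) {
    "debut"
  } else if (runif(1) < config$prior_af_rate) "prior" else "none"
  documented <- status == "debut" && runif(1) < config$af_doc_rate
  n_reports <- if (config$min_reports == config$max_reports) {
    config$min_reports
  } else {
    sample(seq(config$min_reports, config$max_reports), 1)
  }
  anchor <- as.Date("2017-01-01") + (sample.int(1096L, 1) - 1L)

  variables <- list()
  for (spec in schema) {
    p <- class_presence[[spec$class]]
    if (spec$variable_id == "sex" || spec$variable_id == "age") p <- 0.95
    present <- runif(1) < p
    if (!present) {
      # absent booleans may still be explicitly negated (negation noise)
      if (spec$value_type == "boolean" && runif(1) < config$negation_rate) {
        variables[[spec$variable_id]] <- list(value = FALSE, negated = TRUE)
      }
      next
    }
    v <- switch(spec$value_type,
      boolean = list(value = TRUE, negated = FALSE),
      numeric = list(value = sim_value(spec), negated = FALSE),
      categorical = {
        val <- sample(unique(unlist(spec$value_map)), 1)
        list(value = val, negated = FALSE)
      },
      medication = {
        surface <- sample(spec$surfaces, 1)
        list(value = unname(map_surface(surface, spec$atc_map)),
             negated = FALSE, surface = surface)
      })
    variables[[spec$variable_id]] <- v
  }

  # report dates: the onset report (if documented) sits at the debut date;
  # the others are scattered 15..210 days away on either side
  onset_index <- NA_integer_
  offsets <- sample(c(-210:-15, 15:210), n_reports, replace = TRUE)
  if (documented) {
    onset_index <- sample.int(n_reports, 1)
    offsets[onset_index] <- 0L
  }
  report_dates <- anchor + offsets

  # assign each defined variable to a carrier report (preferring the
  # onset report, which describes the debut admission), plus occasionally
  # a second report
  plan <- replicate(n_reports, character(), simplify = FALSE)
  for (vid in names(variables)) {
    carrier <- if (!is.na(onset_index) && runif(1) < 0.75) {
      onset_index
    } else {
      sample.int(n_reports, 1)
    }
    plan[[carrier]] <- c(plan[[carrier]], vid)
    if (n_reports > 1L && runif(1) < 0.3) {
      extra <- sample(setdiff(seq_len(n_reports), carrier), 1)
      plan[[extra]] <- c(plan[[extra]], vid)
    }
  }

  af_mode <- character(n_reports)
  for (r in seq_len(n_reports)) {
    af_mode[r] <- if (!is.na(onset_index) && r == onset_index) {
      "onset"
    } else if (status == "debut" && documented &&
               report_dates[r] > anchor && runif(1) < 0.7) {
      "prior"   # post-debut reports carry the AF as known history
    } else if (status == "prior" && runif(1) < 0.8) {
      "prior"
    } else if (status == "none" && runif(1) < config$negation_rate * 0.5) {
      "negated"
    } else {
      "none"
    }
  }

  list(patient_id = pid, status = status,
       has_prior_af = status == "prior", documented = documented,
       debut_date = if (status == "debut") anchor else as.Date(NA),
       anchor = anchor, n_reports = n_reports,
       report_dates = report_dates, onset_index = onset_index,
       variables = variables, plan = plan, af_mode = af_mode)
}

# fill {slot} placeholders; returns text plus 0-based span of each slot
fill_template <- function(tmpl, values) {
  m <- stringi::stri_locate_all_regex(tmpl, "\\{[a-z_]+\\}")[[1]]
  if (all(is.na(m[, 1]))) return(list(text = tmpl, spans = list()))
  out <- character()
  spans <- list()
  cursor <- 1L
  offset <- 0L
  for (k in seq_len(nrow(m))) {
    name <- substr(tmpl, m[k, 1] + 1L, m[k, 2] - 1L)
    pre <- substr(tmpl, cursor, m[k, 1] - 1L)
    val <- as.character(values[[name]])
    out <- c(out, pre, val)
    start0 <- offset + nchar(pre)
    spans[[name]] <- c(start = start0, end = start0 + nchar(val))
    offset <- start0 + nchar(val)
    cursor <- m[k, 2] + 1L
  }
  out <- c(out, substr(tmpl, cursor, nchar(tmpl)))
  list(text = paste(out, collapse = ""), spans = spans)
}

pick <- function(x) if (length(x) == 1L) x[[1L]] else sample(x, 1)[[1L]]

choose_surface <- function(spec, config) {
  s <- spec$surfaces
  if (length(s) <= 1L) return(s[[1L]])
  if (runif(1) < config$synonym_rate) pick(s[-1L]) else s[[1L]]
}

format_num <- function(x) format(x, trim = TRUE, scientific = FALSE)

# rendered (value string, unit string) honoring alternative units
render_measurement <- function(spec, value, config) {
  alt <- spec$alt_units
  if (length(alt) > 0L && runif(1) < config$synonym_rate) {
    a <- pick(alt)
    raw <- round(value / spec$unit_factors[[a$unit]], a$digits %||% 0L)
    list(value = format_num(raw), unit = a$render %||% a$unit)
  } else {
    list(value = format_num(value), unit = spec$canonical_unit %||% "")
  }
}

#' Render one synthetic discharge report
#'
#' Deterministic given `(profile, report_index, config$seed)`: the
#' rendering RNG stream is derived from the three, so a report can be
#' re-rendered in isolation. Section headings come from the configured
#' language's templates; lab numerics are rendered only inside
#' Complementary Tests and prior-AF phrasing only inside Personal History.
#'
#' @param profile a patient profile from the generator.
#' @param report_index which of the patient's reports to render.
#' @param config a [generation_config()].
#' @param schema,templates loaded schema and templates (defaults load the
#'   bundled ones for `config$language`).
#' @return list with `report` (`report_id`, `patient_id`, `date`, `text`)
#'   and `gold` (section spans, mentions with spans/values/negation flags,
#'   AF flags).
#' @export
render_report <- function(profile, report_index, config,
                          schema = load_schema(config$language),
                          templates = load_templates(config$language)) {
  stopifnot(report_index >= 1L, report_index <= profile$n_reports)
  with_seed(derive_seed(config$seed, profile$patient_id, report_index),
            render_report_impl(profile, report_index, config, schema,
                               templates))
}

render_report_impl <- function(profile, report_index, config, schema,
                               templates) {
  t <- templates
  vars <- profile$plan[[report_index]]
  af_mode <- profile$af_mode[report_index]
  date <- profile$report_dates[report_index]
  report_id <- sprintf("%s-R%d", profile$patient_id, report_index)

  by_class <- split(vars, vapply(vars, function(v) schema[[v]]$class, ""))
  mentions <- list()
  note_mention <- function(vid, section, start, end, text, value, negated,
                           distractor = FALSE) {
    mentions[[length(mentions) + 1L]] <<- data.frame(
      variable_id = vid, section = section, start = start, end = end,
      matched_text = text, value = I(list(value)), negated = negated,
      distractor = distractor, stringsAsFactors = FALSE)
  }

  # one section block: returns list(label, text, sentences are already
  # joined; mention offsets are block-relative and fixed up later)
  blocks <- list()
  add_block <- function(label, heading, sentences, sep = " ") {
    body <- paste(vapply(sentences, `[[`, "", "text"), collapse = sep)
    txt <- if (is.null(heading)) body else paste0(heading, "\n", body)
    prefix <- if (is.null(heading)) 0L else nchar(heading) + 1L
    # fix up sentence-relative mention offsets
    off <- prefix
    for (s in sentences) {
      for (mn in s$mentions) {
        note_mention(mn$vid, label, off + mn$start, off + mn$end, mn$text,
                     mn$value, mn$negated, mn$distractor %||% FALSE)
      }
      off <- off + nchar(s$text) + nchar(sep)
    }
    blocks[[length(blocks) + 1L]] <<- list(label = label, text = txt)
  }
  sentence <- function(text, mentions = list()) {
    list(text = text, mentions = mentions)
  }
  mk_mention <- function(vid, span, text, value, negated = FALSE,
                         distractor = FALSE) {
    list(vid = vid, start = unname(span[["start"]]),
         end = unname(span[["end"]]), text = text, value = value,
         negated = negated, distractor = distractor)
  }

  # --- Header ---
  hdr <- fill_template(t$header, list(date = as.character(date),
                                      patient_id = profile$patient_id))
  add_block("Header", NULL, list(sentence(hdr$text)))

  # --- Reason for consultation ---
  complaint <- pick(t$complaints)
  demo <- intersect(c("sex", "age"), vars)
  rfc <- if (length(demo) == 2L) {
    sexv <- profile$variables$sex$value
    sex_surface <- pick(t$sex_surfaces[[sexv]])
    f <- fill_template(pick(t$reason_demo),
                       list(sex = sex_surface,
                            age = format_num(profile$variables$age$value),
                            complaint = complaint))
    sentence(f$text, list(
      mk_mention("sex", f$spans$sex, sex_surface, sexv),
      mk_mention("age", f$spans$age, format_num(
        profile$variables$age$value), profile$variables$age$value)))
  } else {
    f <- fill_template(pick(t$reason_plain), list(complaint = complaint))
    sentence(f$text)
  }
  add_block("ReasonForConsultation", t$headings$ReasonForConsultation,
            list(rfc))

  # --- Personal history ---
  hist_vars <- by_class$history %||% character()
  ph <- list()
  for (vid in hist_vars) {
    spec <- schema[[vid]]
    v <- profile$variables[[vid]]
    surface <- choose_surface(spec, config)
    tmpl <- pick(if (v$negated) t$history_negated else t$history_affirmed)
    f <- fill_template(tmpl, list(surface = surface))
    ph[[length(ph) + 1L]] <- sentence(f$text, list(
      mk_mention(vid, f$spans$surface, surface, v$value, v$negated)))
  }
  if (af_mode == "prior") {
    ph[[length(ph) + 1L]] <- sentence(pick(t$af_prior))
  }
  if (length(ph) == 0L && runif(1) < 0.5) {
    ph <- list(sentence(pick(t$filler$PersonalHistory)))
  }
  if (length(ph) > 0L) {
    add_block("PersonalHistory", t$headings$PersonalHistory, ph)
  }

  # --- Current illness ---
  ci <- list()
  onset_in_ci <- af_mode == "onset" && runif(1) < 0.3
  if (onset_in_ci) ci[[1L]] <- sentence(pick(t$af_onset_current_illness))
  if (runif(1) < 0.6) {
    ci[[length(ci) + 1L]] <- sentence(pick(t$filler$CurrentIllness))
  }
  if (length(ci) > 0L) {
    add_block("CurrentIllness", t$headings$CurrentIllness, ci)
  }

  # --- General exploration ---
  if (runif(1) < 0.4) {
    add_block("GeneralExploration", t$headings$GeneralExploration,
              list(sentence(pick(t$filler$GeneralExploration))))
  }

  # --- Complementary tests (labs and echo numerics live here only) ---
  num_vars <- c(by_class$lab %||% character(),
                by_class$echo %||% character())
  if (length(num_vars) > 0L) {
    ct <- list()
    for (vid in num_vars) {
      spec <- schema[[vid]]
      v <- profile$variables[[vid]]
      surface <- choose_surface(spec, config)
      meas <- render_measurement(spec, v$value, config)
      tmpl <- pick(if (spec$class == "echo") t$echo else t$lab)
      f <- fill_template(tmpl, list(surface = surface, value = meas$value,
                                    unit = meas$unit))
      ct[[length(ct) + 1L]] <- sentence(f$text, list(
        mk_mention(vid, f$spans$surface, surface, v$value)))
    }
    add_block("ComplementaryTests", t$headings$ComplementaryTests, ct,
              sep = "\n")
  }

  # --- Diagnosis ---
  dx <- list()
  if (af_mode == "onset" && !onset_in_ci) {
    tmpl_set <- if (runif(1) < 0.75) t$af_onset_qualified else
      t$af_onset_bare
    dx[[1L]] <- sentence(pick(tmpl_set))
  } else if (af_mode == "onset" && onset_in_ci && runif(1) < 0.5) {
    dx[[1L]] <- sentence(pick(t$af_onset_qualified))
  } else if (af_mode == "negated") {
    dx[[1L]] <- sentence(pick(t$af_negated))
  }
  if (length(dx) == 0L) dx <- list(sentence(pick(t$filler$Diagnosis)))
  add_block("Diagnosis", t$headings$Diagnosis, dx)

  # --- Treatment (medications, procedures) ---
  rx_vars <- c(by_class$medication %||% character(),
               by_class$procedure %||% character())
  rx <- list()
  for (vid in rx_vars) {
    spec <- schema[[vid]]
    v <- profile$variables[[vid]]
    if (spec$value_type == "medication") {
      surface <- v$surface
      f <- fill_template(pick(t$medication), list(surface = surface))
      rx[[length(rx) + 1L]] <- sentence(f$text, list(
        mk_mention(vid, f$spans$surface, surface, v$value)))
    } else {
      surface <- choose_surface(spec, config)
      tmpl <- pick(if (v$negated) t$procedure_negated else
        t$procedure_affirmed)
      f <- fill_template(tmpl, list(surface = surface))
      rx[[length(rx) + 1L]] <- sentence(f$text, list(
        mk_mention(vid, f$spans$surface, surface, v$value, v$negated)))
    }
  }
  if (length(rx) == 0L && runif(1) < 0.5) {
    rx <- list(sentence(pick(t$filler$Treatment)))
  }
  if (length(rx) > 0L) {
    add_block("Treatment", t$headings$Treatment, rx)
  }

  # --- Evolution (fillers and out-of-section lab distractors) ---
  ev <- list()
  if (runif(1) < config$distractor_rate) {
    lab_ids <- names(schema)[vapply(schema, function(s)
      s$class == "lab", logical(1))]
    vid <- pick(lab_ids)
    spec <- schema[[vid]]
    val <- sim_value(spec)
    f <- fill_template(t$distractor_lab[[1L]],
                       list(surface = spec$surfaces[[1L]],
                            value = format_num(val),
                            unit = spec$canonical_unit))
    ev[[1L]] <- sentence(f$text, list(
      mk_mention(vid, f$spans$surface, spec$surfaces[[1L]], val,
                 distractor = TRUE)))
  }
  if (runif(1) < 0.6 || length(ev) > 0L) {
    ev[[length(ev) + 1L]] <- sentence(pick(t$filler$Evolution))
  }
  if (length(ev) > 0L) {
    add_block("Evolution", t$headings$Evolution, ev)
  }

  # --- assemble; block i spans [start_i, start_{i+1}) ---
  texts <- vapply(blocks, `[[`, "", "text")
  texts <- paste0(texts, c(rep("\n\n", length(texts) - 1L), ""))
  starts <- cumsum(c(0L, nchar(texts)[-length(texts)]))
  full <- paste(texts, collapse = "")
  sections <- data.frame(
    label = vapply(blocks, `[[`, "", "label"),
    start = as.integer(starts),
    end = as.integer(starts + nchar(texts)),
    stringsAsFactors = FALSE)

  mentions_df <- if (length(mentions)) do.call(rbind, mentions) else
    cbind(empty_mentions(), data.frame(distractor = logical()))
  if (nrow(mentions_df) > 0L) {
    block_of <- match(mentions_df$section,
                      vapply(blocks, `[[`, "", "label"))
    mentions_df$start <- mentions_df$start + starts[block_of]
    mentions_df$end <- mentions_df$end + starts[block_of]
  }

  list(report = list(report_id = report_id,
                     patient_id = profile$patient_id,
                     date = date, text = full),
       gold = list(report_id = report_id,
                   patient_id = profile$patient_id, date = date,
                   sections = sections, mentions = mentions_df,
                   af_new_onset = af_mode == "onset",
                   af_prior_history = af_mode == "prior"))
}

#' Generate a synthetic corpus with ground truth
#'
#' Produces discharge reports, a coded-system export with controlled
#' false-positive/false-negative AF coding errors, and gold annotations
#' (section spans, variable mentions, per-report AF flags, patient truth
#' vectors). The coded export corrupts the true AF labels with exact-count
#' sampling, so realized corruption fractions converge to the configured
#' rates. Echo parameters are never coded; other coded values are masked
#' at `coded_missing_rate`.
#'
#' @param config a [generation_config()].
#' @return object of class `af_corpus`: list with `reports`, `coded`
#'   (data.frame), `gold` (`$reports`, `$patients`), `profiles`, `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generation_config"))
  schema <- load_schema(config$language)
  templates <- load_templates(config$language)
  if (config$n_patients == 0L) {
    return(structure(list(reports = list(),
                          coded = empty_coded(schema),
                          gold = list(reports = list(), patients = list()),
                          profiles = list(), config = config),
                     class = "af_corpus"))
  }
  profiles <- with_seed(config$seed, {
    lapply(seq_len(config$n_patients), sample_profile, config = config,
           schema = schema, templates = templates)
  })
  reports <- list()
  gold_reports <- list()
  for (p in profiles) {
    for (r in seq_len(p$n_reports)) {
      rendered <- render_report(p, r, config, schema, templates)
      reports[[length(reports) + 1L]] <- rendered$report
      gold_reports[[length(gold_reports) + 1L]] <- rendered$gold
    }
  }
  names(reports) <- vapply(reports, `[[`, "", "report_id")
  names(gold_reports) <- names(reports)

  gold_patients <- lapply(profiles, function(p) {
    list(patient_id = p$patient_id, status = p$status,
         has_af = p$status == "debut",
         debut_date = p$debut_date, has_prior_af = p$has_prior_af,
         documented = p$documented,
         onset_report_id = if (!is.na(p$onset_index))
           sprintf("%s-R%d", p$patient_id, p$onset_index) else
             NA_character_,
         variables = lapply(p$variables, `[[`, "value"))
  })
  names(gold_patients) <- vapply(profiles, `[[`, "", "patient_id")

  coded <- with_seed(derive_seed(config$seed, "coded"),
                     build_coded_export(profiles, schema, config))

  structure(list(reports = reports, coded = coded,
                 gold = list(reports = gold_reports,
                             patients = gold_patients),
                 profiles = profiles, config = config),
            class = "af_corpus")
}

coded_variable_ids <- function(schema) {
  names(schema)[vapply(schema, function(s)
    s$class %in% c("demographic", "history", "lab", "echo"), logical(1))]
}

empty_coded <- function(schema) {
  cols <- c("patient_id", "coded_af", "coding_date",
            coded_variable_ids(schema))
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                               cols), stringsAsFactors = FALSE)
  df
}

build_coded_export <- function(profiles, schema, config) {
  pids <- vapply(profiles, `[[`, "", "patient_id")
  status <- vapply(profiles, `[[`, "", "status")
  true_af <- pids[status == "debut"]
  other <- pids[status != "debut"]

  n_keep <- round(length(true_af) * (1 - config$coding_fn_rate))
  keep <- if (n_keep > 0) sample(true_af, n_keep) else character()
  n_fp <- if (config$coding_fp_rate < 1) {
    round(n_keep * config$coding_fp_rate / (1 - config$coding_fp_rate))
  } else {
    length(other)
  }
  fp <- if (n_fp > 0) sample(other, min(n_fp, length(other))) else
    character()

  jit <- function(n) {
    j <- config$date_jitter_days
    if (j == 0L) rep(0L, n) else sample(seq(-j, j), n, replace = TRUE)
  }
  coding_date <- setNames(rep(as.Date(NA), length(pids)), pids)
  by_pid <- setNames(profiles, pids)
  if (length(keep)) {
    coding_date[keep] <- as.Date(vapply(keep, function(pid)
      as.character(by_pid[[pid]]$debut_date), "")) + jit(length(keep))
  }
  if (length(fp)) {
    coding_date[fp] <- as.Date(vapply(fp, function(pid) {
      rd <- by_pid[[pid]]$report_dates
      as.character(rd[sample.int(length(rd), 1L)])
    }, "")) + jit(length(fp))
  }

  vars <- coded_variable_ids(schema)
  rows <- lapply(profiles, function(p) {
    vals <- lapply(vars, function(vid) {
      if (schema[[vid]]$class == "echo") return(NA)  # never coded
      v <- p$variables[[vid]]
      if (is.null(v)) return(NA)
      if (runif(1) < config$coded_missing_rate) return(NA)
      v$value
    })
    names(vals) <- vars
    c(list(patient_id = p$patient_id,
           coded_af = as.integer(p$patient_id %in% c(keep, fp)),
           coding_date = coding_date[[p$patient_id]]), vals)
  })
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(lapply(r, function(x) if (is.null(x)) NA else x),
                  stringsAsFactors = FALSE)
  }))
  df$coding_date <- as.Date(df$coding_date)
  rownames(df) <- NULL
  df
}

#' Derive the gold value map of one report from its gold mentions
#'
#' Mirrors the extraction contract: distractor mentions are excluded, an
#' affirmed mention provides the value, and a boolean with only negated
#' mentions is an explicit `FALSE`.
#'
#' @param gold_entry one element of `corpus$gold$reports`.
#' @param schema the schema used to generate the corpus.
#' @return named list of values.
#' @export
gold_report_values <- function(gold_entry, schema) {
  m <- gold_entry$mentions
  m <- m[!m$distractor, , drop = FALSE]
  values <- list()
  for (spec in schema) {
    mm <- m[m$variable_id == spec$variable_id, , drop = FALSE]
    if (nrow(mm) == 0L) next
    aff <- mm[!mm$negated, , drop = FALSE]
    if (nrow(aff) > 0L) {
      values[[spec$variable_id]] <- aff$value[[1L]]
    } else if (spec$value_type == "boolean") {
      values[[spec$variable_id]] <- FALSE
    }
  }
  values
}

#' Report-level gold labels of a corpus
#'
#' @param corpus an `af_corpus`.
#' @return data.frame with `report_id`, `patient_id`, `text`, `label`
#'   (`af_onset` / `negative`).
#' @export
labeled_reports <- function(corpus) {
  g <- corpus$gold$reports
  data.frame(
    report_id = vapply(g, `[[`, "", "report_id"),
    patient_id = vapply(g, `[[`, "", "patient_id"),
    text = vapply(corpus$reports, `[[`, "", "text"),
    label = ifelse(vapply(g, function(x) isTRUE(x$af_new_onset),
                          logical(1)), "af_onset", "negative"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Reports usable as classifier negatives
#'
#' Reports of patients with no AF in either the gold truth or the coded
#' export (so no negative can simultaneously appear as a coded positive).
#'
#' @param corpus an `af_corpus`.
#' @return list of reports.
#' @export
negative_pool_reports <- function(corpus) {
  status <- vapply(corpus$gold$patients, `[[`, "", "status")
  coded_pos <- corpus$coded$patient_id[corpus$coded$coded_af == 1]
  ok <- names(status)[status == "none" & !(names(status) %in% coded_pos)]
  Filter(function(r) r$patient_id %in% ok, corpus$reports)
}
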
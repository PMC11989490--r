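#' The closed set of standardized discharge-report section labels
#'
#' Nine standardized sections plus `Unknown`, which is reserved for text
#' before the first recognized heading (or a whole report with no
#' recognized heading).
#'
#' @return character vector of the ten labels.
#' @export
section_labels <- function() {
  c("Header", "ReasonForConsultation", "PersonalHistory", "CurrentIllness",
    "GeneralExploration", "ComplementaryTests", "Diagnosis", "Treatment",
    "Evolution", "Unknown")
}

afdebut_extdata <- function(file) {
  system.file("extdata", file, package = "afdebut", mustWork = TRUE)
}

pick_language <- function(cfg, language, what) {
  if (!language %in% names(cfg)) {
    stop("configuration error: no '", language, "' entry in ", what,
         " (available: ", paste(names(cfg), collapse = ", "), ")",
         call. = FALSE)
  }
  cfg[[language]]
}

#' Load a heading lexicon
#'
#' A heading lexicon maps section labels to heading surface forms. Surface
#' forms are compared case-insensitively after accent folding and stripping
#' of one trailing colon.
#'
#' @param language `"es"` or `"en"` (for the bundled lexicons).
#' @param path optional path to a YAML lexicon file; defaults to the
#'   bundled `headings.yaml`.
#' @return named list: section label -> character vector of surface forms.
#' @export
load_heading_lexicon <- function(language = "es", path = NULL) {
  cfg <- yaml::read_yaml(path %||% afdebut_extdata("headings.yaml"))
  lex <- pick_language(cfg, language, "heading lexicon")
  bad <- setdiff(names(lex), section_labels())
  if (length(bad)) {
    stop("configuration error: unknown section labels in lexicon: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  lapply(lex, fold_text)
}

#' Construct a negation rule set
#'
#' @param pre_triggers phrases that negate a following mention.
#' @param post_triggers phrases that negate a preceding mention.
#' @param terminators scope-breaking tokens (conjunctions, punctuation).
#' @param scope_window maximum number of tokens a trigger reaches.
#' @return object of class `negation_rules`.
#' @export
negation_rules <- function(pre_triggers, post_triggers, terminators,
                           scope_window = 5L) {
  scope_window <- as.integer(scope_window)
  if (is.na(scope_window) || scope_window < 1L) {
    stop("configuration error: scope_window must be >= 1", call. = FALSE)
  }
  if (length(pre_triggers) == 0L || length(post_triggers) == 0L) {
    stop("configuration error: trigger lists must be non-empty",
         call. = FALSE)
  }
  tok <- function(phrases) {
    lapply(fold_text(phrases), function(p) tokenize_spans(p)$token)
  }
  structure(
    list(pre_triggers = fold_text(pre_triggers),
         post_triggers = fold_text(post_triggers),
         terminators = fold_text(terminators),
         scope_window = scope_window,
         pre_tokens = tok(pre_triggers),
         post_tokens = tok(post_triggers)),
    class = "negation_rules")
}

#' Load a bundled negation rule set
#'
#' @inheritParams load_heading_lexicon
#' @return object of class `negation_rules`.
#' @export
load_negation_rules <- function(language = "es", path = NULL) {
  cfg <- yaml::read_yaml(path %||% afdebut_extdata("negation.yaml"))
  r <- pick_language(cfg, language, "negation rules")
  negation_rules(r$pre_triggers, r$post_triggers, r$terminators,
                 r$scope_window %||% 5L)
}

#' Load atrial-fibrillation mention patterns
#'
#' @inheritParams load_heading_lexicon
#' @return list with components `bare` and `onset`, each a character vector
#'   of regexes over folded text.
#' @export
load_af_patterns <- function(language = "es", path = NULL) {
  cfg <- yaml::read_yaml(path %||% afdebut_extdata("af_patterns.yaml"))
  p <- pick_language(cfg, language, "AF patterns")
  stopifnot(length(p$bare) > 0L, length(p$onset) > 0L)
  p
}

# generator sentence templates (internal)
load_templates <- function(language = "es", path = NULL) {
  cfg <- yaml::read_yaml(path %||% afdebut_extdata("templates.yaml"))
  pick_language(cfg, language, "templates")
}

regex_ok <- function(p) {
  !inherits(try(stringi::stri_detect_regex("x", p), silent = TRUE),
            "try-error")
}

#' Load the variable extraction schema
#'
#' Each schema entry describes one clinical variable: its value type
#' (boolean, numeric, categorical or medication), the regex patterns that
#' detect it, the report sections the patterns are allowed to search, and
#' (where applicable) unit-normalization factors, a categorical value map
#' or an ATC medication map. The entry's `class` (demographic, history,
#' lab, echo, medication, procedure) determines the temporal window used
#' when per-report vectors are merged into a patient vector.
#'
#' @param language `"es"` or `"en"`; selects the pattern set.
#' @param path optional path to a schema YAML; defaults to the bundled
#'   demonstrator schema.
#' @return list of `variable_spec` objects, named by variable id.
#' @export
load_schema <- function(language = "es", path = NULL) {
  cfg <- yaml::read_yaml(path %||% afdebut_extdata("schema.yaml"))
  specs <- lapply(cfg$variables, function(v) {
    patterns <- v$patterns[[language]]
    if (is.null(patterns)) {
      stop("configuration error: variable '", v$id, "' has no '", language,
           "' patterns", call. = FALSE)
    }
    spec <- list(
      variable_id = v$id,
      value_type = match.arg(v$type,
                             c("boolean", "numeric", "categorical",
                               "medication")),
      class = match.arg(v$class,
                        c("demographic", "history", "lab", "echo",
                          "medication", "procedure")),
      target_sections = v$sections,
      patterns = unlist(patterns),
      surfaces = unlist(v$surfaces[[language]] %||% character()),
      value_map = v$value_map %||% NULL,
      atc_map = v$atc_map %||% NULL,
      canonical_unit = v$units$canonical %||% NULL,
      unit_factors = if (!is.null(v$units$factors))
        unlist(v$units$factors) else NULL,
      alt_units = v$units$alt %||% list(),
      sim = v$sim %||% NULL,
      window_days_before = v$window_days_before %||% NULL,
      window_days_after = v$window_days_after %||% NULL)
    validate_variable_spec(spec)
    structure(spec, class = "variable_spec")
  })
  names(specs) <- vapply(specs, `[[`, "", "variable_id")
  specs
}

validate_variable_spec <- function(spec) {
  if (length(spec$target_sections) == 0L ||
      !all(spec$target_sections %in% section_labels())) {
    stop("configuration error: variable '", spec$variable_id,
         "' has invalid target sections", call. = FALSE)
  }
  if (!all(vapply(spec$patterns, regex_ok, logical(1)))) {
    stop("configuration error: variable '", spec$variable_id,
         "' has a pattern that does not compile", call. = FALSE)
  }
  if (spec$value_type == "numeric" &&
      !all(grepl("(?<value>", spec$patterns, fixed = TRUE))) {
    stop("configuration error: numeric variable '", spec$variable_id,
         "' must define a (?<value>...) capture group", call. = FALSE)
  }
  if (spec$value_type == "medication" && length(spec$atc_map) == 0L) {
    stop("configuration error: medication variable '", spec$variable_id,
         "' must define a non-empty atc_map", call. = FALSE)
  }
  if (spec$value_type == "categorical" && length(spec$value_map) == 0L) {
    stop("configuration error: categorical variable '", spec$variable_id,
         "' must define a non-empty value_map", call. = FALSE)
  }
  invisible(spec)
}

#' Map variable ids to temporal classes
#'
#' @param schema a schema as returned by [load_schema()].
#' @return named character vector: variable id -> class.
#' @export
variable_class_map <- function(schema) {
  vapply(schema, `[[`, "", "class")
}
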
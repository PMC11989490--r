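#' Temporal-window configuration for vector overlapping
#'
#' Lab values are admitted from a window before the debut date (default
#' 180 days, i.e. six months, with nothing after debut under the literal
#' reading of "prior"); echocardiographic parameters from a symmetric
#' 90-day window. History, demographic, medication and procedure values
#' use an unbounded window before debut and nothing after, unless
#' configured otherwise.
#'
#' @param lab_window_days_before,lab_window_days_after lab window (days).
#' @param echo_window_days_before,echo_window_days_after echo window (days).
#' @param other_window_days_before,other_window_days_after window for the
#'   remaining classes; `Inf` before, 0 after by default.
#' @return object of class `overlap_config`.
#' @export
overlap_config <- function(lab_window_days_before = 180,
                           lab_window_days_after = 0,
                           echo_window_days_before = 90,
                           echo_window_days_after = 90,
                           other_window_days_before = Inf,
                           other_window_days_after = 0) {
  w <- c(lab_window_days_before, lab_window_days_after,
         echo_window_days_before, echo_window_days_after,
         other_window_days_after)
  if (any(w < 0)) stop("configuration error: windows must be >= 0",
                       call. = FALSE)
  structure(list(
    lab = c(before = lab_window_days_before, after = lab_window_days_after),
    echo = c(before = echo_window_days_before,
             after = echo_window_days_after),
    other = c(before = other_window_days_before,
              after = other_window_days_after)),
    class = "overlap_config")
}

class_window <- function(config, class) {
  if (class %in% names(config)) config[[class]] else config$other
}

#' Merge a patient's report vectors into one debut-anchored vector
#'
#' For each variable, the candidates are the non-missing values whose
#' report date falls inside the variable class's temporal window relative
#' to the debut date; the chosen candidate minimizes the absolute distance
#' to debut, with ties broken toward the earlier report and then the
#' lexicographically smaller report id.
#'
#' @param vectors list of `report_vector` objects for one patient.
#' @param debut_date a `Date` (the AF debut anchor).
#' @param config an [overlap_config()].
#' @param class_map named character vector: variable id -> class (see
#'   [variable_class_map()]). Variables absent from the map use the
#'   `other` window.
#' @return object of class `patient_vector`: list with `patient_id`,
#'   `debut_date`, `values`, `source` (per-variable report id, date and
#'   signed day distance), and `missing_count` over `names(class_map)`.
#' @export
merge_patient <- function(vectors, debut_date, config = overlap_config(),
                          class_map = character()) {
  pids <- unique(vapply(vectors, `[[`, "", "patient_id"))
  if (length(pids) > 1L) {
    stop("input error: report vectors from multiple patients: ",
         paste(pids, collapse = ", "), call. = FALSE)
  }
  debut_date <- as.Date(debut_date)

  values <- list()
  source <- list()
  var_ids <- unique(c(names(class_map),
                      unlist(lapply(vectors, function(v) names(v$values)))))
  for (vid in var_ids) {
    cls <- if (vid %in% names(class_map)) class_map[[vid]] else "other"
    w <- class_window(config, cls)
    cand <- list()
    for (v in vectors) {
      if (is.null(v$values[[vid]])) next
      delta <- as.numeric(as.Date(v$report_date) - debut_date)
      if (delta < -w[["before"]] || delta > w[["after"]]) next
      cand[[length(cand) + 1L]] <- list(value = v$values[[vid]],
                                        report_id = v$report_id,
                                        date = as.Date(v$report_date),
                                        delta = delta)
    }
    if (length(cand) == 0L) next
    deltas <- vapply(cand, `[[`, 0, "delta")
    ids <- vapply(cand, `[[`, "", "report_id")
    ord <- order(abs(deltas), deltas, ids)
    best <- cand[[ord[1L]]]
    values[[vid]] <- best$value
    source[[vid]] <- list(report_id = best$report_id,
                          report_date = best$date,
                          days_from_debut = best$delta)
  }
  eval_vars <- if (length(class_map)) names(class_map) else var_ids
  structure(
    list(patient_id = if (length(pids)) pids else NA_character_,
         debut_date = debut_date, values = values, source = source,
         missing_count = sum(!(eval_vars %in% names(values)))),
    class = "patient_vector")
}

#' Resolve the AF debut date from a patient's report vectors
#'
#' The debut is the date of the earliest report asserting a new AF onset,
#' provided no chronologically earlier report of the same patient asserts
#' prior AF history (an onset claim contradicted by earlier history
#' resolves to "no debut" rather than guessing). Reports dated after the
#' debut that carry any AF flag are exposed as recurrence candidates; they
#' are not modelled further.
#'
#' @param vectors list of `report_vector` objects for one patient.
#' @return list with `debut_date` (`Date` or `NA`), `af_onset_report_id`
#'   (or `NA`) and `recurrence_report_ids` (character vector).
#' @export
resolve_debut <- function(vectors) {
  if (length(vectors) == 0L) {
    return(list(debut_date = as.Date(NA), af_onset_report_id = NA_character_,
                recurrence_report_ids = character()))
  }
  pids <- unique(vapply(vectors, `[[`, "", "patient_id"))
  if (length(pids) > 1L) {
    stop("input error: report vectors from multiple patients",
         call. = FALSE)
  }
  dates <- as.Date(vapply(vectors, function(v) as.character(v$report_date),
                          ""))
  ids <- vapply(vectors, `[[`, "", "report_id")
  onset <- vapply(vectors, function(v) isTRUE(v$af_new_onset), logical(1))
  prior <- vapply(vectors, function(v) isTRUE(v$af_prior_history),
                  logical(1))

  debut_date <- as.Date(NA)
  debut_id <- NA_character_
  cand <- order(dates, ids)[onset[order(dates, ids)]]
  for (i in cand) {
    if (!any(prior & dates < dates[i])) {
      debut_date <- dates[i]
      debut_id <- ids[i]
      break
    }
  }
  rec <- character()
  if (!is.na(debut_date)) {
    rec <- ids[(onset | prior) & dates > debut_date]
  }
  list(debut_date = debut_date, af_onset_report_id = debut_id,
       recurrence_report_ids = rec)
}

#' Compare per-variable missingness between coded and extracted sources
#'
#' @param extracted,coded data.frames with a `patient_id` column and one
#'   column per variable (`NA` = missing). Patients are aligned on the
#'   shared ids; disjoint id sets are an input error.
#' @return data.frame with one row per shared variable plus an `overall`
#'   row: missing fraction in each source and the relative reduction
#'   `(coded - extracted) / coded` (`NA` when the coded source has no
#'   missing values).
#' @export
missingness <- function(extracted, coded) {
  shared_ids <- intersect(extracted$patient_id, coded$patient_id)
  if (length(shared_ids) == 0L) {
    stop("input error: extracted and coded sources share no patient ids",
         call. = FALSE)
  }
  vars <- intersect(setdiff(names(extracted), "patient_id"),
                    setdiff(names(coded), "patient_id"))
  e <- extracted[match(shared_ids, extracted$patient_id), vars,
                 drop = FALSE]
  c_ <- coded[match(shared_ids, coded$patient_id), vars, drop = FALSE]
  n <- length(shared_ids)
  # reduction is computed from the missing-cell counts, not the already
  # divided fractions, so it agrees exactly with a direct tally
  k_e <- vapply(e, function(x) sum(is.na(x)), 0)
  k_c <- vapply(c_, function(x) sum(is.na(x)), 0)
  red <- ifelse(k_c > 0, (k_c - k_e) / k_c, NA_real_)
  out <- data.frame(variable = vars, coded_missing = unname(k_c) / n,
                    extracted_missing = unname(k_e) / n,
                    reduction = unname(red), stringsAsFactors = FALSE)
  tot_c <- sum(k_c)
  tot_e <- sum(k_e)
  rbind(out, data.frame(
    variable = "overall", coded_missing = tot_c / (n * length(vars)),
    extracted_missing = tot_e / (n * length(vars)),
    reduction = if (tot_c > 0) (tot_c - tot_e) / tot_c else NA_real_,
    stringsAsFactors = FALSE))
}
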
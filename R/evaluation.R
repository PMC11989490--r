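#' Score extracted report vectors against gold annotations
#'
#' Every (report, variable) pair is one evaluation cell. TP: present in
#' both with matching values (numeric within a relative tolerance,
#' boolean/categorical/medication exact); FP: extracted present but gold
#' absent, or values mismatched (a wrong asserted value counts against
#' precision; set `count_mismatch_as_fn = TRUE` to also count it as a
#' miss); FN: gold present, extracted absent; TN: absent in both.
#' Ratios with zero denominators are `NA` and excluded from macro
#' averages.
#'
#' @param extracted list of `report_vector` objects (or lists with
#'   `report_id` and `values`).
#' @param gold list of gold entries with `report_id` and `values` (a named
#'   list of ground-truth values per variable).
#' @param variables character vector of variable ids to evaluate.
#' @param numeric_tolerance relative tolerance for numeric equality.
#' @param count_mismatch_as_fn also count a mismatched value as a FN.
#' @return list with `per_variable` (counts + metrics per variable),
#'   `aggregate` (micro-averaged over all cells), `macro` (mean of
#'   per-variable metrics, `NA` excluded) and `n_cells`.
#' @export
score_vectors <- function(extracted, gold, variables,
                          numeric_tolerance = 0.01,
                          count_mismatch_as_fn = FALSE) {
  e_ids <- vapply(extracted, `[[`, "", "report_id")
  g_ids <- vapply(gold, `[[`, "", "report_id")
  if (!setequal(e_ids, g_ids) || anyDuplicated(e_ids) ||
      anyDuplicated(g_ids)) {
    stop("input error: extracted and gold report ids are not aligned",
         call. = FALSE)
  }
  gold <- gold[match(e_ids, g_ids)]

  counts <- matrix(0L, nrow = length(variables), ncol = 4,
                   dimnames = list(variables, c("tp", "fp", "fn", "tn")))
  for (i in seq_along(extracted)) {
    ev <- extracted[[i]]$values
    gv <- gold[[i]]$values
    for (v in variables) {
      e_has <- !is.null(ev[[v]])
      g_has <- !is.null(gv[[v]])
      cell <- if (!e_has && !g_has) {
        "tn"
      } else if (e_has && !g_has) {
        "fp"
      } else if (!e_has && g_has) {
        "fn"
      } else if (values_match(ev[[v]], gv[[v]], numeric_tolerance)) {
        "tp"
      } else {
        "fp"
      }
      counts[v, cell] <- counts[v, cell] + 1L
      if (cell == "fp" && e_has && g_has && count_mismatch_as_fn) {
        counts[v, "fn"] <- counts[v, "fn"] + 1L
      }
    }
  }
  per_variable <- data.frame(variable = variables, counts,
                             row.names = NULL, stringsAsFactors = FALSE)
  met <- t(apply(counts, 1, function(r) {
    confusion_metrics(r[["tp"]], r[["fp"]], r[["fn"]], r[["tn"]])
  }))
  per_variable <- cbind(per_variable, met)
  rownames(per_variable) <- NULL
  tot <- colSums(counts)
  aggregate <- confusion_metrics(tot[["tp"]], tot[["fp"]], tot[["fn"]],
                                 tot[["tn"]])
  macro <- colMeans(met, na.rm = TRUE)
  list(per_variable = per_variable, aggregate = aggregate, macro = macro,
       n_cells = length(extracted) * length(variables),
       numeric_tolerance = numeric_tolerance)
}

values_match <- function(e, g, tol) {
  if (is.numeric(g) && is.numeric(e)) {
    if (g == 0) return(e == 0)
    return(abs(e - g) <= tol * abs(g))
  }
  identical(as.character(e), as.character(g)) ||
    (is.logical(e) && is.logical(g) && e == g)
}

#' Fraction of gold AF-onset patients detected
#'
#' @param gold_onset_patients character vector of patient ids with a true
#'   AF onset (non-empty).
#' @param detected_onset_patients character vector of detected patient ids.
#' @return `|gold intersect detected| / |gold|`.
#' @export
detection_rate <- function(gold_onset_patients, detected_onset_patients) {
  gold_onset_patients <- unique(gold_onset_patients)
  if (length(gold_onset_patients) == 0L) {
    stop("input error: empty gold onset set", call. = FALSE)
  }
  length(intersect(gold_onset_patients, detected_onset_patients)) /
    length(gold_onset_patients)
}
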
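#' Segment a discharge report into standardized sections
#'
#' Deterministic heading-lexicon segmentation: a line whose content (after
#' trimming, accent/case folding and stripping one trailing colon) equals a
#' lexicon surface form opens a section of the corresponding label; the
#' section extends from the heading line start to the next recognized
#' heading or the end of the text. Text before the first recognized heading
#' is labeled `Unknown`. The module boundary allows a learned segmenter to
#' be swapped in later.
#'
#' @param text report text (single string).
#' @param lexicon heading lexicon as returned by [load_heading_lexicon()].
#' @return data.frame with columns `label`, `start`, `end` (0-based,
#'   half-open character offsets). Spans are non-overlapping, sorted, and
#'   jointly cover `[0, nchar(text))`; empty text yields zero rows.
#' @examples
#' lex <- load_heading_lexicon("en")
#' segment("DIAGNOSIS:\nAF\nTREATMENT:\napixaban", lex)
#' @export
segment <- function(text, lexicon) {
  stopifnot(is.character(text), length(text) == 1L)
  n <- nchar(text)
  empty <- data.frame(label = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (is.na(text) || n == 0L) return(empty)

  lookup <- unlist(lapply(names(lexicon), function(lab) {
    setNames(rep(lab, length(lexicon[[lab]])), lexicon[[lab]])
  }))

  nl <- stringi::stri_locate_all_fixed(text, "\n")[[1]]
  nl_pos <- if (all(is.na(nl[, 1]))) integer() else nl[, 1]  # 1-based
  line_starts0 <- c(0L, as.integer(nl_pos))                  # 0-based
  line_ends0 <- c(as.integer(nl_pos) - 1L, n)                # excl. newline

  keys <- fold_text(substr(rep(text, length(line_starts0)),
                           line_starts0 + 1L, line_ends0))
  keys <- sub(":$", "", trimws(keys))
  hit <- keys %in% names(lookup)

  if (!any(hit)) {
    return(data.frame(label = "Unknown", start = 0L, end = n,
                      stringsAsFactors = FALSE))
  }
  h_start <- line_starts0[hit]
  h_label <- unname(lookup[keys[hit]])
  starts <- h_start
  labels <- h_label
  if (h_start[1] > 0L) {
    starts <- c(0L, starts)
    labels <- c("Unknown", labels)
  }
  ends <- c(starts[-1], n)
  keep <- ends > starts  # drop zero-width span if heading is the last char
  data.frame(label = labels[keep], start = as.integer(starts[keep]),
             end = as.integer(ends[keep]), stringsAsFactors = FALSE)
}

#' Section every report of a corpus
#'
#' @param reports list of reports (each a list with `report_id` and `text`).
#' @param lexicon heading lexicon.
#' @return named list of section span tables, one per report.
#' @export
segment_corpus <- function(reports, lexicon) {
  out <- lapply(reports, function(r) segment(r$text, lexicon))
  names(out) <- vapply(reports, `[[`, "", "report_id")
  out
}
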
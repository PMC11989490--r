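#' Decide whether a mention is negated
#'
#' NegEx-style trigger/scope detection. A mention is negated when a
#' pre-trigger phrase ends within `scope_window` tokens before the mention
#' with no terminator token in between, or a post-trigger phrase starts
#' within `scope_window` tokens after the mention with no terminator in
#' between. Distance is counted in tokens (punctuation characters count as
#' tokens); the trigger adjacent to the mention is at distance 1. Callers
#' are expected to pass a single sentence, so negation never crosses
#' sentence boundaries.
#'
#' @param text sentence text.
#' @param start,end mention span, 0-based half-open character offsets into
#'   `text`.
#' @param rules a [negation_rules()] object.
#' @return `TRUE` if the mention is negated.
#' @examples
#' rules <- load_negation_rules("en")
#' is_negated("denies atrial fibrillation", 7, 26, rules)
#' is_negated("atrial fibrillation present", 0, 19, rules)
#' @export
is_negated <- function(text, start, end, rules) {
  stopifnot(inherits(rules, "negation_rules"))
  n <- nchar(text)
  if (start < 0 || end > n || end <= start) {
    stop("bounds error: mention span [", start, ", ", end,
         ") outside text of length ", n, call. = FALSE)
  }
  toks <- tokenize_spans(text)
  if (nrow(toks) == 0L) return(FALSE)

  mention <- which(toks$end > start & toks$start < end)
  if (length(mention) == 0L) return(FALSE)
  first <- min(mention)
  last <- max(mention)

  # pre side: walk backwards from the mention
  before <- rev(seq_len(first - 1L))
  if (scan_side(toks$token, before, rules$pre_tokens, rules$terminators,
                rules$scope_window, forward = FALSE)) {
    return(TRUE)
  }
  # post side: walk forwards from the mention
  after <- seq(last + 1L, length.out = max(0L, nrow(toks) - last))
  scan_side(toks$token, after, rules$post_tokens, rules$terminators,
            rules$scope_window, forward = TRUE)
}

# Walk token indices away from the mention (already ordered nearest-first).
# A trigger phrase counts if its mention-side end sits at distance
# <= scope_window, with no terminator strictly between.
scan_side <- function(tokens, idx, trigger_tokens, terminators,
                      scope_window, forward) {
  if (length(idx) == 0L) return(FALSE)
  for (d in seq_along(idx)) {
    if (d > scope_window) break
    i <- idx[d]
    if (tokens[i] %in% terminators) break
    for (phr in trigger_tokens) {
      k <- length(phr)
      span <- if (forward) i + seq_len(k) - 1L else i - rev(seq_len(k)) + 1L
      if (min(span) < 1L || max(span) > length(tokens)) next
      if (all(tokens[span] == phr)) return(TRUE)
    }
  }
  FALSE
}
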
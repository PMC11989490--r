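#' Case- and accent-fold text
#'
#' Lower-cases and strips Latin diacritics (plus the micro sign, so that
#' `µmol/l` matches `umol/l`). The mapping is strictly one character to one
#' character, so character offsets into the folded string are valid offsets
#' into the original string.
#'
#' @param x character vector.
#' @return character vector of the same length and the same `nchar()`.
#' @export
fold_text <- function(x) {
  chartr("áàâäãéèêëíìîïóòôöõúùûüñçµ",
         "aaaaaeeeeiiiiooooouuuuncu",
         tolower(x))
}

# substring by 0-based half-open character span
span_text <- function(text, start, end) {
  substr(text, start + 1L, end)
}

#' Tokenize text with character spans
#'
#' Tokens are maximal runs of letters/digits, or single punctuation
#' characters (punctuation is kept so that negation-scope terminators such
#' as commas are visible as tokens). Offsets are 0-based, half-open.
#'
#' @param text a single string.
#' @return data.frame with columns `start`, `end`, `token` (folded form).
#' @export
tokenize_spans <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(start = integer(), end = integer(),
                      token = character(), stringsAsFactors = FALSE))
  }
  m <- stringi::stri_locate_all_regex(
    text, "[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]")[[1]]
  if (all(is.na(m[, 1]))) {
    return(data.frame(start = integer(), end = integer(),
                      token = character(), stringsAsFactors = FALSE))
  }
  data.frame(start = m[, 1] - 1L, end = m[, 2],
             token = fold_text(substring(text, m[, 1], m[, 2])),
             stringsAsFactors = FALSE)
}

# Sentence spans (0-based half-open) covering all of `text`.
# Boundaries: newline, or a period followed by whitespace and an upper-case
# letter. Negation never crosses these boundaries.
sentence_spans <- function(text) {
  n <- nchar(text)
  if (n == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- stringi::stri_locate_all_regex(
    text, "\\n|\\.(?=\\s+\\p{Lu})")[[1]]
  cuts <- if (all(is.na(m[, 1]))) integer() else m[, 2]  # 1-based end incl.
  starts <- c(0L, cuts)
  ends <- c(cuts, n)
  keep <- ends > starts
  data.frame(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

# index (row) of the sentence containing 0-based position `pos`
sentence_index_at <- function(sentences, pos) {
  i <- which(sentences$start <= pos & pos < sentences$end)
  if (length(i) == 0L) NA_integer_ else i[1L]
}

#' Read / write JSON-lines files
#'
#' One JSON object per line, UTF-8. Used for corpora, sectioned reports,
#' report vectors and gold annotations.
#'
#' @param records a list of named lists.
#' @param path file path.
#' @return `read_jsonl()` returns a list of named lists.
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"))
  }, character(1))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con = con, useBytes = FALSE)
  invisible(path)
}

#' @rdname write_jsonl
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    jsonlite::fromJSON(l, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  })
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, keeping stage outputs pure
#' functions of their inputs and seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# small deterministic string hash -> non-negative integer < 2^31 - 1
hash_string <- function(x) {
  h <- 0
  for (cp in utf8ToInt(enc2utf8(x))) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

# derive a child seed from a parent seed and any scalar components
derive_seed <- function(seed, ...) {
  h <- as.integer(seed) %% 2147483647
  for (part in list(...)) {
    p <- if (is.character(part)) hash_string(part) else as.integer(part)
    h <- (h * 7919 + (p %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
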
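#' Deterministic suffix-stripping stemmer
#'
#' Reduces a lemma to a crude word-family stem by stripping the longest
#' matching derivational or inflectional suffix from a fixed, per-language
#' table. It is intentionally lightweight: its only job in the scoring
#' pipeline is to decide whether two lemmas belong to the same word family
#' (e.g. Spanish *flor* / *florista*), which drives the stem correction of
#' the word-similarity score. Lexicon entries may override the stem
#' explicitly, in which case this function is never consulted for them.
#'
#' @param lemma Character vector of lemmas.
#' @param language Language tag; `"es"` (default) and `"en"` ship suffix
#'   tables, any other tag falls back to lowercasing only.
#' @return Lowercase character vector of stems, same length as `lemma`.
#' @examples
#' stem_word(c("flor", "florista"))
#' @export
stem_word <- function(lemma, language = "es") {
  suffixes <- switch(language,
    es = c(
      "aciones", "uciones", "amiento", "imiento", "acion", "ucion",
      "adora", "adores", "adoras", "ador", "istas", "ista", "eros", "eras",
      "ero", "era", "osos", "osas", "oso", "osa", "mente", "idad", "idades",
      "anza", "encia", "ancia", "es", "s", "a", "o", "e"
    ),
    en = c(
      "izations", "ization", "fulness", "ousness", "ations", "ation",
      "ments", "ment", "ness", "ists", "ist", "ers", "er", "ingly", "ing",
      "edly", "ed", "ly", "ies", "es", "s"
    ),
    character(0)
  )
  out <- tolower(lemma)
  if (!length(suffixes)) return(out)
  suffixes <- suffixes[order(-nchar(suffixes))]
  vapply(out, function(w) {
    for (suf in suffixes) {
      # keep a stem of at least 3 characters so short roots survive
      if (endsWith(w, suf) && nchar(w) - nchar(suf) >= 3) {
        return(substr(w, 1L, nchar(w) - nchar(suf)))
      }
    }
    w
  }, character(1), USE.NAMES = FALSE)
}
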
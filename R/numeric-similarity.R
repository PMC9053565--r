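#' Rounding candidates of a quantity
#'
#' People rarely retain an exact figure they have just heard, so an answer
#' quoting a rounded version of the true quantity still shows understanding.
#' For each power of ten below the number of digits of `n`, both the
#' rounded-down and rounded-up multiples are admitted: for every `k` in
#' `1..(digits(n) - 1)`, `floor(n / 10^k) * 10^k` and
#' `ceiling(n / 10^k) * 10^k`. Duplicates collapse and `n` itself is
#' excluded (an exact answer is scored separately).
#'
#' @param n A single non-negative integer-valued number.
#' @return Sorted numeric vector of candidate values.
#' @examples
#' rounding_candidates(2569) # 2000 2500 2560 2570 2600 3000
#' @export
rounding_candidates <- function(n) {
  stopifnot(length(n) == 1, n >= 0, n == floor(n))
  digits <- nchar(sprintf("%.0f", n))
  if (digits < 2) return(numeric(0))
  ks <- seq_len(digits - 1)
  cand <- unlist(lapply(10^ks, function(p) c(floor(n / p) * p, ceiling(n / p) * p)))
  sort(unique(cand[cand != n]))
}

#' Score a numeric answer against a gold quantity
#'
#' An exact value scores 1. A value among the gold quantity's
#' [rounding_candidates()] scores 0.9 when an over/under qualifier is
#' present and correct (strictly: "over" when the gold value exceeds the
#' stated value, "under" when it falls below), and 0.7 otherwise — including
#' when the qualifier is absent or wrong, since the rounded value still
#' matches. Any other value scores 0.
#'
#' @param gold_value Gold-standard quantity (non-negative integer).
#' @param value Quantity stated in the answer.
#' @param qualifier `"none"`, `"over"` or `"under"`.
#' @return One of 0, 0.7, 0.9, 1.
#' @examples
#' score_quantity(2569, 2500, "over") # 0.9
#' score_quantity(2569, 2500)         # 0.7
#' @export
score_quantity <- function(gold_value, value, qualifier = c("none", "over", "under")) {
  qualifier <- match.arg(qualifier)
  if (value == gold_value) return(1.0)
  if (!value %in% rounding_candidates(gold_value)) return(0)
  correct <- (qualifier == "over" && gold_value > value) ||
    (qualifier == "under" && gold_value < value)
  if (correct) 0.9 else 0.7
}

#' Default over/under marker lexicons
#'
#' Marker phrases that, when immediately preceding a number, qualify it as
#' an over- or under-estimate. Shipped for Spanish and English; any tibble
#' with columns `phrase` and `qualifier` works.
#'
#' @param language `"es"` or `"en"`.
#' @return Tibble with columns `phrase`, `qualifier`.
#' @export
default_markers <- function(language = "es") {
  path <- system.file("extdata", paste0("markers-", language, ".tsv"),
                      package = "cogniscore")
  if (!nzchar(path)) {
    abort(paste0("no marker lexicon shipped for language '", language, "'"),
          class = "cogniscore_settings_error")
  }
  read_markers(path)
}

#' @rdname default_markers
#' @param path Path to a tab-separated file with two columns: marker phrase
#'   and `over`/`under`.
#' @export
read_markers <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           col.names = c("phrase", "qualifier"),
                           comment.char = "#", strip.white = TRUE,
                           fileEncoding = "UTF-8")
  bad <- setdiff(unique(raw$qualifier), c("over", "under"))
  if (length(bad)) {
    abort(paste0("marker qualifier must be over/under, got: ", toString(bad)),
          class = "cogniscore_schema_error")
  }
  as_tibble(raw)
}

#' Extract qualified quantities from annotated tokens
#'
#' Every numeric token becomes a quantity; a marker phrase from the marker
#' lexicon whose tokens immediately precede the number sets its qualifier.
#'
#' @param answer An [annotated_tokens()] tibble.
#' @param markers Marker tibble (`phrase`, `qualifier`), e.g.
#'   [default_markers()].
#' @return Tibble with columns `value`, `qualifier`, `token_index`.
#' @export
extract_quantities <- function(answer, markers = default_markers("es")) {
  answer <- annotated_tokens(answer)
  idx <- which(answer$is_numeric)
  if (!length(idx)) {
    return(tibble(value = numeric(0), qualifier = character(0),
                  token_index = integer(0)))
  }
  marker_words <- strsplit(tolower(markers$phrase), "\\s+")
  purrr::map_dfr(idx, function(i) {
    value <- suppressWarnings(as.numeric(gsub("[^0-9]", "", answer$surface[i])))
    if (is.na(value)) {
      value <- suppressWarnings(as.numeric(gsub("[^0-9]", "", answer$lemma[i])))
    }
    if (is.na(value)) return(NULL)
    qualifier <- "none"
    for (m in seq_along(marker_words)) {
      w <- marker_words[[m]]
      len <- length(w)
      if (i - len >= 1 &&
          identical(tolower(answer$surface[(i - len):(i - 1)]), w)) {
        qualifier <- markers$qualifier[m]
        break
      }
    }
    tibble(value = value, qualifier = qualifier, token_index = i)
  })
}
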
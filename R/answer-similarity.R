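#' Annotated token lists
#'
#' Both gold-standard and user answers enter the scorer as ordered token
#' tables carrying surface form, lemma and a coarse part of speech. The
#' annotation itself (tokenisation, lemmatisation, tagging) is pluggable:
#' any upstream annotator producing this table works.
#'
#' @param tokens A data frame with columns `surface`, `lemma`, `pos` (one of
#'   noun, verb, adjective, adverb, number, other) and optionally
#'   `is_numeric` (implied by `pos == "number"`).
#' @return A validated tibble of class `annotated_tokens`. May have zero
#'   rows (a silent answer).
#' @export
annotated_tokens <- function(tokens) {
  if (inherits(tokens, "annotated_tokens")) return(tokens)
  tokens <- as_tibble(tokens)
  required <- c("surface", "lemma", "pos")
  missing <- setdiff(required, names(tokens))
  if (length(missing)) {
    abort(paste0("annotated tokens lack column(s): ", toString(missing)),
          class = "cogniscore_schema_error")
  }
  if (!"is_numeric" %in% names(tokens)) {
    tokens$is_numeric <- tokens$pos == "number"
  }
  ok <- tokens$pos %in% c(pos_categories(), "number", "other")
  if (!all(ok)) {
    abort(paste0("unknown token pos: ", toString(unique(tokens$pos[!ok]))),
          class = "cogniscore_schema_error")
  }
  if (any(tokens$is_numeric != (tokens$pos == "number"))) {
    abort("pos == 'number' and is_numeric must agree",
          class = "cogniscore_schema_error")
  }
  class(tokens) <- c("annotated_tokens", class(tokens))
  tokens
}

#' Read annotated tokens from a JSON file
#'
#' The file is a JSON array of objects with fields `surface`, `lemma`,
#' `pos`, and optionally `is_numeric`.
#'
#' @param path File path.
#' @return An [annotated_tokens()] tibble.
#' @export
read_annotated_tokens <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (length(raw) == 0) {
    raw <- data.frame(surface = character(), lemma = character(),
                      pos = character())
  }
  annotated_tokens(raw)
}

content_group <- function(pos) {
  # numbers aggregate with nouns: they state nominal facts
  dplyr::case_when(
    pos %in% c("noun", "verb", "number") ~ "content",
    pos %in% c("adjective", "adverb") ~ "modifier",
    TRUE ~ "ignored"
  )
}

#' Best match of one gold token in a user answer
#'
#' For a gold content word, the maximum [word_similarity()] score over the
#' answer tokens of the same lexical category; 0 when the answer has none.
#' Numeric gold tokens are matched against the quantities extracted from the
#' answer via [score_quantity()] instead.
#'
#' @param kb A [lexicon_graph()].
#' @param gold_token One-row [annotated_tokens()] slice.
#' @param answer An [annotated_tokens()] tibble (the user's response).
#' @param params A [similarity_params()] object.
#' @param markers Marker lexicon for quantity qualifiers.
#' @return A single number in \[0, 1\].
#' @export
best_match <- function(kb, gold_token, answer, params = similarity_params(),
                       markers = default_markers(kb$language_tag)) {
  answer <- annotated_tokens(answer)
  if (gold_token$pos == "number") {
    gold_q <- extract_quantities(annotated_tokens(gold_token), markers)
    if (nrow(gold_q) == 0) return(0)
    ans_q <- extract_quantities(answer, markers)
    if (nrow(ans_q) == 0) return(0)
    return(max(purrr::map_dbl(
      seq_len(nrow(ans_q)),
      ~ score_quantity(gold_q$value[1], ans_q$value[.x], ans_q$qualifier[.x])
    )))
  }
  same_pos <- answer[answer$pos == gold_token$pos, , drop = FALSE]
  if (nrow(same_pos) == 0) return(0)
  max(purrr::map_dbl(
    same_pos$lemma,
    ~ word_similarity(kb, gold_token$lemma, .x, gold_token$pos, params)$score
  ))
}

#' Answer-level similarity (the `sim` metric)
#'
#' Scores a user's free-text answer against the gold standard as a weighted
#' average of best-match word similarities, partitioned by lexical category:
#' \deqn{sim = 0.8\,\frac{\sum noun^*_i + \sum verb^*_i}{N_{noun}+N_{verb}}
#'       + 0.2\,\frac{\sum adj^*_i + \sum adv^*_i}{N_{adj}+N_{adv}}}
#' where \eqn{x^*_i} is the highest similarity of the i-th gold word of
#' category \eqn{x} against the same-category words of the answer. Nouns and
#' verbs carry most of a sentence's semantics, hence the 0.8 weight;
#' adjectives and adverbs provide nuance. Numeric gold tokens count in the
#' noun+verb group and are matched by tolerant quantity scoring. When the
#' gold answer has no adjectives/adverbs (or, symmetrically, no
#' nouns/verbs/numbers) the weight of the empty group is reassigned to the
#' other, so a verbatim-correct answer always reaches 1.
#'
#' @param kb A [lexicon_graph()].
#' @param gold,answer [annotated_tokens()] tibbles. `gold` must contain at
#'   least one content token (noun/verb/adjective/adverb/number).
#' @param params A [similarity_params()] object.
#' @param markers Marker lexicon for quantity qualifiers.
#' @return A `sim_breakdown` object: `sim`, `content_term`, `modifier_term`,
#'   category counts, and a `best_matches` tibble with the winning score per
#'   gold content word.
#' @examples
#' kb <- build_fixture_lexicon(seed = 1)
#' gold <- annotated_tokens(tibble::tibble(
#'   surface = c("montaña", "blanca"), lemma = c("montaña", "blanco"),
#'   pos = c("noun", "adjective")
#' ))
#' ans <- annotated_tokens(tibble::tibble(
#'   surface = c("monte", "blanco"), lemma = c("monte", "blanco"),
#'   pos = c("noun", "adjective")
#' ))
#' sim_score(kb, gold, ans)$sim
#' @export
sim_score <- function(kb, gold, answer, params = similarity_params(),
                      markers = default_markers(kb$language_tag)) {
  gold <- annotated_tokens(gold)
  answer <- annotated_tokens(answer)
  gold$group <- content_group(gold$pos)
  scored <- gold[gold$group != "ignored", , drop = FALSE]
  if (nrow(scored) == 0) {
    abort("gold answer has no content tokens (noun/verb/adj/adv/number); cannot score",
          class = "cogniscore_unusable_gold")
  }
  scored$x_star <- purrr::map_dbl(
    seq_len(nrow(scored)),
    ~ best_match(kb, scored[.x, ], answer, params, markers)
  )
  n_content <- sum(scored$group == "content")
  n_modifier <- sum(scored$group == "modifier")
  content_term <- if (n_content) mean(scored$x_star[scored$group == "content"]) else NA_real_
  modifier_term <- if (n_modifier) mean(scored$x_star[scored$group == "modifier"]) else NA_real_
  sim <- if (n_content && n_modifier) {
    0.8 * content_term + 0.2 * modifier_term
  } else if (n_content) {
    content_term
  } else {
    modifier_term
  }
  structure(
    list(
      sim = sim,
      content_term = content_term,
      modifier_term = modifier_term,
      n_noun = sum(scored$pos %in% c("noun", "number")),
      n_verb = sum(scored$pos == "verb"),
      n_adj = sum(scored$pos == "adjective"),
      n_adv = sum(scored$pos == "adverb"),
      best_matches = scored[, c("surface", "lemma", "pos", "group", "x_star")]
    ),
    class = "sim_breakdown"
  )
}

#' @export
print.sim_breakdown <- function(x, ...) {
  cat(sprintf("<sim_breakdown: sim = %.3f (content %.3f, modifier %s)>\n",
              x$sim, x$content_term,
              if (is.na(x$modifier_term)) "-" else sprintf("%.3f", x$modifier_term)))
  print(x$best_matches)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sim_breakdown <- function(x, ...) {
  x$best_matches
}

#' @exportS3Method generics::glance
glance.sim_breakdown <- function(x, ...) {
  tibble(sim = x$sim, content_term = x$content_term,
         modifier_term = x$modifier_term, n_noun = x$n_noun,
         n_verb = x$n_verb, n_adj = x$n_adj, n_adv = x$n_adv)
}

#' Rank candidate answers by decreasing similarity to the gold standard
#'
#' Paraphrases of the gold answer should outrank partially related answers,
#' which in turn outrank unrelated ones. Ties keep input order.
#'
#' @inheritParams sim_score
#' @param answers A list of [annotated_tokens()] tibbles.
#' @return Tibble with `answer_id` (input position), `sim`, and the
#'   breakdowns as a list-column, sorted by decreasing `sim`.
#' @export
rank_paraphrase_degradation <- function(kb, gold, answers,
                                        params = similarity_params(),
                                        markers = default_markers(kb$language_tag)) {
  stopifnot(length(answers) >= 1)
  breakdowns <- purrr::map(answers, ~ sim_score(kb, gold, .x, params, markers))
  tibble(
    answer_id = seq_along(answers),
    sim = purrr::map_dbl(breakdowns, "sim"),
    breakdown = breakdowns
  ) %>%
    arrange(desc(.data$sim), .data$answer_id)
}
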
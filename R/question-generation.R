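#' Annotated news items
#'
#' A news item ready for question generation: a topic, a title, and
#' paragraphs of annotated sentences. Sentence tokens extend
#' [annotated_tokens()] with a named-entity tag (`ne_tag`: person,
#' organisation, location, none) and a noun-phrase chunk label (`chunk`:
#' `B-NP`/`I-NP`/`O`). Verbs are identified by `pos == "verb"`. The first
#' paragraph is the lead paragraph used for the news summary and for the
#' attention-demanding question.
#'
#' @param topic One of economy, politics, science, society, sports.
#' @param title Title text.
#' @param paragraphs List of paragraphs, each a list of sentence token
#'   tables.
#' @param language Language tag.
#' @return An object of class `annotated_news`.
#' @export
annotated_news <- function(topic, title, paragraphs, language = "es") {
  topics <- c("economy", "politics", "science", "society", "sports")
  if (!topic %in% topics) {
    abort(paste0("topic must be one of: ", toString(topics)),
          class = "cogniscore_schema_error")
  }
  if (!length(paragraphs) || !length(paragraphs[[1]])) {
    abort("news item needs a non-empty lead paragraph",
          class = "cogniscore_schema_error")
  }
  paragraphs <- purrr::map(paragraphs, function(par) {
    purrr::map(par, annotated_sentence)
  })
  structure(list(topic = topic, title = title, paragraphs = paragraphs,
                 language = language),
            class = "annotated_news")
}

annotated_sentence <- function(tokens) {
  tokens <- as_tibble(tokens)
  if (!"ne_tag" %in% names(tokens)) tokens$ne_tag <- "none"
  if (!"chunk" %in% names(tokens)) tokens$chunk <- "O"
  tokens$ne_tag[is.na(tokens$ne_tag)] <- "none"
  tokens$chunk[is.na(tokens$chunk)] <- "O"
  bad <- setdiff(unique(tokens$ne_tag),
                 c("person", "organisation", "location", "none"))
  if (length(bad)) {
    abort(paste0("unknown ne_tag: ", toString(bad)),
          class = "cogniscore_schema_error")
  }
  annotated_tokens(tokens)
}

#' Read an annotated news item from JSON
#'
#' The file holds `topic`, `title`, `language` and `paragraphs`: an array of
#' paragraphs, each an array of sentences, each an array of token objects
#' (`surface`, `lemma`, `pos`, `is_numeric`, `ne_tag`, `chunk`).
#'
#' @param path File path.
#' @return An [annotated_news()] object.
#' @export
read_news <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  paragraphs <- purrr::map(raw$paragraphs, function(par) {
    purrr::map(par, function(sent) {
      purrr::map_dfr(sent, function(tok) {
        tibble(
          surface = tok$surface, lemma = tok$lemma %||% tok$surface,
          pos = tok$pos %||% "other",
          is_numeric = isTRUE(tok$is_numeric) || identical(tok$pos, "number"),
          ne_tag = tok$ne_tag %||% "none", chunk = tok$chunk %||% "O"
        )
      })
    })
  })
  annotated_news(raw$topic, raw$title, paragraphs,
                 language = raw$language %||% "es")
}

news_sentences <- function(news) {
  purrr::flatten(news$paragraphs)
}

sentence_text <- function(tokens) {
  txt <- paste(tokens$surface, collapse = " ")
  gsub(" ([.,;:!?])", "\\1", txt)
}

#' Extract named entities from a news item
#'
#' Contiguous runs of tokens sharing a person/organisation/location tag form
#' one entity. Entities are deduplicated, keeping first-appearance order.
#'
#' @param news An [annotated_news()] object.
#' @return Tibble with columns `entity`, `type`.
#' @export
extract_entities <- function(news) {
  out <- purrr::map_dfr(news_sentences(news), function(tokens) {
    if (!nrow(tokens)) return(NULL)
    tagged <- tokens$ne_tag != "none"
    if (!any(tagged)) return(NULL)
    run <- cumsum(c(TRUE, tokens$ne_tag[-1] != tokens$ne_tag[-nrow(tokens)]))
    purrr::map_dfr(split(seq_len(nrow(tokens)), run), function(idx) {
      if (tokens$ne_tag[idx[1]] == "none") return(NULL)
      tibble(entity = paste(tokens$surface[idx], collapse = " "),
             type = tokens$ne_tag[idx[1]])
    })
  })
  if (!nrow(out)) return(tibble(entity = character(), type = character()))
  distinct(out, .data$entity, .keep_all = TRUE)
}

#' Load a question template set
#'
#' Template sets hold four dichotomous templates per entity type, one
#' follow-up essay template per (entity type, reply) combination, wh
#' templates, yes/no reply markers and the subject pronoun used in
#' what-question gold answers. Spanish and English sets ship with the
#' package; `ENTIDAD` marks the entity slot, `PREDICADO` the predicate slot
#' of who-questions.
#'
#' @param language `"es"` or `"en"`, or use `path` for a custom set.
#' @param path Optional path to a custom template JSON file.
#' @return A list of class `question_templates`.
#' @export
load_templates <- function(language = "es", path = NULL) {
  path <- path %||% system.file("extdata", paste0("templates-", language, ".json"),
                                package = "cogniscore")
  if (!nzchar(path) || !file.exists(path)) {
    abort(paste0("no template set for language '", language, "'"),
          class = "cogniscore_settings_error")
  }
  tpl <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (type in names(tpl$dichotomous)) {
    if (length(tpl$dichotomous[[type]]) != 4) {
      abort(paste0("template set must hold exactly four dichotomous templates",
                   " for type '", type, "'"),
            class = "cogniscore_settings_error")
    }
  }
  all_tpl <- c(unlist(tpl$dichotomous), unlist(tpl$follow_up))
  n_slots <- lengths(regmatches(all_tpl, gregexpr("ENTIDAD", all_tpl)))
  if (any(n_slots != 1)) {
    abort("every entity template must contain the ENTIDAD placeholder exactly once",
          class = "cogniscore_settings_error")
  }
  structure(tpl, class = "question_templates")
}

template_type <- function(type) {
  # organisations reuse the person template set
  if (type == "organisation") "person" else type
}

#' Generate a dichotomous (yes/no) question about an entity
#'
#' One of the four templates for the entity type is drawn uniformly with the
#' seeded generator and the entity substituted. These closed questions relax
#' the user and route the dialogue.
#'
#' @param entity Entity surface text.
#' @param type `"person"`, `"organisation"` or `"location"`.
#' @param templates A [load_templates()] set.
#' @param seed Integer seed; the same seed yields the same question.
#' @return Question text.
#' @export
dichotomous_question <- function(entity, type, templates = load_templates(),
                                 seed = NULL) {
  pool <- templates$dichotomous[[template_type(type)]]
  if (is.null(pool)) {
    abort(paste0("no dichotomous templates for entity type '", type, "'"),
          class = "cogniscore_settings_error")
  }
  chosen <- with_local_seed(seed, sample(pool, 1))
  sub("ENTIDAD", entity, chosen, fixed = TRUE)
}

#' Classify a free-text reply as yes, no or n/a
#'
#' A reply counts as "yes" when it contains a yes marker and no no marker
#' (and conversely); anything else — including silence and mixed signals —
#' is "na".
#'
#' @param text Reply text.
#' @param templates A [load_templates()] set (provides the marker lists).
#' @return `"yes"`, `"no"` or `"na"`.
#' @export
classify_reply <- function(text, templates = load_templates()) {
  words <- tolower(unlist(strsplit(text, "[^[:alnum:]áéíóúüñ]+")))
  words <- words[nzchar(words)]
  has_yes <- any(words %in% tolower(templates$yes_markers))
  has_no <- any(words %in% tolower(templates$no_markers))
  if (has_yes && !has_no) "yes" else if (has_no && !has_yes) "no" else "na"
}

#' Follow-up essay question conditioned on the user's reply
#'
#' @inheritParams dichotomous_question
#' @param reply `"yes"`, `"no"` or `"na"` (see [classify_reply()]).
#' @return Question text.
#' @export
follow_up_question <- function(entity, type, reply = c("yes", "no", "na"),
                               templates = load_templates()) {
  reply <- match.arg(reply)
  tpl <- templates$follow_up[[template_type(type)]][[reply]]
  if (is.null(tpl)) {
    abort(paste0("no follow-up template for (", type, ", ", reply, ")"),
          class = "cogniscore_settings_error")
  }
  sub("ENTIDAD", entity, tpl, fixed = TRUE)
}

np_spans <- function(tokens) {
  starts <- which(tokens$chunk == "B-NP")
  purrr::map(starts, function(s) {
    e <- s
    while (e + 1 <= nrow(tokens) && tokens$chunk[e + 1] == "I-NP") e <- e + 1
    s:e
  })
}

np_content <- function(tokens, idx) {
  # drop leading function words (determiners) from the answer span
  while (length(idx) > 1 && tokens$pos[idx[1]] == "other") idx <- idx[-1]
  idx
}

ineligible <- function(msg) {
  abort(msg, class = "cogniscore_ineligible_sentence")
}

#' Wh-question with automatically extracted gold answer
#'
#' Builds an attention-demanding question about a sentence together with its
#' gold-standard answer: for "who" questions the gold is the noun phrase
#' preceding the main verb; for "what" questions it is that subject
#' (pronominalised) plus the verb complex and the object noun phrase; for
#' "which places" questions it is every location entity mentioned in the
#' news item.
#'
#' @param sentence An annotated sentence (tokens with `chunk` labels).
#' @param kind `"who"`, `"what"` or `"which_places"`.
#' @param templates A [load_templates()] set.
#' @param news The enclosing [annotated_news()] item (required for
#'   `which_places`).
#' @return A list with `question` (text), `gold` ([annotated_tokens()]),
#'   `gold_text` and `kind`. Signals a `cogniscore_ineligible_sentence`
#'   condition when the sentence lacks the needed structure, so callers can
#'   try another sentence.
#' @export
wh_question_with_gold <- function(sentence, kind = c("who", "what", "which_places"),
                                  templates = load_templates(), news = NULL) {
  kind <- match.arg(kind)
  if (kind == "which_places") {
    if (is.null(news)) {
      abort("which_places questions need the enclosing news item",
            class = "cogniscore_settings_error")
    }
    locs <- filter(extract_entities(news), .data$type == "location")
    if (!nrow(locs)) ineligible("news item mentions no locations")
    gold <- annotated_tokens(tibble(
      surface = locs$entity, lemma = locs$entity, pos = "noun"
    ))
    return(list(question = templates$wh$which_places, gold = gold,
                gold_text = paste(locs$entity, collapse = ", "),
                kind = kind))
  }
  sentence <- annotated_sentence(sentence)
  verbs <- which(sentence$pos == "verb")
  if (!length(verbs)) ineligible("sentence has no verb")
  v <- verbs[1]
  spans <- np_spans(sentence)
  before <- spans[purrr::map_lgl(spans, ~ max(.x) < v)]
  if (!length(before)) ineligible("no noun phrase precedes the verb")
  subject <- np_content(sentence, before[[length(before)]])
  if (kind == "who") {
    gold <- sentence[subject, , drop = FALSE]
    predicate <- sentence$surface[v:nrow(sentence)]
    predicate <- predicate[!predicate %in% c(".", ",", ";", "!", "?")]
    question <- sub("PREDICADO", paste(predicate, collapse = " "),
                    templates$wh$who, fixed = TRUE)
    return(list(question = question, gold = annotated_tokens(gold),
                gold_text = paste(gold$surface, collapse = " "), kind = kind))
  }
  # what: verb complex = maximal verb/adverb run from the main verb, ending
  # at a verb; gold = subject pronoun + verb complex + object NP content
  e <- v
  while (e + 1 <= nrow(sentence) && sentence$pos[e + 1] %in% c("verb", "adverb")) {
    e <- e + 1
  }
  while (sentence$pos[e] != "verb") e <- e - 1
  complex <- v:e
  after <- spans[purrr::map_lgl(spans, ~ min(.x) > e)]
  object <- if (length(after)) np_content(sentence, after[[1]]) else integer(0)
  object <- object[sentence$pos[object] != "other"]
  pronoun <- tibble(surface = templates$subject_pronoun,
                    lemma = tolower(templates$subject_pronoun),
                    pos = "other", is_numeric = FALSE,
                    ne_tag = "none", chunk = "O")
  gold <- bind_rows(pronoun, sentence[complex, ], sentence[object, ])
  list(question = templates$wh$what, gold = annotated_tokens(gold),
       gold_text = paste(gold$surface, collapse = " "), kind = kind)
}

#' Build a three-stage dialogue session from a news item
#'
#' Stage 1 presents the news (title plus lead paragraph). Stage 2 relaxes
#' and distracts the user: one dichotomous question about the first entity,
#' the follow-up selected by the (assumed) reply, and a second, user-centred
#' essay question about the next entity. Stage 3 asks one attention-demanding
#' wh-question about the first eligible sentence of the lead paragraph (who,
#' then what, then which-places as fallbacks), with its gold answer
#' attached. Deterministic for a fixed seed and reply path.
#'
#' @param news An [annotated_news()] item with at least one entity and one
#'   wh-eligible sentence (or location mentions).
#' @param templates A [load_templates()] set.
#' @param seed Integer seed for template draws.
#' @param reply Assumed reply path for the dichotomous question (`"yes"`,
#'   `"no"` or `"na"`).
#' @return A `dialogue_session` object: `topic`, `title`, `stage1_text`,
#'   a 4-row `questions` tibble (`stage`, `type`, `question`, `gold`
#'   list-column) and the `seed`.
#' @export
build_session <- function(news, templates = load_templates(news$language),
                          seed = 1, reply = "yes") {
  entities <- extract_entities(news)
  if (!nrow(entities)) {
    abort("cannot build session: news item has no named entities",
          class = "cogniscore_session_error")
  }
  e1 <- entities[1, ]
  e2 <- if (nrow(entities) >= 2) entities[2, ] else e1
  q1 <- dichotomous_question(e1$entity, e1$type, templates, seed = seed)
  q2 <- follow_up_question(e1$entity, e1$type, reply, templates)
  q3 <- follow_up_question(e2$entity, e2$type, "na", templates)
  lead <- news$paragraphs[[1]]
  wh <- NULL
  for (sent in lead) {
    for (kind in c("who", "what")) {
      wh <- tryCatch(
        wh_question_with_gold(sent, kind, templates, news = news),
        cogniscore_ineligible_sentence = function(e) NULL
      )
      if (!is.null(wh)) break
    }
    if (!is.null(wh)) break
  }
  if (is.null(wh)) {
    wh <- tryCatch(
      wh_question_with_gold(lead[[1]], "which_places", templates, news = news),
      cogniscore_ineligible_sentence = function(e) NULL
    )
  }
  if (is.null(wh)) {
    abort("cannot build session: no sentence is eligible for a wh-question",
          class = "cogniscore_session_error")
  }
  if (!nrow(wh$gold)) {
    abort("attention-demanding question produced an empty gold answer",
          class = "cogniscore_session_error")
  }
  questions <- tibble(
    stage = c(2L, 2L, 2L, 3L),
    type = c("dichotomous", "essay", "essay", "attention"),
    kind = c(NA_character_, NA_character_, NA_character_, wh$kind),
    question = c(q1, q2, q3, wh$question),
    gold = list(NULL, NULL, NULL, wh$gold)
  )
  structure(
    list(topic = news$topic, title = news$title,
         stage1_text = paste(
           c(news$title, purrr::map_chr(lead, sentence_text)),
           collapse = " "
         ),
         questions = questions, seed = seed, reply = reply),
    class = "dialogue_session"
  )
}

#' @export
print.dialogue_session <- function(x, ...) {
  cat("<dialogue_session [", x$topic, "]: ", x$title, ">\n", sep = "")
  for (i in seq_len(nrow(x$questions))) {
    cat(sprintf("  stage %d (%s): %s\n", x$questions$stage[i],
                x$questions$type[i], x$questions$question[i]))
  }
  invisible(x)
}
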
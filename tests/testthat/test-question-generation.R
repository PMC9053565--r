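drugring_es <- function() read_news(extdata("news-drugring-es.json"))
drugring_en <- function() read_news(extdata("news-drugring-en.json"))
bonds_en <- function() read_news(extdata("news-bonds-en.json"))

test_that("annotated news validates topic and lead paragraph", {
  expect_error(annotated_news("weather", "t", list(list(tok("a")))),
               class = "cogniscore_schema_error")
  expect_error(annotated_news("society", "t", list()),
               class = "cogniscore_schema_error")
  expect_error(
    annotated_news("society", "t", list(list(
      tibble::tibble(surface = "x", lemma = "x", pos = "noun", ne_tag = "city")
    ))),
    class = "cogniscore_schema_error"
  )
})

test_that("contiguous tag runs become multi-word entities, deduplicated in order", {
  news <- drugring_es()
  ents <- extract_entities(news)
  expect_equal(ents$entity, c("Policía Nacional", "Galicia", "Madrid", "Alicante"))
  expect_equal(ents$type, c("organisation", "location", "location", "location"))
})

test_that("dichotomous questions draw one of four templates, seeded and uniform", {
  tpl <- load_templates("es")
  q <- dichotomous_question("Madrid", "location", tpl, seed = 3)
  expect_identical(q, dichotomous_question("Madrid", "location", tpl, seed = 3))
  expect_true(grepl("Madrid", q, fixed = TRUE))
  expect_false(grepl("ENTIDAD", q, fixed = TRUE))
  draws <- vapply(1:4000, function(s) {
    dichotomous_question("X", "location", tpl, seed = s)
  }, character(1))
  freqs <- table(draws) / length(draws)
  expect_equal(length(freqs), 4)
  expect_true(all(abs(freqs - 0.25) < 0.03))
})

test_that("organisations reuse the person templates and follow-ups cover all replies", {
  tpl <- load_templates("es")
  q <- dichotomous_question("Policía Nacional", "organisation", tpl, seed = 1)
  expect_true(grepl("Policía Nacional", q, fixed = TRUE))
  expect_equal(follow_up_question("Iberdrola", "organisation", "yes", tpl),
               "¿Qué datos conoces de la vida de Iberdrola?")
  expect_equal(follow_up_question("Madrid", "location", "no", tpl),
               "¿Por qué no has estado en Madrid?")
  expect_equal(follow_up_question("Madrid", "location", "na", tpl),
               "¿Podrías contarme algo relacionado con Madrid?")
})

test_that("replies classify as yes/no/na from marker words", {
  tpl <- load_templates("es")
  expect_equal(classify_reply("Sí, claro que lo conozco", tpl), "yes")
  expect_equal(classify_reply("no, nunca", tpl), "no")
  expect_equal(classify_reply("puede ser", tpl), "na")
  expect_equal(classify_reply("", tpl), "na")
  # mixed signals are inconclusive
  expect_equal(classify_reply("sí y no", tpl), "na")
})

test_that("who-question gold is the subject noun phrase without its determiner", {
  tpl <- load_templates("en")
  sent <- news_sentences(drugring_en())[[1]]
  wh <- wh_question_with_gold(sent, "who", tpl)
  expect_equal(wh$gold_text, "National Police")
  expect_true(startsWith(wh$question, "Who "))
  expect_true(grepl("dismantled", wh$question))
})

test_that("what-question gold is pronoun + verb complex + object noun phrase", {
  tpl <- load_templates("en")
  sent <- news_sentences(bonds_en())[[1]]
  wh <- wh_question_with_gold(sent, "what", tpl)
  expect_equal(wh$gold_text, "It will automatically extend social electric bonds")
})

test_that("which-places gold lists every location in the news item", {
  tpl <- load_templates("en")
  news <- drugring_en()
  wh <- wh_question_with_gold(news_sentences(news)[[1]], "which_places", tpl,
                              news = news)
  expect_equal(wh$gold$surface, c("Galicia", "Madrid", "Alicante"))
})

test_that("ineligible sentences signal a typed condition", {
  tpl <- load_templates("en")
  no_verb <- tibble::tibble(
    surface = c("The", "house"), lemma = c("the", "house"),
    pos = c("other", "noun"), ne_tag = "none", chunk = c("B-NP", "I-NP")
  )
  expect_error(wh_question_with_gold(no_verb, "who", tpl),
               class = "cogniscore_ineligible_sentence")
  no_subject <- tibble::tibble(
    surface = c("Runs", "fast"), lemma = c("run", "fast"),
    pos = c("verb", "adverb"), ne_tag = "none", chunk = "O"
  )
  expect_error(wh_question_with_gold(no_subject, "who", tpl),
               class = "cogniscore_ineligible_sentence")
  no_locations <- bonds_en()
  # missing news argument is a usage problem, not ineligibility
  expect_error(
    wh_question_with_gold(news_sentences(no_locations)[[1]], "which_places", tpl),
    class = "cogniscore_settings_error"
  )
  expect_error(
    wh_question_with_gold(news_sentences(no_locations)[[1]], "which_places",
                          tpl, news = no_locations),
    class = "cogniscore_ineligible_sentence"
  )
})

test_that("a session has the three-stage structure and is deterministic", {
  news <- drugring_es()
  s <- build_session(news, seed = 5, reply = "yes")
  expect_s3_class(s, "dialogue_session")
  expect_equal(s$questions$stage, c(2L, 2L, 2L, 3L))
  expect_equal(s$questions$type, c("dichotomous", "essay", "essay", "attention"))
  expect_true(grepl("Policía Nacional", s$questions$question[1], fixed = TRUE))
  # the attention question carries the gold answer
  gold <- s$questions$gold[[4]]
  expect_false(is.null(gold))
  expect_equal(paste(gold$surface, collapse = " "), "Policía Nacional")
  expect_true(grepl(news$title, s$stage1_text, fixed = TRUE))
  s2 <- build_session(news, seed = 5, reply = "yes")
  expect_identical(s$questions, s2$questions)
  # a different reply path changes the follow-up, not the structure
  s3 <- build_session(news, seed = 5, reply = "no")
  expect_false(identical(s$questions$question[2], s3$questions$question[2]))
  expect_identical(s$questions$question[1], s3$questions$question[1])
})

test_that("a news item without entities cannot seed a session", {
  plain <- annotated_news("society", "t", list(list(
    tibble::tibble(surface = c("Llueve", "."), lemma = c("llover", "."),
                   pos = c("verb", "other"), ne_tag = "none", chunk = "O")
  )))
  expect_error(build_session(plain, load_templates("es")),
               class = "cogniscore_session_error")
})

test_that("template sets are validated on load", {
  bad <- withr::local_tempfile(fileext = ".json")
  tpl <- jsonlite::fromJSON(extdata("templates-es.json"), simplifyVector = TRUE)
  tpl$dichotomous$person <- tpl$dichotomous$person[1:3]
  jsonlite::write_json(tpl, bad, auto_unbox = TRUE)
  expect_error(load_templates(path = bad), class = "cogniscore_settings_error")
  expect_error(load_templates("xx"), class = "cogniscore_settings_error")
})

test_that("sessions built from the English fixtures use their fallback kinds", {
  # drugring-en: who is eligible on the first sentence
  s1 <- build_session(drugring_en(), seed = 2)
  expect_equal(s1$questions$kind[4], "who")
  # bonds-en: subject is not before... who eligible too (Government precedes verb)
  s2 <- build_session(bonds_en(), seed = 2)
  expect_true(s2$questions$kind[4] %in% c("who", "what", "which_places"))
})
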
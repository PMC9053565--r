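#' Lexical knowledge graph
#'
#' The similarity engine grounds every word comparison in a lexicon graph:
#' lemmas attached to synsets, semantic relations between synsets
#' (holonym/hypernym/hyponym/meronym/related), and up to three semantic
#' label hierarchies per synset (WordNet Domains, Adimen SUMO, Top
#' Ontology). Noun and verb synsets may carry all three label kinds;
#' adjective and adverb synsets carry Top Ontology labels only, reflecting
#' the sparser coverage of those categories in multilingual wordnets.
#'
#' @param entries Tibble with columns `lemma`, `pos`, `stem`, and list-column
#'   `synset_ids`.
#' @param synsets Tibble with columns `id`, `pos`, list-column `lemmas`,
#'   `wordnet_domain`, `adimen_sumo` (character, `NA` allowed) and
#'   list-column `top_ontology`.
#' @param relations Tibble with columns `from`, `to` (synset ids) and `kind`
#'   (one of `r toString(relation_kinds())`). Missing inverse edges
#'   (hypernym/hyponym, holonym/meronym, related/related) are completed.
#' @param language_tag Language of the lemmas, e.g. `"es"`.
#' @return An object of class `lexicon_graph`.
#' @seealso [load_lexicon()], [build_fixture_lexicon()], [relation_summary()]
#' @export
lexicon_graph <- function(entries, synsets, relations, language_tag = "es") {
  entries <- as_tibble(entries)
  synsets <- as_tibble(synsets)
  relations <- as_tibble(relations)
  if (nrow(relations) == 0) {
    relations <- tibble(from = character(), to = character(), kind = character())
  }
  relations <- complete_inverse_relations(relations)
  kb <- structure(
    list(entries = entries, synsets = synsets, relations = relations,
         language_tag = language_tag),
    class = "lexicon_graph"
  )
  validate_lexicon(kb)
  kb
}

pos_categories <- function() c("noun", "verb", "adjective", "adverb")

relation_kinds <- function() c("holonym", "hypernym", "hyponym", "meronym", "related")

inverse_kind <- function(kind) {
  c(holonym = "meronym", meronym = "holonym",
    hypernym = "hyponym", hyponym = "hypernym",
    related = "related")[kind]
}

complete_inverse_relations <- function(relations) {
  if (nrow(relations) == 0) return(relations)
  inv <- tibble(
    from = relations$to,
    to = relations$from,
    kind = unname(inverse_kind(relations$kind))
  )
  distinct(bind_rows(relations, inv), .data$from, .data$to, .data$kind)
}

validate_lexicon <- function(kb) {
  en <- kb$entries
  sy <- kb$synsets
  re <- kb$relations
  bad_pos <- setdiff(unique(c(en$pos, sy$pos)), pos_categories())
  if (length(bad_pos)) {
    abort(paste0("unknown part of speech: ", toString(bad_pos)),
          class = "cogniscore_schema_error")
  }
  if (nrow(en)) {
    if (any(!nzchar(en$stem)) || any(en$stem != tolower(en$stem))) {
      abort("entry stems must be non-empty and lowercase",
            class = "cogniscore_schema_error")
    }
    if (anyDuplicated(paste(en$lemma, en$pos))) {
      dup <- en$lemma[duplicated(paste(en$lemma, en$pos))][1]
      abort(paste0("duplicate entry for lemma '", dup, "'"),
            class = "cogniscore_schema_error")
    }
    for (i in seq_len(nrow(en))) {
      ids <- en$synset_ids[[i]]
      hit <- match(ids, sy$id)
      if (anyNA(hit)) {
        abort(paste0("entry '", en$lemma[i], "' references missing synset '",
                     ids[which(is.na(hit))[1]], "'"),
              class = "cogniscore_integrity_error")
      }
      if (any(sy$pos[hit] != en$pos[i])) {
        abort(paste0("entry '", en$lemma[i], "' (", en$pos[i],
                     ") references a synset of another category"),
              class = "cogniscore_integrity_error")
      }
    }
  }
  if (nrow(sy)) {
    aa <- sy$pos %in% c("adjective", "adverb")
    if (any(aa & (!is.na(sy$wordnet_domain) | !is.na(sy$adimen_sumo)))) {
      abort("adjective/adverb synsets may carry only top-ontology labels",
            class = "cogniscore_schema_error")
    }
  }
  if (nrow(re)) {
    missing <- setdiff(unique(c(re$from, re$to)), sy$id)
    if (length(missing)) {
      abort(paste0("relation references missing synset '", missing[1], "'"),
            class = "cogniscore_integrity_error")
    }
    bad_kind <- setdiff(unique(re$kind), relation_kinds())
    if (length(bad_kind)) {
      abort(paste0("unknown relation kind: ", toString(bad_kind)),
            class = "cogniscore_schema_error")
    }
    cross <- sy$pos[match(re$from, sy$id)] != sy$pos[match(re$to, sy$id)]
    if (any(cross)) {
      abort("relations may not cross part-of-speech boundaries",
            class = "cogniscore_integrity_error")
    }
  }
  invisible(kb)
}

#' @export
print.lexicon_graph <- function(x, ...) {
  cat("<lexicon_graph [", x$language_tag, "]: ",
      nrow(x$entries), " entries, ", nrow(x$synsets), " synsets, ",
      nrow(x$relations), " directed relations>\n", sep = "")
  invisible(x)
}

#' Read or write a lexicon graph as JSON
#'
#' The on-disk format is a UTF-8 JSON object with `language_tag`, an
#' `entries` array (`lemma`, `pos`, `stem`, `synset_ids`) and a `synsets`
#' array (`id`, `pos`, `lemmas`, `wordnet_domain`, `adimen_sumo`,
#' `top_ontology`, and a `relations` object keyed by relation kind). A
#' machine-readable JSON Schema ships in
#' `system.file("extdata", "lexicon-schema.json", package = "cogniscore")`.
#' Relations stored in one direction only are completed with their inverses
#' on load.
#'
#' @param path Path to a lexicon JSON file.
#' @return `load_lexicon()` returns a [lexicon_graph()]; `write_lexicon()`
#'   returns `path` invisibly.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("lexicon file not found: ", path),
          class = "cogniscore_schema_error")
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(paste0("cannot parse lexicon JSON: ",
                                     conditionMessage(e)),
                              class = "cogniscore_schema_error")
  )
  for (field in c("entries", "synsets")) {
    if (is.null(raw[[field]])) {
      abort(paste0("lexicon file lacks required field '", field, "'"),
            class = "cogniscore_schema_error")
    }
  }
  str_or_na <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  entries <- purrr::map_dfr(raw$entries, function(e) {
    for (field in c("lemma", "pos", "stem")) {
      if (is.null(e[[field]])) {
        abort(paste0("entry record missing '", field, "' near lemma '",
                     str_or_na(e$lemma), "'"),
              class = "cogniscore_schema_error")
      }
    }
    tibble(lemma = e$lemma, pos = e$pos, stem = e$stem,
           synset_ids = list(as.character(unlist(e$synset_ids))))
  })
  if (!length(raw$entries)) {
    entries <- tibble(lemma = character(), pos = character(),
                      stem = character(), synset_ids = list())
  }
  synsets <- purrr::map_dfr(raw$synsets, function(s) {
    if (is.null(s$id) || is.null(s$pos)) {
      abort("synset record missing 'id' or 'pos'",
            class = "cogniscore_schema_error")
    }
    tibble(id = s$id, pos = s$pos,
           lemmas = list(as.character(unlist(s$lemmas))),
           wordnet_domain = str_or_na(s$wordnet_domain),
           adimen_sumo = str_or_na(s$adimen_sumo),
           top_ontology = list(as.character(unlist(s$top_ontology))))
  })
  if (!length(raw$synsets)) {
    synsets <- tibble(id = character(), pos = character(), lemmas = list(),
                      wordnet_domain = character(), adimen_sumo = character(),
                      top_ontology = list())
  }
  relations <- purrr::map_dfr(raw$synsets, function(s) {
    purrr::map_dfr(names(s$relations), function(kind) {
      tos <- as.character(unlist(s$relations[[kind]]))
      if (!length(tos)) return(NULL)
      tibble(from = s$id, to = tos, kind = kind)
    })
  })
  if (nrow(relations) == 0) {
    relations <- tibble(from = character(), to = character(), kind = character())
  }
  lexicon_graph(entries, synsets, relations,
                language_tag = raw$language_tag %||% "es")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @rdname load_lexicon
#' @param kb A [lexicon_graph()].
#' @export
write_lexicon <- function(kb, path) {
  stopifnot(inherits(kb, "lexicon_graph"))
  syn_list <- purrr::pmap(kb$synsets, function(id, pos, lemmas, wordnet_domain,
                                               adimen_sumo, top_ontology) {
    edges <- kb$relations[kb$relations$from == id, , drop = FALSE]
    rel <- split(edges$to, edges$kind)
    rel <- purrr::map(rel, sort)
    list(id = id, pos = pos, lemmas = as.list(lemmas),
         wordnet_domain = if (is.na(wordnet_domain)) NULL else wordnet_domain,
         adimen_sumo = if (is.na(adimen_sumo)) NULL else adimen_sumo,
         top_ontology = as.list(top_ontology),
         relations = rel)
  })
  ent_list <- purrr::pmap(kb$entries, function(lemma, pos, stem, synset_ids) {
    list(lemma = lemma, pos = pos, stem = stem, synset_ids = as.list(synset_ids))
  })
  out <- list(language_tag = kb$language_tag, entries = ent_list,
              synsets = syn_list)
  write_json_atomic(out, path)
  invisible(path)
}

write_json_atomic <- function(x, path, ...) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, ...)
  file.rename(tmp, path)
  invisible(path)
}

lexicon_entry <- function(kb, lemma, pos) {
  hit <- kb$entries$lemma == lemma & kb$entries$pos == pos
  if (!any(hit)) {
    # case-insensitive fallback so surface-cased lemmas still resolve
    hit <- tolower(kb$entries$lemma) == tolower(lemma) & kb$entries$pos == pos
  }
  kb$entries[hit, , drop = FALSE]
}

word_synsets <- function(kb, lemma, pos) {
  e <- lexicon_entry(kb, lemma, pos)
  if (nrow(e) == 0) character(0) else e$synset_ids[[1]]
}

word_stem <- function(kb, lemma, pos) {
  e <- lexicon_entry(kb, lemma, pos)
  if (nrow(e) == 1) e$stem else stem_word(lemma, kb$language_tag)
}

pos_graph <- function(kb, pos) {
  ids <- kb$synsets$id[kb$synsets$pos == pos]
  edges <- kb$relations[kb$relations$from %in% ids & kb$relations$to %in% ids, ]
  igraph::graph_from_data_frame(
    d = unique(edges[, c("from", "to")]),
    directed = FALSE,
    vertices = data.frame(name = ids)
  )
}

#' Shortest taxonomy path between two words
#'
#' Minimum number of semantic-relation edges separating any synset of `w1`
#' from any synset of `w2`, traversing all five stored relation kinds as
#' undirected edges within one part of speech. Words sharing a synset are at
#' distance 0; out-of-vocabulary words and disconnected pairs are at
#' distance `Inf`.
#'
#' @param kb A [lexicon_graph()].
#' @param w1,w2 Lemmas.
#' @param pos Shared part of speech of the two lemmas.
#' @return A single non-negative number, possibly `Inf`.
#' @export
shortest_path_distance <- function(kb, w1, w2, pos = "noun") {
  s1 <- word_synsets(kb, w1, pos)
  s2 <- word_synsets(kb, w2, pos)
  if (!length(s1) || !length(s2)) return(Inf)
  if (length(intersect(s1, s2))) return(0)
  g <- pos_graph(kb, pos)
  d <- igraph::distances(g, v = s1, to = s2)
  min(d)
}

#' Summarise the lexical relationship of a word pair
#'
#' Computes every ingredient the similarity score needs for one same-pos
#' word pair: synonymy (shared synset or identical lemma), direct relation
#' (one word's synset is holonym/hypernym/hyponym/meronym/related of the
#' other's, or the two share an Adimen SUMO or Top Ontology label), shared
#' WordNet domain, shared stem, and the raw taxonomy distance. Out-of-
#' vocabulary words get all graph-based flags `FALSE` and infinite distance;
#' the stem comparison still applies, so the stem correction can rescue
#' morphologically related pairs the lexicon does not know.
#'
#' @inheritParams shortest_path_distance
#' @return A one-row tibble with columns `word1`, `word2`, `pos`,
#'   `are_synonyms`, `directly_related`, `same_wordnet_domain`, `same_stem`,
#'   `taxonomy_distance`.
#' @examples
#' kb <- build_fixture_lexicon(seed = 1)
#' relation_summary(kb, "monte", "montaña")
#' @export
relation_summary <- function(kb, w1, w2, pos = "noun") {
  s1 <- word_synsets(kb, w1, pos)
  s2 <- word_synsets(kb, w2, pos)
  same_stem <- word_stem(kb, w1, pos) == word_stem(kb, w2, pos)
  identical_lemma <- tolower(w1) == tolower(w2)
  if (!length(s1) || !length(s2)) {
    return(tibble(
      word1 = w1, word2 = w2, pos = pos,
      are_synonyms = identical_lemma,
      directly_related = FALSE,
      same_wordnet_domain = FALSE,
      same_stem = same_stem,
      taxonomy_distance = if (identical_lemma) 0 else Inf
    ))
  }
  syn1 <- kb$synsets[match(s1, kb$synsets$id), ]
  syn2 <- kb$synsets[match(s2, kb$synsets$id), ]
  are_synonyms <- identical_lemma || length(intersect(s1, s2)) > 0
  direct_edge <- any(kb$relations$from %in% s1 & kb$relations$to %in% s2)
  shared_sumo <- length(intersect(
    syn1$adimen_sumo[!is.na(syn1$adimen_sumo)],
    syn2$adimen_sumo[!is.na(syn2$adimen_sumo)]
  )) > 0
  shared_topo <- length(intersect(
    unlist(syn1$top_ontology), unlist(syn2$top_ontology)
  )) > 0
  same_domain <- length(intersect(
    syn1$wordnet_domain[!is.na(syn1$wordnet_domain)],
    syn2$wordnet_domain[!is.na(syn2$wordnet_domain)]
  )) > 0
  tibble(
    word1 = w1, word2 = w2, pos = pos,
    are_synonyms = are_synonyms,
    directly_related = direct_edge || shared_sumo || shared_topo,
    same_wordnet_domain = same_domain,
    same_stem = same_stem,
    taxonomy_distance = shortest_path_distance(kb, w1, w2, pos)
  )
}
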
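#' Default fixture-lexicon description
#'
#' A compact Spanish lexicon description exercising every structure the
#' similarity engine consumes: a synonym-rich mountain family with hypernym,
#' hyponym, meronym and related links and domain/ontology labels; two
#' material nouns sharing WordNet domain "substance" at taxonomy distance 3;
#' two profession nouns sharing domain "person" in disjoint components; a
#' flower/florist pair sharing a stem without synonymy; household, person
#' and motion-verb families supporting paraphrase-degradation examples; and
#' adjective/adverb synsets that carry only top-ontology labels.
#'
#' @return A list with elements `language`, `synsets`, `relations`,
#'   `stem_overrides` and `non_synonym_pairs`, suitable for
#'   [build_fixture_lexicon()].
#' @export
default_lexicon_spec <- function() {
  syn <- function(id, pos, lemmas, domain = NULL, sumo = NULL, topo = character()) {
    list(id = id, pos = pos, lemmas = lemmas, wordnet_domain = domain,
         adimen_sumo = sumo, top_ontology = topo)
  }
  list(
    language = "es",
    synsets = list(
      # mountain family (semantic-record example for a noun)
      syn("n-montana", "noun", c("montaña", "monte"),
          domain = "Object", sumo = "LandArea",
          topo = c("Geography", "Geology")),
      syn("n-elevacion", "noun", "elevación"),
      syn("n-alpes", "noun", "Alpes"),
      syn("n-volcan", "noun", "volcán"),
      syn("n-vertiente", "noun", "vertiente"),
      syn("n-cumbre", "noun", "cumbre"),
      syn("n-montanero", "noun", c("montañero", "alpinista")),
      # materials: shared domain, path distance 3, no direct relation
      syn("n-madera", "noun", "madera", domain = "substance"),
      syn("n-material", "noun", "material"),
      syn("n-papel", "noun", c("papel", "folio"), domain = "substance"),
      syn("n-carton", "noun", "cartón", domain = "substance"),
      # professions: shared domain, disconnected components
      syn("n-panadero", "noun", "panadero", domain = "person"),
      syn("n-maestro", "noun", "maestro", domain = "person"),
      # shared stem without synonymy
      syn("n-flor", "noun", "flor", domain = "plants"),
      syn("n-florista", "noun", "florista", domain = "person"),
      # people and dwellings for sentence-level examples
      syn("n-persona", "noun", "persona", domain = "person"),
      syn("n-profesor", "noun", "profesor", domain = "person"),
      syn("n-hombre", "noun", "hombre", domain = "person"),
      syn("n-vivienda", "noun", "vivienda"),
      syn("n-casa", "noun", c("casa", "hogar")),
      syn("n-apartamento", "noun", "apartamento"),
      syn("n-silla", "noun", "silla"),
      syn("n-tienda", "noun", "tienda"),
      # verbs
      syn("v-mover", "verb", "mover"),
      syn("v-llevar", "verb", c("llevar", "transportar")),
      syn("v-sacar", "verb", "sacar"),
      syn("v-romper", "verb", "romper"),
      # adjectives/adverbs: top-ontology labels only
      syn("a-blanco", "adjective", "blanco", topo = "Colour"),
      syn("a-peligroso", "adjective", "peligroso", topo = "Quality"),
      syn("r-bien", "adverb", "bien", topo = "Manner")
    ),
    relations = list(
      c("n-montana", "hypernym", "n-elevacion"),
      c("n-montana", "hyponym", "n-alpes"),
      c("n-montana", "hyponym", "n-volcan"),
      c("n-montana", "meronym", "n-vertiente"),
      c("n-montana", "meronym", "n-cumbre"),
      c("n-montana", "related", "n-montanero"),
      c("n-madera", "hypernym", "n-material"),
      c("n-papel", "hypernym", "n-material"),
      c("n-carton", "hypernym", "n-papel"),
      c("n-profesor", "hypernym", "n-persona"),
      c("n-hombre", "hypernym", "n-persona"),
      c("n-casa", "hypernym", "n-vivienda"),
      c("n-apartamento", "hypernym", "n-vivienda"),
      c("v-llevar", "hypernym", "v-mover"),
      c("v-sacar", "hypernym", "v-mover")
    ),
    stem_overrides = c(),
    non_synonym_pairs = list(
      c("flor", "florista"),
      c("madera", "cartón"),
      c("panadero", "maestro")
    )
  )
}

#' Build a lexicon graph from a fixture description
#'
#' Synthetic stand-in for a full multilingual wordnet: materialises a
#' [lexicon_graph()] from a declarative description of synsets, relations
#' and stems. Output is deterministic for a fixed seed (the seed only
#' shuffles record order, so two runs with the same seed serialize
#' identically).
#'
#' @param spec A description list as returned by [default_lexicon_spec()].
#' @param seed Integer seed controlling record order.
#' @return A validated [lexicon_graph()].
#' @examples
#' kb <- build_fixture_lexicon(seed = 1)
#' shortest_path_distance(kb, "madera", "cartón")
#' @export
build_fixture_lexicon <- function(spec = default_lexicon_spec(), seed = 1) {
  synsets <- purrr::map_dfr(spec$synsets, function(s) {
    tibble(
      id = s$id, pos = s$pos, lemmas = list(s$lemmas),
      wordnet_domain = s$wordnet_domain %||% NA_character_,
      adimen_sumo = s$adimen_sumo %||% NA_character_,
      top_ontology = list(s$top_ontology %||% character())
    )
  })
  relations <- if (length(spec$relations)) {
    purrr::map_dfr(spec$relations, function(r) {
      tibble(from = r[[1]], kind = r[[2]], to = r[[3]])
    })[, c("from", "to", "kind")]
  } else {
    tibble(from = character(), to = character(), kind = character())
  }
  # entries derive from synset membership; a lemma may live in many synsets
  membership <- tidyr::unnest(
    synsets[, c("id", "pos", "lemmas")],
    cols = "lemmas"
  )
  entries <- membership %>%
    rename(lemma = "lemmas") %>%
    group_by(.data$lemma, .data$pos) %>%
    summarise(synset_ids = list(sort(unique(.data$id))), .groups = "drop")
  overrides <- spec$stem_overrides
  entries$stem <- ifelse(
    entries$lemma %in% names(overrides),
    unname(overrides[entries$lemma]),
    stem_word(entries$lemma, spec$language %||% "es")
  )
  entries <- entries[, c("lemma", "pos", "stem", "synset_ids")]
  # contradiction check: declared non-synonym pairs must not share a synset
  for (pair in spec$non_synonym_pairs %||% list()) {
    shared <- intersect(
      unlist(entries$synset_ids[entries$lemma == pair[[1]]]),
      unlist(entries$synset_ids[entries$lemma == pair[[2]]])
    )
    if (length(shared)) {
      abort(paste0("fixture spec declares ('", pair[[1]], "', '", pair[[2]],
                   "') non-synonyms but they share synset '", shared[1], "'"),
            class = "cogniscore_spec_error")
    }
  }
  with_local_seed(seed, {
    entries <- entries[sample.int(nrow(entries)), ]
    synsets <- synsets[sample.int(nrow(synsets)), ]
  })
  lexicon_graph(entries, synsets, relations,
                language_tag = spec$language %||% "es")
}
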
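# independent oracles and fixture builders used across the suite

# brute-force breadth-first search over an undirected edge list;
# deliberately independent of the package's graph machinery
bfs_distance <- function(edges, from, to) {
  if (from == to) return(0)
  nodes <- unique(c(edges$from, edges$to, from, to))
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (node in frontier) {
      nb <- c(edges$to[edges$from == node], edges$from[edges$to == node])
      new <- nb[dist[nb] == Inf]
      dist[new] <- dist[node] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  unname(dist[to])
}

# oracle distance between two words: min BFS distance over synset pairs
oracle_word_distance <- function(kb, w1, w2, pos = "noun") {
  e1 <- kb$entries[kb$entries$lemma == w1 & kb$entries$pos == pos, ]
  e2 <- kb$entries[kb$entries$lemma == w2 & kb$entries$pos == pos, ]
  if (nrow(e1) == 0 || nrow(e2) == 0) return(Inf)
  s1 <- e1$synset_ids[[1]]
  s2 <- e2$synset_ids[[1]]
  if (length(intersect(s1, s2))) return(0)
  ids <- kb$synsets$id[kb$synsets$pos == pos]
  edges <- kb$relations[kb$relations$from %in% ids & kb$relations$to %in% ids, ]
  min(outer(s1, s2, Vectorize(function(a, b) bfs_distance(edges, a, b))))
}

# entropy-based oracle for gain ratio on an already-discrete table;
# computed with straight table()/log2 arithmetic
oracle_gain_ratio <- function(x, y) {
  ent <- function(v) {
    p <- as.vector(table(v)) / length(v)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  hy <- ent(y)
  cond <- 0
  for (v in unique(x)) {
    sel <- x == v
    cond <- cond + mean(sel) * ent(y[sel])
  }
  si <- ent(x)
  if (si == 0) return(0)
  max(hy - cond, 0) / si
}

# random chain-and-cluster lexicon for property tests: `n_syn` noun synsets,
# random tree-ish relations, a couple of synonym groups
random_lexicon <- function(n_syn, seed) {
  set.seed(seed)
  ids <- sprintf("s%03d", seq_len(n_syn))
  lemmas <- sprintf("word%03d", seq_len(n_syn))
  spec <- list(
    language = "es",
    synsets = lapply(seq_len(n_syn), function(i) {
      list(id = ids[i], pos = "noun", lemmas = lemmas[i],
           wordnet_domain = sample(c(NA, "d1", "d2"), 1),
           adimen_sumo = NULL, top_ontology = character())
    }),
    relations = if (n_syn > 1) {
      lapply(2:n_syn, function(i) {
        parent <- sample(max(1, i - 4):(i - 1), 1)
        # leave some nodes disconnected to test infinite distances
        if (runif(1) < 0.15) NULL else {
          c(ids[i], sample(c("hypernym", "holonym", "related"), 1), ids[parent])
        }
      })
    } else {
      list()
    },
    stem_overrides = c(),
    non_synonym_pairs = list()
  )
  spec$relations <- Filter(Negate(is.null), spec$relations)
  build_fixture_lexicon(spec, seed = seed)
}

tok <- function(surface, lemma = tolower(surface), pos = "noun") {
  tibble::tibble(surface = surface, lemma = lemma, pos = pos)
}

toks <- function(...) dplyr::bind_rows(...)

fixture_kb <- function() build_fixture_lexicon(seed = 1)

# shared fixture: a gold sentence and three progressively degraded answers
degradation_gold <- function() {
  annotated_tokens(toks(
    tok("hombre"), tok("lleva", "llevar", "verb"), tok("silla"), tok("casa")
  ))
}

degradation_answers <- function() {
  list(
    paraphrase = annotated_tokens(toks(
      tok("persona"), tok("transporta", "transportar", "verb"),
      tok("silla"), tok("hogar")
    )),
    partial = annotated_tokens(toks(
      tok("profesor"), tok("mueve", "mover", "verb"), tok("tienda")
    )),
    unrelated = annotated_tokens(toks(
      tok("flor"), tok("rompe", "romper", "verb"), tok("madera")
    ))
  )
}

extdata <- function(file) system.file("extdata", file, package = "cogniscore")
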
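#' Word-similarity parameters
#'
#' Parameters of the taxonomy path-based word similarity
#' \deqn{s(w_1, w_2) = (1-\gamma)\,\alpha_s\,\beta^{d(w_1,w_2)} + \gamma}
#' where \eqn{\alpha_s} is 0.9 for synonym pairs and 0.85 otherwise,
#' \eqn{\beta} is an exponential depth-decay factor applied per taxonomy
#' step, \eqn{d} is the shortest relation path (0 for synonym or directly
#' related pairs), and \eqn{\gamma} is a correction that lifts the score of
#' word pairs sharing a WordNet domain (0.25) or a stem (0.5).
#'
#' @param alpha_synonym \eqn{\alpha_s} for synonym pairs.
#' @param alpha_default \eqn{\alpha_s} for all other pairs.
#' @param beta Depth decay per taxonomy edge, in (0, 1).
#' @param gamma_domain Correction for same-WordNet-domain non-synonym pairs.
#' @param gamma_stem Correction for same-stem non-synonym pairs whose
#'   uncorrected similarity is at most `stem_threshold`.
#' @param stem_threshold Uncorrected-similarity ceiling under which the stem
#'   correction applies.
#' @param identical_word_score Score assigned when the two lemmas are equal.
#' @param rounding_decimals Decimals used when reporting scores (half away
#'   from zero); internal computation is never rounded.
#' @return A list of class `similarity_params`.
#' @export
similarity_params <- function(alpha_synonym = 0.9,
                              alpha_default = 0.85,
                              beta = 0.7,
                              gamma_domain = 0.25,
                              gamma_stem = 0.5,
                              stem_threshold = 0.85,
                              identical_word_score = 1.0,
                              rounding_decimals = 2L) {
  p <- list(
    alpha_synonym = alpha_synonym, alpha_default = alpha_default,
    beta = beta, gamma_domain = gamma_domain, gamma_stem = gamma_stem,
    stem_threshold = stem_threshold,
    identical_word_score = identical_word_score,
    rounding_decimals = as.integer(rounding_decimals)
  )
  vals <- unlist(p[c("alpha_synonym", "alpha_default", "beta", "gamma_domain",
                     "gamma_stem", "identical_word_score")])
  if (any(vals < 0 | vals > 1)) {
    abort("similarity parameters must lie in [0, 1]",
          class = "cogniscore_settings_error")
  }
  if (p$beta <= 0 || p$beta >= 1) {
    abort("beta must lie strictly in (0, 1)",
          class = "cogniscore_settings_error")
  }
  if (p$alpha_synonym < p$alpha_default) {
    abort("alpha_synonym must be at least alpha_default",
          class = "cogniscore_settings_error")
  }
  structure(p, class = "similarity_params")
}

#' Uncorrected word similarity (depth-decayed alpha)
#'
#' The \eqn{\alpha_s \beta^d} term: identical lemmas score
#' `identical_word_score`; synonyms score `alpha_synonym`; directly related
#' pairs (holonym/hypernym/hyponym/meronym/related, or sharing a hierarchy
#' category) score `alpha_default` with the exponent at zero; otherwise
#' `alpha_default * beta^d` with `d` the shortest taxonomy path, and 0 when
#' the pair is disconnected or out of vocabulary.
#'
#' @inheritParams relation_summary
#' @param params A [similarity_params()] object.
#' @param summary Optional precomputed [relation_summary()] row.
#' @return A single number in \[0, 1\].
#' @export
base_similarity <- function(kb, w1, w2, pos = "noun",
                            params = similarity_params(),
                            summary = NULL) {
  if (tolower(w1) == tolower(w2)) return(params$identical_word_score)
  rs <- summary %||% relation_summary(kb, w1, w2, pos)
  if (rs$are_synonyms) return(params$alpha_synonym)
  if (rs$directly_related) return(params$alpha_default)
  if (is.infinite(rs$taxonomy_distance)) return(0)
  params$alpha_default * params$beta^rs$taxonomy_distance
}

#' Correction factor for a word pair
#'
#' By default \eqn{\gamma = 0}. Same-stem pairs that are not synonyms and
#' whose uncorrected similarity does not exceed `stem_threshold` receive
#' `gamma_stem`; otherwise non-synonym pairs sharing a WordNet domain
#' receive `gamma_domain`. The stem rule wins when both apply, since words
#' of one family should end up more similar than words merely sharing a
#' domain. Synonym pairs are never corrected.
#'
#' @param summary A one-row [relation_summary()] tibble (only the
#'   `are_synonyms`, `same_wordnet_domain` and `same_stem` flags are used).
#' @param base Uncorrected similarity of the pair.
#' @inheritParams base_similarity
#' @return One of `0`, `params$gamma_domain`, `params$gamma_stem`.
#' @export
select_gamma <- function(summary, base, params = similarity_params()) {
  stopifnot(base >= 0, base <= 1)
  if (summary$are_synonyms) return(0)
  if (summary$same_stem && base <= params$stem_threshold) {
    return(params$gamma_stem)
  }
  if (summary$same_wordnet_domain) return(params$gamma_domain)
  0
}

#' Corrected similarity of one word pair
#'
#' Full assessment of a same-pos word pair: uncorrected score, correction
#' factor and final score \eqn{(1-\gamma)\,\alpha_s\,\beta^d + \gamma}. The
#' uncorrected score can be injected through `base` (e.g. when reproducing a
#' score obtained on another lexicon); relation flags still come from the
#' lexicon, so the correction logic is exercised unchanged.
#'
#' @inheritParams base_similarity
#' @param base Optional injected uncorrected similarity overriding
#'   [base_similarity()].
#' @return A one-row tibble: `word1`, `word2`, `pos`, `alpha_used`,
#'   `distance_used`, `gamma_used`, `base_score`, `score`, `score_rounded`.
#' @examples
#' kb <- build_fixture_lexicon(seed = 1)
#' word_similarity(kb, "monte", "montaña")
#' word_similarity(kb, "madera", "cartón", base = 0.27)
#' @export
word_similarity <- function(kb, w1, w2, pos = "noun",
                            params = similarity_params(),
                            base = NULL) {
  rs <- relation_summary(kb, w1, w2, pos)
  identical_lemma <- tolower(w1) == tolower(w2)
  base_score <- base %||% base_similarity(kb, w1, w2, pos, params, summary = rs)
  gamma <- select_gamma(rs, base_score, params)
  score <- (1 - gamma) * base_score + gamma
  tibble(
    word1 = w1, word2 = w2, pos = pos,
    alpha_used = if (identical_lemma || rs$are_synonyms) {
      params$alpha_synonym
    } else {
      params$alpha_default
    },
    distance_used = if (rs$are_synonyms || rs$directly_related) {
      0
    } else {
      rs$taxonomy_distance
    },
    gamma_used = gamma,
    base_score = base_score,
    score = score,
    score_rounded = round_half_away(score, params$rounding_decimals)
  )
}
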
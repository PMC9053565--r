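Package: cogniscore
Title: Transparent Cognitive Screening from Conversational Answer Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores free-text answers against automatically extracted gold
    standards using taxonomy path-based word similarity with correction
    factors and tolerant numeric matching, generates dialogue sessions
    (dichotomous, distractor and attention-demanding questions) from
    annotated news items, and screens for cognitive impairment from
    session-derived features with gain-ratio attribute ranking and grouped
    k-fold cross-validation. Ships a synthetic cohort generator so the
    screening stage can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    knitr,
    randomForest,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
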
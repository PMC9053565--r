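{
  "topic": "society",
  "title": "Dangerous drug trafficking ring dismantled",
  "language": "en",
  "paragraphs": [
    [
      [
        {"surface": "National", "lemma": "national", "pos": "noun", "ne_tag": "organisation", "chunk": "B-NP"},
        {"surface": "Police", "lemma": "police", "pos": "noun", "ne_tag": "organisation", "chunk": "I-NP"},
        {"surface": "has", "lemma": "have", "pos": "verb", "ne_tag": "none", "chunk": "O"},
        {"surface": "dismantled", "lemma": "dismantle", "pos": "verb", "ne_tag": "none", "chunk": "O"},
        {"surface": "a", "lemma": "a", "pos": "other", "ne_tag": "none", "chunk": "B-NP"},
        {"surface": "dangerous", "lemma": "dangerous", "pos": "adjective", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": "drug", "lemma": "drug", "pos": "noun", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": "trafficking", "lemma": "trafficking", "pos": "noun", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": "ring", "lemma": "ring", "pos": "noun", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": "that", "lemma": "that", "pos": "other", "ne_tag": "none", "chunk": "O"},
        {"surface": "operated", "lemma": "operate", "pos": "verb", "ne_tag": "none", "chunk": "O"},
        {"surface": "in", "lemma": "in", "pos": "other", "ne_tag": "none", "chunk": "O"},
        {"surface": "Galicia", "lemma": "galicia", "pos": "noun", "ne_tag": "location", "chunk": "B-NP"},
        {"surface": ",", "lemma": ",", "pos": "other", "ne_tag": "none", "chunk": "O"},
        {"surface": "Madrid", "lemma": "madrid", "pos": "noun", "ne_tag": "location", "chunk": "B-NP"},
        {"surface": "and", "lemma": "and", "pos": "other", "ne_tag": "none", "chunk": "O"},
        {"surface": "Alicante", "lemma": "alicante", "pos": "noun", "ne_tag": "location", "chunk": "B-NP"},
        {"surface": ".", "lemma": ".", "pos": "other", "ne_tag": "none", "chunk": "O"}
      ]
    ]
  ]
}
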
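{
  "topic": "economy",
  "title": "Social electric bonds extended",
  "language": "en",
  "paragraphs": [
    [
      [
        {"surface": "The", "lemma": "the", "pos": "other", "ne_tag": "none", "chunk": "B-NP"},
        {"surface": "Government", "lemma": "government", "pos": "noun", "ne_tag": "organisation", "chunk": "I-NP"},
        {"surface": "will", "lemma": "will", "pos": "verb", "ne_tag": "none", "chunk": "O"},
        {"surface": "automatically", "lemma": "automatically", "pos": "adverb", "ne_tag": "none", "chunk": "O"},
        {"surface": "extend", "lemma": "extend", "pos": "verb", "ne_tag": "none", "chunk": "O"},
        {"surface": "the", "lemma": "the", "pos": "other", "ne_tag": "none", "chunk": "B-NP"},
        {"surface": "social", "lemma": "social", "pos": "adjective", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": "electric", "lemma": "electric", "pos": "adjective", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": "bonds", "lemma": "bond", "pos": "noun", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": "until", "lemma": "until", "pos": "other", "ne_tag": "none", "chunk": "O"},
        {"surface": "September", "lemma": "september", "pos": "noun", "ne_tag": "none", "chunk": "O"},
        {"surface": "15th", "lemma": "15th", "pos": "other", "ne_tag": "none", "chunk": "O"},
        {"surface": ".", "lemma": ".", "pos": "other", "ne_tag": "none", "chunk": "O"}
      ]
    ]
  ]
}
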
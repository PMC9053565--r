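{
  "topic": "society",
  "title": "Desarticulada una red de narcotraficantes",
  "language": "es",
  "paragraphs": [
    [
      [
        {"surface": "La", "lemma": "el", "pos": "other", "ne_tag": "none", "chunk": "B-NP"},
        {"surface": "Policía", "lemma": "policía", "pos": "noun", "ne_tag": "organisation", "chunk": "I-NP"},
        {"surface": "Nacional", "lemma": "nacional", "pos": "noun", "ne_tag": "organisation", "chunk": "I-NP"},
        {"surface": "ha", "lemma": "haber", "pos": "verb", "ne_tag": "none", "chunk": "O"},
        {"surface": "desarticulado", "lemma": "desarticular", "pos": "verb", "ne_tag": "none", "chunk": "O"},
        {"surface": "una", "lemma": "uno", "pos": "other", "ne_tag": "none", "chunk": "B-NP"},
        {"surface": "peligrosa", "lemma": "peligroso", "pos": "adjective", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": "red", "lemma": "red", "pos": "noun", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": "de", "lemma": "de", "pos": "other", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": "narcotraficantes", "lemma": "narcotraficante", "pos": "noun", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": "que", "lemma": "que", "pos": "other", "ne_tag": "none", "chunk": "O"},
        {"surface": "operaba", "lemma": "operar", "pos": "verb", "ne_tag": "none", "chunk": "O"},
        {"surface": "en", "lemma": "en", "pos": "other", "ne_tag": "none", "chunk": "O"},
        {"surface": "Galicia", "lemma": "galicia", "pos": "noun", "ne_tag": "location", "chunk": "B-NP"},
        {"surface": ",", "lemma": ",", "pos": "other", "ne_tag": "none", "chunk": "O"},
        {"surface": "Madrid", "lemma": "madrid", "pos": "noun", "ne_tag": "location", "chunk": "B-NP"},
        {"surface": "y", "lemma": "y", "pos": "other", "ne_tag": "none", "chunk": "O"},
        {"surface": "Alicante", "lemma": "alicante", "pos": "noun", "ne_tag": "location", "chunk": "B-NP"},
        {"surface": ".", "lemma": ".", "pos": "other", "ne_tag": "none", "chunk": "O"}
      ],
      [
        {"surface": "En", "lemma": "en", "pos": "other", "ne_tag": "none", "chunk": "O"},
        {"surface": "la", "lemma": "el", "pos": "other", "ne_tag": "none", "chunk": "B-NP"},
        {"surface": "operación", "lemma": "operación", "pos": "noun", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": "se", "lemma": "se", "pos": "other", "ne_tag": "none", "chunk": "O"},
        {"surface": "han", "lemma": "haber", "pos": "verb", "ne_tag": "none", "chunk": "O"},
        {"surface": "intervenido", "lemma": "intervenir", "pos": "verb", "ne_tag": "none", "chunk": "O"},
        {"surface": "1000", "lemma": "1000", "pos": "number", "is_numeric": true, "ne_tag": "none", "chunk": "B-NP"},
        {"surface": "kilos", "lemma": "kilo", "pos": "noun", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": "de", "lemma": "de", "pos": "other", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": "cocaína", "lemma": "cocaína", "pos": "noun", "ne_tag": "none", "chunk": "I-NP"},
        {"surface": ".", "lemma": ".", "pos": "other", "ne_tag": "none", "chunk": "O"}
      ]
    ]
  ]
}
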
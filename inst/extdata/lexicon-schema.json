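{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "cogniscore lexicon graph",
  "type": "object",
  "required": ["entries", "synsets"],
  "properties": {
    "language_tag": {"type": "string"},
    "entries": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["lemma", "pos", "stem", "synset_ids"],
        "properties": {
          "lemma": {"type": "string"},
          "pos": {"enum": ["noun", "verb", "adjective", "adverb"]},
          "stem": {"type": "string", "minLength": 1},
          "synset_ids": {"type": "array", "items": {"type": "string"}}
        }
      }
    },
    "synsets": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "pos", "lemmas"],
        "properties": {
          "id": {"type": "string"},
          "pos": {"enum": ["noun", "verb", "adjective", "adverb"]},
          "lemmas": {"type": "array", "items": {"type": "string"}},
          "wordnet_domain": {"type": ["string", "null"]},
          "adimen_sumo": {"type": ["string", "null"]},
          "top_ontology": {"type": "array", "items": {"type": "string"}},
          "relations": {
            "type": "object",
            "propertyNames": {
              "enum": ["holonym", "hypernym", "hyponym", "meronym", "related"]
            },
            "additionalProperties": {
              "type": "array",
              "items": {"type": "string"}
            }
          }
        }
      }
    }
  }
}
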
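{
  "language": "es",
  "subject_pronoun": "Ello",
  "yes_markers": ["sí", "si", "claro", "por supuesto", "efectivamente", "desde luego"],
  "no_markers": ["no", "nunca", "jamás", "tampoco"],
  "dichotomous": {
    "person": [
      "¿Has oído hablar de ENTIDAD?",
      "¿Conoces a ENTIDAD?",
      "¿Te suena el nombre de ENTIDAD?",
      "¿Sabes quién es ENTIDAD?"
    ],
    "location": [
      "¿Has estado alguna vez en ENTIDAD?",
      "¿Conoces ENTIDAD?",
      "¿Te gustaría visitar ENTIDAD?",
      "¿Sabes dónde está ENTIDAD?"
    ]
  },
  "follow_up": {
    "person": {
      "yes": "¿Qué datos conoces de la vida de ENTIDAD?",
      "no": "¿Por qué ha saltado a los medios de comunicación ENTIDAD?",
      "na": "¿Qué visión de ENTIDAD nos dan los medios de comunicación?"
    },
    "location": {
      "yes": "Cuéntame qué es lo que más te ha gustado de ENTIDAD",
      "no": "¿Por qué no has estado en ENTIDAD?",
      "na": "¿Podrías contarme algo relacionado con ENTIDAD?"
    }
  },
  "wh": {
    "who": "¿Quién PREDICADO?",
    "what": "¿Qué ha pasado según la noticia?",
    "which_places": "¿Qué lugares menciona la noticia?"
  }
}
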
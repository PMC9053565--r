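{
  "language": "en",
  "subject_pronoun": "It",
  "yes_markers": ["yes", "sure", "certainly", "indeed", "absolutely"],
  "no_markers": ["no", "never", "nope"],
  "dichotomous": {
    "person": [
      "Have you ever heard about ENTIDAD?",
      "Do you know ENTIDAD?",
      "Does the name ENTIDAD ring a bell?",
      "Do you know who ENTIDAD is?"
    ],
    "location": [
      "Have you ever been to ENTIDAD?",
      "Do you know ENTIDAD?",
      "Would you like to visit ENTIDAD?",
      "Do you know where ENTIDAD is?"
    ]
  },
  "follow_up": {
    "person": {
      "yes": "What facts do you know about ENTIDAD's life?",
      "no": "Why has ENTIDAD jumped into the media?",
      "na": "Which is the view of ENTIDAD in the media?"
    },
    "location": {
      "yes": "Tell me what you liked the most about ENTIDAD",
      "no": "Why have you never been to ENTIDAD?",
      "na": "Could you tell me anything about ENTIDAD?"
    }
  },
  "wh": {
    "who": "Who PREDICADO?",
    "what": "What does the news say will happen?",
    "which_places": "Which places does the news item mention?"
  }
}
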
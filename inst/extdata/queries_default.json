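[
  {
    "query_id": "causal_shoulder_symptom_vaccine",
    "ordered": false,
    "max_sentence_span": 4,
    "max_intervening_words": 50,
    "require_same_section": true,
    "items": [
      "shoulder_symptom",
      {
        "query_id": "pair_vaccine",
        "ordered": true,
        "max_sentence_span": 1,
        "max_intervening_words": 2,
        "require_same_section": true,
        "items": [
          "causal_trigger",
          "vaccine"
        ]
      }
    ]
  },
  {
    "query_id": "causal_shoulder_symptom_cause_accident",
    "ordered": false,
    "max_sentence_span": 4,
    "max_intervening_words": 50,
    "require_same_section": true,
    "items": [
      "shoulder_symptom",
      {
        "query_id": "pair_cause_accident",
        "ordered": true,
        "max_sentence_span": 1,
        "max_intervening_words": 2,
        "require_same_section": true,
        "items": [
          "causal_trigger",
          "cause_accident"
        ]
      }
    ]
  },
  {
    "query_id": "causal_shoulder_symptom_cause_work",
    "ordered": false,
    "max_sentence_span": 4,
    "max_intervening_words": 50,
    "require_same_section": true,
    "items": [
      "shoulder_symptom",
      {
        "query_id": "pair_cause_work",
        "ordered": true,
        "max_sentence_span": 1,
        "max_intervening_words": 2,
        "require_same_section": true,
        "items": [
          "causal_trigger",
          "cause_work"
        ]
      }
    ]
  },
  {
    "query_id": "causal_shoulder_symptom_cause_medical_condition",
    "ordered": false,
    "max_sentence_span": 4,
    "max_intervening_words": 50,
    "require_same_section": true,
    "items": [
      "shoulder_symptom",
      {
        "query_id": "pair_cause_medical_condition",
        "ordered": true,
        "max_sentence_span": 1,
        "max_intervening_words": 2,
        "require_same_section": true,
        "items": [
          "causal_trigger",
          "cause_medical_condition"
        ]
      }
    ]
  },
  {
    "query_id": "causal_shoulder_symptom_cause_exercise",
    "ordered": false,
    "max_sentence_span": 4,
    "max_intervening_words": 50,
    "require_same_section": true,
    "items": [
      "shoulder_symptom",
      {
        "query_id": "pair_cause_exercise",
        "ordered": true,
        "max_sentence_span": 1,
        "max_intervening_words": 2,
        "require_same_section": true,
        "items": [
          "causal_trigger",
          "cause_exercise"
        ]
      }
    ]
  },
  {
    "query_id": "causal_shoulder_symptom_cause_daily_activity",
    "ordered": false,
    "max_sentence_span": 4,
    "max_intervening_words": 50,
    "require_same_section": true,
    "items": [
      "shoulder_symptom",
      {
        "query_id": "pair_cause_daily_activity",
        "ordered": true,
        "max_sentence_span": 1,
        "max_intervening_words": 2,
        "require_same_section": true,
        "items": [
          "causal_trigger",
          "cause_daily_activity"
        ]
      }
    ]
  },
  {
    "query_id": "causal_shoulder_symptom_cause_unknown",
    "ordered": false,
    "max_sentence_span": 1,
    "max_intervening_words": 50,
    "require_same_section": true,
    "items": [
      "shoulder_symptom",
      "cause_unknown"
    ]
  },
  {
    "query_id": "causal_shoulder_diagnosis_vaccine",
    "ordered": false,
    "max_sentence_span": 4,
    "max_intervening_words": 50,
    "require_same_section": true,
    "items": [
      "shoulder_diagnosis",
      {
        "query_id": "pair_vaccine",
        "ordered": true,
        "max_sentence_span": 1,
        "max_intervening_words": 2,
        "require_same_section": true,
        "items": [
          "causal_trigger",
          "vaccine"
        ]
      }
    ]
  },
  {
    "query_id": "causal_shoulder_diagnosis_cause_accident",
    "ordered": false,
    "max_sentence_span": 4,
    "max_intervening_words": 50,
    "require_same_section": true,
    "items": [
      "shoulder_diagnosis",
      {
        "query_id": "pair_cause_accident",
        "ordered": true,
        "max_sentence_span": 1,
        "max_intervening_words": 2,
        "require_same_section": true,
        "items": [
          "causal_trigger",
          "cause_accident"
        ]
      }
    ]
  },
  {
    "query_id": "causal_shoulder_diagnosis_cause_work",
    "ordered": false,
    "max_sentence_span": 4,
    "max_intervening_words": 50,
    "require_same_section": true,
    "items": [
      "shoulder_diagnosis",
      {
        "query_id": "pair_cause_work",
        "ordered": true,
        "max_sentence_span": 1,
        "max_intervening_words": 2,
        "require_same_section": true,
        "items": [
          "causal_trigger",
          "cause_work"
        ]
      }
    ]
  },
  {
    "query_id": "causal_shoulder_diagnosis_cause_medical_condition",
    "ordered": false,
    "max_sentence_span": 4,
    "max_intervening_words": 50,
    "require_same_section": true,
    "items": [
      "shoulder_diagnosis",
      {
        "query_id": "pair_cause_medical_condition",
        "ordered": true,
        "max_sentence_span": 1,
        "max_intervening_words": 2,
        "require_same_section": true,
        "items": [
          "causal_trigger",
          "cause_medical_condition"
        ]
      }
    ]
  },
  {
    "query_id": "causal_shoulder_diagnosis_cause_exercise",
    "ordered": false,
    "max_sentence_span": 4,
    "max_intervening_words": 50,
    "require_same_section": true,
    "items": [
      "shoulder_diagnosis",
      {
        "query_id": "pair_cause_exercise",
        "ordered": true,
        "max_sentence_span": 1,
        "max_intervening_words": 2,
        "require_same_section": true,
        "items": [
          "causal_trigger",
          "cause_exercise"
        ]
      }
    ]
  },
  {
    "query_id": "causal_shoulder_diagnosis_cause_daily_activity",
    "ordered": false,
    "max_sentence_span": 4,
    "max_intervening_words": 50,
    "require_same_section": true,
    "items": [
      "shoulder_diagnosis",
      {
        "query_id": "pair_cause_daily_activity",
        "ordered": true,
        "max_sentence_span": 1,
        "max_intervening_words": 2,
        "require_same_section": true,
        "items": [
          "causal_trigger",
          "cause_daily_activity"
        ]
      }
    ]
  },
  {
    "query_id": "causal_shoulder_diagnosis_cause_unknown",
    "ordered": false,
    "max_sentence_span": 1,
    "max_intervening_words": 50,
    "require_same_section": true,
    "items": [
      "shoulder_diagnosis",
      "cause_unknown"
    ]
  }
]
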
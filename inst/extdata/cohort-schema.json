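{
  "schema_version": "1.0",
  "format": "UTF-8 JSON array; one object per patient; keys in the order listed below; missing values encoded as null (an absent key is equivalent to null); all day counts are integers with day 0 = initial diagnosis",
  "fields": [
    {"field": "patient_id", "type": "string", "possible_values": "zero-padded numeric string, unique within a cohort"},
    {"field": "sex", "type": "category", "possible_values": ["male", "female"]},
    {"field": "age_at_diagnosis", "type": "integer (years)", "possible_values": ">= 0"},
    {"field": "smoking_status", "type": "category", "possible_values": ["never", "former", "current", "unknown"]},
    {"field": "primary_site", "type": "category", "possible_values": ["oral_cavity", "oropharynx", "hypopharynx", "larynx", "cup"]},
    {"field": "grading", "type": "category or null", "possible_values": ["G1", "G2", "G3"], "note": "null for ungraded tumors, e.g. HPV-associated carcinoma"},
    {"field": "pt_stage", "type": "ordinal category", "possible_values": ["pTis", "pT1", "pT2", "pT3", "pT4", "pT4a", "pT4b"], "ordinal_labels": {"pTis": 0, "pT1": 1, "pT2": 2, "pT3": 3, "pT4": 4, "pT4a": 5, "pT4b": 6}},
    {"field": "pn_stage", "type": "ordinal category", "possible_values": ["pN0", "pN1", "pN2", "pN2a", "pN2b", "pN2c", "pN3"], "ordinal_labels": {"pN0": 0, "pN1": 1, "pN2": 2, "pN2a": 2, "pN2b": 2, "pN2c": 2, "pN3": 3}},
    {"field": "lymphatic_invasion", "type": "boolean or null", "possible_values": [true, false, null]},
    {"field": "vascular_invasion", "type": "boolean or null", "possible_values": [true, false, null]},
    {"field": "perineural_invasion", "type": "boolean or null", "possible_values": [true, false, null]},
    {"field": "carcinoma_in_situ", "type": "boolean or null", "possible_values": [true, false, null]},
    {"field": "hpv_positive", "type": "boolean or null", "possible_values": [true, false, null]},
    {"field": "resection_margin_positive", "type": "boolean or null", "possible_values": [true, false, null]},
    {"field": "blood", "type": "map parameter-name -> object", "possible_values": "objects with keys value (finite number), unit (string), group (string, e.g. hematology, inflammation, electrolytes, renal)"},
    {"field": "icd_codes", "type": "array of strings", "possible_values": "ICD-10 code strings, possibly empty"},
    {"field": "tma_density", "type": "map or null", "possible_values": "keys CD3_tumor_center, CD3_invasion_front, CD8_tumor_center, CD8_invasion_front; values cells per mm^2 (number >= 0) or null"},
    {"field": "recurrence_days", "type": "integer or null", "possible_values": ">= 0; days since initial diagnosis"},
    {"field": "death_days", "type": "integer or null", "possible_values": ">= 0; days since initial diagnosis; defines the end of follow-up when present"},
    {"field": "death_tumor_specific", "type": "boolean or null", "possible_values": [true, false, null], "note": "null = cause of death unknown"},
    {"field": "followup_days", "type": "integer", "possible_values": ">= 0; required"}
  ]
}
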
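{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "gvhdgrade/patient-record-v1",
  "title": "GvHD patient record, schema version 1.0",
  "type": "object",
  "required": ["schema_version", "patient_id", "timeline"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "patient_id": {"type": "string"},
    "notes": {"type": "string"},
    "timeline": {
      "type": "object",
      "required": ["hct_date"],
      "properties": {
        "hct_date": {"type": "string", "format": "date"},
        "dli_dates": {"type": "array", "items": {"type": "string", "format": "date"}},
        "episodes": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["onset_date", "manifestation_class"],
            "properties": {
              "onset_date": {"type": "string", "format": "date"},
              "end_of_activity_date": {"type": ["string", "null"], "format": "date"},
              "manifestation_class": {
                "enum": ["acute_features", "chronic_features", "both", "undefined_other"]
              },
              "organs": {"type": "array", "items": {"type": "string"}},
              "sequelae_present": {"type": "boolean"},
              "first_episode": {"type": "boolean"}
            }
          }
        },
        "immunosuppression": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["drug", "start_date"],
            "properties": {
              "drug": {"type": "string"},
              "start_date": {"type": "string", "format": "date"},
              "stop_date": {"type": ["string", "null"], "format": "date"},
              "doses": {
                "type": "array",
                "items": {
                  "type": "object",
                  "required": ["date", "dose_mg_kg_day"],
                  "properties": {
                    "date": {"type": "string", "format": "date"},
                    "dose_mg_kg_day": {"type": "number", "minimum": 0}
                  }
                }
              },
              "taper_attempts": {
                "type": "array",
                "items": {
                  "type": "object",
                  "required": ["date", "dose", "control_lost"],
                  "properties": {
                    "date": {"type": "string", "format": "date"},
                    "dose": {"type": "number", "minimum": 0},
                    "control_lost": {"type": "boolean"}
                  }
                }
              }
            }
          }
        }
      }
    },
    "visits": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["date", "type"],
        "properties": {
          "date": {"type": "string", "format": "date"},
          "type": {"enum": ["acute", "chronic"]},
          "findings": {
            "type": "object",
            "properties": {
              "rash_bsa_pct": {"type": "number", "minimum": 0, "maximum": 100},
              "bullae_desquamation_bsa_pct": {"type": "number", "minimum": 0, "maximum": 100},
              "generalized_erythroderma": {"type": "boolean"},
              "bilirubin_mg_dl": {"type": "number", "minimum": 0},
              "bilirubin_umol_l": {"type": "number", "minimum": 0},
              "anorexia_with_weight_loss": {"type": "boolean"},
              "nausea_days": {"type": "integer", "minimum": 0},
              "vomiting_episodes_per_day": {"type": "integer", "minimum": 0},
              "vomiting_days": {"type": "integer", "minimum": 0},
              "upper_gi_biopsy_positive": {"type": ["boolean", "null"]},
              "stool_volume_ml_per_day": {"type": ["number", "null"], "minimum": 0},
              "stool_episodes_per_day": {"type": ["integer", "null"], "minimum": 0},
              "severe_abdominal_pain": {"type": "boolean"},
              "ileus": {"type": "boolean"},
              "grossly_bloody_stools": {"type": "boolean"},
              "is_pediatric": {"type": "boolean"},
              "patient_weight_kg": {"type": ["number", "null"], "exclusiveMinimum": 0},
              "karnofsky_pct": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
              "attribution": {
                "type": "object",
                "additionalProperties": {"enum": ["gvhd", "mixed", "non_gvhd_only"]}
              }
            }
          },
          "scores": {
            "type": "object",
            "additionalProperties": {"type": "integer", "minimum": 0, "maximum": 3}
          },
          "attribution": {
            "type": "object",
            "additionalProperties": {"enum": ["gvhd", "mixed", "non_gvhd_only"]}
          },
          "lung": {
            "type": "object",
            "properties": {
              "pft_score": {"type": ["integer", "null"], "minimum": 0, "maximum": 3},
              "pft_date": {"type": ["string", "null"], "format": "date"},
              "dyspnea_score": {"type": ["integer", "null"], "minimum": 0, "maximum": 3}
            }
          },
          "karnofsky_pct": {"type": ["number", "null"], "minimum": 0, "maximum": 100},
          "undefined_other": {"type": "array", "items": {"type": "string"}}
        }
      }
    }
  }
}
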
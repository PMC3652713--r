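{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "oash20 registry resource",
  "description": "Structural contract for the packaged 20-condition classification scheme. The loader enforces these checks in code (no JSON-schema validator is a package dependency); this file documents the contract for external consumers.",
  "type": "object",
  "required": ["scheme", "version", "dialects", "conditions", "definitions", "schemes", "mcc_threshold_default"],
  "properties": {
    "scheme": {"type": "string"},
    "version": {"type": "string"},
    "mcc_threshold_default": {"type": "integer", "minimum": 1},
    "dialects": {
      "type": "array",
      "minItems": 5,
      "maxItems": 5,
      "items": {
        "type": "object",
        "required": ["dialect_id", "name", "unit_of_analysis", "condition_data_kind", "operator", "sampling_frame", "data_source"],
        "properties": {
          "dialect_id": {"enum": ["NHIS", "NAMCS", "MEPS", "NIS", "CMS"]},
          "unit_of_analysis": {"enum": ["individual", "visit", "hospitalization"]},
          "condition_data_kind": {"enum": ["self_report", "checkbox", "ccs_codes", "icd9_codes"]}
        }
      }
    },
    "conditions": {
      "type": "array",
      "minItems": 20,
      "maxItems": 20,
      "items": {
        "type": "object",
        "required": ["condition_id", "display_name", "sub_conditions", "mappings"],
        "properties": {
          "condition_id": {"type": "string", "pattern": "^[a-z][a-z0-9_]*$"},
          "display_name": {"type": "string"},
          "scope_note": {"type": "string"},
          "sub_conditions": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["name"],
              "properties": {
                "name": {"type": "string"},
                "alias_of": {"type": ["string", "null"]}
              }
            }
          },
          "mappings": {
            "type": "object",
            "propertyNames": {"enum": ["NHIS", "NAMCS", "MEPS", "NIS", "CMS"]},
            "additionalProperties": {
              "type": "object",
              "required": ["state", "kind"],
              "properties": {
                "state": {"enum": ["measured", "related_proxy", "unavailable"]},
                "kind": {"enum": ["icd9cm", "ccs", "survey_item", "checkbox", "unavailable"]},
                "cells": {"type": "array", "items": {"type": "string"}},
                "cell_labels": {"type": "array", "items": {"type": "string"}},
                "item_label": {"type": "string"},
                "source_cell": {"type": "string"},
                "note": {"type": "string"},
                "anomaly": {"type": "string"},
                "drop_invalid_tokens": {"type": "boolean"}
              }
            }
          }
        }
      }
    },
    "definitions": {
      "type": "array",
      "minItems": 10,
      "maxItems": 10,
      "items": {
        "type": "object",
        "required": ["source", "year", "duration_criterion", "functional_limitation", "ongoing_care"]
      }
    },
    "schemes": {
      "type": "array",
      "minItems": 5,
      "maxItems": 5,
      "items": {
        "type": "object",
        "required": ["scheme_name", "source", "first_year", "n_conditions", "method"]
      }
    }
  }
}
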
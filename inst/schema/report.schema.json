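{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "netLTP pipeline report",
  "type": "object",
  "required": ["meta", "plasticity"],
  "properties": {
    "meta": {
      "type": "object",
      "required": ["package", "version", "seed", "networks"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "seed": {"type": "integer"},
        "networks": {"type": ["array", "string"]},
        "noiseSd": {"type": "number"},
        "activityThresholdSd": {"type": "number"}
      }
    },
    "plasticity": {
      "description": "combined per-layer plasticity table (network, layer, plasticityPct, n)",
      "type": ["object", "array"]
    }
  },
  "patternProperties": {
    "^(CA|DG)$": {
      "type": "object",
      "required": ["classification", "latency", "ltp", "kcsd"],
      "properties": {
        "classification": {
          "type": "object",
          "properties": {
            "baseline": {"$ref": "#/definitions/classPhase"},
            "post_tetanic": {"$ref": "#/definitions/classPhase"}
          }
        },
        "latency": {
          "type": "object",
          "required": ["baseline", "post_tetanic", "changePct", "recruitmentFold"]
        },
        "ltp": {
          "type": "object",
          "required": ["plasticity", "detect"]
        },
        "kcsd": {
          "type": "object",
          "required": ["lambda", "nSinks", "nSources"],
          "properties": {
            "lambda": {"type": "number", "minimum": 0},
            "nSinks": {"type": "integer", "minimum": 0},
            "nSources": {"type": "integer", "minimum": 0},
            "sinkIntegral": {"type": "number", "maximum": 0},
            "sourceIntegral": {"type": "number", "minimum": 0}
          }
        }
      }
    }
  },
  "definitions": {
    "classPhase": {
      "type": "object",
      "required": ["accuracy", "k"],
      "properties": {
        "accuracy": {"type": "number", "minimum": 0, "maximum": 1},
        "nComponents": {"type": "integer", "minimum": 1},
        "k": {"type": "integer", "minimum": 2}
      }
    }
  }
}
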
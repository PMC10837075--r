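{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "mmus run configuration",
  "description": "Configuration consumed by runExperiment(); YAML and JSON are accepted. Pixel indices in ROIs are 0-based, half-open; well centres are 1-based pixel coordinates.",
  "type": "object",
  "required": ["phantom", "acquisition", "rois", "pairings"],
  "properties": {
    "session": {"type": "string", "default": "session1"},
    "seed": {"type": "integer", "description": "master RNG seed; overrides acquisition.seed"},
    "output_dir": {"type": "string", "description": "where results.csv is written; omit to only return the table"},
    "phantom": {
      "type": "object",
      "required": ["grid_shape", "wells"],
      "properties": {
        "grid_shape": {"type": "array", "items": {"type": "integer", "minimum": 1}, "minItems": 2, "maxItems": 2},
        "pixel_pitch": {"type": "number", "exclusiveMinimum": 0, "default": 0.1, "description": "mm"},
        "background_echogenicity": {"type": "number", "minimum": 0, "default": 1},
        "wells": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["center", "half_size", "elastic_modulus", "concentration"],
            "properties": {
              "center": {"type": "array", "items": {"type": "integer"}, "minItems": 2, "maxItems": 2},
              "half_size": {"type": "array", "items": {"type": "integer", "minimum": 0}, "minItems": 1, "maxItems": 2},
              "elastic_modulus": {"type": "number", "exclusiveMinimum": 0, "description": "Pa"},
              "concentration": {"type": "number", "minimum": 0, "description": "nM"},
              "agent": {"enum": ["MGV", "GV", "MNP"], "default": "MGV"}
            }
          }
        }
      }
    },
    "acquisition": {
      "type": "object",
      "properties": {
        "frame_rate": {"type": "number", "exclusiveMinimum": 0, "default": 500, "description": "Hz; must exceed 2*f0"},
        "n_frames": {"type": "integer", "minimum": 1, "default": 500},
        "f0": {"type": "number", "exclusiveMinimum": 0, "default": 5, "description": "magnetic drive frequency, Hz"},
        "field_strength": {"type": "number", "exclusiveMinimum": 0, "default": 30, "description": "mT"},
        "center_freq": {"type": "number", "exclusiveMinimum": 0, "default": 15.6, "description": "MHz"},
        "sound_speed": {"type": "number", "exclusiveMinimum": 0, "default": 1540, "description": "m/s"},
        "n_loops": {"type": "integer", "minimum": 1, "default": 20},
        "noise_sd": {"type": "number", "minimum": 0, "default": 0.05},
        "coupling_kappa": {"type": "number", "exclusiveMinimum": 0, "default": 1, "description": "um*Pa/(nM*mT^2)"},
        "seed": {"type": "integer", "default": 1}
      }
    },
    "rois": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["label", "x0", "z0", "x1", "z1"],
        "properties": {
          "label": {"type": "string"},
          "x0": {"type": "integer", "minimum": 0},
          "z0": {"type": "integer", "minimum": 0},
          "x1": {"type": "integer", "exclusiveMinimum": 0},
          "z1": {"type": "integer", "exclusiveMinimum": 0}
        }
      }
    },
    "pairings": {
      "type": "array",
      "description": "sample/background ROI label pairs quantified on every map",
      "items": {
        "type": "object",
        "required": ["sample", "background"],
        "properties": {
          "sample": {"type": "string"},
          "background": {"type": "string"}
        }
      }
    },
    "options": {
      "type": "object",
      "properties": {
        "reject_loops": {"type": "boolean", "default": false},
        "reject_threshold": {"type": ["number", "null"], "default": null, "description": "rad; null = 3x lower quartile of loop motion metrics"},
        "decimals": {"type": "integer", "minimum": 0, "default": 1}
      }
    },
    "schedule": {
      "type": ["object", "null"],
      "description": "longitudinal mode: parallel arrays of strictly increasing days and positive moduli (Pa) substituted into all wells",
      "properties": {
        "day": {"type": "array", "items": {"type": "number"}},
        "modulus": {"type": "array", "items": {"type": "number", "exclusiveMinimum": 0}}
      }
    }
  }
}
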
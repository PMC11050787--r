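{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "ligsim experiment summary",
  "type": "object",
  "required": ["quantities", "experiment", "seed"],
  "properties": {
    "experiment": {
      "type": "string",
      "enum": ["worked_example", "flexion_compare", "pcl_sweep"]
    },
    "seed": {"type": "integer"},
    "quantities": {
      "type": "object",
      "description": "Experiment-specific named numeric results (N, mm, deg, %)."
    }
  }
}
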
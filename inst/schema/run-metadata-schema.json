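{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "abasim run metadata sidecar",
  "type": "object",
  "required": ["kind", "package", "package_version"],
  "properties": {
    "kind": {
      "type": "string",
      "enum": ["trajectory", "dose_response", "synthetic_plate",
               "steady_state", "hill_fit", "biosensor_fit",
               "linear_fit", "sensitivity"]
    },
    "package": {"type": "string", "const": "abasim"},
    "package_version": {"type": "string"},
    "model_id": {"type": "string"},
    "mode": {"type": ["string", "null"]},
    "params": {"type": "object"},
    "params_digest": {"type": "string"},
    "seed": {"type": ["integer", "number"]},
    "t_end": {"type": "number"},
    "noise_sd": {"type": "number"},
    "noise_type": {"type": "string"}
  }
}
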
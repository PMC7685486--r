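{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "pipeline_config",
  "description": "Pipeline job configuration: schema file locations for the five data common specification components plus the ordered list of functions to execute, each with named parameters and declared input/output datatypes.",
  "type": "object",
  "required": ["experiment", "phasedesc", "phase", "action", "player", "functions"],
  "properties": {
    "experiment": {"type": "string", "minLength": 1},
    "phasedesc": {"type": "string", "minLength": 1},
    "phase": {"type": "string", "minLength": 1},
    "action": {"type": "string", "minLength": 1},
    "player": {"type": "string", "minLength": 1},
    "functions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "inputs", "outputs"],
        "properties": {
          "name": {"type": "string", "minLength": 1},
          "params": {"type": "object"},
          "inputs": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["datatype", "source"],
              "properties": {
                "datatype": {"type": "string", "minLength": 1},
                "source": {"type": "string", "enum": ["initial", "prior"]}
              }
            }
          },
          "outputs": {"type": "array", "items": {"type": "string", "minLength": 1}}
        }
      }
    }
  }
}
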
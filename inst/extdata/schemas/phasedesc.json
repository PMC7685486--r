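{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "phasedesc",
  "description": "Phase descriptions: time-indexed node/edge attribute sequences, node/edge initial conditions, and the action set available during the phase.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["ph_sch_id", "action_set"],
    "additionalProperties": false,
    "properties": {
      "ph_sch_id": {"type": "string", "minLength": 1},
      "action_set": {"type": "array", "items": {"type": "string", "minLength": 1}, "uniqueItems": true},
      "node_attributes": {"type": "object"},
      "edge_attributes": {"type": "object"},
      "node_initial_conditions": {"type": "object"},
      "edge_initial_conditions": {"type": "object"}
    }
  }
}
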
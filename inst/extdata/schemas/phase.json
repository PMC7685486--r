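{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "phase",
  "description": "Structural phase records: id, order in the experiment, begin timestamp, duration in time increments, time unit, participating nodes, undirected edges (sorted 2-element arrays of player ids) and edge meanings.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["ph_sch_id", "exp_id", "seq_index", "t_ph_begin", "t_p", "u_p", "nodes", "edges"],
    "additionalProperties": false,
    "properties": {
      "ph_sch_id": {"type": "string", "minLength": 1},
      "exp_id": {"type": "string", "minLength": 1},
      "seq_index": {"type": "integer", "minimum": 1},
      "t_ph_begin": {"type": "string", "pattern": "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?Z$"},
      "t_p": {"type": "number", "exclusiveMinimum": 0},
      "u_p": {"type": "string", "minLength": 1},
      "nodes": {"type": "array", "items": {"type": "string", "minLength": 1}, "uniqueItems": true},
      "edges": {
        "type": "array",
        "uniqueItems": true,
        "items": {"type": "array", "minItems": 2, "maxItems": 2, "items": {"type": "string"}}
      },
      "edge_meanings": {"type": "array", "items": {"type": "string"}}
    }
  }
}
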
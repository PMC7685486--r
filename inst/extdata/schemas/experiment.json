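{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "experiment",
  "description": "Experiment description and initial parameters: id, phase count, player count, begin/end timestamps, player roster and invariant player attributes.",
  "type": "object",
  "required": ["exp_id", "n_p", "n", "t_begin", "t_end", "players"],
  "additionalProperties": false,
  "properties": {
    "exp_id": {"type": "string", "minLength": 1},
    "n_p": {"type": "integer", "minimum": 1},
    "n": {"type": "integer", "minimum": 0},
    "t_begin": {"type": "string", "pattern": "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?Z$"},
    "t_end": {"type": "string", "pattern": "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?Z$"},
    "players": {"type": "array", "items": {"type": "string", "minLength": 1}, "uniqueItems": true},
    "player_attributes": {"type": "object"}
  }
}
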
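{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "player",
  "description": "Player roster records linking player ids to the experiment, with optional invariant attributes (e.g. age, gender).",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["player_id", "exp_id"],
    "additionalProperties": false,
    "properties": {
      "player_id": {"type": "string", "minLength": 1},
      "exp_id": {"type": "string", "minLength": 1},
      "attributes": {"type": "object"}
    }
  }
}
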
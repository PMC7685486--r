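{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "raw_session_csv",
  "description": "Raw experiment event log (canonical CSV dialect), one event per row: session id, phase index, player id, ISO-8601 timestamp, event type, optional target player and JSON payload.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["session_id", "phase_index", "player_id", "timestamp_iso", "event_type"],
    "properties": {
      "session_id": {"type": "string", "minLength": 1},
      "phase_index": {"type": "integer", "minimum": 0},
      "player_id": {"type": "string", "minLength": 1},
      "timestamp_iso": {"type": "string", "pattern": "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?Z$"},
      "event_type": {"type": "string", "minLength": 1},
      "target_player": {"anyOf": [{"type": "string"}, {"type": "null"}]},
      "payload_json": {"anyOf": [{"type": "string"}, {"type": "null"}]}
    }
  }
}
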
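{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "action",
  "description": "Action tuples: (sigma, action, initiator, target, time, payload) with a phase reference. sigma links related actions (a request and its reply share one sigma). Time is phase-relative, 0 <= time; the per-phase upper bound t_p is enforced by the phase-specialized schema and record validators.",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["sigma", "action", "initiator", "time", "ph_sch_id"],
    "properties": {
      "sigma": {"type": "string", "minLength": 1},
      "action": {"type": "string", "minLength": 1},
      "initiator": {"type": "string", "minLength": 1},
      "target": {"anyOf": [{"type": "string"}, {"type": "null"}]},
      "time": {"type": "number", "minimum": 0},
      "ph_sch_id": {"type": "string", "minLength": 1},
      "payload": {}
    }
  }
}
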
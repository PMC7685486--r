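# Data common specification — on-disk format

One experiment is stored as five JSON documents, each gated by a JSON
Schema (draft 2020-12 subset) shipped under `inst/extdata/schemas/`. Field
names are snake_case transliterations of the abstract data model's symbols.

## experiment.json (single object)

| field | type | meaning |
|---|---|---|
| `exp_id` | string | unique experiment id |
| `n_p` | integer ≥ 1 | number of phases |
| `n` | integer | number of unique players over all phases (must equal `|players|`) |
| `t_begin`, `t_end` | ISO-8601 UTC string | experiment start / end timestamps (`t_begin ≤ t_end`) |
| `players` | array of unique strings | player ids |
| `player_attributes` | object (optional) | player id → invariant attributes (age, gender, …) |

## phase.json (array, one object per phase)

| field | type | meaning |
|---|---|---|
| `ph_sch_id` | string | unique phase id |
| `exp_id` | string | parent experiment |
| `seq_index` | integer in `1..n_p` | position in the phase sequence |
| `t_ph_begin` | ISO-8601 UTC string | phase start timestamp |
| `t_p` | number > 0 | number of time increments in the phase |
| `u_p` | string | unit of one increment (`"seconds"`, `"days"`, …) |
| `nodes` | array of strings | participating players (⊆ experiment `players`) |
| `edges` | array of 2-element arrays | undirected edges; each pair sorted; may be empty |
| `edge_meanings` | array of strings | e.g. `"communication channel"` |

## phasedesc.json (array, one object per phase)

| field | type | meaning |
|---|---|---|
| `ph_sch_id` | string | phase reference |
| `action_set` | array of strings | permissible actions during the phase |
| `node_attributes`, `edge_attributes` | object (optional) | entity id → list of `(time, attributes)` pairs (time-indexed sequences) |
| `node_initial_conditions`, `edge_initial_conditions` | object (optional) | entity id → initial conditions (e.g. dealt letters, thresholds) |

## player.json (array)

`player_id`, `exp_id`, optional `attributes` object per entry.

## action.json (array, one object per action tuple)

| field | type | meaning |
|---|---|---|
| `sigma` | string | action-sequence id: `initiator + "-" + counter` (ASCII hyphen); a request and its reply share one sigma |
| `action` | string | action name, drawn from the phase's `action_set` |
| `initiator` | string | acting player (a phase node) |
| `target` | string or null | target player, when the action has one |
| `time` | number | phase-relative time in `u_p` units, `0 ≤ time ≤ t_p` (the upper bound is cross-document and enforced by the record validators and the phase-specialized schema) |
| `ph_sch_id` | string | phase reference |
| `payload` | any JSON (optional) | free-form action payload (letter, word, DIFI value, …) |

## Raw event-log dialect (`raw_session_csv`)

CSV columns: `session_id`, `phase_index`, `player_id`, `timestamp_iso`,
`event_type`, `target_player`, `payload_json`. Administrative event types
(`session_start`, `player_join`, `phase_start`, `edge`, `session_end`)
describe the session structure — `phase_start` carries
`{ph_sch_id, t_p, u_p, action_set, ...}` in its payload — and action event
types (`difi_submit`, `request_letter`, `reply_letter`, `form_word`,
`send_message`, `join_forum`, `input_rating`) become action tuples.
Sequence counters travel in payloads; a reply references its request by
`req_initiator`/`req_counter`, which is how shared sigmas are rebuilt.

## Pipeline job configuration (`pipeline_config`)

Object with the five component schema locations (`experiment`,
`phasedesc`, `phase`, `action`, `player`) plus `functions`: the ordered
list of entries `{name, params, inputs: [{datatype, source:
initial|prior}], outputs: [datatype]}`.
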
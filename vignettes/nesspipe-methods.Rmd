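---
title: "Methods: data model, pipeline engine, and behavior models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data model, pipeline engine, and behavior models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nesspipe)
```

nesspipe analyzes *networked social science experiments*: studies in which
human subjects are nodes of a graph, prescribed communication channels are
edges, and everything a subject does is a timestamped, payload-carrying
action. The package has three layers — a validated data model, a
schema-gated pipeline engine, and the analysis/modeling functions that run
inside it — plus synthetic-data generators that emulate two experiment
designs end to end. This vignette explains the science and the design
choices; the README shows the quick-start workflow.

## The data model

An experiment is a sequence of *phases*. The experiment record carries the
roster (`n` unique players, invariant attributes such as age or gender)
and the global timestamps; each phase carries its own network `G(V', E')`
over a subset of the players (possibly with no edges at all — subjects
acting alone), a duration `t_p` in units `u_p`, time-indexed node and edge
attributes, initial conditions, and the permissible action set `A`.

The atom of all analytics is the **action tuple**
`(sigma, action, initiator, target, time, payload)`. The sequence id
`sigma` links causally related actions: when player `v1` requests the
letter "z" from `v3`, the request opens a sequence `"v1-0"` (initiator id,
ASCII hyphen, a player-specific counter), and `v3`'s reply carries the
same `sigma`. Grouping tuples by `sigma` (`link_action_sequences()`) is
what makes request/reply latency and response-rate analyses possible.

On disk the model is five JSON documents (see `SCHEMA.md`), each with a
published JSON Schema. Loading validates every document *before* decoding
and then resolves all cross-references; writing re-checks the invariants
and refuses to emit inconsistent records. One bound is deliberately split:
an action's `time` must lie in `[0, t_p]`, but `t_p` lives in the phase
record, so the generic action schema enforces only `time >= 0` while
`action_schema_for_phase()` stamps a phase's bound into a specialized
schema and the record validators enforce it unconditionally.

Two serialization choices were genuinely open. The time-indexed attribute
sequences (node and edge attributes over time) have no canonical concrete
form; we store them as per-entity lists of `(time, attributes)` pairs.
And sequence-length bookkeeping (how many attributes, how many initial
conditions) is implicit in array lengths, never stored redundantly.

## The pipeline engine

The engine is the invariant part of every pipeline. A *job configuration*
names the component schema locations and an ordered list of functions;
each entry declares its input datatypes (from the initial files or from a
prior entry's outputs), its parameters, and its output datatypes. For
every entry, in order, the engine:

1. locates each input (prior outputs first, then initial files);
2. applies the registered transformation for the `(function, datatype)`
   pair — identity when none is registered — validating the
   transformation's input and its output against their schemas;
3. invokes the function only when every input validated;
4. validates every declared output and stores it for downstream entries.

The first failed validation terminates the run *gracefully*: the affected
function body never executes, the manifest built so far is preserved, and
the diagnostic names the datatype and the first violated constraint. The
manifest therefore records exactly one validation event per boundary
crossing, which the test suite checks as an invariant.

Composition is sequential only — the engine deliberately has no DAG
scheduling, retries, or caching — and `compose_pipelines()` over a split
of a function list is output-for-output identical to one flat run, which
is also tested. Functions are in-process R callables registered by name;
an out-of-process tool is wrapped by an adapter callable, which is the
seam for multi-language function catalogs. Datatype ids must be unique
per run: producing the same datatype twice is an error rather than a
silent overwrite.

The schema evaluator itself is authored in the package (`schema_check()`):
a JSON Schema draft 2020-12 *subset* covering the keywords the shipped
schemas use (type, enum, const, properties/required/additionalProperties,
items, array and numeric bounds, string length and pattern, anyOf). It
reports the first violation with a JSON-path-style location, which is what
the engine's fail-fast contract needs.

## Graph dynamical systems

Contagion-style experiments are modeled as a synchronous **graph
dynamical system**: a graph, a finite node-state space, and one local
function per node that maps the *restricted state* (the node's own state
followed by its neighbors' states — length degree + 1) to the node's next
state. All nodes update in parallel from the pre-step configuration, so
processing order cannot matter; only nodes carry state (edge states are
out of scope).

The built-in local rule is **progressive threshold dynamics**: a node in
state 1 stays 1; a node in state 0 activates when at least `theta` of its
neighbors are active. Although the general formulation counts the closed
neighborhood, the threshold branch only applies when the node's own state
is 0, so counting neighbors alone is equivalent; the implementation counts
neighbors and the tests pin the equivalence. Thresholds must satisfy
`0 <= theta_i <= degree(v_i) + 1`; `theta_i = degree + 1` makes a node
unreachable by contagion. Progressive dynamics are monotone, so a fixed
point is reached in at most `n` steps; `gds_simulate()` stops at the first
repeated configuration and records that time.

`threshold_example()` reconstructs the six-node worked instance used in
the documentation: thresholds `(1, 1, 2, 3, 1, 2)`, only `v1` initially
active. One textual ambiguity had to be resolved: the narrative lists
`v2`'s local function over a three-node neighborhood yet counts `v2` among
`v4`'s neighbors; the reconstruction includes the `{v2, v4}` edge, which
is required for `v4`'s activation at `t = 2`, and every stated dynamical
fact (three active nodes at `t = 1`, `v3` frozen forever, fixed point at
`t = 3`) holds under it. The seed node's own threshold is unobservable
from the dynamics (it starts active and the rule is progressive); it is
fixed at 1.

## Behavior models: transition matrices and the multinomial logit

Phase-level behavior is modeled as a first-order Markov chain on integer
action codes. `discrete_action_sequence()` produces the per-player coded
vectors: the phase is cut into `t_p / resolution` bins (default 1 time
unit), a bin holds the code of the action falling in `(t-1, t]`, empty
bins hold the no-op code 1 ("thinking"), and when several actions share a
bin the *latest* wins while a side table preserves the displaced ones.
The anagram-game coding is thinking = 1, request = 2, reply = 3,
form word = 4 (the no-op and form-word codes are fixed by the design; the
request/reply ordering is this package's convention).

`estimate_transition_matrix()` pools transition counts across sequences
(never across sequence boundaries) and forms
`pi_ij = (c_ij + alpha) / (c_i. + m alpha)`. Defaults: `alpha = 0` for
reporting, so the estimate is the pure MLE and unobserved rows are
honestly `NA` and flagged; `alpha = 1` inside cross-validation, so
held-out transitions unseen in training still have finite log-likelihood.

`fit_behavior_logit()` parameterizes the same rows as a baseline-category
multinomial logit (baseline = thinking), one coefficient block per source
action, fit by maximum likelihood via `nnet::multinom` with tight
convergence tolerances. With no covariates the two routes must agree —
the intercept-only multinomial MLE is exactly the empirical frequency
table — and the suite holds them to within `1e-6`, which doubles as an
independent cross-check of both implementations. Per-step covariates
enter through an extractor function; coefficient recovery from data
simulated under known coefficients (5000 steps, one standard-normal
covariate, agreement within three standard errors) is tested. Degenerate
sources (all transitions to one destination) are reported as boundary
estimates with a diagnostic instead of being forced through the
optimizer.

## The anagram-game ABM

The agent-based model replays the collaborative anagram game: `n` players
on a d-regular communication network, each holding three dealt letters
and a current action state (initially thinking). At each of `duration`
1-unit steps (default 300 — a five-minute game at one-second steps) each
player draws its next action from the transition-matrix row of its
current action. Draws become tuples: a *request* targets a uniform random
neighbor for a uniform random letter under a fresh sigma; a *reply*
serves the oldest pending incoming request under that request's sigma,
and the requester gains the letter; *form word* emits a concatenation of
letters the player holds (word validity is not modeled — the model is
defined at the action-tuple level). A reply drawn with an empty request
queue emits an *unsolicited* reply (fresh sigma, uniform neighbor and
letter, flagged in the payload) rather than nothing: this keeps the tuple
stream a lossless readout of the underlying chain, so the
discrete-sequence → transition-matrix path recovers the generating matrix
up to sampling noise, and the closure test (50 sessions × 300 steps,
maximum entry error ≤ 0.05) stays a test of the inference path rather
than of a censoring artifact. The clocked one-action-per-step reading of
the game (rather than an event-driven one) is this package's choice.

## Model evaluation

`kl_divergence()` uses natural logarithms and symmetric
epsilon-smoothing (`epsilon = 1e-10` added to every cell of both vectors
before renormalization), so comparisons between histograms with empty
bins are finite; `epsilon = 0` gives the raw divergence.
`compare_experiment_model()` applies it per shared statistic and attaches
the paired tables. The matched-seed closure property — a model
regenerated under the generating seed has divergence exactly 0 from its
own data — is what the end-to-end suite asserts. `r_squared()` and
`k_fold_indices()`/`cross_validate()` complete the evaluation layer; the
fold partition is a seeded permutation split with sizes differing by at
most one, and each sequence is scored exactly once as validation data.

## Synthetic data: what it does and does not emulate

Two generators define the package's study conditions.

`generate_anagram_session()` emits a three-phase session in the raw
event-log dialect: phases 1 and 3 are identity measurements (DIFI scores,
the distance between a movable self circle and a group circle, range
`[-100, 125]`) on an *empty* network — one submission per player, drawn
uniformly over the legal range at a uniform random time within a
60-second phase; phase 2 is the ABM above (default `n = 6`, `d = 5`,
i.e. the complete graph, 300 steps). Uniform DIFI draws claim no
behavioral model: the generator exercises the data path, not identity
psychology. The manifest records the true transition matrix, the DIFI
values, and the per-action counts, and the suite checks that the raw-log
transform and the analytics recover them exactly.

`generate_contagion_experiment()` emits the two-arm health-behavior
design directly in the common specification: 98 nodes per arm, degree 6
(294 edges each), 13 daily increments; arm 1 a ring lattice (the
clustered-lattice construction realized as `k/2` nearest neighbors per
side — the design names the topology but not a construction), arm 2 a
random regular graph drawn by the pairing model with rejection of
self-loops and multi-edges. Adoption follows progressive threshold
dynamics with `theta = 2` everywhere and 3 seeds per arm, adjacent on the
lattice: a complex contagion needs at least two reinforcing neighbors,
and a single seed cannot start a `theta = 2` cascade on a ring lattice,
so these are the smallest values under which the lattice arm spreads —
reproducing the qualitative clustered-network advantage — while the
random arm's scattered seeds typically fail to ignite. Messaging is
rule-generated (each adopter messages its not-yet-adopted neighbors daily;
a join is filed under the sigma of the earliest message that reached the
joiner), which is a deliberate simplification of real forum behavior.

What passing tests on these generators shows: the pipelines, schemas,
transforms, and inference paths are internally consistent and recover
known ground truth. What they do not show: anything about real subjects —
real DIFI distributions are not uniform, real players act in bursts
rather than per-second Markov steps, and real adoption is noisier than a
deterministic threshold rule.

## Numerical and scale choices

Timestamps are ISO-8601 UTC with millisecond precision; phase-internal
times are real numbers in `u_p` units from the phase start, rounded to
3 decimals so CSV/JSON round-trips are exact. Histogram bins are
half-open `((b-1)w, bw]`, 1-based, default width 30 time units; an action
at exactly `t = 0` is counted in bin 1 so totals are conserved. The
random-regular sampler retries whole pairings (budget `1e5`; at
`n = 98, k = 6` about one pairing in six thousand is simple, so a draw
costs well under a second). The logit optimizer runs with
`reltol = 1e-14` so the intercept-only equivalence holds at `1e-6`.
Problem sizes in the suite — 50 ABM sessions for matrix recovery, 56 for
the stationary-distribution check, 100 random instances for the GDS
oracle, 1000 random pairs for the divergence property — were chosen so
each property is measured well inside its tolerance while the whole suite
runs in about a minute.

## Scope and limitations

The engine is sequential by design; no provenance graph is kept (the
manifest is a log). Analyst-defined metrics (action distances, ranks,
scores) are a plug-in hook (`score_actions()`), not built-ins. The
conditional-random-field, hierarchical, and multilinear property models,
the DIFI/public-goods regression layers, and model fusion are out of
scope: their specifications live outside this package's sources. Edge
states in the dynamical systems and non-progressive (reversible)
threshold variants are likewise excluded.
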
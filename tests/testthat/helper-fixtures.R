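# Shared fixtures and independent oracles used across the suite.

# A well-mixed irreducible 4-action transition matrix (thinking, request,
# reply, form word) used wherever a "true" behavior model is needed.
fixture_pi <- function() {
  matrix(c(0.50, 0.25, 0.15, 0.10,
           0.30, 0.30, 0.30, 0.10,
           0.40, 0.20, 0.20, 0.20,
           0.45, 0.25, 0.10, 0.20), 4, 4, byrow = TRUE)
}

# Stationary distribution of a row-stochastic matrix by eigen-analysis
# (independent of any package code path).
stationary_eigen <- function(P) {
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v / sum(v)
}

# Brute-force synchronous threshold step: per-node recomputation straight
# from the edge list, no shared code with the simulator.
brute_threshold_step <- function(nodes, edges, theta, config) {
  vapply(nodes, function(v) {
    if (config[[v]] == 1) return(1)
    nbrs <- c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
    if (sum(config[nbrs] == 1) >= theta[[v]]) 1 else 0
  }, numeric(1))
}

# A tiny hand-buildable phase with a known action log.
hand_phase <- function(actions = action_tuples(), t_p = 5,
                       action_set = c("thinking", "request_letter",
                                      "reply_letter", "form_word"),
                       nodes = c("v1", "v2", "v3"),
                       edges = rbind(c("v1", "v2"), c("v2", "v3"))) {
  phase_record(ph_sch_id = "hp1", exp_id = "he1", seq_index = 1,
               t_ph_begin = "2026-03-01T00:00:00Z", t_p = t_p,
               u_p = "seconds", nodes = nodes, edges = edges,
               action_set = action_set, actions = actions)
}

# One cached synthetic session reused by several test files (generation is
# seeded, so this is deterministic).
cached_session <- local({
  ses <- NULL
  function() {
    if (is.null(ses)) {
      ses <<- generate_anagram_session(n = 6, d = 5, true_Pi = fixture_pi(),
                                       duration = 300, seed = 42)
    }
    ses
  }
})
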
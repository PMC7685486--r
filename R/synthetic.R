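# ---------------------------------------------------------------------------
# Synthetic experiment generators.  Every emitted artifact carries a
# ground-truth manifest so downstream pipelines can be checked against the
# quantities that generated the data.
# ---------------------------------------------------------------------------

ISO_WRITE <- "%Y-%m-%dT%H:%M:%OS3Z"

iso_at <- function(t0, offset_secs = 0) {
  format(as.POSIXct(t0, tz = "UTC") + offset_secs, ISO_WRITE, tz = "UTC")
}

#' Generate a synthetic three-phase collective-identity session
#'
#' Emulates a session of the collective-identity experiment in the raw
#' event-log dialect: phases 1 and 3 are identity (DIFI) measurements on an
#' empty network -- one submission per player, drawn uniformly on
#' `[-100, 125]` at a uniform random time -- and phase 2 is the group
#' anagram game on a d-regular network, driven by the Markov-chain ABM with
#' the supplied true transition matrix. The returned manifest records the
#' ground truth (true matrix, DIFI values, per-action counts) that the
#' analytics pipelines should recover from the emitted log.
#'
#' @param n Number of players.
#' @param d Regular degree of the anagram-game network.
#' @param true_Pi Row-stochastic 4 x 4 transition matrix (codes: thinking,
#'   request, reply, form word) driving phase 2.
#' @param duration Phase-2 length in seconds (default 300).
#' @param seed Integer seed (all randomness).
#' @param out_dir Optional directory; when given, writes `raw_log.csv` and
#'   `manifest.json` there.
#' @param session_id Session identifier (becomes the experiment id).
#' @param difi_t_p Duration of each DIFI phase in seconds (default 60).
#' @return A list of class `anagram_session`: `raw` (the event-log data
#'   frame), `manifest` (ground truth), `abm` (the `abm_result` behind
#'   phase 2), and `files` (paths, when written).
#' @export
generate_anagram_session <- function(n, d, true_Pi, duration = 300, seed = 1,
                                     out_dir = NULL, session_id = "session-1",
                                     difi_t_p = 60) {
  set.seed(seed)
  if (inherits(true_Pi, "transition_matrix")) true_Pi <- true_Pi$pi
  stopifnot(nrow(true_Pi) == 4, ncol(true_Pi) == 4)
  t0 <- as.POSIXct("2026-01-05 12:00:00", tz = "UTC")
  gap <- 5
  ph_begin <- c(0, difi_t_p + gap, difi_t_p + gap + duration + gap)
  players <- default_node_ids(n)
  counters <- setNames(integer(n), players)
  rows <- list()
  add <- function(phase, player, t_abs, type, target = NA_character_,
                  payload = NULL) {
    rows[[length(rows) + 1L]] <<- data.frame(
      session_id = session_id, phase_index = phase, player_id = player,
      timestamp_iso = iso_at(t0, t_abs), event_type = type,
      target_player = target,
      payload_json = if (is.null(payload)) NA_character_ else
        as.character(jsonlite::toJSON(payload, auto_unbox = TRUE)),
      stringsAsFactors = FALSE)
  }

  add(0L, "system", 0, "session_start", payload = list(n_p = 3))
  for (p in players) add(0L, p, 0, "player_join")

  # phase 2: run the ABM first (it consumes the RNG stream after the seed)
  abm <- simulate_anagram_abm(
    abm_config(n = n, d = d, Pi = true_Pi, duration = duration, seed = NULL),
    ph_sch_id = paste0(session_id, "-ph2"), exp_id = session_id)

  difi <- list()
  for (phase in c(1L, 3L)) {
    pb <- ph_begin[phase]
    meta <- list(ph_sch_id = sprintf("%s-ph%d", session_id, phase),
                 t_p = difi_t_p, u_p = "seconds",
                 action_set = list("submit_difi"))
    add(phase, "system", pb, "phase_start", payload = meta)
    vals <- round(stats::runif(n, -100, 125), 2)
    times <- round(sort(stats::runif(n, 1, difi_t_p)), 3)
    ord <- sample.int(n)  # who submits when
    for (i in seq_len(n)) {
      p <- players[ord[i]]
      add(phase, p, pb + times[i], "difi_submit",
          payload = list(difi = vals[ord[i]], counter = counters[[p]]))
      counters[[p]] <- counters[[p]] + 1L
    }
    difi[[paste0("phase", phase)]] <- setNames(as.list(vals), players)
  }

  # phase 2 raw events, re-keyed to session-wide per-player counters
  pb2 <- ph_begin[2]
  meta2 <- list(ph_sch_id = paste0(session_id, "-ph2"),
                t_p = duration, u_p = "seconds",
                action_set = list("thinking", "request_letter",
                                  "reply_letter", "form_word"),
                edge_meanings = list("communication channel"),
                node_initial_conditions = abm$phase$node_initial_conditions)
  add(2L, "system", pb2, "phase_start", payload = meta2)
  e <- abm$graph$edges
  for (i in seq_len(nrow(e))) add(2L, e[i, 1], pb2, "edge", target = e[i, 2])
  req_map <- list()  # ABM sigma -> (initiator, session-wide counter)
  acts <- abm$actions
  for (j in seq_len(nrow(acts))) {
    v <- acts$initiator[j]; a <- acts$action[j]; pl <- acts$payload[[j]]
    t_abs <- pb2 + acts$time[j]
    if (a == "request_letter") {
      req_map[[acts$sigma[j]]] <- list(init = v, counter = counters[[v]])
      add(2L, v, t_abs, "request_letter", target = acts$target[j],
          payload = list(letter = pl$letter, counter = counters[[v]]))
      counters[[v]] <- counters[[v]] + 1L
    } else if (a == "reply_letter") {
      ref <- req_map[[acts$sigma[j]]]
      if (!is.null(ref)) {
        add(2L, v, t_abs, "reply_letter", target = acts$target[j],
            payload = list(letter = pl$letter, req_initiator = ref$init,
                           req_counter = ref$counter))
      } else {  # unsolicited reply opens its own sequence
        add(2L, v, t_abs, "reply_letter", target = acts$target[j],
            payload = list(letter = pl$letter, unsolicited = TRUE,
                           counter = counters[[v]]))
        counters[[v]] <- counters[[v]] + 1L
      }
    } else if (a == "form_word") {
      add(2L, v, t_abs, "form_word",
          payload = list(word = pl$word, counter = counters[[v]]))
      counters[[v]] <- counters[[v]] + 1L
    }
  }
  add(0L, "system", ph_begin[3] + difi_t_p + gap, "session_end")

  raw <- do.call(rbind, rows)
  raw <- raw[order(parse_iso8601(raw$timestamp_iso),
                   seq_len(nrow(raw))), , drop = FALSE]
  rownames(raw) <- NULL

  counts2 <- table(factor(acts$action, levels = c("request_letter",
                                                  "reply_letter", "form_word")))
  manifest <- list(
    session_id = session_id, seed = seed,
    params = list(n = n, d = d, duration = duration, difi_t_p = difi_t_p),
    true_pi = apply(unname(true_Pi), 1, as.list),
    difi = difi,
    action_counts = list(
      submit_difi_phase1 = n, submit_difi_phase3 = n,
      request_letter = as.integer(counts2[["request_letter"]]),
      reply_letter = as.integer(counts2[["reply_letter"]]),
      form_word = as.integer(counts2[["form_word"]])),
    n_action_events = 2L * n + nrow(acts))

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    raw_path <- file.path(out_dir, "raw_log.csv")
    man_path <- file.path(out_dir, "manifest.json")
    utils::write.csv(raw, raw_path, row.names = FALSE, na = "")
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(raw = raw_path, manifest = man_path)
  }
  structure(list(raw = raw, manifest = manifest, abm = abm, files = files),
            class = "anagram_session")
}

#' Generate a synthetic two-network contagion experiment
#'
#' Emulates the data-model shape of a two-arm health-behavior contagion
#' experiment: one arm is a 98-node degree-6 clustered (ring) lattice, the
#' other a 98-node degree-6 random regular network, each observed over 13
#' daily time increments. Adoption spreads by progressive threshold
#' dynamics; a node emits a `join_forum` tuple at its adoption time (under
#' the sequence id of the message that triggered it, when one exists) and
#' every adopter sends `send_message` tuples to its not-yet-adopted
#' neighbors at each increment.
#'
#' @param n Total players over both arms (must be even; default 196).
#' @param k Degree in both arms (default 6).
#' @param thetas Adoption threshold(s), recycled per arm (default 2).
#' @param seeds_per_arm Number of initially adopted nodes per arm (default
#'   3; lattice-arm seeds are adjacent on the ring).
#' @param t_p Number of daily increments (default 13).
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, the five common
#'   specification files and `manifest.json` are written there.
#' @return A list of class `contagion_experiment`: `spec` (a
#'   `common_spec`), `manifest` (adoption times, seeds, thresholds), and
#'   `files` (when written).
#' @export
generate_contagion_experiment <- function(n = 196, k = 6, thetas = 2,
                                          seeds_per_arm = 3, t_p = 13,
                                          seed = 1, out_dir = NULL) {
  stopifnot(n %% 2 == 0, seeds_per_arm >= 1)
  set.seed(seed)
  half <- n / 2
  players <- default_node_ids(n)
  arm_nodes <- list(players[1:half], players[(half + 1):n])
  graphs <- list(
    make_ring_lattice(half, k, nodes = arm_nodes[[1]]),
    make_random_regular(half, k, nodes = arm_nodes[[2]]))
  seeds_by_arm <- list(
    arm_nodes[[1]][seq_len(seeds_per_arm)],            # adjacent on the ring
    sample(arm_nodes[[2]], seeds_per_arm))
  t0 <- as.POSIXct("2026-02-02 00:00:00", tz = "UTC")
  exp_id <- "contagion-1"

  phases <- list(); adoption <- list()
  for (arm in 1:2) {
    g <- graphs[[arm]]
    th <- rep_len(thetas, length(g$nodes))
    run <- run_contagion_phase(g, setNames(th, g$nodes),
                               seeds_by_arm[[arm]], t_p)
    at <- run$adoption_times
    adoption[[arm]] <- at
    adj <- adjacency_list(g)
    counters <- setNames(integer(length(g$nodes)), g$nodes)
    msg_to <- list()  # earliest message sigma+sender targeting each node

    sigma <- character(0); act <- character(0); init <- character(0)
    targ <- character(0); tim <- numeric(0)
    emit <- function(sg, a, v, w, t) {
      kk <- length(sigma) + 1L
      sigma[kk] <<- sg; act[kk] <<- a; init[kk] <<- v
      targ[kk] <<- if (is.null(w)) NA_character_ else w; tim[kk] <<- t
    }
    for (t in seq_len(t_p)) {
      adopters <- names(at)[!is.na(at) & at < t]
      for (v in adopters) {
        for (w in adj[[v]]) {
          if (!is.na(at[[w]]) && at[[w]] <= t - 1) next  # already adopted
          sg <- make_sequence_id(v, counters[[v]])
          counters[[v]] <- counters[[v]] + 1L
          emit(sg, "send_message", v, w, t)
          if (is.null(msg_to[[w]])) msg_to[[w]] <- list(sigma = sg, from = v)
        }
      }
      # adoptions at time t join under the sigma of the triggering message
      for (v in names(at)[!is.na(at) & at == t]) {
        ref <- msg_to[[v]]
        if (!is.null(ref)) {
          emit(ref$sigma, "join_forum", v, ref$from, t)
        } else {
          sg <- make_sequence_id(v, counters[[v]])
          counters[[v]] <- counters[[v]] + 1L
          emit(sg, "join_forum", v, NULL, t)
        }
      }
    }
    # seed adoptions at t = 0
    for (v in seeds_by_arm[[arm]]) {
      sg <- make_sequence_id(v, counters[[v]])
      counters[[v]] <- counters[[v]] + 1L
      emit(sg, "join_forum", v, NULL, 0)
    }
    actions <- action_tuples(sigma = sigma, action = act, initiator = init,
                             target = targ, time = tim)
    actions <- actions[order(actions$time), , drop = FALSE]
    rownames(actions) <- NULL

    nic <- setNames(lapply(seq_along(g$nodes), function(i) {
      list(theta = th[i], seed_node = g$nodes[i] %in% seeds_by_arm[[arm]])
    }), g$nodes)
    phases[[arm]] <- phase_record(
      ph_sch_id = sprintf("%s-arm%d", exp_id, arm), exp_id = exp_id,
      seq_index = arm, t_ph_begin = iso_at(t0, (arm - 1) * 3600),
      t_p = t_p, u_p = "days", nodes = g$nodes, edges = g$edges,
      edge_meanings = "communication channel between health buddies",
      node_initial_conditions = nic,
      action_set = c("send_message", "join_forum", "input_rating_content"),
      actions = actions)
  }

  exp <- experiment_record(
    exp_id = exp_id, n_p = 2L, players = players,
    t_begin = iso_at(t0, 0), t_end = iso_at(t0, (t_p + 1) * 86400))
  spec <- structure(list(
    experiment = exp, phases = phases,
    players = data.frame(player_id = players, exp_id = exp_id,
                         stringsAsFactors = FALSE)), class = "common_spec")

  manifest <- list(
    exp_id = exp_id, seed = seed,
    params = list(n = n, k = k, thetas = thetas,
                  seeds_per_arm = seeds_per_arm, t_p = t_p),
    seeds = setNames(seeds_by_arm, c("lattice", "random")),
    n_edges = vapply(graphs, function(g) nrow(g$edges), integer(1)),
    adoption_times = setNames(lapply(adoption, as.list),
                              c("lattice", "random")))
  files <- NULL
  if (!is.null(out_dir)) {
    files <- write_common_spec(spec, out_dir)
    man_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, manifest = man_path)
  }
  structure(list(spec = spec, manifest = manifest, files = files),
            class = "contagion_experiment")
}
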
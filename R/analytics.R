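# ---------------------------------------------------------------------------
# Experimental data transformation (raw event logs -> data common
# specification) and the data-analytics operations on action tuples.
# ---------------------------------------------------------------------------

#' Event vocabulary of the raw session-log dialect
#'
#' The canonical raw CSV dialect has columns `session_id`, `phase_index`,
#' `player_id`, `timestamp_iso`, `event_type`, `target_player`,
#' `payload_json`. Administrative events (`session_start`, `player_join`,
#' `phase_start`, `edge`, `session_end`) describe the experiment structure;
#' action events become action tuples. This constant maps action event
#' types to action names.
#'
#' @format Named character vector: event type -> action name.
#' @export
RAW_ACTION_EVENTS <- c(difi_submit = "submit_difi",
                       request_letter = "request_letter",
                       reply_letter = "reply_letter",
                       form_word = "form_word",
                       send_message = "send_message",
                       join_forum = "join_forum",
                       input_rating = "input_rating_content")

RAW_ADMIN_EVENTS <- c("session_start", "player_join", "phase_start",
                      "edge", "session_end")

time_unit_seconds <- function(u_p) {
  switch(u_p, seconds = 1, minutes = 60, hours = 3600, days = 86400,
         stop(sprintf("unknown time unit '%s'", u_p)))
}

parse_payload <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  jsonlite::fromJSON(x, simplifyVector = FALSE)
}

#' Transform raw experiment logs into the data common specification
#'
#' The entry point of the data-transformation pipeline: reads a raw session
#' event log (canonical CSV dialect), reconstructs the experiment and phase
#' structure from administrative events, turns every action event into
#' exactly one action tuple (request/reply events of one exchange share a
#' sequence id sigma), and returns a validated `common_spec`. Unknown event
#' types abort the transform listing the offending rows.
#'
#' @param raw Path to the raw CSV log, or an equivalent data frame.
#' @param out_dir Optional directory; when given, the five common
#'   specification files are also written there via [write_common_spec()].
#' @param registry Schema registry for validation.
#' @return A `common_spec` object (see [read_common_spec()]).
#' @export
edtp_transform <- function(raw, out_dir = NULL,
                           registry = default_schema_registry()) {
  if (is.character(raw)) {
    raw <- utils::read.csv(raw, colClasses = c(
      session_id = "character", phase_index = "integer",
      player_id = "character", timestamp_iso = "character",
      event_type = "character", target_player = "character",
      payload_json = "character"))
  }
  for (col in c("session_id", "player_id", "timestamp_iso", "event_type",
                "target_player", "payload_json")) {
    raw[[col]] <- as.character(raw[[col]])
  }
  raw$phase_index <- as.integer(raw$phase_index)
  v <- validate_instance(raw, "raw_session_csv", registry)
  if (v$verdict != 1L) stop("raw log fails its schema: ", v$diagnostics)

  known <- c(RAW_ADMIN_EVENTS, names(RAW_ACTION_EVENTS))
  bad <- which(!(raw$event_type %in% known))
  if (length(bad) > 0) {
    stop(sprintf("unknown event type(s) '%s' at row(s) %s",
                 paste(unique(raw$event_type[bad]), collapse = "', '"),
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  ts <- parse_iso8601(raw$timestamp_iso)
  if (anyNA(ts)) stop("unparseable timestamps in the raw log")
  for (p in unique(raw$player_id)) {
    tp <- ts[raw$player_id == p]
    if (is.unsorted(tp)) {
      stop(sprintf("timestamps for player '%s' are not nondecreasing", p))
    }
  }

  session_id <- raw$session_id[1]
  if (!all(raw$session_id == session_id)) {
    stop("a raw log must contain exactly one session")
  }
  joins <- raw[raw$event_type == "player_join", , drop = FALSE]
  players <- unique(joins$player_id)
  starts <- raw[raw$event_type == "phase_start", , drop = FALSE]
  if (nrow(starts) == 0) stop("raw log contains no phase_start events")
  n_p <- nrow(starts)

  phases <- vector("list", n_p)
  for (i in seq_len(n_p)) {
    srow <- starts[i, ]
    meta <- parse_payload(srow$payload_json)
    if (is.null(meta$t_p) || is.null(meta$u_p)) {
      stop(sprintf("phase_start for phase %d lacks t_p/u_p metadata",
                   srow$phase_index))
    }
    ph_id <- if (!is.null(meta$ph_sch_id)) meta$ph_sch_id else
      sprintf("%s-ph%d", session_id, srow$phase_index)
    sel_edges <- raw$event_type == "edge" & raw$phase_index == srow$phase_index
    edges <- if (any(sel_edges)) {
      cbind(raw$player_id[sel_edges], raw$target_player[sel_edges])
    } else NULL

    sel <- raw$phase_index == srow$phase_index &
      raw$event_type %in% names(RAW_ACTION_EVENTS)
    ph_events <- raw[sel, , drop = FALSE]
    unit <- time_unit_seconds(meta$u_p)
    t0 <- parse_iso8601(srow$timestamp_iso)
    if (nrow(ph_events) > 0) {
      payloads <- lapply(ph_events$payload_json, parse_payload)
      times <- round(as.numeric(difftime(ts[sel], t0, units = "secs")) / unit, 3)
      sigma <- character(nrow(ph_events))
      for (j in seq_len(nrow(ph_events))) {
        pl <- payloads[[j]]
        if (ph_events$event_type[j] %in% c("reply_letter", "join_forum") &&
            !is.null(pl$req_initiator)) {
          # a response joins the sequence opened by the request/message
          sigma[j] <- make_sequence_id(pl$req_initiator, pl$req_counter)
        } else {
          if (is.null(pl$counter)) {
            stop(sprintf("action event at row %d lacks a sequence counter",
                         which(sel)[j]))
          }
          sigma[j] <- make_sequence_id(ph_events$player_id[j], pl$counter)
        }
      }
      actions <- action_tuples(
        sigma = sigma,
        action = unname(RAW_ACTION_EVENTS[ph_events$event_type]),
        initiator = ph_events$player_id,
        target = ifelse(is.na(ph_events$target_player) |
                          !nzchar(ph_events$target_player),
                        NA_character_, ph_events$target_player),
        time = times,
        payload = lapply(payloads, function(p) {
          p[setdiff(names(p), c("counter", "req_initiator", "req_counter"))]
        }))
    } else {
      actions <- action_tuples()
    }

    phases[[i]] <- phase_record(
      ph_sch_id = ph_id, exp_id = session_id,
      seq_index = srow$phase_index,
      t_ph_begin = srow$timestamp_iso,
      t_p = as.numeric(meta$t_p), u_p = meta$u_p,
      nodes = players, edges = edges,
      edge_meanings = if (!is.null(meta$edge_meanings))
        unlist(meta$edge_meanings) else character(0),
      node_initial_conditions = meta$node_initial_conditions,
      action_set = unlist(meta$action_set),
      actions = actions)
  }

  exp <- experiment_record(
    exp_id = session_id, n_p = n_p, players = players,
    t_begin = raw$timestamp_iso[which.min(ts)],
    t_end = raw$timestamp_iso[which.max(ts)])
  for (ph in phases) validate_phase_record(ph, exp)
  structure(list(experiment = exp, phases = phases,
                 players = data.frame(player_id = players, exp_id = session_id,
                                      stringsAsFactors = FALSE)),
            class = "common_spec")
}

phase_action_times <- function(phase, action) {
  if (!(action %in% phase$action_set)) {
    stop(sprintf("action '%s' is not in the phase action set", action))
  }
  phase$actions[phase$actions$action == action, , drop = FALSE]
}

#' Cumulative action progression per player
#'
#' For one action, builds each player's nondecreasing step series of
#' cumulative counts over phase time. Players with no such actions get a
#' constant-zero series (the single anchor row at time 0).
#'
#' @param phase A [phase_record()].
#' @param action Action name (must be in the phase action set).
#' @return Data frame with columns `player`, `time`, `count`: one row at
#'   time 0 per player, then one row per action occurrence.
#' @export
action_progression <- function(phase, action) {
  acts <- phase_action_times(phase, action)
  out <- lapply(phase$nodes, function(v) {
    tv <- sort(acts$time[acts$initiator == v])
    data.frame(player = v, time = c(0, tv),
               count = c(0, seq_along(tv)), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Histogram of action times
#'
#' Counts occurrences of one action in half-open time bins
#' `((b-1)*w, b*w]`, 1-based, covering `(0, t_p]` (an action at exactly
#' time 0 is counted in bin 1). Bin counts sum to the action's total.
#'
#' @param phase A [phase_record()].
#' @param action Action name.
#' @param bin_width Bin width in phase time units (default 30).
#' @return Data frame with columns `bin`, `t_lo`, `t_hi`, `count`.
#' @export
action_histogram <- function(phase, action, bin_width = 30) {
  stopifnot(bin_width > 0)
  acts <- phase_action_times(phase, action)
  n_bins <- ceiling(phase$t_p / bin_width)
  counts <- integer(n_bins)
  if (nrow(acts) > 0) {
    b <- pmax(1L, ceiling(acts$time / bin_width))
    tab <- table(factor(b, levels = seq_len(n_bins)))
    counts <- as.integer(tab)
  }
  data.frame(bin = seq_len(n_bins),
             t_lo = (seq_len(n_bins) - 1) * bin_width,
             t_hi = pmin(seq_len(n_bins) * bin_width, phase$t_p),
             count = counts)
}

#' Time deltas between related actions
#'
#' For every action sequence (sigma group) that contains the initiating
#' action, computes the delay until the responding action of the same
#' sequence (`delta = t_response - t_initiate`, always >= 0 because groups
#' are time-ordered). Sequences with an initiating action but no response
#' are reported as unanswered.
#'
#' @param phase A [phase_record()].
#' @param initiating,responding Action names (e.g. a letter request and the
#'   letter reply).
#' @return A list: `deltas` (data frame `sigma`, `t_initiate`, `t_respond`,
#'   `delta`) and `unanswered` (character vector of sigmas).
#' @export
related_action_deltas <- function(phase, initiating, responding) {
  stopifnot(initiating %in% phase$action_set,
            responding %in% phase$action_set)
  groups <- link_action_sequences(phase$actions)
  deltas <- list(); unanswered <- character(0)
  for (sg in names(groups)) {
    g <- groups[[sg]]
    ti <- g$time[g$action == initiating]
    if (length(ti) == 0) next
    tr <- g$time[g$action == responding & g$time >= ti[1]]
    if (length(tr) == 0) {
      unanswered <- c(unanswered, sg)
    } else {
      deltas[[length(deltas) + 1L]] <- data.frame(
        sigma = sg, t_initiate = ti[1], t_respond = tr[1],
        delta = tr[1] - ti[1], stringsAsFactors = FALSE)
    }
  }
  deltas <- if (length(deltas)) do.call(rbind, deltas) else
    data.frame(sigma = character(0), t_initiate = numeric(0),
               t_respond = numeric(0), delta = numeric(0))
  rownames(deltas) <- NULL
  list(deltas = deltas, unanswered = unanswered)
}

#' Default integer coding of a phase's action set
#'
#' The no-op action takes code 1; the remaining actions are coded 2, 3, ...
#' in action-set order. For the anagram game this gives thinking = 1,
#' request = 2, reply = 3, form word = 4.
#'
#' @param action_set Character vector of action names.
#' @param noop Name of the no-op action (default `"thinking"`); prepended
#'   if absent from the set.
#' @return Named integer vector: action name -> code.
#' @export
action_code_map <- function(action_set, noop = "thinking") {
  others <- setdiff(action_set, noop)
  setNames(seq_len(length(others) + 1L), c(noop, others))
}

#' Discrete-time action sequences per player
#'
#' Partitions the phase into `t_p / resolution` whole bins and assigns each
#' player one integer action code per bin: the code of the action whose
#' time falls in `(t-1, t]` (at unit resolution), the no-op code for empty
#' bins, and -- when several actions share a bin -- the code of the latest
#' action in the bin, with all displaced actions preserved in a collision
#' table.
#'
#' @param phase A [phase_record()].
#' @param resolution Bin width in phase time units (default 1); `t_p` must
#'   divide into whole bins.
#' @param code_map Named integer action coding (default
#'   [action_code_map()] of the phase action set).
#' @param noop No-op action name used for empty bins.
#' @return A list of class `discrete_sequences`: `sequences` (integer
#'   matrix, players x bins), `code_map`, `t_p`, `resolution`, and
#'   `collisions` (data frame of displaced actions).
#' @export
discrete_action_sequence <- function(phase, resolution = 1,
                                     code_map = NULL, noop = "thinking") {
  n_bins <- phase$t_p / resolution
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("t_p must divide into whole bins at the given resolution")
  }
  n_bins <- as.integer(round(n_bins))
  if (is.null(code_map)) code_map <- action_code_map(phase$action_set, noop)
  acts <- phase$actions
  if (nrow(acts) > 0 && !all(acts$action %in% names(code_map))) {
    bad <- setdiff(unique(acts$action), names(code_map))
    stop(sprintf("no code for action '%s'", bad[1]))
  }
  seqs <- matrix(code_map[[noop]], nrow = length(phase$nodes), ncol = n_bins,
                 dimnames = list(phase$nodes, NULL))
  collisions <- list()
  if (nrow(acts) > 0) {
    bin <- pmax(1L, as.integer(ceiling(acts$time / resolution)))
    ord <- order(acts$time)  # later actions overwrite earlier ones
    for (j in ord) {
      v <- acts$initiator[j]
      prev <- seqs[v, bin[j]]
      if (prev != code_map[[noop]]) {
        collisions[[length(collisions) + 1L]] <- data.frame(
          player = v, bin = bin[j], displaced_code = prev,
          stringsAsFactors = FALSE)
      }
      seqs[v, bin[j]] <- code_map[[acts$action[j]]]
    }
  }
  collisions <- if (length(collisions)) do.call(rbind, collisions) else
    data.frame(player = character(0), bin = integer(0),
               displaced_code = integer(0))
  structure(list(sequences = seqs, code_map = code_map,
                 t_p = phase$t_p, resolution = resolution,
                 collisions = collisions),
            class = "discrete_sequences")
}

#' Per-action occurrence counts by phase and overall
#'
#' Counts every action's occurrences at the end of each phase, plus the
#' totals over all phases (rows with `phase = "all"`). Actions in a
#' phase's action set that never occurred appear with count 0.
#'
#' @param spec A `common_spec`, or a list of [phase_record()]s.
#' @return Data frame with columns `phase` (ph_sch_id or `"all"`),
#'   `action`, `count`.
#' @export
action_summary <- function(spec) {
  phases <- if (inherits(spec, "common_spec")) spec$phases else spec
  rows <- list()
  for (ph in phases) {
    for (a in ph$action_set) {
      rows[[length(rows) + 1L]] <- data.frame(
        phase = ph$ph_sch_id, action = a,
        count = sum(ph$actions$action == a), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(phase = character(0), action = character(0),
                      count = integer(0)))
  }
  df <- do.call(rbind, rows)
  tot <- stats::aggregate(count ~ action, data = df, FUN = sum)
  tot <- data.frame(phase = "all", action = tot$action, count = tot$count,
                    stringsAsFactors = FALSE)
  out <- rbind(df, tot)
  rownames(out) <- NULL
  out
}

#' Mean windowed action counts across experiments
#'
#' Bins one action's occurrences into windows of size `s` for each supplied
#' phase (all phases must share `t_p`) and averages the per-window totals
#' across them.
#'
#' @param phases List of [phase_record()]s (e.g. the same phase of several
#'   experiment runs).
#' @param action Action name.
#' @param s Window size in phase time units (> 0).
#' @return Data frame with columns `window`, `t_lo`, `t_hi`, `mean_count`.
#' @export
windowed_average <- function(phases, action, s) {
  stopifnot(s > 0, length(phases) >= 1)
  tps <- vapply(phases, `[[`, numeric(1), "t_p")
  if (length(unique(tps)) != 1) {
    stop("all phases must share the same duration t_p")
  }
  hists <- lapply(phases, action_histogram, action = action, bin_width = s)
  counts <- do.call(cbind, lapply(hists, `[[`, "count"))
  h1 <- hists[[1]]
  data.frame(window = h1$bin, t_lo = h1$t_lo, t_hi = h1$t_hi,
             mean_count = rowMeans(counts))
}

#' Possible versus occurred neighbor-pair interactions
#'
#' For each action, the number of possible directed neighbor interactions
#' (`2 * |E|` ordered pairs for interactive actions, 0 otherwise) against
#' the number of distinct `(initiator, target)` pairs that actually
#' occurred.
#'
#' @param phase A [phase_record()].
#' @param interactive_actions Actions counted as interactive; defaults to
#'   the actions observed with a non-missing target.
#' @return Data frame with columns `action`, `possible`, `occurred`.
#' @export
related_action_summary <- function(phase, interactive_actions = NULL) {
  acts <- phase$actions
  if (is.null(interactive_actions)) {
    interactive_actions <- unique(acts$action[!is.na(acts$target)])
  }
  rows <- lapply(phase$action_set, function(a) {
    sel <- acts$action == a & !is.na(acts$target)
    occurred <- if (any(sel)) {
      nrow(unique(acts[sel, c("initiator", "target")]))
    } else 0L
    possible <- if (a %in% interactive_actions) 2L * nrow(phase$edges) else 0L
    data.frame(action = a, possible = possible, occurred = occurred,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' Apply an analyst-supplied scoring metric to action tuples
#'
#' The plug-in hook for custom action metrics (distances, ranks, scores):
#' the analyst supplies the callable; the package supplies the iteration
#' and the output table.
#'
#' @param phase A [phase_record()].
#' @param action Action name to score.
#' @param scorer A function `(payload, row)` returning one numeric score;
#'   `row` is the one-row action-tuple data frame.
#' @return Data frame with columns `sigma`, `initiator`, `time`, `score`.
#' @export
score_actions <- function(phase, action, scorer) {
  acts <- phase_action_times(phase, action)
  score <- vapply(seq_len(nrow(acts)), function(i) {
    as.numeric(scorer(acts$payload[[i]], acts[i, , drop = FALSE]))
  }, numeric(1))
  data.frame(sigma = acts$sigma, initiator = acts$initiator,
             time = acts$time, score = score, stringsAsFactors = FALSE)
}
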
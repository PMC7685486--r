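# ---------------------------------------------------------------------------
# Data common specification: in-memory records, invariants, readers/writers.
#
# An experiment is stored on disk as five JSON documents (experiment, phase,
# phasedesc, player, action), each gated by a schema from
# default_schema_registry().  In memory the same information lives in an
# `experiment_record`, a list of `phase_record`s (actions attached as a
# data frame), and a player table; together a `common_spec` object.
# ---------------------------------------------------------------------------

ISO_FMT <- "%Y-%m-%dT%H:%M:%OSZ"       # parsing (fraction optional)
ISO_FMT_OUT <- "%Y-%m-%dT%H:%M:%OS3Z"  # writing (millisecond precision)

#' Format / parse ISO-8601 UTC timestamps
#'
#' All experiment-level timestamps are ISO-8601 in UTC; phase-internal
#' action times are real numbers in the phase's time unit, measured from the
#' phase begin timestamp.
#'
#' @param t A `POSIXct` (for `format_iso8601`) or character (for
#'   `parse_iso8601`).
#' @return A character vector / `POSIXct` vector.
#' @export
format_iso8601 <- function(t) {
  format(as.POSIXct(t, tz = "UTC"), ISO_FMT_OUT, tz = "UTC")
}

#' @rdname format_iso8601
#' @export
parse_iso8601 <- function(t) {
  as.POSIXct(t, format = ISO_FMT, tz = "UTC")
}

#' Build an action-sequence identifier
#'
#' Related actions (e.g. a letter request and its reply) are linked by a
#' shared sequence id sigma, formed by concatenating the initiator's id, an
#' ASCII hyphen, and a player-specific counter. Distinct (initiator,
#' counter) pairs yield distinct ids. Vectorized.
#'
#' @param initiator Player id(s).
#' @param counter Non-negative integer counter(s).
#' @return Character vector of sequence ids, e.g. `"v1-0"`.
#' @export
make_sequence_id <- function(initiator, counter) {
  stopifnot(is.character(initiator), length(initiator) >= 1)
  counter <- as.integer(counter)
  if (anyNA(counter) || any(counter < 0)) {
    stop("sequence counter must be a non-negative integer")
  }
  paste0(initiator, "-", counter)
}

#' Construct a table of action tuples
#'
#' One row per action: the sequence id `sigma`, the action name, the
#' initiating player, the (possibly missing) target player, the
#' phase-relative time, and a free-form payload (list column).
#'
#' @param sigma,action,initiator Character vectors (recycled to a common
#'   length).
#' @param target Character vector; `NA` for actions without a target.
#' @param time Numeric vector of phase-relative times.
#' @param payload A list of payload documents (or `NULL` for none).
#' @return A data frame of class `action_tuples`.
#' @export
action_tuples <- function(sigma = character(0), action = character(0),
                          initiator = character(0), target = NA_character_,
                          time = numeric(0), payload = NULL) {
  n <- max(length(sigma), length(action), length(initiator), length(time))
  if (n == 0) {
    df <- data.frame(sigma = character(0), action = character(0),
                     initiator = character(0), target = character(0),
                     time = numeric(0), stringsAsFactors = FALSE)
    df$payload <- list()
  } else {
    df <- data.frame(sigma = rep_len(as.character(sigma), n),
                     action = rep_len(as.character(action), n),
                     initiator = rep_len(as.character(initiator), n),
                     target = rep_len(as.character(target), n),
                     time = rep_len(as.numeric(time), n),
                     stringsAsFactors = FALSE)
    df$payload <- if (is.null(payload)) rep(list(NULL), n) else rep_len(payload, n)
  }
  class(df) <- c("action_tuples", class(df))
  df
}

#' Construct an experiment record
#'
#' @param exp_id Experiment id.
#' @param n_p Number of phases (>= 1).
#' @param players Character vector of unique player ids.
#' @param t_begin,t_end ISO-8601 UTC timestamps (strings or `POSIXct`).
#' @param player_attributes Optional named list: player id -> named
#'   attribute list (invariant across phases, e.g. age, gender).
#' @return An object of class `experiment_record`.
#' @export
experiment_record <- function(exp_id, n_p, players, t_begin, t_end,
                              player_attributes = NULL) {
  rec <- structure(list(
    exp_id = as.character(exp_id),
    n_p = as.integer(n_p),
    n = length(players),
    t_begin = if (is.character(t_begin)) t_begin else format_iso8601(t_begin),
    t_end = if (is.character(t_end)) t_end else format_iso8601(t_end),
    players = as.character(players),
    player_attributes = player_attributes
  ), class = "experiment_record")
  validate_experiment_record(rec)
  rec
}

#' Validate an experiment record's invariants
#'
#' Checks `n == |players|`, unique player ids, `t_begin <= t_end` and
#' `n_p >= 1`; stops on the first violation.
#'
#' @param rec An `experiment_record`.
#' @return Invisibly `TRUE`.
#' @export
validate_experiment_record <- function(rec) {
  stopifnot(inherits(rec, "experiment_record"))
  if (rec$n != length(rec$players)) {
    stop("experiment invariant violated: n must equal the number of players")
  }
  if (anyDuplicated(rec$players)) {
    stop("experiment invariant violated: player ids must be unique")
  }
  if (rec$n_p < 1) stop("experiment invariant violated: n_p must be >= 1")
  tb <- parse_iso8601(rec$t_begin); te <- parse_iso8601(rec$t_end)
  if (is.na(tb) || is.na(te)) {
    stop("experiment timestamps must be ISO-8601 UTC")
  }
  if (tb > te) stop("experiment invariant violated: t_begin must be <= t_end")
  invisible(TRUE)
}

#' Construct a phase record
#'
#' A phase carries the network imposed on the players during that phase
#' (possibly empty), time-indexed node/edge attributes, initial conditions,
#' the permissible action set, and the recorded action tuples.
#'
#' @param ph_sch_id Phase schema id.
#' @param exp_id Parent experiment id.
#' @param seq_index Position of the phase in the experiment (1-based).
#' @param t_ph_begin ISO-8601 UTC timestamp of the phase start.
#' @param t_p Number of time increments in the phase (> 0).
#' @param u_p Time-unit label of one increment (e.g. "seconds", "days").
#' @param nodes Character vector of participating player ids.
#' @param edges Two-column character matrix of undirected edges (stored
#'   canonically with each row sorted), or a list of 2-element vectors.
#' @param edge_meanings Character vector of edge-meaning strings.
#' @param node_attributes,edge_attributes Named lists: entity ->
#'   list of `(time, attributes)` pairs (time-indexed sequences).
#' @param node_initial_conditions,edge_initial_conditions Named lists of
#'   initial conditions.
#' @param action_set Character vector of permissible action names.
#' @param actions An [action_tuples()] data frame.
#' @return An object of class `phase_record`.
#' @export
phase_record <- function(ph_sch_id, exp_id, seq_index, t_ph_begin, t_p, u_p,
                         nodes, edges = NULL, edge_meanings = character(0),
                         node_attributes = NULL, edge_attributes = NULL,
                         node_initial_conditions = NULL,
                         edge_initial_conditions = NULL,
                         action_set = character(0),
                         actions = action_tuples()) {
  edges <- canonical_edges(edges)
  rec <- structure(list(
    ph_sch_id = as.character(ph_sch_id),
    exp_id = as.character(exp_id),
    seq_index = as.integer(seq_index),
    t_ph_begin = if (is.character(t_ph_begin)) t_ph_begin else format_iso8601(t_ph_begin),
    t_p = as.numeric(t_p),
    u_p = as.character(u_p),
    nodes = as.character(nodes),
    edges = edges,
    edge_meanings = as.character(edge_meanings),
    node_attributes = node_attributes,
    edge_attributes = edge_attributes,
    node_initial_conditions = node_initial_conditions,
    edge_initial_conditions = edge_initial_conditions,
    action_set = as.character(action_set),
    actions = actions
  ), class = "phase_record")
  validate_phase_record(rec)
  rec
}

#' Canonicalize an undirected edge set
#'
#' Edges are stored as a two-column character matrix with each row sorted
#' (undirected, canonical); duplicate edges and self-loops are rejected.
#'
#' @param edges `NULL`, a two-column matrix, or a list of 2-element vectors.
#' @return A two-column character matrix.
#' @export
canonical_edges <- function(edges) {
  if (is.null(edges) || (is.list(edges) && length(edges) == 0)) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("a", "b"))))
  }
  if (is.list(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) as.character(unlist(e))))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have exactly two endpoints")
  storage.mode(edges) <- "character"
  if (any(edges[, 1] == edges[, 2])) stop("self-loop edges are not allowed")
  edges <- t(apply(edges, 1, sort))
  if (nrow(edges) > 0 && anyDuplicated(paste(edges[, 1], edges[, 2]))) {
    stop("duplicate edges are not allowed")
  }
  colnames(edges) <- c("a", "b")
  edges
}

#' Validate a phase record's invariants
#'
#' Checks `seq_index >= 1`, that every edge endpoint lies in `nodes`, every
#' action name is drawn from `action_set`, every action time lies in
#' `[0, t_p]`, and that initiators/targets are phase nodes.
#'
#' @param rec A `phase_record`.
#' @param experiment Optional parent `experiment_record`; when supplied,
#'   also checks `seq_index <= n_p` and `nodes` being registered players.
#' @return Invisibly `TRUE`.
#' @export
validate_phase_record <- function(rec, experiment = NULL) {
  stopifnot(inherits(rec, "phase_record"))
  if (rec$seq_index < 1) stop("phase invariant violated: seq_index must be >= 1")
  if (anyDuplicated(rec$nodes)) stop("phase nodes must be unique")
  if (nrow(rec$edges) > 0 && !all(c(rec$edges) %in% rec$nodes)) {
    bad <- setdiff(c(rec$edges), rec$nodes)
    stop(sprintf("phase invariant violated: edge endpoint '%s' is not a phase node",
                 bad[1]))
  }
  acts <- rec$actions
  if (nrow(acts) > 0) {
    if (!all(acts$action %in% rec$action_set)) {
      bad <- setdiff(unique(acts$action), rec$action_set)
      stop(sprintf("phase invariant violated: action '%s' not in action set",
                   bad[1]))
    }
    if (any(acts$time < 0 | acts$time > rec$t_p)) {
      stop("phase invariant violated: action times must lie in [0, t_p]")
    }
    if (!all(acts$initiator %in% rec$nodes)) {
      bad <- setdiff(unique(acts$initiator), rec$nodes)
      stop(sprintf("phase invariant violated: initiator '%s' is not a phase node",
                   bad[1]))
    }
    tg <- acts$target[!is.na(acts$target)]
    if (!all(tg %in% rec$nodes)) {
      bad <- setdiff(unique(tg), rec$nodes)
      stop(sprintf("phase invariant violated: target '%s' is not a phase node",
                   bad[1]))
    }
  }
  if (!is.null(experiment)) {
    if (rec$seq_index > experiment$n_p) {
      stop("phase invariant violated: seq_index exceeds the experiment's n_p")
    }
    if (!all(rec$nodes %in% experiment$players)) {
      bad <- setdiff(rec$nodes, experiment$players)
      stop(sprintf("cross-reference error: phase node '%s' is not a registered player",
                   bad[1]))
    }
  }
  invisible(TRUE)
}

#' Group action tuples into sequences by sigma
#'
#' Partitions the tuples into groups keyed by sequence id, each group
#' ordered by nondecreasing time. A request and the reply it triggered
#' share one sigma and therefore one group.
#'
#' @param actions An [action_tuples()] data frame.
#' @return A named list of action-tuple data frames (one per sigma), in
#'   order of each sigma's first appearance.
#' @export
link_action_sequences <- function(actions) {
  if (nrow(actions) == 0) return(structure(list(), names = character(0)))
  groups <- split(seq_len(nrow(actions)), factor(actions$sigma,
                                                 levels = unique(actions$sigma)))
  lapply(groups, function(idx) {
    g <- actions[idx[order(actions$time[idx])], , drop = FALSE]
    rownames(g) <- NULL
    g
  })
}

# ---- serialization --------------------------------------------------------

common_spec_paths <- function(dir) {
  comps <- c("experiment", "phase", "phasedesc", "player", "action")
  setNames(file.path(dir, paste0(comps, ".json")), comps)
}

actions_to_instance <- function(phases) {
  out <- list()
  for (ph in phases) {
    a <- ph$actions
    if (nrow(a) == 0) next
    for (i in seq_len(nrow(a))) {
      out[[length(out) + 1L]] <- list(
        sigma = a$sigma[i], action = a$action[i], initiator = a$initiator[i],
        target = if (is.na(a$target[i])) NULL else a$target[i],
        time = a$time[i], ph_sch_id = ph$ph_sch_id,
        payload = a$payload[[i]])
    }
  }
  out
}

phase_to_instance <- function(ph) {
  list(ph_sch_id = ph$ph_sch_id, exp_id = ph$exp_id,
       seq_index = ph$seq_index, t_ph_begin = ph$t_ph_begin,
       t_p = ph$t_p, u_p = ph$u_p,
       nodes = as.list(ph$nodes),
       edges = if (nrow(ph$edges) == 0) list() else
         lapply(seq_len(nrow(ph$edges)), function(i)
           list(ph$edges[[i, 1]], ph$edges[[i, 2]])),
       edge_meanings = as.list(ph$edge_meanings))
}

phasedesc_to_instance <- function(ph) {
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  drop_null(list(ph_sch_id = ph$ph_sch_id,
                 action_set = as.list(ph$action_set),
                 node_attributes = ph$node_attributes,
                 edge_attributes = ph$edge_attributes,
                 node_initial_conditions = ph$node_initial_conditions,
                 edge_initial_conditions = ph$edge_initial_conditions))
}

#' Serialize a common specification into its five component documents
#'
#' Validates the record invariants and returns the decoded JSON documents
#' (`experiment`, `phase`, `phasedesc`, `player`, `action`) without
#' touching disk; [write_common_spec()] and the pipeline transformation
#' layer share this.
#'
#' @param spec A `common_spec` (or list with `experiment`, `phases`,
#'   optionally `players`).
#' @return Named list of the five component instances.
#' @export
common_spec_to_docs <- function(spec) {
  validate_experiment_record(spec$experiment)
  for (ph in spec$phases) validate_phase_record(ph, spec$experiment)
  seqs <- vapply(spec$phases, function(p) p$seq_index, integer(1))
  if (!identical(sort(seqs), seq_along(spec$phases))) {
    stop("phase seq_index values must be 1..n_p with no gaps")
  }
  exp <- spec$experiment
  exp_inst <- list(exp_id = exp$exp_id, n_p = exp$n_p, n = exp$n,
                   t_begin = exp$t_begin, t_end = exp$t_end,
                   players = as.list(exp$players))
  if (!is.null(exp$player_attributes)) {
    exp_inst$player_attributes <- exp$player_attributes
  }
  players <- spec$players
  if (is.null(players)) {
    players <- data.frame(player_id = exp$players, exp_id = exp$exp_id,
                          stringsAsFactors = FALSE)
  }
  player_inst <- lapply(seq_len(nrow(players)), function(i) {
    rec <- list(player_id = players$player_id[i], exp_id = players$exp_id[i])
    if (!is.null(players$attributes) && !is.null(players$attributes[[i]])) {
      rec$attributes <- players$attributes[[i]]
    }
    rec
  })
  list(experiment = exp_inst,
       phase = lapply(spec$phases, phase_to_instance),
       phasedesc = lapply(spec$phases, phasedesc_to_instance),
       player = player_inst,
       action = actions_to_instance(spec$phases))
}

#' Write a data common specification to disk
#'
#' Emits the five JSON documents (`experiment.json`, `phase.json`,
#' `phasedesc.json`, `player.json`, `action.json`) into `dir`. Record
#' invariants are re-checked first and the emitted files are re-validated
#' against their schemas; on any violation nothing usable is left behind
#' and the call errors.
#'
#' @param spec A `common_spec` object (see [read_common_spec()]), or a list
#'   with elements `experiment` (an [experiment_record()]), `phases` (list
#'   of [phase_record()]s) and optionally `players` (data frame with
#'   `player_id`, `exp_id`).
#' @param dir Output directory (created if needed).
#' @param registry Schema registry used for post-write validation.
#' @return Invisibly, the named vector of the five file paths.
#' @export
write_common_spec <- function(spec, dir,
                              registry = default_schema_registry()) {
  docs <- common_spec_to_docs(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- common_spec_paths(dir)
  for (comp in names(docs)) {
    v <- validate_instance(docs[[comp]], comp, registry)
    if (v$verdict != 1L) {
      stop(sprintf("refusing to write '%s': %s", comp, v$diagnostics))
    }
    jsonlite::write_json(docs[[comp]], paths[[comp]], auto_unbox = TRUE,
                         null = "null", na = "null", digits = NA,
                         pretty = TRUE)
  }
  invisible(paths)
}

null_chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)

#' Read and validate a data common specification
#'
#' Loads the five JSON documents, validating each against its schema
#' *before* decoding, then resolves all cross-references (players <-> phase
#' nodes <-> action initiators/targets, action names against the action
#' set, action times against `[0, t_p]`). Any failure aborts the load with
#' the offending file and a diagnostic.
#'
#' @param paths Either a directory containing the five standard file names,
#'   or a named character vector/list with entries `experiment`, `phase`,
#'   `phasedesc`, `player`, `action`.
#' @param registry Schema registry for the component schemas.
#' @return An object of class `common_spec`: a list with `experiment`
#'   (an [experiment_record()]), `phases` (list of [phase_record()]s,
#'   actions attached, ordered by `seq_index`) and `players` (data frame).
#' @export
read_common_spec <- function(paths, registry = default_schema_registry()) {
  if (length(paths) == 1 && is.character(paths) && dir.exists(paths)) {
    paths <- common_spec_paths(paths)
  }
  paths <- as.list(paths)
  need <- c("experiment", "phase", "phasedesc", "player", "action")
  if (!all(need %in% names(paths))) {
    stop("paths must name the five components: ", paste(need, collapse = ", "))
  }
  docs <- list()
  for (comp in need) {
    p <- paths[[comp]]
    if (!file.exists(p)) stop(sprintf("missing input file '%s' (%s)", p, comp))
    doc <- jsonlite::read_json(p)
    v <- validate_instance(doc, comp, registry, canonicalize = FALSE)
    if (v$verdict != 1L) {
      stop(sprintf("validation failed for '%s' (%s): %s", p, comp, v$diagnostics))
    }
    docs[[comp]] <- doc
  }

  e <- docs$experiment
  exp <- structure(list(
    exp_id = e$exp_id, n_p = as.integer(e$n_p), n = as.integer(e$n),
    t_begin = e$t_begin, t_end = e$t_end,
    players = vapply(e$players, as.character, character(1)),
    player_attributes = e$player_attributes
  ), class = "experiment_record")
  validate_experiment_record(exp)

  desc_by_id <- setNames(docs$phasedesc,
                         vapply(docs$phasedesc, `[[`, character(1), "ph_sch_id"))
  acts_by_phase <- split(docs$action,
                         vapply(docs$action, `[[`, character(1), "ph_sch_id"))

  phases <- lapply(docs$phase, function(p) {
    dsc <- desc_by_id[[p$ph_sch_id]]
    if (is.null(dsc)) {
      stop(sprintf("cross-reference error: no phase description for phase '%s'",
                   p$ph_sch_id))
    }
    pa <- acts_by_phase[[p$ph_sch_id]]
    actions <- if (is.null(pa) || length(pa) == 0) action_tuples() else {
      df <- action_tuples(
        sigma = vapply(pa, `[[`, character(1), "sigma"),
        action = vapply(pa, `[[`, character(1), "action"),
        initiator = vapply(pa, `[[`, character(1), "initiator"),
        target = vapply(pa, function(a) null_chr(a$target), character(1)),
        time = vapply(pa, function(a) as.numeric(a$time), numeric(1)),
        payload = lapply(pa, function(a) a$payload))
      df
    }
    rec <- structure(list(
      ph_sch_id = p$ph_sch_id, exp_id = p$exp_id,
      seq_index = as.integer(p$seq_index), t_ph_begin = p$t_ph_begin,
      t_p = as.numeric(p$t_p), u_p = p$u_p,
      nodes = if (length(p$nodes)) vapply(p$nodes, as.character, character(1)) else character(0),
      edges = canonical_edges(p$edges),
      edge_meanings = if (length(p$edge_meanings))
        vapply(p$edge_meanings, as.character, character(1)) else character(0),
      node_attributes = dsc$node_attributes,
      edge_attributes = dsc$edge_attributes,
      node_initial_conditions = dsc$node_initial_conditions,
      edge_initial_conditions = dsc$edge_initial_conditions,
      action_set = if (length(dsc$action_set))
        vapply(dsc$action_set, as.character, character(1)) else character(0),
      actions = actions
    ), class = "phase_record")
    validate_phase_record(rec, exp)
    rec
  })
  phases <- phases[order(vapply(phases, `[[`, integer(1), "seq_index"))]

  known <- vapply(docs$phase, `[[`, character(1), "ph_sch_id")
  orphan <- setdiff(names(acts_by_phase), known)
  if (length(orphan) > 0) {
    stop(sprintf("cross-reference error: actions reference unknown phase '%s'",
                 orphan[1]))
  }

  players <- data.frame(
    player_id = vapply(docs$player, `[[`, character(1), "player_id"),
    exp_id = vapply(docs$player, `[[`, character(1), "exp_id"),
    stringsAsFactors = FALSE)
  players$attributes <- lapply(docs$player, function(p) p$attributes)
  if (!all(players$player_id %in% exp$players)) {
    bad <- setdiff(players$player_id, exp$players)
    stop(sprintf("cross-reference error: player file lists unknown player '%s'",
                 bad[1]))
  }

  structure(list(experiment = exp, phases = phases, players = players),
            class = "common_spec")
}

#' @export
print.common_spec <- function(x, ...) {
  cat(sprintf("<common_spec> experiment '%s': %d players, %d phase(s)\n",
              x$experiment$exp_id, x$experiment$n, length(x$phases)))
  for (ph in x$phases) {
    cat(sprintf("  phase %d '%s': %d nodes, %d edges, %d actions (t_p = %g %s)\n",
                ph$seq_index, ph$ph_sch_id, length(ph$nodes), nrow(ph$edges),
                nrow(ph$actions), ph$t_p, ph$u_p))
  }
  invisible(x)
}
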
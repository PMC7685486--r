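# ---------------------------------------------------------------------------
# Synchronous graph dynamical system (GDS) simulator.
#
# A GDS is (G, W, F, U): an undirected graph, a finite node-state space, a
# per-node local function over the closed 1-neighborhood's restricted
# state, and an update scheme -- synchronous here, so all local functions
# read the pre-step configuration and fire in parallel. Only nodes carry
# state.
# ---------------------------------------------------------------------------

#' Construct a synchronous graph dynamical system
#'
#' @param graph A [ness_graph()].
#' @param state_space Finite set of admissible node states (default `0:1`).
#' @param local_functions Either one function shared by all nodes or a
#'   named list (one per node). Each local function receives the node's
#'   restricted state -- a named vector whose first element is the node's
#'   own state followed by its neighbors' states -- and must return a
#'   single state. Local functions must be pure: the same restricted state
#'   always yields the same output.
#' @return An object of class `gds_system`.
#' @export
gds_system <- function(graph, state_space = 0:1, local_functions) {
  stopifnot(inherits(graph, "ness_graph"))
  if (is.function(local_functions)) {
    local_functions <- setNames(rep(list(local_functions),
                                    length(graph$nodes)), graph$nodes)
  }
  missing <- setdiff(graph$nodes, names(local_functions))
  if (length(missing) > 0) {
    stop(sprintf("every node needs a local function; missing for '%s'",
                 missing[1]))
  }
  structure(list(graph = graph, state_space = state_space,
                 local_functions = local_functions,
                 adjacency = adjacency_list(graph),
                 update_scheme = "synchronous"),
            class = "gds_system")
}

#' @export
print.gds_system <- function(x, ...) {
  cat(sprintf("<gds_system> %d nodes, %d edges, states {%s}, %s update\n",
              length(x$graph$nodes), nrow(x$graph$edges),
              paste(x$state_space, collapse = ","), x$update_scheme))
  invisible(x)
}

check_configuration <- function(system, configuration) {
  nodes <- system$graph$nodes
  if (is.null(names(configuration))) {
    if (length(configuration) != length(nodes)) {
      stop("configuration length must equal the number of nodes")
    }
    names(configuration) <- nodes
  }
  if (!all(nodes %in% names(configuration))) {
    stop("configuration must assign a state to every node")
  }
  configuration <- configuration[nodes]
  if (!all(configuration %in% system$state_space)) {
    stop("configuration contains states outside the state space")
  }
  setNames(as.numeric(configuration), nodes)
}

#' Restricted state of a node
#'
#' The states of a node's closed 1-neighborhood under a configuration: the
#' node's own state first, then its neighbors' states. Its length is
#' `degree + 1`.
#'
#' @param node Node id.
#' @param configuration Named state vector over all nodes.
#' @param graph A [ness_graph()] (or a `gds_system`, whose graph is used).
#' @return Named state vector of length `degree(node) + 1`.
#' @export
restricted_state <- function(node, configuration, graph) {
  if (inherits(graph, "gds_system")) {
    adj <- graph$adjacency
    nodes <- graph$graph$nodes
  } else {
    adj <- adjacency_list(graph)
    nodes <- graph$nodes
  }
  if (!(node %in% nodes)) stop(sprintf("unknown node '%s'", node))
  configuration[c(node, adj[[node]])]
}

#' Progressive threshold local transition
#'
#' A node in state 1 stays in state 1 (progressive dynamics). A node in
#' state 0 moves to 1 when at least `theta` of its neighbors are in state
#' 1, and stays 0 otherwise. Counting neighbors only is equivalent to
#' counting the closed neighborhood here, because the threshold branch only
#' applies when the node's own state is 0.
#'
#' @param own_state 0 or 1.
#' @param neighbor_states Vector of neighbor states (0/1).
#' @param theta Non-negative integer threshold.
#' @return The next state, 0 or 1.
#' @export
threshold_local <- function(own_state, neighbor_states, theta) {
  stopifnot(theta >= 0)
  if (own_state == 1) return(1)
  if (sum(neighbor_states == 1) >= theta) 1 else 0
}

#' Build a progressive threshold GDS
#'
#' @param graph A [ness_graph()].
#' @param theta Per-node thresholds: a single value recycled to all nodes
#'   or a named/positional vector. Each must satisfy
#'   `0 <= theta_i <= degree(v_i) + 1`.
#' @return A `gds_system` whose local functions are [threshold_local()]
#'   with the given thresholds.
#' @export
threshold_system <- function(graph, theta) {
  nodes <- graph$nodes
  if (length(theta) == 1) theta <- setNames(rep(theta, length(nodes)), nodes)
  if (is.null(names(theta))) {
    stopifnot(length(theta) == length(nodes))
    names(theta) <- nodes
  }
  deg <- graph_degrees(graph)
  bad <- names(theta)[theta < 0 | theta > deg[names(theta)] + 1]
  if (length(bad) > 0) {
    stop(sprintf("threshold for node '%s' outside [0, degree + 1]", bad[1]))
  }
  fns <- lapply(nodes, function(v) {
    th <- theta[[v]]
    function(s) threshold_local(s[[1]], s[-1], th)
  })
  sys <- gds_system(graph, 0:1, setNames(fns, nodes))
  sys$theta <- theta[nodes]
  sys
}

#' One synchronous GDS step
#'
#' Every node's next state is computed from the pre-step configuration
#' only; node processing order cannot affect the result.
#'
#' @param system A `gds_system`.
#' @param configuration Named state vector (or unnamed, in node order).
#' @return The next configuration (named, in node order).
#' @export
gds_step <- function(system, configuration) {
  configuration <- check_configuration(system, configuration)
  adj <- system$adjacency
  nxt <- vapply(system$graph$nodes, function(v) {
    s <- configuration[c(v, adj[[v]])]
    out <- system$local_functions[[v]](s)
    if (!(out %in% system$state_space)) {
      stop(sprintf("local function for '%s' returned a state outside the state space", v))
    }
    as.numeric(out)
  }, numeric(1))
  names(nxt) <- system$graph$nodes
  nxt
}

#' Simulate a GDS trajectory
#'
#' Applies the synchronous GDS mapping from `c0` for at most `t_max` steps,
#' stopping early at the first fixed point (the first `t` with
#' `C(t+1) = C(t)`; the repeated configuration is kept in the trajectory).
#'
#' @param system A `gds_system`.
#' @param c0 Initial configuration.
#' @param t_max Maximum number of steps (>= 0).
#' @param seed Optional integer seed, for systems with stochastic local
#'   functions.
#' @return An object of class `gds_trajectory`: `configurations` (matrix,
#'   one row per time 0..T, columns = nodes) and `fixed_point_time` (first
#'   `t` with `C(t+1) = C(t)`, or `NA` if none was reached within
#'   `t_max`).
#' @export
gds_simulate <- function(system, c0, t_max, seed = NULL) {
  stopifnot(t_max >= 0)
  if (!is.null(seed)) set.seed(seed)
  cur <- check_configuration(system, c0)
  traj <- matrix(cur, nrow = 1, dimnames = list("0", system$graph$nodes))
  fixed_point_time <- NA_integer_
  t <- 0L
  while (t < t_max) {
    nxt <- gds_step(system, cur)
    t <- t + 1L
    traj <- rbind(traj, nxt)
    rownames(traj)[t + 1L] <- as.character(t)
    if (identical(unname(nxt), unname(cur))) {
      fixed_point_time <- t - 1L
      break
    }
    cur <- nxt
  }
  structure(list(configurations = traj, fixed_point_time = fixed_point_time),
            class = "gds_trajectory")
}

#' @export
print.gds_trajectory <- function(x, ...) {
  cat(sprintf("<gds_trajectory> %d configurations, fixed point at t = %s\n",
              nrow(x$configurations),
              if (is.na(x$fixed_point_time)) "none" else x$fixed_point_time))
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' One row per time step; first column `time`, then one column per node.
#'
#' @param trajectory A `gds_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- data.frame(time = as.integer(rownames(trajectory$configurations)),
                   trajectory$configurations, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Six-node progressive threshold example
#'
#' The worked threshold-contagion instance used throughout the package's
#' documentation and tests: six nodes, eight edges, thresholds
#' `(1, 1, 2, 3, 1, 2)`, and an initial configuration with only `v1` in
#' state 1. Node `v3` (degree 1, threshold 2) can never activate; the
#' dynamics reach a fixed point at `t = 3`.
#'
#' @return A list with `system` (a `gds_system`) and `c0` (the initial
#'   configuration).
#' @export
threshold_example <- function() {
  nodes <- paste0("v", 1:6)
  edges <- rbind(c("v1", "v2"), c("v2", "v3"), c("v2", "v4"), c("v1", "v4"),
                 c("v1", "v5"), c("v4", "v5"), c("v5", "v6"), c("v4", "v6"))
  g <- ness_graph(nodes, edges)
  theta <- setNames(c(1, 1, 2, 3, 1, 2), nodes)
  c0 <- setNames(c(1, 0, 0, 0, 0, 0), nodes)
  list(system = threshold_system(g, theta), c0 = c0)
}

#' Run one threshold-contagion phase and collect adoption times
#'
#' Builds a progressive threshold GDS on `graph`, seeds the given nodes in
#' state 1 at `t = 0`, simulates `t_p` synchronous steps, and reports when
#' each node first adopted (entered state 1).
#'
#' @param graph A [ness_graph()].
#' @param thetas Thresholds, as in [threshold_system()].
#' @param seeds Character vector of seed node ids (subset of the nodes).
#' @param t_p Number of time increments to simulate (>= 1).
#' @return A list with `adoption_times` (named numeric vector; seeds adopt
#'   at 0, never-adopters are `NA`) and `trajectory` (the
#'   `gds_trajectory`).
#' @export
run_contagion_phase <- function(graph, thetas, seeds, t_p) {
  stopifnot(t_p >= 1)
  if (!all(seeds %in% graph$nodes)) {
    stop("contagion seeds must be nodes of the graph")
  }
  sys <- threshold_system(graph, thetas)
  c0 <- setNames(as.integer(graph$nodes %in% seeds), graph$nodes)
  traj <- gds_simulate(sys, c0, t_p)
  conf <- traj$configurations
  adoption <- vapply(graph$nodes, function(v) {
    hit <- which(conf[, v] == 1)
    if (length(hit) == 0) NA_real_ else as.numeric(rownames(conf)[hit[1]])
  }, numeric(1))
  list(adoption_times = adoption, trajectory = traj)
}
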
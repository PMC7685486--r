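# ---------------------------------------------------------------------------
# Built-in h-function catalog: thin adapters that expose the analysis
# operations to the pipeline engine under stable names, with declared
# datatypes. Five families mirror the five pipelines: data transformation
# (edtp_*), analytics (dap_*), property inference (pip_*), modeling and
# simulation (masp_*), and model evaluation (meapp_*).
# ---------------------------------------------------------------------------

get_phase <- function(spec, params) {
  idx <- params$phase_index
  if (is.null(idx)) stop("parameter 'phase_index' is required")
  spec$phases[[as.integer(idx)]]
}

#' Summary statistics of a discrete action-sequence matrix
#'
#' The statistics compared between experiment and model: the pooled
#' distribution of action codes and the number of active (non no-op)
#' players per time step.
#'
#' @param seqs Integer matrix, players x time bins.
#' @param m Number of action codes.
#' @return Named list of numeric vectors (`code_distribution`,
#'   `active_per_step`).
#' @export
sequence_summaries <- function(seqs, m) {
  list(code_distribution = tabulate(as.vector(seqs), nbins = m),
       active_per_step = colSums(seqs != 1L))
}

#' The built-in h-function catalog
#'
#' Returns the named list of pipeline-callable functions, each with
#' signature `(inputs, params)` where `inputs` is a named list keyed by
#' datatype id and `params` the entry's named parameters. Analysts extend
#' a pipeline by adding entries to this list (or supplying their own) --
#' the engine treats all h-functions uniformly.
#'
#' @return Named list of callables.
#' @export
default_hfunctions <- function() {
  list(
    # -- data transformation ------------------------------------------------
    edtp_transform = function(inputs, params) {
      spec <- edtp_transform(inputs$raw_session_csv)
      c(common_spec_to_docs(spec), list(common_spec = spec))
    },
    load_common_spec = function(inputs, params) {
      list(common_spec = read_common_spec(params$dir))
    },
    # -- data analytics -----------------------------------------------------
    dap_action_progression = function(inputs, params) {
      ph <- get_phase(inputs$common_spec, params)
      list(action_progression_table = action_progression(ph, params$action))
    },
    dap_action_histogram = function(inputs, params) {
      ph <- get_phase(inputs$common_spec, params)
      w <- if (is.null(params$bin_width)) 30 else params$bin_width
      list(action_histogram_table = action_histogram(ph, params$action, w))
    },
    dap_related_action_deltas = function(inputs, params) {
      ph <- get_phase(inputs$common_spec, params)
      list(action_delta_table =
             related_action_deltas(ph, params$initiating, params$responding))
    },
    dap_discrete_sequences = function(inputs, params) {
      ph <- get_phase(inputs$common_spec, params)
      res <- if (is.null(params$resolution)) 1 else params$resolution
      list(discrete_sequences = discrete_action_sequence(ph, resolution = res))
    },
    dap_action_summary = function(inputs, params) {
      list(action_summary_table = action_summary(inputs$common_spec))
    },
    dap_windowed_average = function(inputs, params) {
      ph <- get_phase(inputs$common_spec, params)
      list(windowed_average_table =
             windowed_average(list(ph), params$action, params$s))
    },
    dap_related_action_summary = function(inputs, params) {
      ph <- get_phase(inputs$common_spec, params)
      list(related_action_summary_table = related_action_summary(ph))
    },
    # -- property inference -------------------------------------------------
    pip_transition_matrix = function(inputs, params) {
      ds <- inputs$discrete_sequences
      alpha <- if (is.null(params$alpha)) 0 else params$alpha
      list(transition_matrix = estimate_transition_matrix(
        ds, m = length(ds$code_map), alpha = alpha))
    },
    pip_behavior_logit = function(inputs, params) {
      ds <- inputs$discrete_sequences
      list(behavior_logit = fit_behavior_logit(ds, m = length(ds$code_map)))
    },
    # -- modeling and simulation --------------------------------------------
    masp_simulate_abm = function(inputs, params) {
      tm <- inputs$transition_matrix
      cfg <- abm_config(
        n = params$n, d = params$d, Pi = tm,
        duration = if (is.null(params$duration)) 300 else params$duration,
        seed = params$seed)
      list(abm_output = simulate_anagram_abm(cfg))
    },
    # -- model evaluation ---------------------------------------------------
    meapp_compare = function(inputs, params) {
      ds <- inputs$discrete_sequences
      abm <- inputs$abm_output
      m <- length(ds$code_map)
      obs <- sequence_summaries(ds$sequences, m)
      sim <- sequence_summaries(abm$sequences, m)
      if (length(obs$active_per_step) != length(sim$active_per_step)) {
        obs$active_per_step <- NULL
        sim$active_per_step <- NULL
      }
      list(kl_report = compare_experiment_model(obs, sim))
    },
    meapp_cross_validate = function(inputs, params) {
      ds <- inputs$discrete_sequences
      alpha <- if (is.null(params$alpha)) 1 else params$alpha
      list(cv_table = cross_validate(ds, k = params$k, seed = params$seed,
                                     m = length(ds$code_map), alpha = alpha))
    }
  )
}
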
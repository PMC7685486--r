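# ---------------------------------------------------------------------------
# Pipeline execution engine -- the invariant part of every pipeline.
#
# A job configuration names the component schema locations and an ordered
# list of functions, each with declared input datatypes (drawn from the
# initial files or from prior outputs) and output datatypes. Execution
# walks the list in order; every input is transformed into the required
# datatype (identity when no transformation is registered), validated
# against that datatype's schema, the function is invoked, and every
# output is validated and stored for downstream functions. The first
# validation failure terminates the run gracefully, before the affected
# function body executes, with the accumulated manifest preserved.
# ---------------------------------------------------------------------------

#' Construct a pipeline job configuration in memory
#'
#' @param functions List of function entries; each a list with `name`
#'   (registered h-function id), optional `params` (named list), `inputs`
#'   (list of `list(datatype =, source = "initial"|"prior")`), and
#'   `outputs` (character vector of datatype ids).
#' @param schema_paths Named list/vector locating the five component
#'   schemas (`experiment`, `phasedesc`, `phase`, `action`, `player`);
#'   defaults to the schemas installed with the package.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(functions = list(), schema_paths = NULL) {
  if (is.null(schema_paths)) {
    dir <- system.file("extdata", "schemas", package = "nesspipe")
    schema_paths <- as.list(setNames(
      file.path(dir, paste0(c("experiment", "phasedesc", "phase", "action",
                              "player"), ".json")),
      c("experiment", "phasedesc", "phase", "action", "player")))
  }
  functions <- lapply(functions, function(f) {
    if (is.null(f$params)) f$params <- list()
    f$outputs <- as.character(unlist(f$outputs))
    f$inputs <- lapply(f$inputs, function(i) {
      list(datatype = i$datatype, source = i$source)
    })
    f
  })
  structure(list(schema_paths = schema_paths, functions = functions),
            class = "pipeline_config")
}

config_to_instance <- function(config) {
  c(config$schema_paths,
    list(functions = lapply(config$functions, function(f) {
      list(name = f$name, params = f$params,
           inputs = lapply(f$inputs, function(i)
             list(datatype = i$datatype, source = i$source)),
           outputs = as.list(f$outputs))
    })))
}

#' Load and validate a pipeline job configuration
#'
#' Reads the JSON job description, validates it against the configuration
#' schema *before* use, and checks that the referenced component schema
#' files exist. Execution order is the listed order.
#'
#' @param path Path to the configuration JSON file.
#' @param registry Schema registry holding the `pipeline_config` schema.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path, registry = default_schema_registry()) {
  if (!file.exists(path)) stop(sprintf("configuration file '%s' not found", path))
  doc <- jsonlite::read_json(path)
  v <- validate_instance(doc, "pipeline_config", registry, canonicalize = FALSE)
  if (v$verdict != 1L) {
    stop(sprintf("configuration file '%s' is invalid: %s", path, v$diagnostics))
  }
  comps <- c("experiment", "phasedesc", "phase", "action", "player")
  schema_paths <- doc[comps]
  for (comp in comps) {
    sp <- schema_paths[[comp]]
    if (!file.exists(sp)) {
      stop(sprintf("configuration field '%s' points to a missing schema file '%s'",
                   comp, sp))
    }
  }
  pipeline_config(functions = doc$functions, schema_paths = schema_paths)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> %d function(s):\n", length(x$functions)))
  for (f in x$functions) {
    cat(sprintf("  %s(%s) -> %s\n", f$name,
                paste(vapply(f$inputs, `[[`, character(1), "datatype"),
                      collapse = ", "),
                paste(f$outputs, collapse = ", ")))
  }
  invisible(x)
}

# ---- transformations ------------------------------------------------------

#' Create a transformation registry
#'
#' Maps `(h-function id, input datatype id)` pairs to transformation
#' functions that convert available data instances into the format an
#' h-function requires. Unregistered pairs resolve to the identity
#' transformation.
#'
#' @param entries Named list keyed `"<h>::<datatype>"`; each entry a list
#'   with `fn` (the transformation callable) and `input_datatype` (the
#'   datatype its input is validated against before it runs).
#' @return An object of class `transformation_registry`.
#' @export
transformation_registry <- function(entries = list()) {
  structure(list(entries = entries), class = "transformation_registry")
}

#' Register a transformation for an (h-function, datatype) pair
#'
#' @param registry A [transformation_registry()].
#' @param h H-function id.
#' @param datatype Target input datatype the transformation produces.
#' @param fn Callable `(instance) -> instance`.
#' @param input_datatype Datatype id the raw input is validated against
#'   before `fn` runs.
#' @return The updated registry.
#' @export
register_transformation <- function(registry, h, datatype, fn,
                                    input_datatype) {
  stopifnot(inherits(registry, "transformation_registry"), is.function(fn))
  registry$entries[[paste(h, datatype, sep = "::")]] <-
    list(fn = fn, input_datatype = input_datatype)
  registry
}

#' Resolve the transformation for an (h-function, datatype) pair
#'
#' @inheritParams register_transformation
#' @return A list with `fn`, `input_datatype`, and `identity` (logical);
#'   the identity transformation passes the instance through and validates
#'   it directly against the target datatype.
#' @export
resolve_transformation <- function(h, datatype, registry) {
  e <- registry$entries[[paste(h, datatype, sep = "::")]]
  if (is.null(e)) {
    list(fn = function(x) x, input_datatype = datatype, identity = TRUE)
  } else {
    c(e, list(identity = FALSE))
  }
}

# ---- execution ------------------------------------------------------------

fail_manifest <- function(manifest, step, message) {
  manifest$status <- "failed"
  manifest$error <- list(step = step, message = message)
  class(manifest) <- "run_manifest"
  manifest
}

load_initial_input <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    if (grepl("\\.csv$", x)) return(utils::read.csv(x))
    if (grepl("\\.json$", x)) return(jsonlite::read_json(x))
  }
  x
}

#' Execute a pipeline
#'
#' Runs the configured functions in order. For each function entry, each
#' declared input is located (prior outputs first, then the initial
#' inputs), passed through its transformation, and validated against its
#' datatype's schema; only then is the function body invoked, after which
#' each declared output is validated and stored for downstream entries.
#' Any validation failure terminates the pipeline gracefully -- the
#' affected function body never executes, and the manifest up to the
#' failure is returned with a diagnostic naming the datatype and violated
#' constraint.
#'
#' @param config A [pipeline_config()] (or path to one, loaded via
#'   [load_config()]).
#' @param functions Named list of h-function callables
#'   `(inputs, params) -> named list of outputs`; defaults to the built-in
#'   catalog [default_hfunctions()].
#' @param transformations A [transformation_registry()].
#' @param registry Schema registry gating all boundary validations.
#' @param initial_inputs Named list: datatype id -> instance or file path
#'   (CSV/JSON paths are loaded).
#' @param store Internal: a pre-seeded instance store (used by
#'   [compose_pipelines()] to carry upstream outputs forward).
#' @return An object of class `run_manifest`: `status`
#'   (`"completed"`/`"failed"`), `error` (step and diagnostic on failure),
#'   `log` (one entry per function: inputs with validation verdicts,
#'   whether the body was invoked, outputs with verdicts), `store` (all
#'   accumulated instances), and `outputs` (instances produced by this
#'   run).
#' @export
run_pipeline <- function(config, functions = default_hfunctions(),
                         transformations = transformation_registry(),
                         registry = default_schema_registry(),
                         initial_inputs = list(), store = list()) {
  if (is.character(config)) config <- load_config(config, registry)
  stopifnot(inherits(config, "pipeline_config"))
  v <- validate_instance(config_to_instance(config), "pipeline_config", registry)
  if (v$verdict != 1L) {
    stop(sprintf("invalid pipeline configuration: %s", v$diagnostics))
  }
  manifest <- list(status = "completed", error = NULL, log = list(),
                   store = store, outputs = list())

  for (fi in seq_along(config$functions)) {
    entry <- config$functions[[fi]]
    log <- list(name = entry$name, invoked = FALSE,
                inputs = list(), outputs = list())
    fn <- functions[[entry$name]]
    if (is.null(fn)) {
      manifest$log[[fi]] <- log
      return(fail_manifest(manifest, sprintf("function %d (%s)", fi, entry$name),
                           sprintf("h-function '%s' is not registered", entry$name)))
    }

    inputs <- list()
    for (inp in entry$inputs) {
      dt <- inp$datatype
      raw <- if (identical(inp$source, "prior")) {
        manifest$store[[dt]]
      } else {
        load_initial_input(initial_inputs[[dt]])
      }
      if (is.null(raw)) {
        manifest$log[[fi]] <- log
        return(fail_manifest(manifest, sprintf("function %d (%s), input '%s'",
                                               fi, entry$name, dt),
                             sprintf("input datatype '%s' not found in %s",
                                     dt, if (identical(inp$source, "prior"))
                                       "prior outputs" else "initial inputs")))
      }
      tr <- resolve_transformation(entry$name, dt, transformations)
      if (!tr$identity) {
        # validate the transformation's own input, then transform
        vin <- validate_instance(raw, tr$input_datatype, registry)
        log$inputs[[length(log$inputs) + 1L]] <-
          list(datatype = tr$input_datatype, role = "transformation input",
               verdict = vin$verdict, diagnostics = vin$diagnostics)
        if (vin$verdict != 1L) {
          manifest$log[[fi]] <- log
          return(fail_manifest(manifest,
            sprintf("function %d (%s), transformation input '%s'",
                    fi, entry$name, tr$input_datatype),
            vin$diagnostics))
        }
        raw <- tr$fn(raw)
      }
      vk <- validate_instance(raw, dt, registry)
      log$inputs[[length(log$inputs) + 1L]] <-
        list(datatype = dt, role = "input", source = inp$source,
             transformed = !tr$identity,
             verdict = vk$verdict, diagnostics = vk$diagnostics)
      if (vk$verdict != 1L) {
        manifest$log[[fi]] <- log
        return(fail_manifest(manifest,
          sprintf("function %d (%s), input '%s'", fi, entry$name, dt),
          vk$diagnostics))
      }
      inputs[[dt]] <- raw
    }

    out <- tryCatch(fn(inputs, entry$params), error = function(e) e)
    log$invoked <- TRUE
    if (inherits(out, "error")) {
      manifest$log[[fi]] <- log
      return(fail_manifest(manifest, sprintf("function %d (%s) body",
                                             fi, entry$name),
                           conditionMessage(out)))
    }

    for (dt in entry$outputs) {
      if (is.null(out[[dt]])) {
        manifest$log[[fi]] <- log
        return(fail_manifest(manifest,
          sprintf("function %d (%s), output '%s'", fi, entry$name, dt),
          sprintf("declared output datatype '%s' was not produced", dt)))
      }
      vo <- validate_instance(out[[dt]], dt, registry)
      log$outputs[[length(log$outputs) + 1L]] <-
        list(datatype = dt, verdict = vo$verdict, diagnostics = vo$diagnostics)
      if (vo$verdict != 1L) {
        manifest$log[[fi]] <- log
        return(fail_manifest(manifest,
          sprintf("function %d (%s), output '%s'", fi, entry$name, dt),
          vo$diagnostics))
      }
      if (!is.null(manifest$store[[dt]])) {
        manifest$log[[fi]] <- log
        return(fail_manifest(manifest,
          sprintf("function %d (%s), output '%s'", fi, entry$name, dt),
          sprintf("datatype '%s' was already produced earlier in this run", dt)))
      }
      manifest$store[[dt]] <- out[[dt]]
      manifest$outputs[[dt]] <- out[[dt]]
    }
    manifest$log[[fi]] <- log
  }
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> status: %s, %d function(s) logged\n",
              x$status, length(x$log)))
  for (l in x$log) {
    cat(sprintf("  %s: invoked = %s, %d input check(s), %d output check(s)\n",
                l$name, l$invoked, length(l$inputs), length(l$outputs)))
  }
  if (!is.null(x$error)) {
    cat(sprintf("  error at %s: %s\n", x$error$step, x$error$message))
  }
  invisible(x)
}

#' Serialize a run manifest as JSON
#'
#' Writes the invocation log (not the instance store) -- a record of what
#' ran, what was validated, and where a failure occurred.
#'
#' @param manifest A `run_manifest`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(list(status = manifest$status, error = manifest$error,
                            log = manifest$log),
                       path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' Run several pipelines in sequence, carrying outputs forward
#'
#' Pipelines run in listed order over a shared instance store, so a
#' downstream configuration can consume an upstream pipeline's outputs by
#' datatype id (source `"prior"`). The composition is equivalent to one
#' flat pipeline over the concatenated function lists.
#'
#' @param configs List of [pipeline_config()]s (or paths).
#' @inheritParams run_pipeline
#' @return A list of class `composed_manifest`: `status`, `runs` (one
#'   `run_manifest` per pipeline, up to the first failure), `store`, and
#'   `outputs` (all outputs across pipelines).
#' @export
compose_pipelines <- function(configs, functions = default_hfunctions(),
                              transformations = transformation_registry(),
                              registry = default_schema_registry(),
                              initial_inputs = list()) {
  store <- list(); runs <- list(); outputs <- list()
  for (ci in seq_along(configs)) {
    m <- run_pipeline(configs[[ci]], functions = functions,
                      transformations = transformations, registry = registry,
                      initial_inputs = initial_inputs, store = store)
    runs[[ci]] <- m
    store <- m$store
    outputs <- c(outputs, m$outputs)
    if (m$status != "completed") {
      return(structure(list(status = "failed", runs = runs, store = store,
                            outputs = outputs, error = m$error),
                       class = "composed_manifest"))
    }
  }
  structure(list(status = "completed", runs = runs, store = store,
                 outputs = outputs, error = NULL),
            class = "composed_manifest")
}

#' @export
print.composed_manifest <- function(x, ...) {
  cat(sprintf("<composed_manifest> status: %s, %d pipeline(s)\n",
              x$status, length(x$runs)))
  invisible(x)
}
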
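#' @importFrom jsonlite fromJSON toJSON read_json write_json
#' @importFrom stats setNames
NULL

# ---------------------------------------------------------------------------
# Schema engine: a JSON Schema (draft 2020-12 subset) evaluator plus a
# datatype -> schema registry. Every file that crosses a pipeline function
# boundary is checked here before any function body runs.
#
# Supported keywords: type, enum, const, properties, required,
# additionalProperties, items, minItems, maxItems, uniqueItems, minimum,
# maximum, exclusiveMinimum, exclusiveMaximum, minLength, maxLength,
# pattern, anyOf. This covers every schema shipped with the package.
# ---------------------------------------------------------------------------

#' Canonicalize an R value into JSON-instance form
#'
#' Round-trips `x` through JSON so that objects become named lists, arrays
#' become unnamed lists, and scalars become length-1 atomics -- the form the
#' schema evaluator and all pipeline boundary checks operate on. Data frames
#' serialize row-wise (one object per row).
#'
#' @param x Any JSON-serializable R value.
#' @return The canonical instance (nested lists / atomics).
#' @export
as_instance <- function(x) {
  jsonlite::fromJSON(
    jsonlite::toJSON(x, auto_unbox = TRUE, dataframe = "rows",
                     null = "null", na = "null", digits = NA, force = TRUE),
    simplifyVector = FALSE
  )
}

json_type <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    if (!is.null(names(x)) || length(x) == 0L) {
      # empty list is ambiguous; treat as array unless explicitly named
      if (!is.null(names(x))) return("object")
      return("array")
    }
    return("array")
  }
  if (length(x) != 1L) return("array")
  if (is.character(x)) return("string")
  if (is.logical(x)) return("boolean")
  if (is.numeric(x)) {
    if (is.finite(x) && x == floor(x)) return("integer")
    return("number")
  }
  "unknown"
}

type_matches <- function(actual, wanted) {
  if (wanted == "number") return(actual %in% c("number", "integer"))
  if (wanted == "object" && actual == "array") return(FALSE)
  # an empty unnamed list can stand for an empty object
  if (wanted == "object" && actual == "array") return(FALSE)
  actual == wanted
}

violation <- function(path, keyword, message) {
  list(path = path, keyword = keyword, message = message)
}

scalar_equal <- function(a, b) {
  isTRUE(all.equal(a, b, check.attributes = FALSE)) ||
    identical(as.character(a), as.character(b))
}

# Returns NULL when `x` conforms, else the first violation found.
schema_check <- function(x, schema, path = "$") {
  if (isTRUE(schema)) return(NULL)
  if (isFALSE(schema)) {
    return(violation(path, "false", sprintf("no value admitted at %s", path)))
  }
  tx <- json_type(x)

  if (!is.null(schema$type)) {
    wanted <- unlist(schema$type)
    ok <- any(vapply(wanted, function(w) type_matches(tx, w), logical(1)))
    # a length-0 or length-1 atomic may also stand for an array of scalars
    if (!ok && "array" %in% wanted && !is.list(x) && !is.null(x)) ok <- TRUE
    if (!ok && "object" %in% wanted && is.list(x) && length(x) == 0L) ok <- TRUE
    if (!ok) {
      return(violation(path, "type",
        sprintf("expected type %s but found %s at %s",
                paste(wanted, collapse = "|"), tx, path)))
    }
  }

  if (!is.null(schema$enum)) {
    hit <- any(vapply(schema$enum, function(e) scalar_equal(x, e), logical(1)))
    if (!hit) {
      return(violation(path, "enum",
        sprintf("value at %s is not one of the permitted values", path)))
    }
  }
  if (!is.null(schema$const)) {
    if (!scalar_equal(x, schema$const)) {
      return(violation(path, "const",
        sprintf("value at %s does not equal the required constant", path)))
    }
  }

  if (!is.null(schema$anyOf)) {
    errs <- lapply(schema$anyOf, function(s) schema_check(x, s, path))
    if (all(!vapply(errs, is.null, logical(1)))) {
      return(violation(path, "anyOf",
        sprintf("value at %s matches none of the alternatives", path)))
    }
  }

  if (tx == "string") {
    n <- nchar(x)
    if (!is.null(schema$minLength) && n < schema$minLength) {
      return(violation(path, "minLength",
        sprintf("string at %s shorter than %d", path, schema$minLength)))
    }
    if (!is.null(schema$maxLength) && n > schema$maxLength) {
      return(violation(path, "maxLength",
        sprintf("string at %s longer than %d", path, schema$maxLength)))
    }
    if (!is.null(schema$pattern) && !grepl(schema$pattern, x, perl = TRUE)) {
      return(violation(path, "pattern",
        sprintf("string at %s does not match pattern '%s'", path, schema$pattern)))
    }
  }

  if (tx %in% c("number", "integer")) {
    if (!is.null(schema$minimum) && x < schema$minimum) {
      return(violation(path, "minimum",
        sprintf("value %s at %s below minimum %s", format(x), path,
                format(schema$minimum))))
    }
    if (!is.null(schema$maximum) && x > schema$maximum) {
      return(violation(path, "maximum",
        sprintf("value %s at %s above maximum %s", format(x), path,
                format(schema$maximum))))
    }
    if (!is.null(schema$exclusiveMinimum) && x <= schema$exclusiveMinimum) {
      return(violation(path, "exclusiveMinimum",
        sprintf("value at %s must exceed %s", path,
                format(schema$exclusiveMinimum))))
    }
    if (!is.null(schema$exclusiveMaximum) && x >= schema$exclusiveMaximum) {
      return(violation(path, "exclusiveMaximum",
        sprintf("value at %s must be below %s", path,
                format(schema$exclusiveMaximum))))
    }
  }

  if (json_type(x) == "object" ||
      (is.list(x) && !is.null(names(x)))) {
    if (!is.null(schema$required)) {
      for (k in unlist(schema$required)) {
        if (!(k %in% names(x)) || is.null(x[[k]]) && !k %in% names(x)) {
          if (!(k %in% names(x))) {
            return(violation(path, "required",
              sprintf("required property '%s' is missing at %s", k, path)))
          }
        }
      }
    }
    if (!is.null(schema$properties)) {
      for (k in names(schema$properties)) {
        if (k %in% names(x)) {
          err <- schema_check(x[[k]], schema$properties[[k]],
                              paste0(path, ".", k))
          if (!is.null(err)) return(err)
        }
      }
      if (isFALSE(schema$additionalProperties)) {
        extra <- setdiff(names(x), names(schema$properties))
        if (length(extra) > 0) {
          return(violation(path, "additionalProperties",
            sprintf("unexpected property '%s' at %s", extra[1], path)))
        }
      }
    }
  }

  is_arrayish <- (is.list(x) && is.null(names(x))) ||
    (!is.list(x) && !is.null(x) && length(x) != 1L) ||
    (!is.null(schema$type) && "array" %in% unlist(schema$type) && !is.list(x))
  if (is_arrayish && !is.null(x)) {
    elems <- if (is.list(x)) x else as.list(x)
    n <- length(elems)
    if (!is.null(schema$minItems) && n < schema$minItems) {
      return(violation(path, "minItems",
        sprintf("array at %s has %d items, fewer than %d", path, n,
                schema$minItems)))
    }
    if (!is.null(schema$maxItems) && n > schema$maxItems) {
      return(violation(path, "maxItems",
        sprintf("array at %s has %d items, more than %d", path, n,
                schema$maxItems)))
    }
    if (isTRUE(schema$uniqueItems) && n > 1) {
      keys <- vapply(elems, function(e)
        jsonlite::toJSON(e, auto_unbox = TRUE, null = "null"), character(1))
      if (anyDuplicated(keys)) {
        return(violation(path, "uniqueItems",
          sprintf("array at %s contains duplicate items", path)))
      }
    }
    if (!is.null(schema$items)) {
      for (i in seq_len(n)) {
        err <- schema_check(elems[[i]], schema$items,
                            sprintf("%s[%d]", path, i))
        if (!is.null(err)) return(err)
      }
    }
  }

  NULL
}

# ---------------------------------------------------------------------------
# Registry
# ---------------------------------------------------------------------------

#' Create a datatype -> schema registry
#'
#' The registry realizes the schema-identifier map: every datatype named by
#' a pipeline configuration must resolve to exactly one schema document.
#'
#' @param schemas Named list of schema documents (parsed JSON), keyed by
#'   datatype id.
#' @return An object of class `schema_registry`.
#' @seealso [default_schema_registry()] for the registry pre-loaded with the
#'   data common specification schemas.
#' @export
schema_registry <- function(schemas = list()) {
  structure(list(schemas = schemas), class = "schema_registry")
}

#' Register (or replace) a schema for a datatype
#'
#' @param registry A [schema_registry()].
#' @param datatype Datatype id (string).
#' @param schema Schema document (parsed JSON, i.e. nested lists).
#' @return The updated registry.
#' @export
register_schema <- function(registry, datatype, schema) {
  stopifnot(inherits(registry, "schema_registry"), is.character(datatype))
  registry$schemas[[datatype]] <- schema
  registry
}

#' Resolve the schema for a datatype
#'
#' @inheritParams register_schema
#' @return The schema document; errors (condition class
#'   `nesspipe_unknown_datatype`) if the datatype is not registered.
#' @export
resolve_schema <- function(registry, datatype) {
  stopifnot(inherits(registry, "schema_registry"))
  s <- registry$schemas[[datatype]]
  if (is.null(s)) {
    stop(structure(
      class = c("nesspipe_unknown_datatype", "error", "condition"),
      list(message = sprintf("no schema registered for datatype '%s'", datatype),
           call = sys.call(-1))))
  }
  s
}

#' @export
print.schema_registry <- function(x, ...) {
  cat("<schema_registry>", length(x$schemas), "datatypes:\n")
  cat(" ", paste(sort(names(x$schemas)), collapse = ", "), "\n")
  invisible(x)
}

#' Validate one data instance against a registered datatype schema
#'
#' The schema evaluator of the pipeline model: returns verdict 1 when the
#' instance conforms to the datatype's schema and 0 otherwise, together with
#' a diagnostic naming the first violated constraint and its path. An
#' unresolvable datatype is an error, not a 0 verdict.
#'
#' @param instance A decoded document (nested lists / atomics, or any value
#'   accepted by [as_instance()]).
#' @param datatype Datatype id to validate against.
#' @param registry A [schema_registry()].
#' @param canonicalize If `TRUE` (default) the instance is passed through
#'   [as_instance()] first.
#' @return A list with elements `verdict` (integer 0/1), `datatype`, and
#'   `diagnostics` (character; empty when conforming).
#' @export
validate_instance <- function(instance, datatype, registry,
                              canonicalize = TRUE) {
  schema <- resolve_schema(registry, datatype)
  if (canonicalize) instance <- as_instance(instance)
  err <- schema_check(instance, schema)
  if (is.null(err)) {
    list(verdict = 1L, datatype = datatype, diagnostics = character(0))
  } else {
    list(verdict = 0L, datatype = datatype,
         diagnostics = sprintf("[%s] %s", err$keyword, err$message))
  }
}

#' Registry pre-loaded with the data common specification schemas
#'
#' Loads the schemas shipped under `inst/extdata/schemas/` for the five
#' on-disk components (`experiment`, `phase`, `phasedesc`, `player`,
#' `action`), the pipeline job configuration (`pipeline_config`), and the
#' raw event-log dialect (`raw_session_csv`), plus permissive schemas for
#' the derived analysis tables that flow between pipeline functions.
#'
#' @return A [schema_registry()].
#' @export
default_schema_registry <- function() {
  dir <- system.file("extdata", "schemas", package = "nesspipe")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  schemas <- lapply(files, jsonlite::read_json)
  names(schemas) <- sub("\\.json$", "", basename(files))
  reg <- schema_registry(schemas)
  # Derived tabular datatypes exchanged between analysis functions.  These
  # are arrays of row objects; each gets a light structural schema.
  row_table <- function(required) {
    list(type = "array",
         items = list(type = "object", required = as.list(required)))
  }
  reg <- register_schema(reg, "common_spec",
    list(type = "object",
         required = list("experiment", "phases", "players")))
  reg <- register_schema(reg, "action_progression_table",
    row_table(c("player", "time", "count")))
  reg <- register_schema(reg, "action_histogram_table",
    row_table(c("bin", "t_lo", "t_hi", "count")))
  reg <- register_schema(reg, "action_delta_table",
    list(type = "object", required = list("deltas", "unanswered")))
  reg <- register_schema(reg, "discrete_sequences",
    list(type = "object", required = list("sequences", "code_map", "t_p")))
  reg <- register_schema(reg, "action_summary_table",
    row_table(c("phase", "action", "count")))
  reg <- register_schema(reg, "windowed_average_table",
    row_table(c("window", "t_lo", "t_hi", "mean_count")))
  reg <- register_schema(reg, "related_action_summary_table",
    row_table(c("action", "possible", "occurred")))
  reg <- register_schema(reg, "transition_matrix",
    list(type = "object", required = list("pi", "counts", "m", "alpha")))
  reg <- register_schema(reg, "behavior_logit",
    list(type = "object", required = list("sources", "m")))
  reg <- register_schema(reg, "abm_output",
    list(type = "object", required = list("actions", "phase", "sequences")))
  reg <- register_schema(reg, "kl_report",
    row_table(c("statistic", "kl")))
  reg <- register_schema(reg, "cv_table",
    row_table(c("fold", "n_sequences", "n_transitions", "loglik")))
  reg
}

#' Action-tuple schema specialized to one phase
#'
#' The action tuple's time must satisfy `0 <= time <= t_p`, but `t_p` lives
#' in the phase record; this helper stamps the phase's bound into the
#' generic action schema so [validate_instance()] can enforce it.
#'
#' @param t_p Number of time increments in the phase.
#' @param registry Registry holding the generic `action` schema (defaults to
#'   [default_schema_registry()]).
#' @return A schema document for a single action tuple with the time bound.
#' @export
action_schema_for_phase <- function(t_p, registry = default_schema_registry()) {
  sch <- resolve_schema(registry, "action")
  tuple <- sch$items
  tuple$properties$time$maximum <- t_p
  tuple
}
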
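# Minimal schema set and functions for exercising the engine in isolation.
toy_registry <- function() {
  reg <- default_schema_registry()
  reg <- register_schema(reg, "in1", list(type = "object", required = list("x")))
  reg <- register_schema(reg, "in2", list(type = "object", required = list("y")))
  reg <- register_schema(reg, "mid", list(type = "object", required = list("value")))
  reg <- register_schema(reg, "out2", list(type = "object", required = list("twice")))
  reg
}

toy_functions <- function(trace = NULL) {
  list(
    double_up = function(inputs, params) {
      if (!is.null(trace)) trace$log <- c(trace$log, "double_up")
      list(mid = list(value = inputs$in1$x * 2))
    },
    add_y = function(inputs, params) {
      if (!is.null(trace)) trace$log <- c(trace$log, "add_y")
      list(out2 = list(twice = inputs$mid$value + inputs$in2$y))
    })
}

chain_config <- function() {
  pipeline_config(list(
    list(name = "double_up",
         inputs = list(list(datatype = "in1", source = "initial")),
         outputs = "mid"),
    list(name = "add_y",
         inputs = list(list(datatype = "mid", source = "prior"),
                       list(datatype = "in2", source = "initial")),
         outputs = "out2")))
}

test_that("configuration files validate against the config schema before use", {
  dir <- system.file("extdata", "schemas", package = "nesspipe")
  cfg_doc <- list(
    experiment = file.path(dir, "experiment.json"),
    phasedesc = file.path(dir, "phasedesc.json"),
    phase = file.path(dir, "phase.json"),
    action = file.path(dir, "action.json"),
    player = file.path(dir, "player.json"),
    functions = list(
      list(name = "double_up",
           inputs = list(list(datatype = "in1", source = "initial")),
           outputs = list("mid")),
      list(name = "add_y",
           inputs = list(list(datatype = "mid", source = "prior")),
           outputs = list("out2"))))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg_doc, path, auto_unbox = TRUE)
  cfg <- load_config(path)
  expect_s3_class(cfg, "pipeline_config")
  expect_length(cfg$functions, 2)
  expect_equal(vapply(cfg$functions, `[[`, character(1), "name"),
               c("double_up", "add_y"))

  # empty function list is a valid, zero-task job
  cfg_doc$functions <- list()
  jsonlite::write_json(cfg_doc, path, auto_unbox = TRUE)
  expect_length(load_config(path)$functions, 0)

  # missing 'functions' violates the schema
  cfg_doc$functions <- NULL
  jsonlite::write_json(cfg_doc, path, auto_unbox = TRUE)
  expect_error(load_config(path), "functions")
})

test_that("transformations resolve to the registered callable or the identity", {
  tr <- transformation_registry()
  tr <- register_transformation(tr, "edtp_transform", "parsed_rows",
                                fn = function(x) list(rows = length(x)),
                                input_datatype = "raw_session_csv")
  hit <- resolve_transformation("edtp_transform", "parsed_rows", tr)
  expect_false(hit$identity)
  expect_equal(hit$input_datatype, "raw_session_csv")
  expect_equal(hit$fn(list(1, 2, 3)), list(rows = 3))
  miss <- resolve_transformation("edtp_transform", "other", tr)
  expect_true(miss$identity)
  doc <- list(a = 1)
  expect_identical(miss$fn(doc), doc)
})

test_that("a registered transformation runs between its two validation events", {
  reg <- toy_registry()
  reg <- register_schema(reg, "numbers", list(type = "array"))
  tr <- register_transformation(transformation_registry(), "double_up", "in1",
                                fn = function(nums) list(x = sum(unlist(nums))),
                                input_datatype = "numbers")
  cfg <- pipeline_config(list(
    list(name = "double_up",
         inputs = list(list(datatype = "in1", source = "initial")),
         outputs = "mid")))
  m <- run_pipeline(cfg, functions = toy_functions(), transformations = tr,
                    registry = reg, initial_inputs = list(in1 = list(1, 2, 3)))
  expect_equal(m$status, "completed")
  expect_equal(m$outputs$mid$value, 12)
  roles <- vapply(m$log[[1]]$inputs, `[[`, character(1), "role")
  expect_equal(roles, c("transformation input", "input"))
})

test_that("a two-function chain resolves the second input from prior outputs", {
  m <- run_pipeline(chain_config(), functions = toy_functions(),
                    registry = toy_registry(),
                    initial_inputs = list(in1 = list(x = 5), in2 = list(y = 1)))
  expect_equal(m$status, "completed")
  expect_equal(m$outputs$out2$twice, 11)
  expect_true(m$log[[1]]$invoked)
  expect_true(m$log[[2]]$invoked)
})

test_that("a corrupt second input stops the run exactly as the algorithm prescribes", {
  trace <- new.env(); trace$log <- character(0)
  m <- run_pipeline(chain_config(), functions = toy_functions(trace),
                    registry = toy_registry(),
                    initial_inputs = list(in1 = list(x = 5),
                                          in2 = list(wrong = 1)))
  # hand trace: function 1 validated, invoked, output validated and stored;
  # function 2's first input validates, its second fails, body never runs.
  expect_equal(m$status, "failed")
  expect_equal(trace$log, "double_up")                # only f1 executed
  expect_true(m$log[[1]]$invoked)
  expect_equal(m$log[[1]]$outputs[[1]]$verdict, 1L)
  expect_false(m$log[[2]]$invoked)
  expect_equal(vapply(m$log[[2]]$inputs, `[[`, integer(1), "verdict"),
               c(1L, 0L))
  expect_match(m$error$message, "required property 'y'")
  expect_match(m$error$step, "in2")
  expect_equal(m$outputs$mid$value, 10)               # f1's work preserved
})

test_that("a missing prior datatype and a duplicate output both terminate gracefully", {
  cfg <- pipeline_config(list(
    list(name = "add_y",
         inputs = list(list(datatype = "mid", source = "prior"),
                       list(datatype = "in2", source = "initial")),
         outputs = "out2")))
  m <- run_pipeline(cfg, functions = toy_functions(), registry = toy_registry(),
                    initial_inputs = list(in2 = list(y = 1)))
  expect_equal(m$status, "failed")
  expect_match(m$error$message, "not found in prior outputs")

  dup <- pipeline_config(list(
    list(name = "double_up",
         inputs = list(list(datatype = "in1", source = "initial")),
         outputs = "mid"),
    list(name = "double_up",
         inputs = list(list(datatype = "in1", source = "initial")),
         outputs = "mid")))
  m2 <- run_pipeline(dup, functions = toy_functions(), registry = toy_registry(),
                     initial_inputs = list(in1 = list(x = 1)))
  expect_equal(m2$status, "failed")
  expect_match(m2$error$message, "already produced")
})

test_that("every boundary crossing has exactly one validation event", {
  m <- run_pipeline(chain_config(), functions = toy_functions(),
                    registry = toy_registry(),
                    initial_inputs = list(in1 = list(x = 5), in2 = list(y = 1)))
  n_inputs <- sum(vapply(m$log, function(l) length(l$inputs), integer(1)))
  n_outputs <- sum(vapply(m$log, function(l) length(l$outputs), integer(1)))
  expect_equal(n_inputs, 3)    # in1; mid; in2
  expect_equal(n_outputs, 2)   # mid; out2
})

test_that("composition over a split equals the flat pipeline, and is deterministic", {
  split_cfgs <- list(
    pipeline_config(list(chain_config()$functions[[1]])),
    pipeline_config(list(chain_config()$functions[[2]])))
  flat <- run_pipeline(chain_config(), functions = toy_functions(),
                       registry = toy_registry(),
                       initial_inputs = list(in1 = list(x = 5), in2 = list(y = 1)))
  comp <- compose_pipelines(split_cfgs, functions = toy_functions(),
                            registry = toy_registry(),
                            initial_inputs = list(in1 = list(x = 5),
                                                  in2 = list(y = 1)))
  expect_equal(comp$status, "completed")
  expect_equal(comp$store, flat$store)
  expect_equal(comp$outputs[order(names(comp$outputs))],
               flat$outputs[order(names(flat$outputs))])
  # single-pipeline composition is run_pipeline
  solo <- compose_pipelines(list(chain_config()), functions = toy_functions(),
                            registry = toy_registry(),
                            initial_inputs = list(in1 = list(x = 5),
                                                  in2 = list(y = 1)))
  expect_equal(solo$runs[[1]]$outputs, flat$outputs)
  # identical configs and inputs give identical manifests
  again <- run_pipeline(chain_config(), functions = toy_functions(),
                        registry = toy_registry(),
                        initial_inputs = list(in1 = list(x = 5),
                                              in2 = list(y = 1)))
  expect_equal(again[c("status", "log", "store", "outputs")],
               flat[c("status", "log", "store", "outputs")])
})

test_that("manifests serialize to JSON", {
  m <- run_pipeline(chain_config(), functions = toy_functions(),
                    registry = toy_registry(),
                    initial_inputs = list(in1 = list(x = 5), in2 = list(y = 1)))
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest_json(m, path)
  doc <- jsonlite::read_json(path)
  expect_equal(doc$status, "completed")
  expect_length(doc$log, 2)
})
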
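test_that("sequence ids concatenate initiator, hyphen, counter and stay distinct", {
  expect_identical(make_sequence_id("v1", 0), "v1-0")
  expect_identical(make_sequence_id("p42", 7), "p42-7")
  expect_error(make_sequence_id("v1", -1), "non-negative")
  ids <- as.vector(outer(paste0("p", 1:10), 0:99, make_sequence_id))
  expect_length(unique(ids), 1000)
})

test_that("link_action_sequences partitions tuples into time-ordered sigma groups", {
  acts <- action_tuples(
    sigma = c("v1-0", "v1-0"), action = c("request_letter", "reply_letter"),
    initiator = c("v1", "v3"), target = c("v3", "v1"), time = c(10, 12),
    payload = list(list(letter = "z"), list(letter = "z")))
  g <- link_action_sequences(acts)
  expect_length(g, 1)
  expect_equal(nrow(g[["v1-0"]]), 2)
  expect_equal(g[["v1-0"]]$time, c(10, 12))

  expect_length(link_action_sequences(action_tuples()), 0)

  set.seed(9)
  n <- 50
  sig <- sample(paste0("s", 1:10), n, replace = TRUE)
  acts <- action_tuples(sigma = sig, action = "form_word",
                        initiator = "v1", time = runif(n, 0, 5))
  g <- link_action_sequences(acts)
  # partition: sizes sum to n and match a linear-scan count per sigma
  expect_equal(sum(vapply(g, nrow, integer(1))), n)
  for (s in unique(sig)) expect_equal(nrow(g[[s]]), sum(sig == s))
  for (s in names(g)) expect_false(is.unsorted(g[[s]]$time))
})

test_that("record constructors enforce the schema invariants", {
  expect_error(experiment_record("e", 1, c("v1", "v1"),
                                 "2026-01-01T00:00:00Z", "2026-01-01T01:00:00Z"),
               "unique")
  expect_error(experiment_record("e", 0, "v1",
                                 "2026-01-01T00:00:00Z", "2026-01-01T01:00:00Z"),
               "n_p")
  expect_error(experiment_record("e", 1, "v1",
                                 "2026-01-01T02:00:00Z", "2026-01-01T01:00:00Z"),
               "t_begin")
  # edge endpoint outside nodes
  expect_error(hand_phase(edges = rbind(c("v1", "v9"))), "not a phase node")
  # action outside the action set
  expect_error(hand_phase(actions = action_tuples("v1-0", "dance", "v1",
                                                  NA, 1)),
               "not in action set")
  # action time beyond t_p
  expect_error(hand_phase(actions = action_tuples("v1-0", "form_word", "v1",
                                                  NA, 99)),
               "\\[0, t_p\\]")
  # self-loops and duplicate edges rejected canonically
  expect_error(canonical_edges(rbind(c("a", "a"))), "self-loop")
  expect_error(canonical_edges(rbind(c("a", "b"), c("b", "a"))), "duplicate")
})

test_that("write then read reproduces every field of every record", {
  ses <- cached_session()
  spec <- edtp_transform(ses$raw)
  dir <- withr::local_tempdir()
  paths <- write_common_spec(spec, dir)
  expect_length(paths, 5)
  spec2 <- read_common_spec(dir)
  expect_equal(spec2$experiment, spec$experiment)
  expect_length(spec2$phases, 3)
  expect_equal(vapply(spec2$phases, `[[`, integer(1), "seq_index"), 1:3)
  for (i in seq_along(spec$phases)) {
    expect_equal(spec2$phases[[i]], spec$phases[[i]])
  }
})

test_that("writing refuses records that violate invariants", {
  ses <- cached_session()
  spec <- edtp_transform(ses$raw)
  broken <- spec
  broken$phases[[2]]$edges <- rbind(broken$phases[[2]]$edges, c("v1", "zz"))
  expect_error(write_common_spec(broken, withr::local_tempdir()),
               "not a phase node")
})

test_that("the action file carries one entry per action tuple", {
  set.seed(5)
  n_act <- 1000
  acts <- action_tuples(sigma = make_sequence_id("v1", 0:(n_act - 1)),
                        action = "form_word", initiator = "v1",
                        time = sort(runif(n_act, 0, 5)))
  ph <- hand_phase(actions = acts)
  exp <- experiment_record("he1", 1, c("v1", "v2", "v3"),
                           "2026-03-01T00:00:00Z", "2026-03-01T01:00:00Z")
  dir <- withr::local_tempdir()
  write_common_spec(list(experiment = exp, phases = list(ph)), dir)
  doc <- jsonlite::read_json(file.path(dir, "action.json"))
  expect_length(doc, n_act)
})

test_that("loads abort on cross-reference errors with a diagnostic", {
  ses <- cached_session()
  spec <- edtp_transform(ses$raw)
  dir <- withr::local_tempdir()
  write_common_spec(spec, dir)
  # corrupt: phase references an unregistered player
  ph <- jsonlite::read_json(file.path(dir, "phase.json"))
  ph[[1]]$nodes <- c(ph[[1]]$nodes, list("ghost"))
  jsonlite::write_json(ph, file.path(dir, "phase.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  expect_error(read_common_spec(dir), "ghost")
})

test_that("an empty actions file loads as zero tuples", {
  exp <- experiment_record("he1", 1, c("v1", "v2", "v3"),
                           "2026-03-01T00:00:00Z", "2026-03-01T01:00:00Z")
  dir <- withr::local_tempdir()
  write_common_spec(list(experiment = exp, phases = list(hand_phase())), dir)
  spec <- read_common_spec(dir)
  expect_equal(nrow(spec$phases[[1]]$actions), 0)
})
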
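test_that("the raw-log transform reproduces the generator's ground truth", {
  ses <- cached_session()
  spec <- edtp_transform(ses$raw)
  expect_s3_class(spec, "common_spec")
  expect_length(spec$phases, 3)
  expect_equal(vapply(spec$phases, `[[`, integer(1), "seq_index"), 1:3)

  s <- action_summary(spec)
  man <- ses$manifest$action_counts
  get <- function(phase, action) s$count[s$phase == phase & s$action == action]
  expect_equal(get("session-1-ph1", "submit_difi"), man$submit_difi_phase1)
  expect_equal(get("session-1-ph2", "request_letter"), man$request_letter)
  expect_equal(get("session-1-ph2", "reply_letter"), man$reply_letter)
  expect_equal(get("session-1-ph2", "form_word"), man$form_word)
  expect_equal(sum(s$count[s$phase != "all"]), ses$manifest$n_action_events)

  # request/reply exchanges share a sigma
  ph2 <- spec$phases[[2]]
  groups <- link_action_sequences(ph2$actions)
  both <- Filter(function(g) all(c("request_letter", "reply_letter") %in%
                                   g$action), groups)
  expect_gt(length(both), 0)
  for (g in both[seq_len(min(5, length(both)))]) {
    expect_lte(g$time[g$action == "request_letter"][1],
               g$time[g$action == "reply_letter"][1])
  }
})

test_that("unknown event types abort the transform naming the rows", {
  ses <- cached_session()
  raw <- ses$raw
  raw$event_type[10] <- "teleport"
  expect_error(edtp_transform(raw), "teleport")
})

test_that("a raw log with zero action events yields an empty action set", {
  ses <- cached_session()
  raw <- ses$raw[ses$raw$event_type %in% c("session_start", "player_join",
                                           "phase_start", "edge",
                                           "session_end"), ]
  spec <- edtp_transform(raw)
  expect_equal(sum(vapply(spec$phases, function(p) nrow(p$actions),
                          integer(1))), 0)
})

test_that("action progressions step at the right times and conserve totals", {
  acts <- action_tuples(sigma = make_sequence_id("v1", 0:2),
                        action = "form_word", initiator = "v1",
                        time = c(2, 4, 4.5))
  ph <- hand_phase(actions = acts)
  pr <- action_progression(ph, "form_word")
  v1 <- pr[pr$player == "v1", ]
  expect_equal(v1$time, c(0, 2, 4, 4.5))
  expect_equal(v1$count, 0:3)
  v2 <- pr[pr$player == "v2", ]
  expect_equal(v2$count, 0)                         # constant-zero series
  # conservation against the summary
  s <- action_summary(list(ph))
  finals <- tapply(pr$count, pr$player, max)
  expect_equal(sum(finals), s$count[s$phase == "hp1" & s$action == "form_word"])
  expect_error(action_progression(ph, "dance"), "not in the phase action set")
})

test_that("histograms bin half-open intervals and conserve counts", {
  acts <- action_tuples(sigma = make_sequence_id("v1", 0:2),
                        action = "request_letter", initiator = "v1",
                        target = "v2", time = c(10, 20, 40))
  ph <- hand_phase(actions = acts, t_p = 60)
  h <- action_histogram(ph, "request_letter", bin_width = 30)
  expect_equal(h$count, c(2, 1))
  expect_equal(sum(h$count), 3)
  h0 <- action_histogram(hand_phase(t_p = 60), "request_letter", 30)
  expect_true(all(h0$count == 0))
  # boundary: t = 30 lands in bin 1, t = 30.01 in bin 2, t = 0 in bin 1
  acts <- action_tuples(sigma = make_sequence_id("v1", 0:2),
                        action = "request_letter", initiator = "v1",
                        target = "v2", time = c(0, 30, 30.01))
  h <- action_histogram(hand_phase(actions = acts, t_p = 60),
                        "request_letter", 30)
  expect_equal(h$count, c(2, 1))
})

test_that("request/reply deltas pair within sigma groups and count unanswered", {
  acts <- action_tuples(
    sigma = c("v1-0", "v1-0", "v2-0"),
    action = c("request_letter", "reply_letter", "request_letter"),
    initiator = c("v1", "v2", "v2"), target = c("v2", "v1", "v3"),
    time = c(10, 12, 20))
  ph <- hand_phase(actions = acts, t_p = 60)
  rd <- related_action_deltas(ph, "request_letter", "reply_letter")
  expect_equal(rd$deltas$delta, 2)
  expect_equal(rd$unanswered, "v2-0")
  expect_true(all(rd$deltas$delta >= 0))

  # conservation on a random fixture: answered + unanswered = requests
  set.seed(31)
  n_req <- 40
  req <- action_tuples(sigma = make_sequence_id("v1", 0:(n_req - 1)),
                       action = "request_letter", initiator = "v1",
                       target = "v2", time = sort(runif(n_req, 0, 50)))
  answered <- sample(n_req, 25)
  rep_t <- req$time[answered] + runif(25, 0.1, 5)
  rep_df <- action_tuples(sigma = req$sigma[answered], action = "reply_letter",
                          initiator = "v2", target = "v1", time = pmin(rep_t, 60))
  ph <- hand_phase(actions = rbind(req, rep_df), t_p = 60)
  rd <- related_action_deltas(ph, "request_letter", "reply_letter")
  expect_equal(nrow(rd$deltas) + length(rd$unanswered), n_req)
})

test_that("discrete sequences code bins correctly, fill with the no-op, and conserve", {
  acts <- action_tuples(sigma = c("v1-0", "v1-1"),
                        action = c("form_word", "request_letter"),
                        initiator = "v1", target = c(NA, "v2"),
                        time = c(2, 4))
  ph <- hand_phase(actions = acts, t_p = 5)
  ds <- discrete_action_sequence(ph)
  expect_equal(unname(ds$sequences["v1", ]), c(1, 4, 1, 2, 1))
  expect_equal(unname(ds$sequences["v2", ]), rep(1, 5))   # all no-op
  expect_equal(ds$code_map,
               c(thinking = 1L, request_letter = 2L, reply_letter = 3L,
                 form_word = 4L))
  # conservation: per-code counts = action totals + no-op fill
  counts <- tabulate(ds$sequences, 4)
  expect_equal(counts[4], 1)
  expect_equal(counts[2], 1)
  expect_equal(counts[1], 3 * 5 - 2)
  expect_error(discrete_action_sequence(ph, resolution = 0.7), "whole bins")
})

test_that("collisions within a bin resolve latest-wins and are preserved", {
  acts <- action_tuples(sigma = c("v1-0", "v1-1"),
                        action = c("request_letter", "form_word"),
                        initiator = "v1", target = c("v2", NA),
                        time = c(1.2, 1.9))
  ph <- hand_phase(actions = acts, t_p = 5)
  ds <- discrete_action_sequence(ph)
  expect_equal(unname(ds$sequences["v1", 2]), 4L)   # latest (form word) wins
  expect_equal(nrow(ds$collisions), 1)
  expect_equal(ds$collisions$displaced_code, 2L)
})

test_that("windowed averages reduce to totals for one experiment and average across two", {
  acts <- action_tuples(sigma = make_sequence_id("v1", 0:2),
                        action = "request_letter", initiator = "v1",
                        target = "v2", time = c(5, 15, 25))
  ph1 <- hand_phase(actions = acts, t_p = 30)
  w1 <- windowed_average(list(ph1), "request_letter", s = 10)
  expect_equal(w1$mean_count, c(1, 1, 1))
  expect_equal(windowed_average(list(ph1, ph1), "request_letter", 10)$mean_count,
               w1$mean_count)                       # idempotent mean
  acts2 <- action_tuples(sigma = "v2-0", action = "request_letter",
                         initiator = "v2", target = "v3", time = 5)
  ph2 <- hand_phase(actions = acts2, t_p = 30)
  w <- windowed_average(list(ph1, ph2), "request_letter", 10)
  expect_equal(w$mean_count, c(1, 0.5, 0.5))
})

test_that("related-action summaries bound occurred by possible", {
  # complete graph on 3 nodes: 6 directed pairs per interactive action
  nodes <- c("v1", "v2", "v3")
  edges <- t(utils::combn(nodes, 2))
  acts <- action_tuples(sigma = "v1-0", action = "request_letter",
                        initiator = "v1", target = "v2", time = 1)
  ph <- hand_phase(actions = acts, nodes = nodes, edges = edges)
  rs <- related_action_summary(ph)
  expect_equal(rs$possible[rs$action == "request_letter"], 6)
  expect_equal(rs$occurred[rs$action == "request_letter"], 1)
  # empty network
  ph0 <- hand_phase(edges = NULL)
  rs0 <- related_action_summary(ph0)
  expect_true(all(rs0$possible == 0))
  # random fixtures: occurred <= possible
  ses <- cached_session()
  ph2 <- edtp_transform(ses$raw)$phases[[2]]
  rs2 <- related_action_summary(ph2)
  expect_true(all(rs2$occurred <= pmax(rs2$possible, 0) |
                    rs2$possible == 0))
  inter <- rs2[rs2$action %in% c("request_letter", "reply_letter"), ]
  expect_true(all(inter$occurred <= inter$possible))
})

test_that("the analyst scoring hook applies a custom metric per tuple", {
  acts <- action_tuples(sigma = c("v1-0", "v1-1"), action = "form_word",
                        initiator = "v1", time = c(1, 2),
                        payload = list(list(word = "cat"), list(word = "horse")))
  ph <- hand_phase(actions = acts)
  sc <- score_actions(ph, "form_word", function(payload, row) nchar(payload$word))
  expect_equal(sc$score, c(3, 5))
})
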
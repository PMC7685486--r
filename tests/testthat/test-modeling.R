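test_that("transition-matrix estimation counts hand-checkable transitions", {
  tm <- estimate_transition_matrix(list(c(1, 1, 1, 1)), m = 2)
  expect_equal(tm$pi[1, 1], 1)
  expect_false(tm$defined[2])
  expect_true(all(is.na(tm$pi[2, ])))

  tm <- estimate_transition_matrix(list(c(1, 2, 1, 2, 1)), m = 2)
  expect_equal(tm$pi[1, 2], 1)
  expect_equal(tm$pi[2, 1], 1)

  # no cross-sequence transitions: two sequences vs their concatenation differ
  tm2 <- estimate_transition_matrix(list(c(1, 2), c(2, 1)), m = 2)
  expect_equal(tm2$counts[1, 2], 1)
  expect_equal(tm2$counts[2, 2], 0)

  expect_error(estimate_transition_matrix(list(1:3), m = 1), "at least m = 2")
  expect_warning(estimate_transition_matrix(list(c(1, 2), c(1)), m = 2),
                 "skipping")

  # every defined row sums to 1
  set.seed(8)
  seqs <- lapply(1:4, function(i) sample.int(4, 100, replace = TRUE))
  tm <- estimate_transition_matrix(seqs, 4)
  expect_true(all(abs(rowSums(tm$pi)[tm$defined] - 1) < 1e-9))
  # smoothing defines all rows
  tma <- estimate_transition_matrix(list(c(1, 1)), m = 3, alpha = 1)
  expect_true(all(tma$defined))
  expect_true(all(abs(rowSums(tma$pi) - 1) < 1e-9))
})

test_that("intercept-only multinomial logit reproduces empirical frequencies", {
  for (s in 1:3) {
    set.seed(100 + s)
    seqs <- lapply(1:5, function(i) sample.int(4, 150, replace = TRUE))
    tm <- estimate_transition_matrix(seqs, 4)
    fit <- fit_behavior_logit(seqs, 4)
    for (i in 1:4) {
      expect_equal(predict_transition_row(fit, i), unname(tm$pi[i, ]),
                   tolerance = 1e-6)
    }
  }
})

test_that("degenerate transition classes are reported at the boundary", {
  # action 1 is always followed by action 2
  seqs <- list(c(1, 2, 1, 2), c(1, 2, 2, 1, 2))
  fit <- fit_behavior_logit(seqs, 2)
  expect_true(fit$sources[["1"]]$degenerate)
  expect_match(fit$sources[["1"]]$diagnostic, "boundary")
  expect_equal(predict_transition_row(fit, 1), c(0, 1))
})

test_that("known logit coefficients are recovered from simulated data", {
  set.seed(77)
  n_steps <- 5000
  beta <- rbind(c(-0.5, 0.8),    # class 2 vs baseline: intercept, slope
                c(0.3, -0.6))    # class 3 vs baseline
  x <- rnorm(n_steps)
  s <- integer(n_steps + 1); s[1] <- 1L
  for (t in seq_len(n_steps)) {
    lp <- c(0, beta[, 1] + beta[, 2] * x[t])
    p <- exp(lp) / sum(exp(lp))
    s[t + 1] <- sample.int(3, 1, prob = p)
  }
  fit <- fit_behavior_logit(list(s), m = 3,
                            covariates = function(si, t) c(x = x[t]))
  for (i in as.character(1:3)) {
    src <- fit$sources[[i]]
    expect_false(src$degenerate)
    expect_true(all(abs(src$coefficients - beta) <= 3 * src$std_errors))
  }
})

test_that("predicted rows are proper distributions", {
  set.seed(5)
  seqs <- lapply(1:3, function(i) sample.int(4, 80, replace = TRUE))
  fit <- fit_behavior_logit(seqs, 4)
  for (i in 1:4) {
    p <- predict_transition_row(fit, i)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(sum(p), 1)
  }
  expect_error(predict_transition_row(fit, 9), "cannot predict")
})

test_that("an absorbing thinking row produces a silent ABM", {
  Pi <- diag(4); Pi[1, ] <- c(1, 0, 0, 0)
  abm <- simulate_anagram_abm(abm_config(6, 5, Pi = Pi, seed = 1,
                                         duration = 50))
  expect_equal(nrow(abm$actions), 0)
  expect_true(all(abm$sequences == 1))
})

test_that("ABM action frequencies converge to the stationary distribution of Pi", {
  Pi <- fixture_pi()
  pooled <- integer(0)
  # 6 players x 300 steps x 56 sessions > 1e5 pooled steps
  for (s in 1:56) {
    abm <- simulate_anagram_abm(abm_config(6, 5, Pi = Pi, duration = 300,
                                           seed = 2000 + s))
    pooled <- c(pooled, as.vector(abm$sequences))
  }
  expect_gte(length(pooled), 1e5)
  freq <- tabulate(pooled, 4) / length(pooled)
  expect_lt(max(abs(freq - stationary_eigen(Pi))), 0.02)
})

test_that("the n = 6, d = 5 ABM emits a validating phase record", {
  abm <- simulate_anagram_abm(abm_config(6, 5, Pi = fixture_pi(),
                                         duration = 120, seed = 9))
  expect_true(all(graph_degrees(abm$graph) == 5))
  expect_silent(validate_phase_record(abm$phase))
  reg <- default_schema_registry()
  docs <- common_spec_to_docs(list(
    experiment = experiment_record("sim", 1, abm$phase$nodes,
                                   abm$phase$t_ph_begin,
                                   format_iso8601(parse_iso8601(abm$phase$t_ph_begin) + 120)),
    phases = list(abm$phase)))
  for (comp in names(docs)) {
    expect_equal(validate_instance(docs[[comp]], comp, reg)$verdict, 1L)
  }
  # reply tuples either serve a real request (shared sigma) or are flagged
  replies <- abm$actions[abm$actions$action == "reply_letter", ]
  requests <- abm$actions[abm$actions$action == "request_letter", ]
  served <- replies$sigma %in% requests$sigma
  unsolicited <- vapply(replies$payload, function(p)
    isTRUE(p$unsolicited), logical(1))
  expect_true(all(served | unsolicited))
})

test_that("KL divergence has its closed-form values and Gibbs nonnegativity", {
  expect_equal(kl_divergence(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5), epsilon = 0), log(2))
  expect_error(kl_divergence(c(1, 0), c(1, 0, 0)), "same length")
  set.seed(14)
  for (rep in 1:1000) {
    k <- sample(2:8, 1)
    p <- runif(k); q <- runif(k)
    expect_gte(kl_divergence(p / sum(p), q / sum(q)), 0)
  }
})

test_that("experiment-model comparison reports per-statistic KL with paired tables", {
  obs <- list(hist = c(4, 3, 1), counts = c(10, 2))
  sim <- list(hist = c(2, 4, 2), counts = c(10, 2), extra = c(1))
  rep <- compare_experiment_model(obs, sim)
  expect_setequal(rep$statistic, c("hist", "counts"))
  expect_equal(rep$kl[rep$statistic == "counts"], 0, tolerance = 1e-6)
  expect_equal(rep$kl[rep$statistic == "hist"],
               kl_divergence(c(4, 3, 1), c(2, 4, 2)))
  expect_named(attr(rep, "tables"), c("hist", "counts"))
  expect_error(compare_experiment_model(list(a = 1), list(b = 1)),
               "no shared")
})

test_that("R-squared matches hand computations and rejects degenerate input", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)   # mean predictor
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)  # SS_res 1, SS_tot 2
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r_squared(1:3, 1:4), "lengths")
})

test_that("k-fold partitions cover each index exactly once with balanced sizes", {
  f <- k_fold_indices(10, 5, seed = 1)
  expect_equal(unname(vapply(f, length, integer(1))), rep(2L, 5))
  f <- k_fold_indices(10, 3, seed = 1)
  expect_setequal(unname(vapply(f, length, integer(1))), c(4L, 3L, 3L))
  for (case in list(c(10, 5), c(10, 3), c(7, 7))) {
    f <- k_fold_indices(case[1], case[2], seed = 2)
    expect_equal(sort(unlist(f)), seq_len(case[1]))
  }
  expect_error(k_fold_indices(3, 4, seed = 1), "exceed")
  expect_identical(k_fold_indices(20, 4, seed = 9), k_fold_indices(20, 4, seed = 9))
})

test_that("cross-validation scores every sequence exactly once", {
  set.seed(23)
  seqs <- lapply(1:6, function(i) sample.int(4, 60, replace = TRUE))
  cv <- cross_validate(seqs, k = 6, seed = 3)         # leave-one-out
  expect_equal(nrow(cv), 6)
  expect_equal(sum(cv$n_sequences), 6)
  expect_equal(sum(cv$n_transitions), 6 * 59)
  expect_true(all(is.finite(cv$loglik)))
  # identical sequences give equal fold scores
  same <- rep(list(c(1, 2, 3, 4, 1, 2, 3, 4)), 4)
  cv2 <- cross_validate(same, k = 4, seed = 1)
  expect_lt(diff(range(cv2$loglik)), 1e-9)
  # fixed-seed reproducibility
  expect_identical(cross_validate(seqs, k = 3, seed = 7),
                   cross_validate(seqs, k = 3, seed = 7))
  expect_error(cross_validate(seqs, k = 9, seed = 1), "exceed")
})
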
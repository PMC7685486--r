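# ---------------------------------------------------------------------------
# Property inference, agent-based simulation, and model evaluation.
#
# The behavior model is a first-order Markov chain on the action codes: a
# row-stochastic m x m transition matrix Pi with pi_ij = Pr(a(t+1) = j |
# a(t) = i), estimated from the discrete action sequences and optionally
# parameterized by a baseline-category multinomial logit.
# ---------------------------------------------------------------------------

as_sequence_list <- function(sequences) {
  if (inherits(sequences, "discrete_sequences")) {
    sequences <- sequences$sequences
  }
  if (is.matrix(sequences)) {
    sequences <- lapply(seq_len(nrow(sequences)), function(i) sequences[i, ])
  }
  lapply(sequences, function(s) as.integer(unname(unlist(s))))
}

#' Estimate a Markov transition matrix from action sequences
#'
#' Pools i -> j transition counts across sequences (never across sequence
#' boundaries) and forms `pi_ij = (c_ij + alpha) / (c_i. + m * alpha)`.
#' With `alpha = 0` this is the maximum-likelihood estimate; rows with no
#' observations are then undefined (`NA`) and flagged.
#'
#' @param sequences A list of integer-coded vectors, a matrix (one sequence
#'   per row), or a `discrete_sequences` object from
#'   [discrete_action_sequence()]. Codes must lie in `1..m`. Sequences
#'   shorter than 2 are skipped with a warning.
#' @param m Number of action codes (>= 2).
#' @param alpha Additive smoothing constant (default 0).
#' @return An object of class `transition_matrix`: `pi` (m x m), `counts`,
#'   `row_counts`, `defined` (logical per row), `m`, `alpha`.
#' @export
estimate_transition_matrix <- function(sequences, m, alpha = 0) {
  if (m < 2) stop("a transition matrix needs at least m = 2 actions")
  stopifnot(alpha >= 0)
  seqs <- as_sequence_list(sequences)
  short <- vapply(seqs, length, integer(1)) < 2
  if (any(short)) {
    warning(sprintf("skipping %d sequence(s) shorter than 2", sum(short)))
    seqs <- seqs[!short]
  }
  counts <- matrix(0, m, m)
  for (s in seqs) {
    if (any(s < 1 | s > m)) stop("sequence codes must lie in 1..m")
    from <- s[-length(s)]; to <- s[-1]
    counts <- counts + matrix(tabulate((from - 1L) * m + to, nbins = m * m),
                              m, m, byrow = TRUE)
  }
  row_counts <- rowSums(counts)
  defined <- row_counts > 0 | alpha > 0
  pi <- (counts + alpha) / (row_counts + m * alpha)
  pi[!defined, ] <- NA_real_
  dimnames(pi) <- dimnames(counts) <- list(paste0("a", 1:m), paste0("a", 1:m))
  structure(list(pi = pi, counts = counts, row_counts = row_counts,
                 defined = defined, m = m, alpha = alpha),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> m = %d, alpha = %g, %d of %d rows defined\n",
              x$m, x$alpha, sum(x$defined), x$m))
  print(round(x$pi, 4))
  invisible(x)
}

#' Export a transition matrix or logit fit as block-layout CSV
#'
#' One block of rows per source action: the source, the destination, and
#' the estimate (probability or coefficient).
#'
#' @param x A `transition_matrix` or `behavior_logit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transition_csv <- function(x, path) {
  if (inherits(x, "transition_matrix")) {
    df <- expand.grid(to = seq_len(x$m), from = seq_len(x$m))[, 2:1]
    df$probability <- as.vector(t(x$pi))[(df$from - 1) * x$m + df$to]
    utils::write.csv(df, path, row.names = FALSE)
  } else if (inherits(x, "behavior_logit")) {
    rows <- list()
    for (i in names(x$sources)) {
      src <- x$sources[[i]]
      if (!is.null(src$coefficients)) {
        cf <- src$coefficients
        for (r in seq_len(nrow(cf))) {
          for (c in seq_len(ncol(cf))) {
            rows[[length(rows) + 1L]] <- data.frame(
              from = as.integer(i), to = as.integer(rownames(cf)[r]),
              term = colnames(cf)[c], beta = cf[r, c])
          }
        }
      }
    }
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}

softmax <- function(lp) {
  e <- exp(lp - max(lp))
  e / sum(e)
}

#' Fit a baseline-category multinomial logit behavior model
#'
#' For each current action `i`, fits a multinomial logistic regression of
#' the next action on the supplied covariates (intercept-only by default),
#' with action 1 (the no-op, "thinking") as the baseline category. With no
#' covariates the fitted probabilities equal the empirical transition
#' frequencies of [estimate_transition_matrix()].
#'
#' @param sequences As in [estimate_transition_matrix()].
#' @param m Number of action codes.
#' @param covariates Optional per-step covariate extractor: a function
#'   `(sequence_index, step)` returning a named numeric vector, evaluated
#'   at the step *before* each transition. `NULL` for intercept-only.
#' @param baseline Baseline action code (default 1).
#' @param maxit,reltol Optimizer controls passed to [nnet::multinom()].
#' @return An object of class `behavior_logit`: per-source coefficient
#'   blocks, class levels, convergence diagnostics.
#' @export
fit_behavior_logit <- function(sequences, m, covariates = NULL, baseline = 1L,
                               maxit = 2000, reltol = 1e-14) {
  seqs <- as_sequence_list(sequences)
  seqs <- seqs[vapply(seqs, length, integer(1)) >= 2]
  if (length(seqs) == 0) stop("no sequences of length >= 2 to fit")
  rows <- list()
  for (si in seq_along(seqs)) {
    s <- seqs[[si]]
    for (t in seq_len(length(s) - 1L)) {
      cv <- if (is.null(covariates)) numeric(0) else covariates(si, t)
      rows[[length(rows) + 1L]] <- c(current = s[t], nxt = s[t + 1L], cv)
    }
  }
  steps <- as.data.frame(do.call(rbind, rows))
  covar_names <- setdiff(names(steps), c("current", "nxt"))

  sources <- list()
  for (i in sort(unique(steps$current))) {
    sub <- steps[steps$current == i, , drop = FALSE]
    classes <- sort(unique(sub$nxt))
    if (length(classes) == 1L) {
      sources[[as.character(i)]] <- list(
        degenerate = TRUE, classes = classes, n = nrow(sub),
        coefficients = NULL, std_errors = NULL, converged = TRUE,
        diagnostic = sprintf(
          "all %d transitions from action %d go to action %d (boundary estimate)",
          nrow(sub), i, classes))
      next
    }
    lev <- as.character(classes)
    if (as.character(baseline) %in% lev) {
      lev <- c(as.character(baseline), setdiff(lev, as.character(baseline)))
    }
    sub$nxt_f <- factor(as.character(sub$nxt), levels = lev)
    fml <- if (length(covar_names) == 0) nxt_f ~ 1 else
      stats::as.formula(paste("nxt_f ~", paste(covar_names, collapse = " + ")))
    fit <- nnet::multinom(fml, data = sub, trace = FALSE,
                          maxit = maxit, reltol = reltol)
    converged <- fit$convergence == 0
    if (!converged) {
      stop(sprintf(
        "multinomial logit for source action %d did not converge; fit withheld", i))
    }
    cf <- stats::coef(fit)
    if (is.null(dim(cf))) {  # two classes: coerce to one-row matrix
      cf <- matrix(cf, nrow = 1, dimnames = list(lev[2], names(fit$coefnames)))
      colnames(cf) <- fit$coefnames
    }
    se <- tryCatch(summary(fit)$standard.errors, error = function(e) NULL)
    if (!is.null(se) && is.null(dim(se))) {
      se <- matrix(se, nrow = 1, dimnames = dimnames(cf))
    }
    big <- max(abs(cf))
    sources[[as.character(i)]] <- list(
      degenerate = FALSE, classes = classes, levels = lev, n = nrow(sub),
      coefficients = cf, std_errors = se, converged = converged,
      diagnostic = if (big > 30)
        "coefficients near the boundary (possible separation)" else NA_character_)
  }
  structure(list(sources = sources, m = m, baseline = baseline,
                 covariate_names = covar_names),
            class = "behavior_logit")
}

#' @export
print.behavior_logit <- function(x, ...) {
  cat(sprintf("<behavior_logit> m = %d, baseline = a%d, covariates: %s\n",
              x$m, x$baseline,
              if (length(x$covariate_names)) paste(x$covariate_names, collapse = ", ")
              else "(intercept only)"))
  for (i in names(x$sources)) {
    src <- x$sources[[i]]
    cat(sprintf("  from a%s: n = %d%s\n", i, src$n,
                if (isTRUE(src$degenerate)) " [degenerate]" else ""))
  }
  invisible(x)
}

#' Predicted next-action probabilities from a logit fit
#'
#' Softmax over the baseline-anchored linear predictors for one current
#' action; probabilities over all `m` actions (actions never observed as a
#' destination from this source receive probability 0).
#'
#' @param fit A `behavior_logit`.
#' @param current Current action code.
#' @param covariates Named numeric vector of covariate values (must cover
#'   the fit's covariates); ignored for intercept-only fits.
#' @return Numeric probability vector of length `m`, summing to 1.
#' @export
predict_transition_row <- function(fit, current, covariates = NULL) {
  src <- fit$sources[[as.character(current)]]
  if (is.null(src)) {
    stop(sprintf("no transitions from action %s were observed; cannot predict",
                 as.character(current)))
  }
  p <- numeric(fit$m)
  if (isTRUE(src$degenerate)) {
    p[src$classes] <- 1
    return(p)
  }
  x <- 1  # intercept
  if (length(fit$covariate_names) > 0) {
    if (is.null(covariates) || !all(fit$covariate_names %in% names(covariates))) {
      stop("covariate values required: ",
           paste(fit$covariate_names, collapse = ", "))
    }
    x <- c(1, covariates[fit$covariate_names])
  }
  lp <- c(0, as.vector(src$coefficients %*% x))
  probs <- softmax(lp)
  p[as.integer(src$levels)] <- probs
  p
}

# ---- agent-based model ----------------------------------------------------

#' Configuration for the anagram-game agent-based model
#'
#' @param n Number of players.
#' @param d Regular degree of the communication network (`d < n`, `n*d`
#'   even); `d = n - 1` gives the complete graph.
#' @param Pi Row-stochastic m x m transition matrix (a `transition_matrix`
#'   or plain matrix) driving each player's action chain.
#' @param fit Alternatively, a `behavior_logit` whose predictions drive the
#'   chain (intercept-only fits only).
#' @param duration Number of 1-unit time steps (default 300: a 5-minute
#'   game at 1-second steps).
#' @param letters_per_player Initial letters dealt to each player
#'   (default 3).
#' @param seed Integer seed.
#' @return A list of class `abm_config`.
#' @export
abm_config <- function(n, d, Pi = NULL, fit = NULL, duration = 300,
                       letters_per_player = 3, seed = NULL) {
  stopifnot(d < n, (n * d) %% 2 == 0, duration >= 1)
  if (is.null(Pi) && is.null(fit)) stop("supply a transition matrix or a logit fit")
  if (!is.null(Pi)) {
    if (inherits(Pi, "transition_matrix")) Pi <- Pi$pi
    Pi <- as.matrix(Pi)
    if (nrow(Pi) != ncol(Pi)) stop("Pi must be square")
    if (anyNA(Pi) || any(Pi < 0)) stop("Pi must be fully defined and nonnegative")
    if (any(abs(rowSums(Pi) - 1) > 1e-8)) stop("Pi rows must sum to 1")
  }
  structure(list(n = n, d = d, Pi = Pi, fit = fit, duration = duration,
                 letters_per_player = letters_per_player, seed = seed),
            class = "abm_config")
}

#' Simulate the anagram game as a Markov-chain agent-based model
#'
#' Players sit on a d-regular communication network. Each player carries a
#' current action state (starting at thinking) and at each 1-unit step
#' draws its next action from the transition-matrix row of its current
#' action. Draws map to action tuples: a request goes to a uniform random
#' neighbor for a uniform random letter under a fresh sequence id; a reply
#' serves the oldest pending incoming request under that request's
#' sequence id (an unsolicited reply -- empty queue -- picks a uniform
#' neighbor and letter and is flagged in its payload, so every non-thinking
#' draw emits exactly one tuple); a formed word concatenates letters the
#' player holds. Thinking emits nothing.
#'
#' @param config An [abm_config()].
#' @param ph_sch_id,exp_id Identifiers stamped into the emitted phase
#'   record.
#' @param t_ph_begin Phase begin timestamp.
#' @return A list of class `abm_result`: `actions` (action tuples),
#'   `phase` (a validated [phase_record()]), `sequences` (players x
#'   duration matrix of drawn action codes), `graph`, `config`.
#' @export
simulate_anagram_abm <- function(config, ph_sch_id = "sim-phase2",
                                 exp_id = "sim",
                                 t_ph_begin = "2026-01-01T00:00:00Z") {
  stopifnot(inherits(config, "abm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n; d <- config$d
  players <- default_node_ids(n)
  graph <- if (d == n - 1) {
    ness_graph(players, t(utils::combn(players, 2)))
  } else {
    make_random_regular(n, d, seed = NULL)
  }
  adj <- adjacency_list(graph)
  m <- if (!is.null(config$Pi)) nrow(config$Pi) else config$fit$m
  pi_rows <- if (!is.null(config$Pi)) config$Pi else {
    t(vapply(seq_len(m), function(i) {
      if (is.null(config$fit$sources[[as.character(i)]])) {
        stop(sprintf("logit fit has no block for source action %d", i))
      }
      predict_transition_row(config$fit, i)
    }, numeric(m)))
  }

  letters0 <- setNames(lapply(players, function(p)
    sample(LETTERS, config$letters_per_player, replace = TRUE)), players)
  held <- letters0
  queues <- setNames(vector("list", n), players)   # pending incoming requests
  counters <- setNames(integer(n), players)
  state <- setNames(rep(1L, n), players)
  seqs <- matrix(1L, nrow = n, ncol = config$duration,
                 dimnames = list(players, NULL))

  sigma <- character(0); act <- character(0); init <- character(0)
  targ <- character(0); tim <- numeric(0); payl <- list()
  emit <- function(sg, a, v, w, t, p) {
    k <- length(sigma) + 1L
    sigma[k] <<- sg; act[k] <<- a; init[k] <<- v
    targ[k] <<- if (is.null(w)) NA_character_ else w
    tim[k] <<- t; payl[[k]] <<- p
  }

  for (t in seq_len(config$duration)) {
    for (v in players) {
      nxt <- sample.int(m, 1L, prob = pi_rows[state[[v]], ])
      seqs[v, t] <- nxt
      if (nxt == 2L) {                       # request a letter
        w <- if (length(adj[[v]]) == 1) adj[[v]] else sample(adj[[v]], 1L)
        letter <- sample(LETTERS, 1L)
        sg <- make_sequence_id(v, counters[[v]])
        counters[[v]] <- counters[[v]] + 1L
        emit(sg, "request_letter", v, w, t, list(letter = letter))
        queues[[w]] <- c(queues[[w]],
                         list(list(sigma = sg, from = v, letter = letter)))
      } else if (nxt == 3L) {                # reply to the oldest request
        if (length(queues[[v]]) > 0) {
          req <- queues[[v]][[1]]
          queues[[v]] <- queues[[v]][-1]
          emit(req$sigma, "reply_letter", v, req$from, t,
               list(letter = req$letter))
          held[[req$from]] <- c(held[[req$from]], req$letter)
        } else {                             # unsolicited reply
          w <- if (length(adj[[v]]) == 1) adj[[v]] else sample(adj[[v]], 1L)
          letter <- sample(LETTERS, 1L)
          sg <- make_sequence_id(v, counters[[v]])
          counters[[v]] <- counters[[v]] + 1L
          emit(sg, "reply_letter", v, w, t,
               list(letter = letter, unsolicited = TRUE))
        }
      } else if (nxt == 4L) {                # form a word
        avail <- held[[v]]
        word <- paste(sample(avail, min(3L, length(avail)), replace = TRUE),
                      collapse = "")
        sg <- make_sequence_id(v, counters[[v]])
        counters[[v]] <- counters[[v]] + 1L
        emit(sg, "form_word", v, NULL, t, list(word = word))
      }
      state[[v]] <- nxt
    }
  }

  actions <- action_tuples(sigma = sigma, action = act, initiator = init,
                           target = targ, time = tim, payload = payl)
  phase <- phase_record(
    ph_sch_id = ph_sch_id, exp_id = exp_id, seq_index = 1L,
    t_ph_begin = t_ph_begin, t_p = config$duration, u_p = "seconds",
    nodes = players, edges = graph$edges,
    edge_meanings = "communication channel",
    node_initial_conditions = lapply(letters0, function(l) list(letters = as.list(l))),
    action_set = c("thinking", "request_letter", "reply_letter", "form_word"),
    actions = actions)
  structure(list(actions = actions, phase = phase, sequences = seqs,
                 graph = graph, config = config),
            class = "abm_result")
}

# ---- model evaluation -----------------------------------------------------

#' Kullback-Leibler divergence between two discrete distributions
#'
#' Adds `epsilon` to every cell of both vectors, renormalizes each, and
#' returns `sum(p * ln(p/q))` in nats with the convention `0 * ln 0 = 0`.
#' Nonnegative by Gibbs' inequality; 0 iff the smoothed distributions are
#' equal.
#'
#' @param p,q Nonnegative numeric vectors of equal length.
#' @param epsilon Symmetric smoothing constant (default `1e-10`); pass 0
#'   for the unsmoothed divergence (which may be infinite).
#' @return Nonnegative numeric scalar (nats).
#' @export
kl_divergence <- function(p, q, epsilon = 1e-10) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) stop("p and q must be nonnegative")
  p <- p + epsilon; q <- q + epsilon
  if (sum(p) == 0 || sum(q) == 0) stop("cannot normalize an all-zero vector")
  p <- p / sum(p); q <- q / sum(q)
  terms <- ifelse(p == 0, 0, p * log(p / q))
  sum(terms)
}

#' Compare experiment summaries with simulation summaries
#'
#' For every statistic shared by both summary sets (e.g. per-bin action
#' histograms), reports the Kullback-Leibler divergence of observed from
#' simulated, alongside the paired tables.
#'
#' @param observed,simulated Named lists of nonnegative numeric vectors
#'   with matching names and lengths.
#' @param epsilon Smoothing constant for [kl_divergence()].
#' @return Data frame with columns `statistic`, `kl`; the paired vectors
#'   are attached as attribute `"tables"` (a named list of data frames
#'   with columns `bin`, `observed`, `simulated`).
#' @export
compare_experiment_model <- function(observed, simulated, epsilon = 1e-10) {
  shared <- intersect(names(observed), names(simulated))
  if (length(shared) == 0) stop("no shared statistics to compare")
  tables <- list()
  kl <- vapply(shared, function(s) {
    o <- as.numeric(observed[[s]]); m <- as.numeric(simulated[[s]])
    if (length(o) != length(m)) {
      stop(sprintf("statistic '%s' has mismatched binning", s))
    }
    tables[[s]] <<- data.frame(bin = seq_along(o), observed = o, simulated = m)
    kl_divergence(o, m, epsilon)
  }, numeric(1))
  out <- data.frame(statistic = shared, kl = unname(kl),
                    stringsAsFactors = FALSE)
  attr(out, "tables") <- tables
  attr(out, "epsilon") <- epsilon
  out
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`; at most 1, and negative when the
#' predictions do worse than the observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2);
#'   `observed` must not be constant.
#' @return Numeric scalar `<= 1`.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("lengths must match")
  if (length(observed) < 2) stop("need at least 2 observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values are constant; R-squared undefined")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Random k-fold partition of indices
#'
#' Splits a seeded random permutation of `1..n` into `k` groups whose sizes
#' differ by at most one; every index lands in exactly one group.
#'
#' @param n Number of observations.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed.
#' @return List of `k` integer vectors partitioning `1..n`.
#' @export
k_fold_indices <- function(n, k, seed) {
  if (k > n) stop("k must not exceed n")
  if (k < 2) stop("k must be at least 2")
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  unname(lapply(split(perm, rep(seq_len(k), times = sizes)), unname))
}

sequence_loglik <- function(tm, seqs) {
  ll <- 0; n_trans <- 0L
  for (s in seqs) {
    if (length(s) < 2) next
    from <- s[-length(s)]; to <- s[-1]
    ll <- ll + sum(log(tm$pi[cbind(from, to)]))
    n_trans <- n_trans + length(from)
  }
  list(loglik = ll, n_transitions = n_trans)
}

#' k-fold cross-validation of the Markov behavior model
#'
#' Partitions the sequences into k folds; each fold is scored (held-out
#' log-likelihood of its transitions) under a transition matrix estimated
#' from the other folds. Smoothing is forced positive so held-out
#' transitions unseen in training remain scoreable.
#'
#' @param sequences As in [estimate_transition_matrix()].
#' @param k Number of folds (`2 <= k <=` number of sequences).
#' @param seed Integer seed for the fold assignment.
#' @param m Number of action codes (default: largest code observed).
#' @param alpha Smoothing used for the training fits (default 1; must be
#'   > 0).
#' @return Data frame with one row per fold: `fold`, `n_sequences`,
#'   `n_transitions`, `loglik`, `mean_loglik` (per transition).
#' @export
cross_validate <- function(sequences, k, seed, m = NULL, alpha = 1) {
  stopifnot(alpha > 0)
  seqs <- as_sequence_list(sequences)
  if (k > length(seqs)) stop("k must not exceed the number of sequences")
  if (is.null(m)) m <- max(unlist(seqs))
  folds <- k_fold_indices(length(seqs), k, seed)
  rows <- lapply(seq_along(folds), function(i) {
    test <- seqs[folds[[i]]]
    train <- seqs[-folds[[i]]]
    tm <- estimate_transition_matrix(train, m = m, alpha = alpha)
    sc <- sequence_loglik(tm, test)
    data.frame(fold = i, n_sequences = length(test),
               n_transitions = sc$n_transitions, loglik = sc$loglik,
               mean_loglik = sc$loglik / max(1L, sc$n_transitions))
  })
  do.call(rbind, rows)
}
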
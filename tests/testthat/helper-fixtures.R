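# Shared fixtures, built lazily and cached for the whole test run.

# A clean (noise- and jitter-free) 12-trial session plus its template.
clean_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(target_sequence = rep(0:3, 3),
                               noise_sd = 0, latency_jitter = 0,
                               amplitude_variability = 0, seed = 7)
      session <- simulate_session(cfg)
      template <- template_from_session(session, n = 10)
      cache <<- list(session = session, template = template,
                     epochs = session_epochs(session))
    }
    cache
  }
})

# A trained model at the default study conditions: 160 training trials
# (each target 40 times), default noise and jitter.  Shared across tests
# because backpropagation is the slow step.
trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(target_sequence = rep(0:3, each = 40),
                               seed = 11)
      session <- simulate_session(cfg)
      fit <- train_from_session(session, max_epochs = 6000,
                                learning_rate = 0.05, seed = 42)
      cache <<- list(session = session, fit = fit, model = fit$model)
    }
    cache
  }
})

# Independent reference for the accuracy-mode voting rule, written from
# the verbal description: track the legal labels since the last decision
# and decide a label as soon as it occurs twice among the last three.
reference_am <- function(labels) {
  history <- integer(0)
  decisions <- rep(NA_integer_, length(labels))
  for (i in seq_along(labels)) {
    history <- c(history, labels[i])
    window <- utils::tail(history, 3)
    dup <- window[duplicated(window)]
    if (length(dup) > 0) {
      decisions[i] <- dup[1]
      history <- integer(0)
    }
  }
  decisions
}

# Drive the packaged automaton over a label sequence.
run_am <- function(labels) {
  state <- new_am_state()
  decisions <- rep(NA_integer_, length(labels))
  for (i in seq_along(labels)) {
    st <- am_step(state, labels[i])
    state <- st$state
    decisions[i] <- st$decision
  }
  decisions
}

# A model whose output is a constant, regardless of input: handy for
# driving the decision layer to chosen scores.
constant_model <- function(score, template, n = 31, m = 15,
                           threshold = 0.6) {
  ffnn_model(w = matrix(0, m, n), b = rep(0, m), Hw = rep(0, m),
             Ob = score, threshold = threshold, template = template)
}
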
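test_that("the worked-example scores give a legal trial selecting stimulus 2", {
  d <- judge_trial(c(0.2910, 0.9473, 0.2493, 0.0233), threshold = 0.6)
  expect_equal(d$status, "legal")
  expect_equal(d$selected, 2)
  expect_equal(stimulus_command(d$selected), "right-turn")
})

test_that("multiple or no supra-threshold outputs are illegal", {
  expect_equal(judge_trial(c(0.7, 0.8, 0.1, 0.1))$status, "illegal_multiple")
  expect_equal(judge_trial(c(0.1, 0.2, 0.3, 0.4))$status, "illegal_none")
  expect_true(is.na(judge_trial(c(0.7, 0.8, 0.1, 0.1))$selected))
  # threshold is strict: a score exactly at 0.6 does not count
  expect_equal(judge_trial(c(0.6, 0.2, 0.2, 0.2))$status, "illegal_none")
  expect_error(judge_trial(c(0.7, 0.2)), "exactly 4")
})

test_that("voting follows routes (a)-(d) of the two-of-three rule", {
  expect_equal(run_am(c(1, 1)), c(NA, 1))                 # route a
  expect_equal(run_am(c(1, 2, 1)), c(NA, NA, 1))          # route b
  expect_equal(run_am(c(1, 2, 2)), c(NA, NA, 2))          # route c
  expect_equal(run_am(c(1, 2, 3, 3)), c(NA, NA, NA, 3))   # route d, then a
  expect_equal(run_am(c(1, 2, 3, 2)), c(NA, NA, NA, 2))   # route d, window [2,3]
})

test_that("the voting automaton matches the verbal-rule reference exhaustively", {
  # every label sequence of length 6 over four stimuli
  grid <- expand.grid(rep(list(1:4), 6))
  for (i in seq_len(nrow(grid))) {
    labels <- as.integer(grid[i, ])
    expect_identical(run_am(labels), reference_am(labels))
  }
  # a decision always needs at least two legal trials
  for (l in 1:4) expect_true(is.na(run_am(l)))
})

test_that("the vote window never holds more than two pending labels", {
  set.seed(15)
  state <- new_am_state()
  for (i in 1:500) {
    st <- am_step(state, sample(1:4, 1))
    state <- st$state
    expect_lte(length(state$vote_window), 2)
    if (!is.na(st$decision)) expect_length(state$vote_window, 0)
  }
})

# -- fast mode ----------------------------------------------------------

test_that("a legal first trial emits an immediate command and resets", {
  fx <- clean_fixture()
  model <- trained_fixture()$model
  st <- fm_step(new_fm_state(), fx$epochs[[1]], model)
  expect_equal(st$event, "command")
  expect_equal(st$decision$selected, fx$session$truth[1] + 1)
  expect_equal(st$state$n_accumulated, 0)
  expect_null(st$state$context_sums)
})

test_that("five consecutive illegal trials give exactly one erase event", {
  fx <- clean_fixture()
  low <- constant_model(0.1, template = fx$template)   # every trial illegal
  state <- new_fm_state()
  events <- character(0)
  for (i in 1:10) {
    st <- fm_step(state, fx$epochs[[(i - 1) %% 12 + 1]], low)
    state <- st$state
    events <- c(events, st$event)
    expect_lte(state$n_accumulated, 5)
  }
  expect_equal(which(events == "non_recognition"), c(5, 10))
  expect_equal(sum(events == "command", na.rm = TRUE), 0)
})

test_that("epoch accumulation rescues a trial that is ambiguous alone", {
  model <- trained_fixture()$model
  tpl <- model$template
  # same underlying target buried in heavy independent noise each trial:
  # the 3-trial average clears the threshold where single trials do not
  found <- FALSE
  for (seed in 1:50) {
    set.seed(seed)
    trials <- lapply(1:5, function(i) {
      lapply(0:3, function(k) {
        base <- if (k == 1) {
          c(rep(0, 15), tpl$samples * 15, rep(0, 15))
        } else rep(0, 100)
        p300_epoch(base + rnorm(100, sd = 14), trial_index = i,
                   interval_index = k)
      })
    })
    state <- new_fm_state()
    emitted_at <- NA
    for (i in 1:5) {
      st <- fm_step(state, trials[[i]], model)
      state <- st$state
      if (!is.na(st$event) && st$event == "command") { emitted_at <- i; break }
    }
    if (!is.na(emitted_at) && emitted_at == 3 &&
        st$decision$selected == 2) { found <- TRUE; break }
  }
  expect_true(found)
})

# -- averaging baseline and session-level runs --------------------------

test_that("1-epoch averaging reproduces the plain trial judgement", {
  fx <- clean_fixture()
  model <- trained_fixture()$model
  log1 <- classify_session(fx$session, model, mode = "avg1")
  expect_equal(nrow(log1$events), 12)
  manual <- vapply(seq_len(12), function(i) {
    judge_trial(vapply(fx$epochs[[i]], function(e) {
      ffnn_forward(model, timeshift_features(e, model$template))
    }, numeric(1)), model$threshold)$selected
  }, integer(1))
  expect_equal(log1$events$selected, manual)
})

test_that("n-epoch averaging emits one decision per complete block", {
  fx <- clean_fixture()
  model <- trained_fixture()$model
  log3 <- classify_session(fx$session, model, mode = "avg3")
  expect_equal(nrow(log3$events), 4)       # 12 trials / 3
  log2 <- classify_session(fx$session, model, mode = "avg2")
  expect_equal(nrow(log2$events), 6)
  # at most floor(n/3) decisions from any stream
  expect_lte(nrow(log3$events), 12 %/% 3)
})

test_that("noise-free sessions are classified perfectly in every mode", {
  fx <- clean_fixture()
  model <- trained_fixture()$model
  for (mode in c("avg1", "fm")) {
    log <- classify_session(fx$session, model, mode = mode)
    expect_equal(log$trial_outcome, rep("correct", 12))
    expect_true(all(log$events$correct))
  }
  # AM needs two matching legal trials; the 12-trial rotation decides on
  # repeats only, so check commands, not per-trial attribution
  cfg <- simulation_config(rep(2, 6), noise_sd = 0, latency_jitter = 0,
                           amplitude_variability = 0, seed = 7)
  s_const <- simulate_session(cfg)
  log_am <- classify_session(s_const, model, mode = "am")
  expect_true(all(log_am$events$correct))
  expect_equal(unique(log_am$events$selected), 3)
})

test_that("fast mode never accumulates past its cap on random streams", {
  fx <- clean_fixture()
  set.seed(33)
  for (rep in 1:20) {
    score <- runif(1, -0.5, 0.55)   # sub-threshold: stays illegal
    low <- constant_model(score, template = fx$template)
    state <- new_fm_state()
    erase_gap <- integer(0)
    last_erase <- 0
    for (i in 1:17) {
      st <- fm_step(state, fx$epochs[[(i - 1) %% 12 + 1]], low)
      state <- st$state
      expect_lte(state$n_accumulated, 5)
      if (!is.na(st$event) && st$event == "non_recognition") {
        erase_gap <- c(erase_gap, i - last_erase)
        last_erase <- i
      }
    }
    expect_true(all(erase_gap == 5))
  }
})
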
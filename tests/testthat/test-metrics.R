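test_that("bits per selection hits its closed-form landmarks", {
  expect_equal(bits_per_command(1, 4), 2)
  expect_equal(bits_per_command(0.25, 4), 0)          # chance level
  expect_equal(bits_per_command(0, 4), log2(4) + log2(1 / 3))
  expect_equal(bits_per_command(1, 2), 1)
  # against the formula evaluated term by term
  for (pa in c(0.3, 0.5, 0.624, 0.878, 0.92, 0.99)) {
    oracle <- log2(4) + pa * log2(pa) + (1 - pa) * log2((1 - pa) / 3)
    expect_equal(bits_per_command(pa, 4), oracle, tolerance = 1e-12)
  }
  expect_error(bits_per_command(1.2), "\\[0, 1\\]")
  expect_error(bits_per_command(0.5, K_s = 1), ">= 2")
})

test_that("bits per selection increases with accuracy above chance", {
  pa <- seq(0.25, 1, by = 0.01)
  b <- vapply(pa, bits_per_command, numeric(1))
  expect_true(all(diff(b) > 0))
})

test_that("information transfer rate follows B * 60 / CTI", {
  # perfect accuracy, one command every 1.2 s: 2 bits / 1.2 s = 100 bits/min
  expect_equal(itr(T_exp = 12, N_o = 10, P_a = 1, K_s = 4), 100)
  expect_equal(itr(T_exp = 60, N_o = 0, P_a = 0), 0)
  # doubling the commands in the same time doubles the rate
  expect_equal(itr(100, 40, 0.8), 2 * itr(100, 20, 0.8))
  # halving the elapsed time doubles the rate
  expect_equal(itr(50, 20, 0.8), 2 * itr(100, 20, 0.8))
  expect_error(itr(0, 1, 1), "T_exp")
  expect_error(itr(10, -1, 1), "N_o")
})

test_that("the error-accumulation curve matches its worked example", {
  # wrong recognitions on trials 1 and 2 of 4
  fc <- fatigue_curve(c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(fc$Et, 2)
  expect_equal(fc$En, c(1, 2, 2, 2))
  expect_equal(fc$Er, c(0.5, 1, 1, 1))
  # shifted form runs from -1 up to 0
  fs <- fatigue_curve(c(TRUE, TRUE, FALSE, FALSE), shifted = TRUE)
  expect_equal(fs$Er, c(-0.5, 0, 0, 0))
})

test_that("the accumulation rate is the normalized running count", {
  set.seed(12)
  for (i in 1:100) {
    w <- runif(100) < runif(1, 0.05, 0.5)
    if (!any(w)) w[1] <- TRUE
    fc <- fatigue_curve(w)
    expect_equal(fc$Er, cumsum(w) / sum(w), tolerance = 1e-12)
    expect_equal(fc$Er[100], 1)
    expect_true(all(diff(fc$Er) >= 0))
  }
  expect_warning(out <- fatigue_curve(c(FALSE, FALSE)), "undefined")
  expect_true(all(is.na(out$Er)))
  expect_error(fatigue_curve(logical(0)), "at least one")
})

test_that("an identical curved path correlates perfectly with itself", {
  t <- seq(0, 1, length.out = 50)
  arc <- cbind(t * 100, 30 * sin(pi * t))
  cmp <- compare_trajectories(arc, arc)
  expect_equal(cmp$ppmcc, 1, tolerance = 1e-9)
  expect_equal(cmp$length_difference_pct, 0, tolerance = 1e-9)
})

test_that("path-length differences are reported as a percentage", {
  straight <- cbind(seq(0, 100, length.out = 20), 0)
  longer <- cbind(seq(0, 110, length.out = 20), 0)
  cmp <- compare_trajectories(longer, straight)
  expect_equal(cmp$length_difference_pct, 10, tolerance = 1e-9)
  expect_equal(cmp$length_actual, 110, tolerance = 1e-9)
  expect_equal(cmp$length_desired, 100, tolerance = 1e-9)
})

test_that("lateral-deviation correlation detects mirrored detours", {
  t <- seq(0, 1, length.out = 200)
  wave <- cbind(t * 100, 20 * sin(2 * pi * t))
  mirror <- cbind(t * 100, -20 * sin(2 * pi * t))
  expect_lt(compare_trajectories(wave, mirror)$ppmcc, -0.99)
  # a perfectly straight desired path has no lateral structure:
  # the 0/0 correlation convention yields 0, not a spurious match
  straight <- cbind(t * 100, 0)
  expect_equal(compare_trajectories(wave, straight)$ppmcc, 0)
})

test_that("deviation profiles are invariant to rigid motion of the path", {
  t <- seq(0, 1, length.out = 120)
  wave <- cbind(t * 80, 15 * sin(2 * pi * t) + 5 * sin(4 * pi * t))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- sweep(wave %*% R, 2, c(12, -30), "+")
  cmp <- compare_trajectories(moved, wave)
  expect_equal(cmp$ppmcc, 1, tolerance = 1e-6)
  expect_equal(cmp$length_difference_pct, 0, tolerance = 1e-6)
})

test_that("degenerate trajectories are rejected", {
  pt <- cbind(c(1, 1), c(2, 2))
  line <- cbind(0:5, 0)
  expect_error(compare_trajectories(pt, line), "degenerate")
  expect_error(compare_trajectories(line, pt), "degenerate")
  expect_error(compare_trajectories(cbind(1, 1), line), "at least 2")
})

test_that("session summaries are internally consistent", {
  fx <- clean_fixture()
  model <- trained_fixture()$model
  log <- classify_session(fx$session, model, mode = "fm")
  sm <- session_metrics(log)
  expect_equal(sum(sm$counts), 12)
  expect_equal(sum(sm$rates_pct), 100)
  expect_equal(sm$T_exp, 12 * 1.05)
  expect_equal(sm$P_a, 1)
  expect_equal(sm$N_o, sm$n_commands)
  # noise-free fixture: every trial correct, ITR = 2 bits / 1.05 s
  expect_equal(unname(sm$counts["correct"]), 12)
  expect_equal(sm$itr, 2 * 60 / 1.05, tolerance = 1e-9)
  printed <- capture.output(print(sm))
  expect_match(printed[1], "12 trials")
})
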
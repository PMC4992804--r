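# Nested-loop evaluation written directly from the layer equations.
forward_oracle <- function(model, x) {
  y <- model$Ob
  for (i in seq_len(model$m)) {
    N <- model$b[i]
    for (j in seq_len(model$n)) N <- N + x[j] * model$w[i, j]
    H <- 2 / (1 + exp(-2 * N)) - 1
    y <- y + H * model$Hw[i]
  }
  y
}

random_model <- function(n = 31, m = 15) {
  ffnn_model(matrix(rnorm(m * n), m, n), rnorm(m), rnorm(m), rnorm(1))
}

test_that("the network has m(n+2)+1 parameters and validates sizes", {
  model <- random_model()
  expect_equal(n_parameters(model), 496)
  expect_equal(n_parameters(random_model(n = 10, m = 4)), 49)
  expect_error(ffnn_model(matrix(0, 15, 31), rep(0, 14), rep(0, 15), 0),
               "inconsistent layer sizes")
  expect_error(ffnn_forward(model, rnorm(30)), "expects")
})

test_that("forward pass matches the loop oracle and its edge cases", {
  zero <- ffnn_model(matrix(0, 15, 31), rep(0, 15), rep(0, 15), Ob = 0.7)
  expect_equal(ffnn_forward(zero, rnorm(31)), 0.7)

  # activation is the tanh sigmoid
  expect_equal(p300tsc:::tansig(0), 0)
  expect_equal(p300tsc:::tansig(50), 1)
  expect_equal(p300tsc:::tansig(-50), -1)
  expect_equal(p300tsc:::tansig(0.3), tanh(0.3), tolerance = 1e-12)

  set.seed(31)
  for (case in 1:1000) {
    model <- random_model(n = 7, m = 3)
    x <- rnorm(7)
    expect_equal(ffnn_forward(model, x), forward_oracle(model, x),
                 tolerance = 1e-12)
  }
  # matrix form agrees with the vector form
  model <- random_model()
  X <- matrix(rnorm(10 * 31), 10)
  expect_equal(ffnn_forward(model, X),
               apply(X, 1, function(r) ffnn_forward(model, r)),
               tolerance = 1e-12)
})

separable_set <- function(p = 200, seed = 77) {
  set.seed(seed)
  X <- matrix(0, p, 31)
  labels <- rep(c(1, 0), length.out = p)
  bell <- exp(-((1:31) - 16)^2 / 18)
  for (i in seq_len(p)) {
    X[i, ] <- if (labels[i] == 1) bell + rnorm(31, sd = 0.05)
              else rnorm(31, sd = 0.15)
  }
  list(X = X, labels = labels)
}

test_that("training separates bell-shaped target curves from flat noise", {
  d <- separable_set()
  fit <- train_ffnn(d$X, d$labels, max_epochs = 1500, learning_rate = 0.05,
                    seed = 2)
  scores <- ffnn_forward(fit$model, d$X)
  expect_equal(unname((scores > 0.6)[d$labels == 1]),
               rep(TRUE, sum(d$labels == 1)))
  expect_equal(unname((scores > 0.6)[d$labels == 0]),
               rep(FALSE, sum(d$labels == 0)))
})

test_that("a goal met at initialization runs zero epochs", {
  d <- separable_set(p = 40)
  fit <- train_ffnn(d$X, d$labels, mse_goal = 1e6, seed = 3)
  expect_equal(fit$report$epochs_run, 0)
  expect_equal(fit$report$stop_reason, "mse_goal")
})

test_that("training is deterministic for a fixed seed", {
  d <- separable_set(p = 60)
  f1 <- train_ffnn(d$X, d$labels, max_epochs = 50, seed = 9)
  f2 <- train_ffnn(d$X, d$labels, max_epochs = 50, seed = 9)
  expect_identical(f1$model$w, f2$model$w)
  expect_identical(f1$model$Hw, f2$model$Hw)
  f3 <- train_ffnn(d$X, d$labels, max_epochs = 50, seed = 10)
  expect_false(identical(f1$model$w, f3$model$w))
})

test_that("degenerate splits are rejected", {
  d <- separable_set(p = 4)
  expect_error(train_ffnn(d$X[1:3, ], d$labels[1:3]), "degenerate split")
  expect_error(train_ffnn(d$X, d$labels, split = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(train_ffnn(d$X, c(2, d$labels[-1])), "targets must be 0 or 1")
})

test_that("training loss is non-increasing at a small learning rate", {
  d <- separable_set(p = 80)
  fit <- train_ffnn(d$X, d$labels, split = c(1, 0, 0), max_epochs = 400,
                    learning_rate = 0.005, seed = 4)
  expect_true(all(diff(fit$report$train_mse_trace) <= 1e-10))
})

test_that("interval classification uses a strict threshold", {
  m06 <- constant_model(0.6, template = NULL)
  expect_false(classify_interval(m06, rnorm(31))$is_target)
  m09 <- constant_model(0.9473, template = NULL)
  expect_true(classify_interval(m09, rnorm(31))$is_target)
  m09$threshold <- 1.0
  expect_false(classify_interval(m09, rnorm(31))$is_target)
})

test_that("threshold diagnostic reports the score separation", {
  d <- separable_set()
  fit <- train_ffnn(d$X, d$labels, max_epochs = 1500, learning_rate = 0.05,
                    seed = 2)
  diag <- threshold_diagnostic(fit$model, d$X, d$labels, seed = 1)
  expect_gt(diag$separation, 0)
  expect_gt(min(diag$target_scores), 0.6)
  expect_lt(max(diag$nontarget_scores), 0.6)
})
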
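#' Construct a feedforward network model
#'
#' The classifier is a single-hidden-layer feedforward network: 31 inputs
#' (the time-shift correlations), 15 hidden tansig units, and one linear
#' output neuron, for m * (n + 2) + 1 = 496 trainable parameters.  An
#' interval is flagged as a target when the output score strictly exceeds
#' \code{threshold} (0.6 by default).
#'
#' @param w hidden-layer input weights, m x n matrix.
#' @param b hidden biases, length m.
#' @param Hw hidden-to-output weights, length m.
#' @param Ob output bias, scalar.
#' @param threshold decision cutoff for target classification.
#' @param template optional \code{p300_template} stored alongside the
#'   weights so one model file carries a subject's full configuration.
#' @return An object of class \code{ffnn_model}.
#' @export
ffnn_model <- function(w, b, Hw, Ob, threshold = 0.6, template = NULL) {
  w <- as.matrix(w)
  m <- nrow(w); n <- ncol(w)
  if (length(b) != m || length(Hw) != m || length(Ob) != 1) {
    stop("inconsistent layer sizes: w is ", m, "x", n,
         ", b has ", length(b), ", Hw has ", length(Hw), call. = FALSE)
  }
  structure(
    list(n = n, m = m,
         w = w, b = as.numeric(b),
         Hw = as.numeric(Hw), Ob = as.numeric(Ob),
         threshold = threshold,
         template = template),
    class = "ffnn_model")
}

#' Number of trainable parameters of a network
#' @param model an \code{ffnn_model}.
#' @return \code{m * (n + 2) + 1}.
#' @export
n_parameters <- function(model) {
  model$m * (model$n + 2) + 1
}

#' @export
print.ffnn_model <- function(x, ...) {
  cat(sprintf("FFNN model: %d-%d-1 (%d parameters), threshold %g%s\n",
              x$n, x$m, n_parameters(x), x$threshold,
              if (is.null(x$template)) "" else ", template attached"))
  invisible(x)
}

# hyperbolic tangent sigmoid: 2 / (1 + exp(-2 N)) - 1
tansig <- function(N) 2 / (1 + exp(-2 * N)) - 1

#' Forward pass of the network
#'
#' Hidden activations are \code{tansig(w x + b)}; the output neuron is
#' linear (no squashing), so scores are unbounded and can fall below 0 or
#' above 1.
#'
#' @param model an \code{ffnn_model}.
#' @param x numeric vector of length n, a \code{feature_vector}, or a
#'   p x n matrix of feature rows.
#' @return a scalar score, or a vector of p scores for matrix input.
#' @export
ffnn_forward <- function(model, x) {
  if (inherits(x, "feature_vector")) x <- x$r
  if (is.matrix(x)) {
    if (ncol(x) != model$n) {
      stop("input has ", ncol(x), " features, model expects ", model$n,
           call. = FALSE)
    }
    H <- tansig(x %*% t(model$w) +
                  matrix(model$b, nrow(x), model$m, byrow = TRUE))
    as.numeric(H %*% model$Hw + model$Ob)
  } else {
    if (length(x) != model$n) {
      stop("input has ", length(x), " features, model expects ", model$n,
           call. = FALSE)
    }
    H <- tansig(as.numeric(model$w %*% x) + model$b)
    sum(H * model$Hw) + model$Ob
  }
}

#' Classify one interval's features
#'
#' @param model a trained \code{ffnn_model}.
#' @param x feature vector (length n) or \code{feature_vector}.
#' @return list with \code{score} and \code{is_target}
#'   (\code{score > threshold}, strict: a score exactly at the threshold
#'   is not a target).
#' @export
classify_interval <- function(model, x) {
  score <- ffnn_forward(model, x)
  list(score = score, is_target = score > model$threshold)
}

init_ffnn <- function(n = 31, m = 15, threshold = 0.6, template = NULL) {
  lim_in <- 1 / sqrt(n)
  lim_hid <- 1 / sqrt(m)
  ffnn_model(
    w = matrix(stats::runif(m * n, -lim_in, lim_in), m, n),
    b = stats::runif(m, -lim_in, lim_in),
    Hw = stats::runif(m, -lim_hid, lim_hid),
    Ob = stats::runif(1, -lim_hid, lim_hid),
    threshold = threshold, template = template)
}

mse_of <- function(model, X, T) {
  if (nrow(X) == 0) return(NA_real_)
  mean((ffnn_forward(model, X) - T)^2)
}

#' Train the network by backpropagation
#'
#' Full-batch gradient descent on the mean squared error between the
#' linear output and the 0/1 targets.  The example set is shuffled once
#' and split into training, generalization-test and early-stopping
#' partitions (70/15/15 by default, mirroring the reference training
#' protocol of 160 trials x 4 intervals).  Training ends at
#' \code{max_epochs}, when the training MSE reaches \code{mse_goal}, or
#' when the early-stop partition's MSE has not improved for
#' \code{patience} consecutive epochs (the weights with the best stop-set
#' MSE are kept).  Deterministic for a fixed seed; the caller's RNG state
#' is restored on exit.
#'
#' @param X p x n matrix of feature vectors.
#' @param targets length-p vector of 0/1 labels (1 = elicited P300).
#' @param split fractions for train / generalization-test / early-stop;
#'   must sum to 1 and leave at least one example in each partition.
#' @param max_epochs maximum training epochs (default 9000).
#' @param mse_goal stop when training MSE falls below this (default 1e-5).
#' @param learning_rate gradient-descent step size.
#' @param momentum classical momentum coefficient (0 disables).
#' @param patience early-stopping window, in epochs.
#' @param threshold decision cutoff stored on the returned model.
#' @param template optional \code{p300_template} stored on the model.
#' @param seed integer seed for the shuffle and weight initialization.
#' @return list with \code{model} (trained \code{ffnn_model}) and
#'   \code{report}: epochs run, stop reason, final MSE per partition, and
#'   the per-epoch training MSE trace.
#' @export
train_ffnn <- function(X, targets, split = c(0.70, 0.15, 0.15),
                       max_epochs = 9000, mse_goal = 1e-5,
                       learning_rate = 0.01, momentum = 0,
                       patience = 50, threshold = 0.6,
                       template = NULL, seed = 1L) {
  X <- as.matrix(X)
  targets <- as.numeric(targets)
  p <- nrow(X)
  if (length(targets) != p) stop("one target per row required", call. = FALSE)
  if (!all(targets %in% c(0, 1))) stop("targets must be 0 or 1", call. = FALSE)
  if (abs(sum(split) - 1) > 1e-8 || any(split < 0)) {
    stop("split fractions must be non-negative and sum to 1", call. = FALSE)
  }
  n_train <- round(split[1] * p)
  n_test <- round(split[2] * p)
  n_stop <- p - n_train - n_test
  if (n_train < 1 || (split[2] > 0 && n_test < 1) ||
      (split[3] > 0 && n_stop < 1)) {
    stop("degenerate split: each requested partition needs >= 1 example",
         call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  perm <- sample.int(p)
  idx_train <- perm[seq_len(n_train)]
  idx_test <- if (n_test > 0) perm[n_train + seq_len(n_test)] else integer(0)
  idx_stop <- if (n_stop > 0) perm[n_train + n_test + seq_len(n_stop)] else integer(0)
  Xtr <- X[idx_train, , drop = FALSE]; Ttr <- targets[idx_train]
  Xst <- X[idx_stop, , drop = FALSE]; Tst <- targets[idx_stop]

  model <- init_ffnn(n = ncol(X), threshold = threshold, template = template)
  vel <- list(w = model$w * 0, b = model$b * 0,
              Hw = model$Hw * 0, Ob = 0)
  ptr <- nrow(Xtr)
  bias_mat <- function(b) matrix(b, ptr, length(b), byrow = TRUE)

  best_stop <- Inf; best <- model; since_best <- 0L; prev_stop <- NA_real_
  trace <- numeric(0)
  stop_reason <- "max_epochs"
  epochs_run <- 0L

  if (mse_of(model, Xtr, Ttr) <= mse_goal) {
    stop_reason <- "mse_goal"
  } else {
    for (epoch in seq_len(max_epochs)) {
      H <- tansig(Xtr %*% t(model$w) + bias_mat(model$b))
      y <- as.numeric(H %*% model$Hw + model$Ob)
      err <- y - Ttr
      dy <- 2 * err / ptr                       # d(MSE)/dy
      g_Ob <- sum(dy)
      g_Hw <- as.numeric(t(H) %*% dy)
      dN <- (dy %o% model$Hw) * (1 - H^2)
      g_b <- colSums(dN)
      g_w <- t(dN) %*% Xtr

      vel$w <- momentum * vel$w - learning_rate * g_w
      vel$b <- momentum * vel$b - learning_rate * g_b
      vel$Hw <- momentum * vel$Hw - learning_rate * g_Hw
      vel$Ob <- momentum * vel$Ob - learning_rate * g_Ob
      model$w <- model$w + vel$w
      model$b <- model$b + vel$b
      model$Hw <- model$Hw + vel$Hw
      model$Ob <- model$Ob + vel$Ob

      epochs_run <- epoch
      train_mse <- mse_of(model, Xtr, Ttr)
      trace[epoch] <- train_mse
      if (train_mse <= mse_goal) { stop_reason <- "mse_goal"; break }
      if (n_stop > 0) {
        stop_mse <- mse_of(model, Xst, Tst)
        if (stop_mse < best_stop) {
          best_stop <- stop_mse; best <- model
        }
        # count consecutive worsening epochs; a flat or improving stop-set
        # error (e.g. the slow plateau early in full-batch descent) resets
        if (epoch > 1 && !is.na(prev_stop) && stop_mse > prev_stop) {
          since_best <- since_best + 1L
          if (since_best >= patience) {
            stop_reason <- "early_stop"
            model <- best
            break
          }
        } else {
          since_best <- 0L
        }
        prev_stop <- stop_mse
      }
    }
  }

  report <- list(
    epochs_run = epochs_run,
    stop_reason = stop_reason,
    train_mse = mse_of(model, Xtr, Ttr),
    test_mse = if (n_test > 0)
      mse_of(model, X[idx_test, , drop = FALSE], targets[idx_test])
      else NA_real_,
    stop_mse = if (n_stop > 0) mse_of(model, Xst, Tst) else NA_real_,
    train_mse_trace = trace)
  list(model = model, report = report)
}

#' Threshold selection diagnostic
#'
#' Reproduces the reference threshold-selection inspection: feed the
#' feature vectors of randomly chosen labeled trials through a trained
#' model and summarize the score separation between target and non-target
#' intervals.  The report is descriptive; it does not change the model's
#' threshold (targets scoring above ~0.7 and non-targets below ~0.0
#' motivate the default cutoff of 0.6).
#'
#' @param model a trained \code{ffnn_model}.
#' @param X p x n matrix of feature vectors.
#' @param targets 0/1 labels for the rows of \code{X}.
#' @param n_inspect number of rows to sample (default 80, i.e. 20 trials
#'   of 4 intervals).
#' @param seed integer seed for the row sample.
#' @return list with the sampled target / non-target score vectors, their
#'   ranges, and \code{separation} (min target score - max non-target
#'   score; positive means a clean margin).
#' @export
threshold_diagnostic <- function(model, X, targets, n_inspect = 80, seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  idx <- sample.int(nrow(X), min(n_inspect, nrow(X)))
  scores <- ffnn_forward(model, X[idx, , drop = FALSE])
  lab <- targets[idx]
  ts <- scores[lab == 1]; ns <- scores[lab == 0]
  list(target_scores = ts,
       nontarget_scores = ns,
       target_range = range(ts),
       nontarget_range = range(ns),
       separation = min(ts) - max(ns))
}
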
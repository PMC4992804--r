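#' Feature matrix of a labeled session
#'
#' Extracts every trial's four interval epochs, computes each epoch's
#' 31-point time-shift correlation vector against the template, and
#' labels it 1 when the interval is the trial's true target.
#'
#' @param session a \code{labeled_session}.
#' @param template a \code{p300_template}.
#' @return list with \code{X} (\code{4 * n_trials} x 31 matrix),
#'   \code{labels} (0/1), \code{trial} and \code{interval} (0-based k)
#'   index vectors.
#' @export
session_features <- function(session, template) {
  epochs <- session_epochs(session)
  nt <- length(epochs)
  X <- matrix(NA_real_, nt * 4, 31)
  labels <- integer(nt * 4)
  trial <- integer(nt * 4)
  interval <- integer(nt * 4)
  row <- 0L
  for (i in seq_len(nt)) {
    for (k in 0:3) {
      row <- row + 1L
      X[row, ] <- timeshift_features(epochs[[i]][[k + 1]], template)$r
      labels[row] <- as.integer(session$truth[i] == k)
      trial[row] <- i
      interval[row] <- k
    }
  }
  list(X = X, labels = labels, trial = trial, interval = interval)
}

#' Train a classifier from a labeled training session
#'
#' End-to-end offline training: builds the subject's P300 template from
#' the known target intervals of the first \code{n_template} trials,
#' featurizes all trials, and fits the 31-15-1 network by
#' backpropagation.  The returned model carries the template, so it is
#' self-contained for classification and for saving with
#' \code{\link{save_model}}.
#'
#' @param session a \code{labeled_session} (e.g. 160 trials in the
#'   reference protocol).
#' @param n_template number of trials whose target epochs form the
#'   template (10 in the reference protocol).
#' @param subject_id subject identifier stored on the template.
#' @param ... further arguments passed to \code{\link{train_ffnn}}
#'   (\code{max_epochs}, \code{learning_rate}, \code{seed}, ...).
#' @return list with \code{model} and \code{report} as from
#'   \code{\link{train_ffnn}}.
#' @export
train_from_session <- function(session, n_template = 10,
                               subject_id = "synthetic", ...) {
  template <- template_from_session(session, n = n_template,
                                    subject_id = subject_id)
  feats <- session_features(session, template)
  train_ffnn(feats$X, feats$labels, template = template, ...)
}

#' Single-epoch target-recovery accuracy on a session
#'
#' Classifies each trial from its single-trial scores (no accumulation or
#' voting) and reports the fraction of trials whose legal decision matches
#' the truth; illegal trials count as misses.  This is the raw
#' discriminative performance the decision modes build on.
#'
#' @param session a \code{labeled_session}.
#' @param model a trained \code{ffnn_model} with template.
#' @return fraction of trials correctly recovered, in [0, 1].
#' @export
single_epoch_accuracy <- function(session, model) {
  log <- classify_session(session, model, mode = "avg1")
  mean(log$trial_outcome == "correct")
}
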
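#' Judge one trial from its four interval scores
#'
#' A trial is \emph{legal} when exactly one of the four network outputs
#' strictly exceeds the threshold; the corresponding stimulus is selected.
#' Several outputs above threshold give \code{illegal_multiple}; none give
#' \code{illegal_none}.
#'
#' @param scores numeric vector of exactly 4 network outputs, ordered by
#'   stimulus interval k = 0..3.
#' @param threshold decision cutoff (strict inequality).
#' @param trial_index optional 1-based trial number recorded on the result.
#' @return An object of class \code{trial_decision}: list with
#'   \code{trial_index}, \code{scores}, \code{status} (\code{"legal"},
#'   \code{"illegal_multiple"} or \code{"illegal_none"}) and
#'   \code{selected}, the 1-based stimulus ordinal (\code{NA} unless
#'   legal).
#' @export
judge_trial <- function(scores, threshold = 0.6, trial_index = NA_integer_) {
  if (length(scores) != 4) stop("need exactly 4 scores", call. = FALSE)
  above <- which(scores > threshold)
  status <- if (length(above) == 1) "legal"
            else if (length(above) > 1) "illegal_multiple"
            else "illegal_none"
  structure(
    list(trial_index = trial_index,
         scores = as.numeric(scores),
         status = status,
         selected = if (status == "legal") above else NA_integer_),
    class = "trial_decision")
}

#' @export
print.trial_decision <- function(x, ...) {
  cat(sprintf("Trial %s: %s%s  [%s]\n", x$trial_index, x$status,
              if (!is.na(x$selected))
                paste0(", stimulus ", x$selected,
                       " (", stimulus_command(x$selected), ")") else "",
              paste(sprintf("%.4f", x$scores), collapse = ", ")))
  invisible(x)
}

#' Movement command of a stimulus ordinal
#'
#' The four LED stimuli, right to left, command forward, right-turn,
#' left-turn and backward motion.
#'
#' @param selected 1-based stimulus ordinal(s) in 1..4.
#' @return character vector of command names.
#' @export
stimulus_command <- function(selected) {
  c("forward", "right-turn", "left-turn", "backward")[selected]
}

score_intervals <- function(epochs4, model) {
  vapply(epochs4, function(e) {
    ffnn_forward(model, timeshift_features(e, model$template))
  }, numeric(1))
}

epochs_from_contexts <- function(contexts, trial_index = NA_integer_) {
  lapply(0:3, function(k) {
    p300_epoch(contexts[[k + 1]], trial_index = trial_index,
               interval_index = k,
               start_offset_ms = epoch_start_ms(k))
  })
}

#' Fresh fast-recognition-mode state
#' @return an \code{fm_state} with empty accumulation buffers.
#' @export
new_fm_state <- function() {
  structure(list(context_sums = NULL, n_accumulated = 0L),
            class = "fm_state")
}

#' One fast-recognition-mode step
#'
#' FM decides from the latest legal trial.  Each incoming trial's raw
#' epochs are added to per-interval accumulation buffers; the buffered
#' average is classified.  A legal result emits a command and resets the
#' buffers.  An illegal result carries the buffers into the next trial; at
#' the 5th consecutive illegal trial the buffers are erased and a single
#' non-recognition event is emitted.
#'
#' @param state an \code{fm_state}.
#' @param trial_epochs list of 4 \code{p300_epoch}s of the incoming trial.
#' @param model a trained \code{ffnn_model} with template.
#' @param max_accumulate accumulation cap (5 in the reference system).
#' @return list with \code{state} (updated), \code{decision} (the
#'   \code{trial_decision} on the accumulated average) and \code{event}
#'   (\code{"command"}, \code{"non_recognition"}, or \code{NA} while
#'   accumulating).
#' @export
fm_step <- function(state, trial_epochs, model, max_accumulate = 5L) {
  ctx <- lapply(trial_epochs, `[[`, "context")
  if (is.null(state$context_sums)) {
    state$context_sums <- ctx
  } else {
    state$context_sums <- Map(`+`, state$context_sums, ctx)
  }
  state$n_accumulated <- state$n_accumulated + 1L

  avg_ctx <- lapply(state$context_sums, `/`, state$n_accumulated)
  trial_index <- trial_epochs[[1]]$trial_index
  epochs <- epochs_from_contexts(avg_ctx, trial_index = trial_index)
  scores <- score_intervals(epochs, model)
  decision <- judge_trial(scores, model$threshold, trial_index = trial_index)

  if (decision$status == "legal") {
    state <- new_fm_state()
    event <- "command"
  } else if (state$n_accumulated >= max_accumulate) {
    state <- new_fm_state()
    event <- "non_recognition"
  } else {
    event <- NA_character_
  }
  list(state = state, decision = decision, event = event)
}

#' Fresh accuracy-recognition-mode state
#' @return an \code{am_state} with an empty vote window.
#' @export
new_am_state <- function() {
  structure(list(vote_window = integer(0)), class = "am_state")
}

#' One accuracy-recognition-mode voting step
#'
#' AM decides a target when the same label occurs twice among the last
#' three legal trials.  The automaton keeps at most two pending labels:
#' an incoming label matching a pending one is decided immediately; a
#' third distinct label drops the oldest pending label and voting
#' continues.  Illegal trials are skipped upstream and never reach this
#' automaton.
#'
#' @param state an \code{am_state}.
#' @param legal_label the 1-based stimulus ordinal of a legal trial.
#' @return list with \code{state} (updated) and \code{decision} (the
#'   decided label, or \code{NA} while voting continues).
#' @export
am_step <- function(state, legal_label) {
  if (legal_label %in% state$vote_window) {
    state$vote_window <- integer(0)
    return(list(state = state, decision = legal_label))
  }
  w <- c(state$vote_window, legal_label)
  if (length(w) > 2) w <- w[-1]    # three distinct labels: drop the oldest
  state$vote_window <- w
  list(state = state, decision = NA_integer_)
}

#' Classify a session under a decision mode
#'
#' Runs the full decision pipeline over a labeled session: epochs are
#' extracted per trial, featurized against the model's template, scored by
#' the network, and fed through the selected decision mode.  Outcomes are
#' attributed per trial, as in the reference evaluation: every trial
#' consumed on the way to a command inherits that command's correctness,
#' and trials in runs that end without a command (erased FM buffers,
#' unresolved AM votes, illegal averaging blocks, or the session end)
#' count as non-recognition.
#'
#' @param session a \code{labeled_session}.
#' @param model a trained \code{ffnn_model} carrying its template.
#' @param mode \code{"fm"}, \code{"am"}, \code{"avg1"}, \code{"avg2"} or
#'   \code{"avg3"}.
#' @return An object of class \code{decision_log}: list with \code{mode},
#'   \code{n_trials}, \code{truth} (0-based), \code{events} (data.frame:
#'   trial, type, selected, correct), \code{trial_outcome} (character per
#'   trial: \code{"correct"}, \code{"wrong"}, \code{"non_recognition"})
#'   and \code{scores} (matrix of the scores used at each emitting step,
#'   NA rows elsewhere).
#' @export
classify_session <- function(session, model,
                             mode = c("fm", "am", "avg1", "avg2", "avg3")) {
  mode <- match.arg(mode)
  all_epochs <- session_epochs(session)
  nt <- length(all_epochs)
  truth1 <- session$truth + 1L   # 1-based ordinals for comparison
  outcome <- rep("non_recognition", nt)
  scores_mat <- matrix(NA_real_, nt, 4)
  events <- list()

  emit <- function(trial, type, selected, span) {
    correct <- if (type == "command") selected == truth1[trial] else NA
    events[[length(events) + 1]] <<- data.frame(
      trial = trial, type = type,
      selected = if (type == "command") selected else NA_integer_,
      correct = correct)
    if (type == "command") {
      outcome[span] <<- ifelse(selected == truth1[span], "correct", "wrong")
    } else {
      outcome[span] <<- "non_recognition"
    }
  }

  if (mode %in% c("avg1", "avg2", "avg3")) {
    n_avg <- as.integer(substring(mode, 4))
    n_blocks <- nt %/% n_avg
    for (bl in seq_len(n_blocks)) {
      span <- ((bl - 1) * n_avg + 1):(bl * n_avg)
      ctx <- lapply(0:3, function(k) {
        Reduce(`+`, lapply(span, function(i) all_epochs[[i]][[k + 1]]$context)) / n_avg
      })
      epochs <- epochs_from_contexts(ctx, trial_index = span[n_avg])
      sc <- score_intervals(epochs, model)
      scores_mat[span[n_avg], ] <- sc
      d <- judge_trial(sc, model$threshold, trial_index = span[n_avg])
      emit(span[n_avg],
           if (d$status == "legal") "command" else "non_recognition",
           d$selected, span)
    }
    # leftover trials of an incomplete block stay non-recognition
  } else if (mode == "fm") {
    state <- new_fm_state()
    run_start <- 1L
    for (i in seq_len(nt)) {
      st <- fm_step(state, all_epochs[[i]], model)
      state <- st$state
      scores_mat[i, ] <- st$decision$scores
      if (!is.na(st$event)) {
        emit(i, st$event,
             st$decision$selected, run_start:i)
        run_start <- i + 1L
      }
    }
  } else { # am
    state <- new_am_state()
    span_start <- 1L
    for (i in seq_len(nt)) {
      sc <- score_intervals(all_epochs[[i]], model)
      scores_mat[i, ] <- sc
      d <- judge_trial(sc, model$threshold, trial_index = i)
      if (d$status == "legal") {
        st <- am_step(state, d$selected)
        state <- st$state
        if (!is.na(st$decision)) {
          emit(i, "command", st$decision, span_start:i)
          span_start <- i + 1L
        }
      }
    }
  }

  events <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(trial = integer(0), type = character(0),
               selected = integer(0), correct = logical(0))
  structure(
    list(mode = mode, n_trials = nt, truth = session$truth,
         events = events, trial_outcome = outcome, scores = scores_mat),
    class = "decision_log")
}

#' @export
print.decision_log <- function(x, ...) {
  tab <- table(factor(x$trial_outcome,
                      levels = c("correct", "wrong", "non_recognition")))
  cat(sprintf("Decision log (%s): %d trials -> %d correct / %d wrong / %d non-recognition; %d command(s)\n",
              x$mode, x$n_trials, tab["correct"], tab["wrong"],
              tab["non_recognition"], sum(x$events$type == "command")))
  invisible(x)
}
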
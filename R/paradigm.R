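#' @title Oddball stimulus paradigm timing
#' @description Helpers describing the four-choice LED oddball paradigm:
#'   each of the 4 stimuli flashes for 100 ms followed by a 100 ms
#'   inter-stimulus interval, and a 250 ms gap separates trials, so a trial
#'   lasts 1050 ms.  All timing is in milliseconds; sample indices are
#'   0-based and windows half-open.
#' @name paradigm
NULL

#' Construct a stimulus schedule
#'
#' A schedule records trial onsets plus the paradigm constants from which
#' every per-stimulus flash onset is derived (stimulus \code{k} of a trial
#' starting at \code{t} flashes at \code{t + k * (flash_duration +
#' inter_stimulus_interval)}).
#'
#' @param trial_onsets numeric vector of trial onsets in ms, strictly
#'   increasing and spaced at least one trial length apart.
#' @param flash_duration flash length in ms.
#' @param inter_stimulus_interval gap between flashes in ms.
#' @param inter_trial_interval gap after the last flash interval in ms.
#' @param n_stimuli number of stimuli per trial.
#' @return An object of class \code{stimulus_schedule}.
#' @examples
#' sch <- stimulus_schedule(c(0, 1050, 2100))
#' trial_duration_ms(sch)   # 1050
#' flash_onsets(sch, 1)     # 0 200 400 600
#' @export
stimulus_schedule <- function(trial_onsets,
                              flash_duration = 100,
                              inter_stimulus_interval = 100,
                              inter_trial_interval = 250,
                              n_stimuli = 4) {
  if (length(trial_onsets) < 1) {
    stop("schedule needs at least one trial onset", call. = FALSE)
  }
  trial_len <- n_stimuli * (flash_duration + inter_stimulus_interval) +
    inter_trial_interval
  if (length(trial_onsets) > 1) {
    gaps <- diff(trial_onsets)
    if (any(gaps < trial_len)) {
      stop("trial onsets must be strictly increasing and spaced >= ",
           trial_len, " ms apart", call. = FALSE)
    }
  }
  structure(
    list(trial_onsets = as.numeric(trial_onsets),
         flash_duration = flash_duration,
         inter_stimulus_interval = inter_stimulus_interval,
         inter_trial_interval = inter_trial_interval,
         n_stimuli = n_stimuli),
    class = "stimulus_schedule")
}

#' Trial duration implied by a schedule
#' @param schedule a \code{stimulus_schedule}.
#' @return duration of one trial in ms (1050 in the default paradigm).
#' @export
trial_duration_ms <- function(schedule) {
  schedule$n_stimuli *
    (schedule$flash_duration + schedule$inter_stimulus_interval) +
    schedule$inter_trial_interval
}

#' Flash onsets of every stimulus in a trial
#' @param schedule a \code{stimulus_schedule}.
#' @param trial 1-based trial number.
#' @return numeric vector of \code{n_stimuli} onsets in ms.
#' @export
flash_onsets <- function(schedule, trial) {
  t0 <- schedule$trial_onsets[trial]
  step <- schedule$flash_duration + schedule$inter_stimulus_interval
  t0 + step * (seq_len(schedule$n_stimuli) - 1)
}

#' Number of trials in a schedule
#' @param schedule a \code{stimulus_schedule}.
#' @export
n_trials <- function(schedule) length(schedule$trial_onsets)

#' Stimulus-locked epoch start offsets
#'
#' The P300 search window for stimulus \code{k} (0-based) of a trial
#' starting at \code{t} nominally opens at \code{t + 200 k + 81} ms.  At
#' 250 Hz the sample grid is 4 ms, and 81 ms is off-grid; starts are
#' snapped to the grid (default: up, giving 84, 284, 484, 684 ms).
#'
#' @param k integer vector of 0-based stimulus interval indices.
#' @param sampling_rate sampling rate in Hz.
#' @param grid_snap \code{"up"} (default) or \code{"nearest"}.
#' @param offset_ms nominal post-flash offset before snapping (81 ms).
#' @return epoch start offsets from trial onset, in ms.
#' @export
epoch_start_ms <- function(k, sampling_rate = 250, grid_snap = c("up", "nearest"),
                           offset_ms = 81) {
  grid_snap <- match.arg(grid_snap)
  step <- 1000 / sampling_rate
  raw <- 200 * k + offset_ms
  snapped <- switch(grid_snap,
                    up = ceiling(raw / step) * step,
                    nearest = round(raw / step) * step)
  snapped
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat("Stimulus schedule:", length(x$trial_onsets), "trial(s),",
      x$n_stimuli, "stimuli/trial,",
      trial_duration_ms(x), "ms/trial\n")
  invisible(x)
}
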
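#' Min-max normalization to [0, 1]
#'
#' Epochs and templates are compared on a common [0, 1] scale:
#' \code{(x - min) / (max - min)}.  A constant input has no defined scale
#' and maps to all-0.5 by convention.
#'
#' @param x numeric vector of at least 2 samples.
#' @return numeric vector of the same length with min 0 and max 1
#'   (all 0.5 for constant input).
#' @export
normalize01 <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0.5, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Zero-phase band-pass plus notch filtering
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass, followed
#' by a band-stop notch.  Zero-phase filtering is used so that no group
#' delay is added to the P300 latency, which is the very quantity the
#' time-shift features measure.
#'
#' @param recording an \code{eeg_recording}.
#' @param low,high band-pass corner frequencies in Hz (defaults 8 and 30).
#' @param notch notch centre frequency in Hz (default 60; \code{NA} skips
#'   the notch, e.g. when \code{high} already excludes it).
#' @param order Butterworth order of the band-pass prototype.
#' @param notch_halfwidth half-width of the stop band around \code{notch}, Hz.
#' @return a filtered \code{eeg_recording} of identical shape and rate.
#' @export
bandpass_notch <- function(recording, low = 8, high = 30, notch = 60,
                           order = 4, notch_halfwidth = 2) {
  fs <- recording$sampling_rate
  nyq <- fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stop("need 0 < low < high < sampling_rate/2", call. = FALSE)
  }
  n <- nrow(recording$data)
  # filtfilt needs more than 3x the filter's effective length to settle
  if (n <= 12 * order) {
    stop("signal too short for zero-phase filtering (", n, " samples)",
         call. = FALSE)
  }
  bp <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- apply(recording$data, 2, function(ch) signal::filtfilt(bp, ch))
  if (!is.na(notch) && notch < nyq) {
    bs <- signal::butter(2, c(notch - notch_halfwidth, notch + notch_halfwidth) / nyq,
                         type = "stop")
    out <- apply(out, 2, function(ch) signal::filtfilt(bs, ch))
  }
  eeg_recording(out, fs, recording$channel_labels, recording$start_time)
}

#' Construct an epoch object
#'
#' An epoch is the 280 ms (70 samples at 250 Hz) stimulus-locked window in
#' which an elicited P300 is sought, stored min-max normalized, together
#' with its raw context: the same window extended by 15 samples (60 ms) on
#' each side, from which the 31 shifted slices are cut.
#'
#' @param context raw (unnormalized) numeric vector of
#'   \code{n_samples + 2 * margin} values.
#' @param trial_index 1-based trial number.
#' @param interval_index 0-based stimulus interval k in 0..3.
#' @param start_offset_ms epoch start offset from trial onset, ms.
#' @param n_samples epoch length in samples (70).
#' @param margin context margin on each side, in samples (15).
#' @return An object of class \code{p300_epoch} with fields
#'   \code{samples} (normalized epoch), \code{context} (raw),
#'   \code{trial_index}, \code{interval_index}, \code{start_offset_ms},
#'   \code{margin}.
#' @export
p300_epoch <- function(context, trial_index = NA_integer_,
                       interval_index = NA_integer_,
                       start_offset_ms = NA_real_,
                       n_samples = 70, margin = 15) {
  context <- as.numeric(context)
  if (length(context) != n_samples + 2 * margin) {
    stop("context must have ", n_samples + 2 * margin, " samples, got ",
         length(context), call. = FALSE)
  }
  core <- context[(margin + 1):(margin + n_samples)]
  structure(
    list(samples = normalize01(core),
         context = context,
         trial_index = trial_index,
         interval_index = interval_index,
         start_offset_ms = start_offset_ms,
         margin = margin),
    class = "p300_epoch")
}

#' @export
print.p300_epoch <- function(x, ...) {
  cat(sprintf("P300 epoch: trial %s, interval k=%s, start %+g ms, %d samples (+/-%d context)\n",
              x$trial_index, x$interval_index, x$start_offset_ms,
              length(x$samples), x$margin))
  invisible(x)
}

#' Extract the four stimulus-locked epochs of one trial
#'
#' Cuts, for each stimulus interval k = 0..3, the 70-sample window opening
#' at the grid-snapped offset (84, 284, 484, 684 ms after trial onset at
#' 250 Hz) plus its raw 100-sample context for time-shifting.
#'
#' @param x single-channel numeric signal (e.g. the Cz/Pz/Oz average).
#' @param trial_onset_ms trial onset in ms relative to the first sample.
#' @param sampling_rate sampling rate in Hz.
#' @param trial_index 1-based trial number recorded on the epochs.
#' @param n_samples epoch length in samples.
#' @param margin shift margin in samples on each side.
#' @param grid_snap see \code{\link{epoch_start_ms}}.
#' @return list of 4 \code{p300_epoch} objects, one per interval k = 0..3.
#' @export
extract_epochs <- function(x, trial_onset_ms, sampling_rate = 250,
                           trial_index = NA_integer_,
                           n_samples = 70, margin = 15,
                           grid_snap = "up") {
  step <- 1000 / sampling_rate
  ks <- 0:3
  starts_ms <- epoch_start_ms(ks, sampling_rate, grid_snap)
  lapply(ks, function(k) {
    start_ms <- starts_ms[k + 1]
    # 0-based sample index of the context start (epoch start minus margin)
    ctx_start <- round((trial_onset_ms + start_ms) / step) - margin
    ctx_end <- ctx_start + n_samples + 2 * margin   # half-open
    if (ctx_start < 0 || ctx_end > length(x)) {
      stop("signal too short for trial at ", trial_onset_ms,
           " ms (need samples ", ctx_start, "..", ctx_end, ")", call. = FALSE)
    }
    p300_epoch(x[(ctx_start + 1):ctx_end],
               trial_index = trial_index,
               interval_index = k,
               start_offset_ms = start_ms,
               n_samples = n_samples, margin = margin)
  })
}
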
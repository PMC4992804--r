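#' Canonical P300 deflection waveform
#'
#' A smooth unimodal positive deflection (Gaussian bump) used as the
#' synthetic event-related potential: peak value \code{amplitude} at
#' \code{peak_latency}, decaying to under 1\% of the peak at the window
#' edges when the default width is used and the peak is interior.
#'
#' @param peak_latency peak time in ms within \code{[0, duration]}.
#' @param amplitude peak amplitude in microvolts (>= 0; 0 gives a flat
#'   all-zero waveform).
#' @param duration waveform window length in ms.
#' @param sampling_rate sampling rate in Hz.
#' @param width Gaussian standard deviation in ms; default
#'   \code{min(peak_latency, duration - peak_latency) / 3.2}, which puts
#'   the window edges beyond 3.2 sigma (< 1\% of peak).
#' @return numeric vector of \code{round(duration * sampling_rate / 1000)}
#'   samples at times \code{0, 4, 8, ...} ms (half-open window).
#' @examples
#' w <- p300_waveform(300, 10, 400)
#' (which.max(w) - 1)   # sample 75 = 300 ms at 250 Hz
#' @export
p300_waveform <- function(peak_latency, amplitude, duration,
                          sampling_rate = 250, width = NULL) {
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (peak_latency < 0 || peak_latency > duration) {
    stop("peak_latency must lie in [0, duration]", call. = FALSE)
  }
  n <- round(duration * sampling_rate / 1000)
  t <- (seq_len(n) - 1) * 1000 / sampling_rate
  if (amplitude == 0) return(numeric(n))
  if (is.null(width)) {
    width <- min(peak_latency, duration - peak_latency) / 3.2
    if (width <= 0) {
      stop("peak at the window edge: supply an explicit width", call. = FALSE)
    }
  }
  amplitude * exp(-(t - peak_latency)^2 / (2 * width^2))
}

#' Simulation configuration for a labeled synthetic EEG session
#'
#' Bundles every knob of the session generator.  Defaults describe the
#' reference paradigm: 250 Hz, three channels (Cz, Pz, Oz), a P300 peaking
#' 300 ms post-flash at 15 uV (mid-range of the 10-25 uV amplitudes typical
#' at parietal/occipital sites), +/-40 ms uniform latency jitter (inside the
#' +/-60 ms tolerance of the shift grid), 20\% multiplicative amplitude
#' variability, and band-limited background noise.
#'
#' @param target_sequence integer vector of true target stimuli per trial,
#'   0-based in \code{{0, 1, 2, 3}}.
#' @param sampling_rate Hz.
#' @param n_channels number of channels (labelled Cz, Pz, Oz, Ch4, ...).
#' @param p300_amplitude peak amplitude in uV.
#' @param amplitude_variability half-width v of the per-trial multiplicative
#'   factor, drawn uniform on \code{[1 - v, 1 + v]}.
#' @param p300_peak_latency ms post-flash-onset (default 300).
#' @param p300_width_ms Gaussian sd of the deflection, ms.
#' @param latency_jitter uniform half-width of per-trial latency jitter, ms.
#' @param noise_sd standard deviation of the band-limited background noise,
#'   uV (0 disables noise).
#' @param fatigue_rate per-trial linear coefficient: trial i (1-based) has
#'   amplitude scaled by \code{1 - fatigue_rate * (i - 1)} (floored at 0)
#'   and jitter half-width scaled by \code{1 + fatigue_rate * (i - 1)}.
#'   0 disables the drift.
#' @param seed integer seed; the same seed and config give bit-identical
#'   sessions.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(target_sequence,
                              sampling_rate = 250,
                              n_channels = 3,
                              p300_amplitude = 15,
                              amplitude_variability = 0.2,
                              p300_peak_latency = 300,
                              p300_width_ms = 20,
                              latency_jitter = 40,
                              noise_sd = 48,
                              fatigue_rate = 0,
                              seed = 1L) {
  target_sequence <- as.integer(target_sequence)
  if (length(target_sequence) < 1) {
    stop("need at least one trial", call. = FALSE)
  }
  if (!all(target_sequence %in% 0:3)) {
    stop("target indices must be in {0, 1, 2, 3}", call. = FALSE)
  }
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (latency_jitter < 0) stop("latency_jitter must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (p300_amplitude < 0) stop("p300_amplitude must be >= 0", call. = FALSE)
  structure(
    list(target_sequence = target_sequence,
         n_trials = length(target_sequence),
         sampling_rate = sampling_rate,
         n_channels = n_channels,
         p300_amplitude = p300_amplitude,
         amplitude_variability = amplitude_variability,
         p300_peak_latency = p300_peak_latency,
         p300_width_ms = p300_width_ms,
         latency_jitter = latency_jitter,
         noise_sd = noise_sd,
         fatigue_rate = fatigue_rate,
         seed = as.integer(seed)),
    class = "simulation_config")
}

default_channel_labels <- function(n) {
  base <- c("Cz", "Pz", "Oz")
  if (n <= 3) base[seq_len(n)] else c(base, paste0("Ch", 4:n))
}

#' Simulate a labeled synthetic EEG session
#'
#' Generates a continuous multichannel recording for the four-choice
#' oddball paradigm.  Each trial adds one Gaussian P300 deflection, peaking
#' \code{p300_peak_latency} ms (plus drawn jitter) after the true target's
#' flash onset, identically on every channel, on top of independent white
#' Gaussian noise band-limited to 8-30 Hz and rescaled to \code{noise_sd}.
#' The deflection is truncated beyond 3.2 sigma so that, jitter permitting,
#' it stays inside the target's epoch window and the following interval's
#' overlap region; as in real recordings, the start of the next interval's
#' window can therefore see the tail of the deflection.
#'
#' All randomness flows from \code{config$seed} through R's default
#' generator in a fixed order (per-trial jitters, then per-trial amplitude
#' factors, then the noise matrix); the caller's RNG state is restored on
#' exit.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return An object of class \code{labeled_session}: list with
#'   \code{recording} (\code{eeg_recording}), \code{schedule}
#'   (\code{stimulus_schedule}), \code{truth} (0-based target per trial),
#'   \code{injected_latencies} (drawn jitter in ms per trial) and
#'   \code{config}.
#' @export
simulate_session <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a simulation_config", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  fs <- config$sampling_rate
  step <- 1000 / fs
  nt <- config$n_trials
  schedule <- stimulus_schedule((seq_len(nt) - 1) * 1050)
  n_samples <- round(nt * trial_duration_ms(schedule) / step)

  fatigue <- config$fatigue_rate * (seq_len(nt) - 1)
  jitter_hw <- config$latency_jitter * (1 + fatigue)
  jitters <- stats::runif(nt, -jitter_hw, jitter_hw)
  amp_factor <- stats::runif(nt,
                             1 - config$amplitude_variability,
                             1 + config$amplitude_variability)
  amps <- config$p300_amplitude * pmax(0, 1 - fatigue) * amp_factor

  clean <- numeric(n_samples)
  t_ms <- (seq_len(n_samples) - 1) * step
  width <- config$p300_width_ms
  support <- 3.2 * width
  for (i in seq_len(nt)) {
    k <- config$target_sequence[i]
    peak <- schedule$trial_onsets[i] + 200 * k +
      config$p300_peak_latency + jitters[i]
    idx <- which(t_ms >= peak - support & t_ms <= peak + support)
    if (length(idx) > 0 && amps[i] > 0) {
      clean[idx] <- clean[idx] +
        amps[i] * exp(-(t_ms[idx] - peak)^2 / (2 * width^2))
    }
  }

  labels <- default_channel_labels(config$n_channels)
  data <- matrix(clean, nrow = n_samples, ncol = config$n_channels)
  if (config$noise_sd > 0) {
    noise <- matrix(stats::rnorm(n_samples * config$n_channels),
                    nrow = n_samples)
    bp <- signal::butter(4, c(8, 30) / (fs / 2), type = "pass")
    noise <- apply(noise, 2, function(ch) {
      f <- signal::filtfilt(bp, ch)
      f / stats::sd(f) * config$noise_sd
    })
    data <- data + noise
  }

  structure(
    list(recording = eeg_recording(data, fs, labels),
         schedule = schedule,
         truth = config$target_sequence,
         injected_latencies = jitters,
         config = config),
    class = "labeled_session")
}

#' @export
print.labeled_session <- function(x, ...) {
  if (is.null(x$config)) {
    cat(sprintf("Labeled session: %d trial(s) (loaded from disk)\n",
                length(x$truth)))
  } else {
    cat(sprintf("Labeled synthetic session: %d trial(s), amplitude %g uV, noise sd %g uV, jitter +/-%g ms\n",
                x$config$n_trials, x$config$p300_amplitude,
                x$config$noise_sd, x$config$latency_jitter))
  }
  invisible(x)
}

#' Extract the stimulus-locked epochs of every trial in a session
#'
#' Convenience wrapper: channel-averages the recording and cuts the four
#' interval epochs of every trial.  Synthetic sessions are generated
#' directly in the analysis band, so no additional filtering is applied
#' here; pass the recording through \code{\link{bandpass_notch}} first for
#' raw recorded data.
#'
#' @param session a \code{labeled_session} (or any list with
#'   \code{recording} and \code{schedule} fields).
#' @return list (one element per trial) of lists of 4 \code{p300_epoch}s.
#' @export
session_epochs <- function(session) {
  avg <- average_channels(session$recording)
  lapply(seq_along(session$schedule$trial_onsets), function(i) {
    extract_epochs(avg, session$schedule$trial_onsets[i],
                   sampling_rate = session$recording$sampling_rate,
                   trial_index = i)
  })
}
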
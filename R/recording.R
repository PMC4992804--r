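#' Construct an EEG recording
#'
#' A lightweight container for a multichannel EEG time series: a
#' samples-by-channels numeric matrix in microvolts, the sampling rate, and
#' unique channel labels (Cz, Pz, Oz in the reference montage).
#'
#' @param data numeric matrix, samples x channels, in microvolts.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_labels character vector, one unique label per column.
#' @param start_time offset of the first sample in ms.
#' @return An object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(data, sampling_rate = 250,
                          channel_labels = c("Cz", "Pz", "Oz"),
                          start_time = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric", call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (ncol(data) != length(channel_labels)) {
    stop("need one channel label per column", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  colnames(data) <- channel_labels
  structure(
    list(data = data,
         sampling_rate = sampling_rate,
         channel_labels = channel_labels,
         start_time = start_time),
    class = "eeg_recording")
}

#' Recording duration in ms
#' @param recording an \code{eeg_recording}.
#' @export
duration_ms <- function(recording) {
  nrow(recording$data) / recording$sampling_rate * 1000
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d samples x %d channel(s) [%s] at %g Hz (%.0f ms)\n",
              nrow(x$data), ncol(x$data),
              paste(x$channel_labels, collapse = ", "),
              x$sampling_rate, duration_ms(x)))
  invisible(x)
}

#' Average a set of channels into one signal
#'
#' The classifier operates on the pointwise arithmetic mean of the Cz, Pz
#' and Oz channels; this computes that mean for any requested label set.
#'
#' @param recording an \code{eeg_recording}.
#' @param labels channel labels to average; defaults to all channels.
#' @return numeric vector, one value per sample.
#' @export
average_channels <- function(recording, labels = recording$channel_labels) {
  missing <- setdiff(labels, recording$channel_labels)
  if (length(missing) > 0) {
    stop("channel(s) not present: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rowMeans(recording$data[, labels, drop = FALSE])
}
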
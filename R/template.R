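#' Construct a P300 template object
#'
#' The per-subject reference waveform against which acquired epochs are
#' correlated: an average of elicited P300 epochs, min-max normalized to
#' [0, 1], 70 samples long (280 ms at 250 Hz).
#'
#' @param samples numeric vector of 70 values in [0, 1].
#' @param n_source_epochs number of epochs averaged into the template.
#' @param subject_id subject identifier string.
#' @return An object of class \code{p300_template}.
#' @export
p300_template <- function(samples, n_source_epochs = NA_integer_,
                          subject_id = "unknown") {
  samples <- as.numeric(samples)
  if (length(samples) != 70) {
    stop("template must have 70 samples, got ", length(samples),
         call. = FALSE)
  }
  if (any(samples < 0 | samples > 1)) {
    stop("template samples must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(samples = samples,
         n_source_epochs = n_source_epochs,
         subject_id = subject_id),
    class = "p300_template")
}

#' @export
print.p300_template <- function(x, ...) {
  cat(sprintf("P300 template: subject '%s', averaged from %s epoch(s)\n",
              x$subject_id, x$n_source_epochs))
  invisible(x)
}

#' Build a subject's P300 template from elicited target epochs
#'
#' Pointwise mean of the normalized epochs, re-normalized to [0, 1].  The
#' reference procedure averages ten elicited P300 epochs per subject; any
#' positive number is accepted.  Averaging attenuates uncorrelated noise,
#' so the template is closer to the underlying deflection than the
#' individual epochs it is built from.
#'
#' @param target_epochs non-empty list of \code{p300_epoch} objects (or
#'   numeric vectors of 70 normalized samples), all the same length.
#' @param subject_id subject identifier stored on the template.
#' @return a \code{p300_template}.
#' @export
build_template <- function(target_epochs, subject_id = "unknown") {
  if (length(target_epochs) == 0) {
    stop("need at least one epoch", call. = FALSE)
  }
  mats <- lapply(target_epochs, function(e) {
    if (inherits(e, "p300_epoch")) e$samples else as.numeric(e)
  })
  lens <- vapply(mats, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("epochs have mixed lengths: ", paste(unique(lens), collapse = ", "),
         call. = FALSE)
  }
  avg <- Reduce(`+`, mats) / length(mats)
  p300_template(normalize01(avg),
                n_source_epochs = length(mats),
                subject_id = subject_id)
}

#' Build a template from labeled training trials
#'
#' Selects, from a labeled session, the epoch at the known target interval
#' of each of the first \code{n} trials and averages them.  This automates
#' the reference procedure's manual selection of elicited P300 epochs from
#' offline training data.
#'
#' @param session a \code{labeled_session}.
#' @param n number of training trials to draw target epochs from.
#' @param subject_id subject identifier stored on the template.
#' @return a \code{p300_template}.
#' @export
template_from_session <- function(session, n = 10, subject_id = "unknown") {
  if (n < 1 || n > length(session$truth)) {
    stop("n must be in 1..", length(session$truth), call. = FALSE)
  }
  epochs <- session_epochs(session)
  targets <- lapply(seq_len(n), function(i) {
    epochs[[i]][[session$truth[i] + 1]]
  })
  build_template(targets, subject_id = subject_id)
}
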
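#' @title File formats
#' @description Readers and writers for recordings (delimited text or
#'   EDF), stimulus-event schedules (TSV), truth sequences (TSV), trained
#'   models (JSON) and run configuration (YAML).  All writers round-trip
#'   losslessly at their stated precision: text numerics are written with
#'   17 significant digits; EDF is quantized to its 16-bit integer
#'   encoding.
#' @name signal_io
NULL

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a recording as delimited text
#'
#' One header row (\code{time_ms} then the channel labels), then one row
#' per sample, comma-separated, full double precision.
#'
#' @param recording an \code{eeg_recording}.
#' @param path output file path.
#' @export
write_recording_csv <- function(recording, path) {
  step <- 1000 / recording$sampling_rate
  t_ms <- recording$start_time + (seq_len(nrow(recording$data)) - 1) * step
  m <- cbind(fmt_full(t_ms), apply(recording$data, 2, fmt_full))
  lines <- c(paste(c("time_ms", recording$channel_labels), collapse = ","),
             apply(m, 1, paste, collapse = ","))
  writeLines(lines, path)
}

#' Read a recording from delimited text
#'
#' Expects the dialect of \code{\link{write_recording_csv}}.  The sampling
#' rate is inferred from the time column, which must be uniform.
#'
#' @param path input file path.
#' @param required_channels labels that must be present (matched
#'   case-insensitively), or \code{NULL} to accept any.
#' @return an \code{eeg_recording}.
#' @export
read_recording_csv <- function(path, required_channels = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_ms" %in% names(df)) {
    stop("format error: missing time_ms column in ", path, call. = FALSE)
  }
  t_ms <- df$time_ms
  if (length(t_ms) < 2) stop("format error: need at least 2 samples", call. = FALSE)
  dt <- diff(t_ms)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop("format error: non-uniform sampling in ", path, call. = FALSE)
  }
  labels <- setdiff(names(df), "time_ms")
  check_channels(labels, required_channels, path)
  eeg_recording(as.matrix(df[labels]),
                sampling_rate = 1000 / stats::median(dt),
                channel_labels = labels,
                start_time = t_ms[1])
}

check_channels <- function(labels, required, path) {
  if (is.null(required)) return(invisible())
  missing <- required[!tolower(required) %in% tolower(labels)]
  if (length(missing) > 0) {
    stop("channel error: ", path, " lacks channel(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

# ---- EDF (European Data Format) ---------------------------------------

edf_pad <- function(x, width) {
  s <- sprintf("%-*s", width, as.character(x))
  substr(s, 1, width)
}

#' Write a recording as an EDF file
#'
#' Plain continuous EDF with a single data record spanning the whole
#' recording.  Samples are scaled to the full 16-bit digital range per
#' channel, so the round trip is exact only up to that quantization
#' (about 1/65000 of each channel's amplitude range).
#'
#' @param recording an \code{eeg_recording}.
#' @param path output file path.
#' @export
write_recording_edf <- function(recording, path) {
  data <- recording$data
  ns <- ncol(data)
  n <- nrow(data)
  dmin <- -32768; dmax <- 32767
  pmin <- apply(data, 2, min)
  pmax <- apply(data, 2, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeBin(charToRaw(edf_pad(x, width)), con)
  wr("0", 8)                                   # version
  wr("X X X X", 80)                            # patient id
  wr("Startdate X X X X", 80)                  # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)         # date, time
  wr(256 * (1 + ns), 8)                        # header bytes
  wr("", 44)
  wr(1, 8)                                     # number of data records
  wr(fmt_sig(n / recording$sampling_rate), 8)  # record duration, s
  wr(ns, 4)
  for (lab in recording$channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)            # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(fmt_sig(pmin[i]), 8)
  for (i in seq_len(ns)) wr(fmt_sig(pmax[i]), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)            # prefiltering
  for (i in seq_len(ns)) wr(n, 8)              # samples per record
  for (i in seq_len(ns)) wr("", 32)
  for (i in seq_len(ns)) {
    dig <- round((data[, i] - pmin[i]) / (pmax[i] - pmin[i]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

# 8-char EDF numeric field: as many significant digits as fit
fmt_sig <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g", flag = "-")
    s <- sub("e([+-])0(\\d)$", "e\\1\\2", s)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot format ", x, " into an 8-character EDF field", call. = FALSE)
}

#' Read an EDF recording
#'
#' Reads plain continuous EDF.  Channel labels are matched
#' case-insensitively against \code{required_channels} when given.
#'
#' @param path input file path.
#' @param required_channels labels that must be present, or \code{NULL}.
#' @return an \code{eeg_recording}.
#' @export
read_recording_edf <- function(path, required_channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readBin(con, "raw", width)
    if (length(raw) < width) stop("format error: truncated EDF header in ",
                                  path, call. = FALSE)
    trimws(rawToChar(raw))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  n_records <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("format error: bad EDF signal count", call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) {
    stop("format error: non-uniform sampling across EDF signals", call. = FALSE)
  }
  check_channels(labels, required_channels, path)
  out <- matrix(NA_real_, n_records * spr[1], ns)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[i], size = 2, endian = "little",
                     signed = TRUE)
      if (length(dig) < spr[i]) {
        stop("format error: truncated EDF data in ", path, call. = FALSE)
      }
      phys <- (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) +
        pmin[i]
      out[(r - 1) * spr[1] + seq_len(spr[i]), i] <- phys
    }
  }
  eeg_recording(out, sampling_rate = spr[1] / rec_dur,
                channel_labels = labels)
}

#' Read a recording in either supported format
#' @param path input file path.
#' @param format \code{"csv"}, \code{"edf"}, or \code{"auto"} (by file
#'   extension).
#' @param required_channels see the format-specific readers.
#' @return an \code{eeg_recording}.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           required_channels = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
    else if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
    else stop("format error: cannot infer recording format from extension of ",
              path, call. = FALSE)
  }
  switch(format,
         csv = read_recording_csv(path, required_channels),
         edf = read_recording_edf(path, required_channels))
}

# ---- events and truth --------------------------------------------------

#' Write a stimulus-event schedule as TSV
#'
#' One row per flash: \code{onset_ms}, \code{stimulus_index} (0-based)
#' and \code{is_target} (0/1 against the truth sequence).
#'
#' @param schedule a \code{stimulus_schedule}.
#' @param truth 0-based target per trial (optional; \code{is_target}
#'   written as 0 when absent).
#' @param path output file path.
#' @export
write_events <- function(schedule, path, truth = NULL) {
  rows <- lapply(seq_along(schedule$trial_onsets), function(i) {
    data.frame(onset_ms = flash_onsets(schedule, i),
               stimulus_index = seq_len(schedule$n_stimuli) - 1,
               is_target = if (is.null(truth)) 0L else
                 as.integer(seq_len(schedule$n_stimuli) - 1 == truth[i]))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a stimulus-event schedule from TSV
#'
#' @param path TSV with columns \code{onset_ms} and \code{stimulus_index}
#'   (optional \code{is_target}).
#' @param n_stimuli number of stimuli; indices outside
#'   \code{0..n_stimuli-1} are a format error.
#' @return list with \code{events} (the validated data.frame) and
#'   \code{schedule} (a \code{stimulus_schedule} built from the
#'   stimulus-0 onsets; \code{NULL}, with a warning, for an empty file).
#' @export
read_events <- function(path, n_stimuli = 4) {
  df <- utils::read.delim(path)
  if (!all(c("onset_ms", "stimulus_index") %in% names(df))) {
    stop("format error: events file needs onset_ms and stimulus_index",
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("empty events file: ", path)
    return(list(events = df, schedule = NULL))
  }
  if (is.unsorted(df$onset_ms, strictly = TRUE)) {
    stop("format error: event onsets must be strictly increasing",
         call. = FALSE)
  }
  if (!all(df$stimulus_index %in% 0:(n_stimuli - 1))) {
    stop("format error: stimulus_index outside 0..", n_stimuli - 1,
         call. = FALSE)
  }
  trial_onsets <- df$onset_ms[df$stimulus_index == 0]
  list(events = df,
       schedule = stimulus_schedule(trial_onsets, n_stimuli = n_stimuli))
}

#' Write / read a truth sequence as TSV
#'
#' @param truth 0-based target index per trial.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(
    data.frame(trial = seq_along(truth), target_index = truth),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path)
  if (!"target_index" %in% names(df)) {
    stop("format error: truth file needs a target_index column", call. = FALSE)
  }
  as.integer(df$target_index)
}

# ---- model file --------------------------------------------------------

#' Save a trained model (with its template) as JSON
#'
#' Human-readable structured text holding layer sizes, all weights and
#' biases at full precision, the decision threshold, and the subject's
#' P300 template.
#'
#' @param model an \code{ffnn_model}.
#' @param path output file path.
#' @export
save_model <- function(model, path) {
  obj <- list(
    format = "p300tsc-ffnn",
    n = model$n, m = model$m,
    w = unclass(model$w), b = model$b,
    Hw = model$Hw, Ob = model$Ob,
    threshold = model$threshold)
  if (!is.null(model$template)) {
    obj$template <- list(samples = model$template$samples,
                         n_source_epochs = model$template$n_source_epochs,
                         subject_id = model$template$subject_id)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

#' Load a model saved by \code{\link{save_model}}
#'
#' @param path input file path.
#' @return an \code{ffnn_model}.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("model-format error: cannot parse ", path, " (",
                         conditionMessage(e), ")", call. = FALSE)
                  })
  need <- c("n", "m", "w", "b", "Hw", "Ob", "threshold")
  if (!all(need %in% names(obj))) {
    stop("model-format error: missing field(s) ",
         paste(setdiff(need, names(obj)), collapse = ", "), call. = FALSE)
  }
  w <- as.matrix(obj$w)
  if (!identical(dim(w), c(as.integer(obj$m), as.integer(obj$n))) ||
      length(obj$b) != obj$m || length(obj$Hw) != obj$m) {
    stop("model-format error: stored sizes do not match declared n=",
         obj$n, ", m=", obj$m, call. = FALSE)
  }
  template <- NULL
  if (!is.null(obj$template)) {
    template <- p300_template(obj$template$samples,
                              n_source_epochs = obj$template$n_source_epochs,
                              subject_id = obj$template$subject_id)
  }
  ffnn_model(w, obj$b, obj$Hw, obj$Ob,
             threshold = obj$threshold, template = template)
}

# ---- config and session bundles ---------------------------------------

#' Read a YAML run configuration
#' @param path YAML file path.
#' @return named list of configuration values.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Write a simulated session to a directory
#'
#' Writes \code{recording.csv} (or \code{recording.edf}),
#' \code{events.tsv}, \code{truth.tsv} and a \code{provenance.yaml}
#' snapshot of the generating configuration.
#'
#' @param session a \code{labeled_session}.
#' @param dir output directory (created if needed).
#' @param format \code{"csv"} or \code{"edf"}.
#' @return \code{dir}, invisibly.
#' @export
write_session <- function(session, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec_path <- file.path(dir, paste0("recording.", format))
  if (format == "csv") write_recording_csv(session$recording, rec_path)
  else write_recording_edf(session$recording, rec_path)
  write_events(session$schedule, file.path(dir, "events.tsv"),
               truth = session$truth)
  write_truth(session$truth, file.path(dir, "truth.tsv"))
  prov <- unclass(session$config)
  prov$package_version <- as.character(utils::packageVersion("p300tsc"))
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
  invisible(dir)
}

#' Read a session directory written by \code{\link{write_session}}
#' @param dir session directory.
#' @return a \code{labeled_session} (without injected latencies, which are
#'   generator-internal ground truth and not part of the on-disk formats).
#' @export
read_session <- function(dir) {
  rec_path <- if (file.exists(file.path(dir, "recording.csv")))
    file.path(dir, "recording.csv") else file.path(dir, "recording.edf")
  ev <- read_events(file.path(dir, "events.tsv"))
  structure(
    list(recording = read_recording(rec_path),
         schedule = ev$schedule,
         truth = read_truth(file.path(dir, "truth.tsv")),
         injected_latencies = NULL,
         config = NULL),
    class = "labeled_session")
}
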
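#' Wolpaw bits per selection
#'
#' Information conveyed by one selection among \code{K_s} equiprobable
#' targets at accuracy \code{P_a}:
#' \deqn{B = \log_2 K_s + P_a \log_2 P_a +
#'       (1 - P_a) \log_2\frac{1 - P_a}{K_s - 1}}
#' with the convention \eqn{0 \log 0 = 0}.
#'
#' @param P_a accuracy as a fraction in [0, 1].
#' @param K_s number of selectable stimuli (>= 2).
#' @return bits per selection (0 at chance level \code{1/K_s}).
#' @export
bits_per_command <- function(P_a, K_s = 4) {
  if (P_a < 0 || P_a > 1) stop("P_a must lie in [0, 1]", call. = FALSE)
  if (K_s < 2) stop("K_s must be >= 2", call. = FALSE)
  xlog2 <- function(x) if (x == 0) 0 else x * log2(x)
  log2(K_s) + xlog2(P_a) +
    (if (P_a == 1) 0 else (1 - P_a) * log2((1 - P_a) / (K_s - 1)))
}

#' Information transfer rate in bits per minute
#'
#' Bits per selection divided by the command-time interval
#' \code{CTI = T_exp / N_o} and scaled to minutes.
#'
#' @param T_exp experimental (elapsed session) time in seconds.
#' @param N_o number of correct target events.
#' @param P_a accuracy fraction.
#' @param K_s number of stimuli.
#' @return ITR in bits/min (0 when \code{N_o} is 0).
#' @export
itr <- function(T_exp, N_o, P_a, K_s = 4) {
  if (T_exp <= 0) stop("T_exp must be > 0", call. = FALSE)
  if (N_o < 0) stop("N_o must be >= 0", call. = FALSE)
  if (N_o == 0) return(0)
  bits_per_command(P_a, K_s) * 60 / (T_exp / N_o)
}

#' Summarize a session's decision log
#'
#' Counts correct, wrong and non-recognition trials, and evaluates the
#' information transfer rate from the command events.  \code{T_exp} is the
#' full elapsed session time (all trials, including non-recognition, and
#' the inter-trial gaps that are part of the 1050 ms trial), \code{N_o}
#' the number of correct command events, and \code{P_a} the fraction of
#' command events that were correct.
#'
#' @param log a \code{decision_log} from \code{\link{classify_session}}.
#' @param trial_duration_s trial duration in seconds (1.05 in the
#'   reference paradigm).
#' @param K_s number of stimuli.
#' @return list of class \code{session_metrics} with counts, percentage
#'   rates (summing to 100), \code{T_exp}, \code{N_o}, \code{P_a} and
#'   \code{itr}.
#' @export
session_metrics <- function(log, trial_duration_s = 1.05, K_s = 4) {
  out <- factor(log$trial_outcome,
                levels = c("correct", "wrong", "non_recognition"))
  counts <- as.integer(table(out))
  names(counts) <- levels(out)
  stopifnot(sum(counts) == log$n_trials)
  cmd <- log$events[log$events$type == "command", , drop = FALSE]
  n_correct_ev <- sum(cmd$correct)
  n_cmd <- nrow(cmd)
  P_a <- if (n_cmd > 0) n_correct_ev / n_cmd else 0
  T_exp <- log$n_trials * trial_duration_s
  structure(
    list(n_trials = log$n_trials,
         counts = counts,
         rates_pct = 100 * counts / log$n_trials,
         n_commands = n_cmd,
         T_exp = T_exp,
         N_o = n_correct_ev,
         K_s = K_s,
         P_a = P_a,
         itr = itr(T_exp, n_correct_ev, P_a, K_s)),
    class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf("Session: %d trials, correct/wrong/non-recognition = %.1f/%.1f/%.1f %%\n",
              x$n_trials, x$rates_pct[1], x$rates_pct[2], x$rates_pct[3]))
  cat(sprintf("  %d command(s), accuracy P_a = %.3f, ITR = %.2f bits/min\n",
              x$n_commands, x$P_a, x$itr))
  invisible(x)
}

#' Cumulative wrong-recognition (fatigue) curve
#'
#' Tracks how wrong recognitions accumulate over a session: \code{En} is
#' the running count of wrong recognitions, \code{Et} the session total,
#' and the accumulation rate \code{Er = En / Et} rises from 0 to 1 (an
#' approximately linear rise means errors are uniform over the session; a
#' late steep rise indicates fatigue).  The alternative printed form
#' \code{(En - Et) / Et}, which runs from -1 to 0, is available via
#' \code{shifted = TRUE}.
#'
#' @param wrong_flags logical (or 0/1) vector, one flag per trial.
#' @param shifted use the shifted form \code{(En - Et) / Et}.
#' @return list of class \code{fatigue_curve} with \code{En}, \code{Et}
#'   and \code{Er}; \code{Er} is all-\code{NA} (with a warning) when no
#'   trial is wrong.
#' @export
fatigue_curve <- function(wrong_flags, shifted = FALSE) {
  if (length(wrong_flags) < 1) stop("need at least one trial", call. = FALSE)
  w <- as.numeric(as.logical(wrong_flags))
  En <- cumsum(w)
  Et <- sum(w)
  if (Et == 0) {
    warning("no wrong recognitions: accumulation rate undefined")
    Er <- rep(NA_real_, length(w))
  } else {
    Er <- if (shifted) (En - Et) / Et else En / Et
  }
  structure(list(En = En, Et = Et, Er = Er), class = "fatigue_curve")
}

resample_arclength <- function(xy, n_points) {
  xy <- as.matrix(xy)
  seg <- sqrt(rowSums(diff(xy)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate (zero-length) trajectory", call. = FALSE)
  si <- seq(0, total, length.out = n_points)
  cbind(stats::approx(s, xy[, 1], xout = si, ties = "ordered")$y,
        stats::approx(s, xy[, 2], xout = si, ties = "ordered")$y)
}

lateral_deviation <- function(xy) {
  # signed perpendicular distance from the chord joining the endpoints
  a <- xy[1, ]; b <- xy[nrow(xy), ]
  chord <- b - a
  len <- sqrt(sum(chord^2))
  if (len == 0) return(rep(0, nrow(xy)))
  nrm <- c(-chord[2], chord[1]) / len
  as.numeric((sweep(xy, 2, a)) %*% nrm)
}

#' Compare an executed trajectory with the desired one
#'
#' Both trajectories are resampled to a common normalized arc-length
#' parameterization; the Pearson correlation is computed between their
#' lateral-deviation profiles (signed perpendicular distance from each
#' path's own start-to-end chord), and the path-length difference is
#' reported as a percentage of the desired length.
#'
#' @param actual,desired two-column matrices (or data.frames) of x, y
#'   coordinates in cm, at least 2 points each.
#' @param n_points number of arc-length stations for resampling.
#' @return list with \code{ppmcc}, \code{length_difference_pct},
#'   \code{length_actual} and \code{length_desired}.
#' @export
compare_trajectories <- function(actual, desired, n_points = 200) {
  actual <- as.matrix(actual); desired <- as.matrix(desired)
  if (nrow(actual) < 2 || nrow(desired) < 2) {
    stop("trajectories need at least 2 points", call. = FALSE)
  }
  path_len <- function(xy) sum(sqrt(rowSums(diff(xy)^2)))
  la <- path_len(actual); ld <- path_len(desired)
  if (la <= 0 || ld <= 0) {
    stop("degenerate (zero-length) trajectory", call. = FALSE)
  }
  ra <- resample_arclength(actual, n_points)
  rd <- resample_arclength(desired, n_points)
  list(ppmcc = ppmcc(lateral_deviation(ra), lateral_deviation(rd)),
       length_difference_pct = (la - ld) / ld * 100,
       length_actual = la,
       length_desired = ld)
}
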
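#' Pearson product-moment correlation between two epochs
#'
#' The similarity measure at the core of the classifier: the centered
#' product-moment correlation between an acquired 70-sample epoch P and
#' the subject's template Q.  If either input is constant the coefficient
#' is 0/0; by convention 0 (no correlation) is returned.
#'
#' @param p,q numeric vectors of equal length (>= 2).
#' @return correlation in [-1, 1].
#' @export
ppmcc <- function(p, q) {
  if (length(p) != length(q)) {
    stop("length mismatch: ", length(p), " vs ", length(q), call. = FALSE)
  }
  if (length(p) < 2) stop("need at least 2 samples", call. = FALSE)
  dp <- p - mean(p)
  dq <- q - mean(q)
  denom <- sqrt(sum(dp^2) * sum(dq^2))
  if (denom == 0) return(0)
  r <- sum(dp * dq) / denom
  # guard against rounding drift past +/-1
  max(-1, min(1, r))
}

#' Time-shift correlation feature vector
#'
#' The 31-element feature vector of one epoch: the epoch's acquisition
#' window is slid over its raw context in 1-sample (4 ms) steps across
#' +/-15 samples (+/-60 ms), each 70-sample slice is min-max normalized,
#' and its correlation with the template is recorded.  Element i
#' corresponds to a shift of (i - 16) * 4 ms, so a P300 arriving delta ms
#' late peaks at index 16 + delta/4.  A matched epoch produces a
#' bell-shaped curve over the 31 shifts; mismatched signals do not.
#'
#' @param epoch a \code{p300_epoch} carrying its raw context.
#' @param template a \code{p300_template} (or numeric vector of 70
#'   samples).
#' @return An object of class \code{feature_vector}: list with \code{r}
#'   (31 correlations), \code{interval_index}, \code{trial_index}.
#' @export
timeshift_features <- function(epoch, template) {
  if (!inherits(epoch, "p300_epoch") || is.null(epoch$context)) {
    stop("epoch must carry its raw shift context", call. = FALSE)
  }
  q <- if (inherits(template, "p300_template")) template$samples else
    as.numeric(template)
  n <- length(q)
  margin <- epoch$margin
  if (length(epoch$context) != n + 2 * margin) {
    stop("context length ", length(epoch$context),
         " does not match template length ", n, " plus margins",
         call. = FALSE)
  }
  shifts <- seq(-margin, margin)
  r <- vapply(shifts, function(s) {
    slice <- epoch$context[(margin + s + 1):(margin + s + n)]
    ppmcc(normalize01(slice), q)
  }, numeric(1))
  structure(
    list(r = r,
         shifts_ms = shifts * 4,
         interval_index = epoch$interval_index,
         trial_index = epoch$trial_index),
    class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("Time-shift features: %d shifts, max r = %.4f at %+d ms\n",
              length(x$r), max(x$r), x$shifts_ms[which.max(x$r)]))
  invisible(x)
}
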
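#' Photoacoustic signal container
#'
#' A `pa_signal` is a uniformly sampled real-valued trace: amplitude samples,
#' the sampling interval `ts` (seconds), the absolute time of the first sample
#' `t0` (seconds), an optional class label, and free-form metadata.
#'
#' @param samples numeric vector of amplitudes (arbitrary units), length >= 4,
#'   all finite.
#' @param ts sampling interval in seconds (> 0).
#' @param t0 time of the first sample in seconds.
#' @param label class label (`"HF"`, `"HM"`, `"A1"`, `"A2"`, `"L"`, ...) or
#'   `"unlabeled"`.
#' @param meta named list of annotations.
#' @return an object of class `pa_signal`.
#' @examples
#' s <- pa_signal(sin(2 * pi * 3e6 * (0:99) * 1e-8), ts = 1e-8)
#' length(s$samples)
#' @export
pa_signal <- function(samples, ts, t0 = 0, label = "unlabeled", meta = list()) {
  samples <- as.numeric(samples)
  if (length(samples) < 4L) stop("pa_signal: need at least 4 samples")
  if (!all(is.finite(samples))) stop("pa_signal: non-finite amplitude values")
  if (!is.numeric(ts) || length(ts) != 1L || !is.finite(ts) || ts <= 0) {
    stop("pa_signal: ts must be a positive scalar (seconds)")
  }
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0)) {
    stop("pa_signal: t0 must be a finite scalar (seconds)")
  }
  structure(
    list(samples = samples, ts = ts, t0 = t0,
         label = as.character(label), meta = meta),
    class = "pa_signal"
  )
}

#' @export
print.pa_signal <- function(x, ...) {
  cat(sprintf(
    "<pa_signal> %d samples, ts = %.4g s (fs = %.4g Hz), t0 = %.4g s, label = %s\n",
    length(x$samples), x$ts, 1 / x$ts, x$t0, x$label))
  invisible(x)
}

# Shared onset rule: first index where |y| reaches `frac` of max |y|.
# Used by the identification window alignment and the time-of-arrival feature.
onset_index <- function(y, frac = 0.1) {
  m <- max(abs(y))
  if (m == 0) stop("onset_index: all-zero signal")
  which(abs(y) >= frac * m)[1]
}

#' Time vector of a signal
#'
#' @param signal a [pa_signal()].
#' @return absolute sample times in seconds.
#' @export
pa_time <- function(signal) {
  signal$t0 + (seq_along(signal$samples) - 1) * signal$ts
}
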
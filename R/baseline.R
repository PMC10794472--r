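# Benchmark feature families: time-domain descriptors, frequency-domain
# descriptors from a band fit to the dB power spectrum (the quantitative-
# ultrasound convention), and ARMA(2,2) coefficients by two-stage
# Hannan-Rissanen least squares.

#' Time-domain features
#'
#' Four descriptors of the raw trace: maximum amplitude, time of arrival
#' (`t0 + ts * (first index with |y| >= 10% of max |y|)`, the same onset rule
#' as the identification stage), root-mean-square value, and area under the
#' curve (trapezoidal integral of `|y|` over the declared window).
#'
#' @param signal a [pa_signal()] (not all-zero).
#' @param sample_id identifier carried into the feature vector.
#' @return a `pa_features` object (family `"TD"`).
#' @export
time_domain_features <- function(signal, sample_id = NA_character_) {
  stopifnot(inherits(signal, "pa_signal"))
  y <- signal$samples
  if (max(abs(y)) == 0) stop("time_domain_features: all-zero signal")
  k0 <- onset_index(y)
  pa_features(
    sample_id = sample_id, label = signal$label, family = "TD",
    values = c(max_amplitude = max(y),
               arrival_time = signal$t0 + signal$ts * (k0 - 1),
               rms = sqrt(mean(y^2)),
               auc = trapz(abs(y), signal$ts)))
}

#' One-sided power spectral density (periodogram)
#'
#' Plain periodogram of the onset-aligned analysis window with a taper (Hann
#' by default), scaled as a one-sided density `|X(f)|^2 / (fs * sum(w^2))`
#' with interior bins doubled, and reported in dB. `nfft` may be raised above
#' the window length for zero-padded grid interpolation; the default is the
#' plain (unpadded) periodogram. With `window = "rect"` (and the default
#' `nfft`), Parseval holds: `sum(10^(power_db/10)) * df` equals the signal's
#' mean power.
#'
#' @param signal a [pa_signal()] of length >= 16.
#' @param window `"hann"` or `"rect"`.
#' @param nfft FFT length (default: the onset-aligned window length).
#' @param align_onset shift the window so it starts at the detected onset.
#' @return an object of class `pa_spectrum` with `frequencies` (Hz),
#'   `power_db`, `resolution` (the data-limited bin width `fs / N`, Hz),
#'   `df` (grid spacing `fs / nfft`, Hz).
#' @export
power_spectrum <- function(signal, window = c("hann", "rect"), nfft = NULL,
                           align_onset = TRUE) {
  stopifnot(inherits(signal, "pa_signal"))
  window <- match.arg(window)
  y <- signal$samples
  if (align_onset) {
    k0 <- onset_index(y)
    y <- y[k0:length(y)]
  }
  N <- length(y)
  if (N < 16L) stop("power_spectrum: need at least 16 samples")
  fs <- 1 / signal$ts
  w <- switch(window,
              hann = 0.5 * (1 - cos(2 * pi * (0:(N - 1)) / (N - 1))),
              rect = rep(1, N))
  if (is.null(nfft)) nfft <- N
  nfft <- as.integer(nfft)
  if (nfft < N) stop("power_spectrum: nfft smaller than the window")
  X <- stats::fft(c(y * w, rep(0, nfft - N)))
  nh <- nfft %/% 2L
  p <- Mod(X[1:(nh + 1L)])^2 / (fs * sum(w^2))
  scale2 <- rep(2, nh + 1L)
  scale2[1] <- 1
  if (nfft %% 2L == 0L) scale2[nh + 1L] <- 1
  p <- p * scale2
  p <- pmax(p, .Machine$double.xmin)
  structure(
    list(frequencies = (0:nh) * fs / nfft,
         power_db = 10 * log10(p),
         resolution = fs / N,
         df = fs / nfft),
    class = "pa_spectrum"
  )
}

#' Frequency-domain features
#'
#' Least-squares line fit of `power_db` against frequency over the analysis
#' band (default 1-20 MHz): spectral slope (dB/MHz), magnitude intercept
#' (extrapolation of the band fit to 0 Hz, in dB), midband fit (fitted value
#' at the band center), and peak frequency (argmax of `power_db` in the band,
#' Hz).
#'
#' @param signal a [pa_signal()].
#' @param band numeric length-2, band edges in Hz (must lie below Nyquist).
#' @param sample_id identifier carried into the feature vector.
#' @param spectrum optional precomputed [power_spectrum()].
#' @return a `pa_features` object (family `"FD"`).
#' @export
frequency_domain_features <- function(signal, band = c(1e6, 2e7),
                                      sample_id = NA_character_,
                                      spectrum = NULL) {
  stopifnot(inherits(signal, "pa_signal"))
  if (length(band) != 2L || band[1] >= band[2]) stop("frequency_domain_features: bad band")
  ps <- if (is.null(spectrum)) power_spectrum(signal) else spectrum
  if (band[2] > max(ps$frequencies)) {
    stop("frequency_domain_features: band extends beyond the Nyquist frequency")
  }
  sel <- ps$frequencies >= band[1] & ps$frequencies <= band[2]
  if (sum(sel) < 3L) stop("frequency_domain_features: fewer than 3 bins in band")
  f_mhz <- ps$frequencies[sel] / 1e6
  p_db <- ps$power_db[sel]
  fit <- stats::lm.fit(cbind(1, f_mhz), p_db)
  intercept <- fit$coefficients[1]
  slope <- fit$coefficients[2]
  mid_mhz <- mean(band) / 1e6
  pa_features(
    sample_id = sample_id, label = signal$label, family = "FD",
    values = c(slope = unname(slope),
               intercept = unname(intercept),
               midband_fit = unname(intercept + slope * mid_mhz),
               peak_frequency = ps$frequencies[sel][which.max(p_db)]))
}

#' ARMA(2,2) coefficient features (Hannan-Rissanen)
#'
#' Two-stage long-autoregression procedure on the onset-aligned trace:
#' (1) a high-order AR fit by least squares yields innovation estimates;
#' (2) `y(k)` is regressed on `y(k-1), y(k-2)` and the lagged innovations
#' `e(k-1), e(k-2)`. The four coefficients `(a1, a2, b1, b2)` are the
#' features, with the AR sign convention
#' `y(k) = a1 y(k-1) + a2 y(k-2) + e(k) + b1 e(k-1) + b2 e(k-2)`.
#' Both regressions use the pseudo-inverse (minimum-norm solution), so the
#' noise-free case -- where the innovation columns vanish -- degrades to the
#' pure AR(2) recurrence. A fit whose AR polynomial has a root on or inside
#' the unit circle (non-stationary) is flagged in `meta$stationary` but the
#' coefficients are still returned.
#'
#' @param signal a [pa_signal()] with at least 50 onset-aligned samples
#'   (assumed already at the analysis rate, e.g. 100 MS/s).
#' @param p,q ARMA orders (fixed to 2, 2).
#' @param sample_id identifier carried into the feature vector.
#' @param ar_order stage-1 long-AR order (default `min(20, N %/% 5)`).
#' @return a `pa_features` object (family `"ARMA"`).
#' @export
arma_features <- function(signal, p = 2L, q = 2L, sample_id = NA_character_,
                          ar_order = NULL) {
  stopifnot(inherits(signal, "pa_signal"))
  if (p != 2L || q != 2L) stop("arma_features: only ARMA(2,2) is supported")
  y <- signal$samples
  k0 <- onset_index(y)
  y <- y[k0:length(y)]
  N <- length(y)
  if (N < 50L) stop("arma_features: need at least 50 onset-aligned samples")
  if (is.null(ar_order)) ar_order <- min(20L, N %/% 5L)
  L <- as.integer(ar_order)
  # Stage 1: long AR by least squares -> innovations.
  rows <- (L + 1L):N
  Xar <- sapply(seq_len(L), function(l) y[rows - l])
  phi <- pa_pinv(Xar) %*% y[rows]
  e_full <- rep(0, N)
  e_full[rows] <- y[rows] - drop(Xar %*% phi)
  # Stage 2: regress y on its own lags and lagged innovations.
  rows2 <- (L + 3L):N
  X2 <- cbind(y[rows2 - 1L], y[rows2 - 2L], e_full[rows2 - 1L], e_full[rows2 - 2L])
  coef <- drop(pa_pinv(X2) %*% y[rows2])
  names(coef) <- c("a1", "a2", "b1", "b2")
  # Stationarity: roots of z^2 - a1 z - a2 must be inside the unit circle.
  roots <- polyroot(c(-coef["a2"], -coef["a1"], 1))
  stationary <- all(Mod(roots) < 1 + 1e-8)
  pa_features(sample_id = sample_id, label = signal$label, family = "ARMA",
              values = coef,
              meta = list(stationary = stationary, ar_order = L))
}

#' Extract one feature family from a trace
#'
#' Dispatcher over the four families.
#'
#' @param signal a [pa_signal()].
#' @param family `"TD"`, `"FD"`, `"ARMA"` or `"SS"`.
#' @param sample_id identifier carried into the feature vector.
#' @param ... family-specific options (`band` for FD; [identify_ss()] options
#'   for SS).
#' @return a `pa_features` object, or `NULL` if the sample was excluded.
#' @export
extract_features <- function(signal, family = c("TD", "FD", "ARMA", "SS"),
                             sample_id = NA_character_, ...) {
  family <- match.arg(family)
  switch(family,
         TD = time_domain_features(signal, sample_id = sample_id),
         FD = frequency_domain_features(signal, sample_id = sample_id, ...),
         ARMA = arma_features(signal, sample_id = sample_id),
         SS = extract_ss_features(signal, sample_id = sample_id, ...))
}
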
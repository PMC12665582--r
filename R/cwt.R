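#' Morlet continuous wavelet scalogram of one channel
#'
#' Complex Morlet transform (centre frequency `omega0 = 6` cycles) evaluated
#' on the pinned geometric grid of [cwt_frequency_grid()] via FFT
#' convolution with an analytic Gaussian frequency window (sd `f / omega0`,
#' peak gain 2, so a tone of amplitude A has envelope ~A).
#'
#' @param x Numeric vector (one channel of one epoch), length >= fs (1 s).
#' @param fs Sampling rate (Hz); must exceed twice the top grid frequency.
#' @param omega0 Morlet centre frequency in cycles (default 6).
#' @return Object of class `scalogram`: list with `freqs_hz`, `amplitude`
#'   (frequency x time, nonnegative), `fs`.
#' @export
morlet_scalogram <- function(x, fs, omega0 = 6) {
  if (length(x) < fs) stop("signal shorter than 1 s")
  freqs <- cwt_frequency_grid()
  if (fs / 2 <= max(freqs)) stop("fs incompatible with the 0.5-45 Hz grid")
  amp <- t(cpp_cwt_amplitude(as.numeric(x), fs, freqs, omega0))
  structure(list(freqs_hz = freqs, amplitude = amp, fs = fs),
            class = "scalogram")
}

#' Band-resolved envelope series from a scalogram
#'
#' For grid frequencies inside the band (half-open `[lo, hi)`): `AM(t)` is
#' the band-mean amplitude, `centroid_t(t)` the amplitude^2-weighted mean
#' frequency, and `BM(t)` the amplitude^2-weighted SD of frequency about
#' `centroid_t` (the instantaneous bandwidth).
#'
#' @param s A `scalogram`.
#' @param band Band name or row from [canonical_bands()].
#' @return List with equal-length numeric series `AM`, `centroid_t`, `BM`.
#' @export
band_envelope <- function(s, band) {
  stopifnot(inherits(s, "scalogram"))
  if (is.character(band)) band <- get_band(band)
  idx <- band_grid_indices(s$freqs_hz, band)
  if (length(idx) == 0) stop("empty band slice")
  A <- s$amplitude[idx, , drop = FALSE]
  f <- s$freqs_hz[idx]
  P <- A * A
  rp <- colSums(P)
  ok <- rp > 0
  cen <- rep(0.5 * (band$lo_hz + band$hi_hz), ncol(A))
  cen[ok] <- colSums(P[, ok, drop = FALSE] * f) / rp[ok]
  bm <- numeric(ncol(A))
  if (any(ok)) {
    d2 <- (matrix(f, length(f), ncol(A)) - matrix(cen, length(f), ncol(A), byrow = TRUE))^2
    bm[ok] <- sqrt(colSums((P * d2)[, ok, drop = FALSE]) / rp[ok])
  }
  list(AM = colMeans(A), centroid_t = cen, BM = bm)
}

# Per-band edge trim (s) for time-averaged CWT statistics: 1 s cone-of-
# influence proxy for theta/alpha/beta; delta keeps the full span (its
# wavelet is longer than any affordable trim).
cwt_trim_s <- function() c(delta = 0, theta = 1, alpha = 1, beta = 1)

#' Time-frequency descriptors of one (channel, band) pair
#'
#' Reference-path computation of the 10 per-(channel, band) features:
#' `meanAM`/`meanBM` (temporal means of the [band_envelope()] series),
#' `spectralEntropy` (Shannon entropy of the time-averaged within-band power
#' across grid frequencies, normalised by `log(#band frequencies)`),
#' `frequencyCentroid` (power-weighted mean grid frequency),
#' `meanPeakAmplitude` (temporal mean of the max-over-frequency amplitude),
#' `peakFrequency` (grid frequency with largest time-summed power),
#' `skewness`/`kurtosis` (third/fourth standardised moments of the AM
#' series, excess-kurtosis convention; both 0 for a constant AM series, with
#' an error flag), and Hjorth `mobility`/`complexity` delegated to
#' [hjorth_params()] on the FIR band-filtered series. Statistics exclude the
#' first/last second of the epoch except in the delta band.
#'
#' @param s A `scalogram` of the epoch channel.
#' @param band Band name or row.
#' @param band_signal The same channel band-filtered with [band_kernel()]
#'   (zero phase); if NULL it is computed from `x_raw`.
#' @param x_raw Optional raw channel series (used when `band_signal` is NULL).
#' @return Named numeric vector of the 10 features.
#' @export
tf_band_features <- function(s, band, band_signal = NULL, x_raw = NULL) {
  stopifnot(inherits(s, "scalogram"))
  if (is.character(band)) band <- get_band(band)
  if (is.null(band_signal)) {
    if (is.null(x_raw)) stop("need band_signal or x_raw")
    band_signal <- zero_phase_filter(x_raw, band_kernel(s$fs, band))
  }
  env <- band_envelope(s, band)
  idx <- band_grid_indices(s$freqs_hz, band)
  f <- s$freqs_hz[idx]
  n <- ncol(s$amplitude)
  trim <- unname(cwt_trim_s()[band$name])
  tsec <- (seq_len(n) - 1) / s$fs
  keep <- tsec >= trim & tsec < n / s$fs - trim

  A <- s$amplitude[idx, keep, drop = FALSE]
  P <- A * A
  pbar <- rowMeans(P)
  ptot <- sum(pbar)
  if (ptot > 0) {
    p <- pbar / ptot
    entropy <- if (length(p) > 1) -sum(ifelse(p > 0, p * log(p), 0)) / log(length(p)) else 0
    fcen <- sum(p * f)
  } else {
    entropy <- 0
    fcen <- 0.5 * (band$lo_hz + band$hi_hz)
  }
  am <- env$AM[keep]
  mu <- mean(am)
  m2 <- mean((am - mu)^2)
  if (m2 <= 1e-24 * (mu^2 + 1e-300)) {
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((am - mu)^3) / m2^1.5
    kurt <- mean((am - mu)^4) / m2^2 - 3
  }
  # Hjorth on the FIR band signal uses a uniform 1-s trim (filter transients),
  # independent of the CWT trim rule.
  hkeep <- tsec >= 1 & tsec < n / s$fs - 1
  hp <- hjorth_params(band_signal[hkeep], s$fs)
  c(meanAM = mu,
    meanBM = mean(env$BM[keep]),
    spectralEntropy = entropy,
    frequencyCentroid = fcen,
    meanPeakAmplitude = mean(apply(A, 2, max)),
    peakFrequency = f[which.max(rowSums(P))],
    skewness = skew,
    kurtosis = kurt,
    hjorthMobility = hp$mobility_hz,
    hjorthComplexity = hp$complexity)
}

#' Hjorth mobility and complexity
#'
#' `mobility_hz = (fs / 2 pi) * sqrt(var(diff(x)) / var(x))` (the dominant
#' frequency of the signal, in Hz up to the discrete-difference correction
#' `sin(pi f / fs) / (pi f / fs)`), and `complexity = mobility(diff(x)) /
#' mobility(x)` (unitless spectral-spread factor, 1 for a pure sinusoid).
#' Variances are computed about the mean of each (differenced) series.
#'
#' @param x Numeric series, length >= 3.
#' @param fs Sampling rate (Hz).
#' @return List with `mobility_hz`, `complexity`, and logical `flag` (TRUE
#'   when the input had (near-)zero variance and the features were set to 0).
#' @export
hjorth_params <- function(x, fs) {
  if (length(x) < 3) stop("need at least 3 samples")
  v0 <- stats::var(x) * (length(x) - 1) / length(x)
  d1 <- diff(x)
  v1 <- stats::var(d1) * (length(d1) - 1) / length(d1)
  if (!is.finite(v0) || v0 <= 0 || v1 <= 0) {
    return(list(mobility_hz = 0, complexity = 0, flag = TRUE))
  }
  d2 <- diff(d1)
  v2 <- stats::var(d2) * (length(d2) - 1) / length(d2)
  mob <- fs / (2 * pi) * sqrt(v1 / v0)
  cmplx <- if (v2 > 0) sqrt(v2 / v1) / sqrt(v1 / v0) else 0
  list(mobility_hz = mob, complexity = cmplx, flag = FALSE)
}
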
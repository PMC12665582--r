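#' @useDynLib sleepdepEEG, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Windowed-sinc FIR band-pass kernel
#'
#' Hamming windowed-sinc design. The kernel is built as the difference of two
#' unit-DC-gain low-pass kernels with cutoffs at the band edges, so the gain
#' is ~0.5 at each edge and ~1 in the passband. The length is set by the
#' narrower of the two transition widths (`ceil(3.3 * fs / trans)`, forced
#' odd). A high-pass-only kernel (`hi_hz >= fs/2`) uses spectral inversion,
#' and a low-pass-only kernel is obtained with `lo_hz <= 0`.
#'
#' @param fs Sampling rate (Hz).
#' @param lo_hz,hi_hz Band edges (Hz).
#' @param trans_lo,trans_hi Transition widths at each edge (Hz).
#' @return Numeric vector (odd length) of filter taps.
#' @export
fir_bandpass_kernel <- function(fs, lo_hz, hi_hz, trans_lo, trans_hi) {
  stopifnot(fs > 0)
  has_lo <- lo_hz > 0
  has_hi <- hi_hz < fs / 2
  if (!has_lo && !has_hi) stop("kernel would be all-pass")
  trans <- c(if (has_lo) trans_lo, if (has_hi) trans_hi)
  n <- ceiling(3.3 * fs / min(trans))
  if (n %% 2 == 0) n <- n + 1
  lp <- function(fc) {
    m <- seq_len(n) - 1 - (n - 1) / 2
    h <- 2 * fc / fs * sinc_(2 * fc / fs * m) * hamming_(n)
    h / sum(h) # unit DC gain
  }
  if (has_lo && has_hi) {
    lp(hi_hz) - lp(lo_hz)
  } else if (has_lo) {
    d <- numeric(n); d[(n + 1) / 2] <- 1
    d - lp(lo_hz)
  } else {
    lp(hi_hz)
  }
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

hamming_ <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Zero-phase FIR filtering via the squared magnitude response
#'
#' Applies the filter forward and backward (zero phase) by multiplying the
#' zero-padded FFT of each column with `|H(f)|^2`, where `H` is the kernel's
#' frequency response. Equivalent to `filtfilt` with zero-padded edges; the
#' passband gain is the square of the single-pass gain (~1 for the designs
#' used here) and stopband attenuation is doubled in dB.
#'
#' @param x Numeric vector or matrix (samples x channels).
#' @param h FIR kernel from [fir_bandpass_kernel()].
#' @return Filtered data, same shape as `x`.
#' @export
zero_phase_filter <- function(x, h) {
  vec <- is.null(dim(x))
  X <- as.matrix(x)
  if (nrow(X) < length(h)) {
    stop("signal shorter than filter kernel (", length(h), " taps)")
  }
  out <- cpp_zero_phase_filter(X, h)
  if (vec) drop(out) else out
}

#' Single-pass frequency response of a kernel on a frequency grid
#' @param h FIR kernel.
#' @param fs Sampling rate (Hz).
#' @param freqs Frequencies (Hz) at which to evaluate.
#' @return Complex response (magnitude is the single-pass gain).
#' @keywords internal
fir_response <- function(h, fs, freqs) {
  m <- outer(freqs / fs, seq_along(h) - 1)
  drop(exp(-2i * pi * m) %*% h)
}

#' Band-decomposition kernel for one canonical band
#'
#' Transition widths are `max(0.2 * edge, 0.5 Hz)` so that even the delta
#' kernel (~6.6 s) fits comfortably inside a 20-s epoch; the broadband
#' preprocessing filter (which runs on whole recordings) instead uses the
#' narrower `max(0.2 * edge, 0.1 Hz)` rule, see [bandpass_recording()].
#'
#' @param fs Sampling rate (Hz).
#' @param band Band name or row from [canonical_bands()].
#' @return FIR kernel.
#' @export
band_kernel <- function(fs, band) {
  if (is.character(band)) band <- get_band(band)
  fir_bandpass_kernel(
    fs, band$lo_hz, band$hi_hz,
    trans_lo = max(0.2 * band$lo_hz, 0.5),
    trans_hi = max(0.2 * band$hi_hz, 0.5)
  )
}
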
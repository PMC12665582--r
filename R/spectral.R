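#' Welch power spectral density
#'
#' Hamming-windowed, 50%-overlap segment-averaged periodogram with window
#' power correction and one-sided density scaling (power in uV^2/Hz), so
#' that the integral of the PSD over frequency recovers signal variance and
#' a sinusoid of amplitude A contributes A^2/2.
#'
#' @param x Numeric vector (or samples x channels matrix).
#' @param fs Sampling rate (Hz).
#' @param window_s Segment length in seconds.
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return Object of class `psd`: list with `freqs_hz`, `power` (matrix
#'   nfreq x nchannels, or vector for vector input), `window_s`, `overlap`.
#' @export
welch_psd <- function(x, fs, window_s, overlap = 0.5) {
  vec <- is.null(dim(x))
  X <- as.matrix(x)
  wlen <- round(window_s * fs)
  if (wlen > nrow(X)) stop("window longer than signal")
  step <- max(1, round(wlen * (1 - overlap)))
  cube <- cpp_segment_ffts(X, as.integer(wlen), as.integer(step))
  psd_from_cube(cube, fs, wlen, vec = vec, window_s = window_s, overlap = overlap)
}

# assemble a one-sided density-scaled PSD from a segment-FFT cube
psd_from_cube <- function(cube, fs, wlen, vec = FALSE, window_s, overlap) {
  win <- hamming_(wlen)
  U <- sum(win^2)
  nf <- dim(cube)[1]
  acc <- cpp_cube_meanpow(cube) / (fs * U)
  scale <- rep(2, nf)
  scale[1] <- 1
  if (wlen %% 2 == 0) scale[nf] <- 1
  power <- acc * scale
  freqs <- (seq_len(nf) - 1) * fs / wlen
  structure(list(freqs_hz = freqs,
                 power = if (vec) drop(power) else power,
                 window_s = window_s, overlap = overlap),
            class = "psd")
}

# trapezoidal integral of y(f) over grid points with lo <= f < hi
trapz_band <- function(freqs, y, lo, hi) {
  idx <- which(freqs >= lo & freqs < hi)
  if (length(idx) < 2) return(sum(y[idx]) * mean(diff(freqs)))
  f <- freqs[idx]
  v <- y[idx]
  sum((v[-1] + v[-length(v)]) / 2 * diff(f))
}

#' Per-band absolute and relative powers of an epoch
#'
#' For each canonical band the PSD is estimated per channel with that band's
#' Welch window (10/8/4/2 s for delta/theta/alpha/beta, Hamming, 50%
#' overlap), integrated (trapezoid) over the half-open band interval, then
#' averaged across channels. Relative power normalises by the sum of the
#' four band powers, so it sums to 1 by construction.
#'
#' @param epoch An `eeg_epoch` (channels x samples at 256 Hz).
#' @return List with `absPower` (uV^2, named by band), `relPower`, and
#'   logical `flag` (all-zero epoch).
#' @export
band_powers <- function(epoch) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  X <- t(epoch$data)
  if (all(X == 0)) {
    z <- stats::setNames(numeric(4), canonical_bands()$name)
    return(list(absPower = z, relPower = z, flag = TRUE))
  }
  bands <- canonical_bands()
  absp <- numeric(nrow(bands))
  for (b in seq_len(nrow(bands))) {
    psd <- welch_psd(X, epoch$fs, bands$welch_window_s[b])
    per_ch <- apply(psd$power, 2, trapz_band, freqs = psd$freqs_hz,
                    lo = bands$lo_hz[b], hi = bands$hi_hz[b])
    absp[b] <- mean(per_ch)
  }
  names(absp) <- bands$name
  list(absPower = absp, relPower = absp / sum(absp), flag = FALSE)
}

#' Band power ratios
#'
#' `theta/alpha`, `delta/theta` and `beta/alpha` with a denominator floor of
#' 1e-12 uV^2 (floored denominators are flagged).
#'
#' @param absPower Named band powers from [band_powers()].
#' @return List with the three ratios and logical `flag`.
#' @export
power_ratios <- function(absPower) {
  eps <- 1e-12
  flag <- any(absPower[c("alpha", "theta")] < eps)
  d <- pmax(absPower, eps)
  list(ratio_theta_alpha = unname(absPower["theta"] / d["alpha"]),
       ratio_delta_theta = unname(absPower["delta"] / d["theta"]),
       ratio_beta_alpha = unname(absPower["beta"] / d["alpha"]),
       flag = flag)
}

#' Spectral edge frequency
#'
#' Smallest frequency at which the cumulative trapezoid-integrated power
#' reaches a fraction `q` of the total, with linear interpolation between
#' grid points.
#'
#' @param psd A `psd` object (vector power) or a list with `freqs_hz` and
#'   `power`.
#' @param q Proportion in (0, 1).
#' @return Frequency in Hz (NA with a warning for zero total power).
#' @export
spectral_edge <- function(psd, q) {
  stopifnot(q > 0, q < 1)
  f <- psd$freqs_hz
  p <- as.numeric(psd$power)
  if (length(f) < 2) stop("PSD grid too short")
  seg <- (p[-1] + p[-length(p)]) / 2 * diff(f)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) {
    warning("zero total power; spectral edge undefined")
    return(NA_real_)
  }
  target <- q * total
  i <- which(cum >= target)[1]
  if (i == 1) return(f[1])
  # linear interpolation inside segment i-1
  frac <- (target - cum[i - 1]) / (cum[i] - cum[i - 1])
  f[i - 1] + frac * (f[i] - f[i - 1])
}

#' The 13 channel-averaged spectral features of an epoch
#'
#' Absolute and relative band powers (x4 each), the three band ratios, and
#' the 50% and 95% spectral edge frequencies. SEFs are computed from the
#' broadband (0.5-45 Hz) channel-mean PSD estimated with the delta-band
#' window settings (10 s, Hamming, 50% overlap), the finest frequency
#' resolution among the configured windows.
#'
#' @param epoch An `eeg_epoch`.
#' @param cubes Optional list of precomputed segment-FFT cubes (one per
#'   band, in canonical band order) to avoid recomputation in batch use.
#' @return Named numeric vector of length 13 (attribute `flag` TRUE for a
#'   degenerate all-zero epoch).
#' @export
spectral_features <- function(epoch, cubes = NULL) {
  bands <- canonical_bands()
  if (is.null(cubes)) {
    bp <- band_powers(epoch)
    psd <- welch_psd(t(epoch$data), epoch$fs, get_band("delta")$welch_window_s)
  } else {
    absp <- numeric(nrow(bands))
    for (b in seq_len(nrow(bands))) {
      wlen <- round(bands$welch_window_s[b] * epoch$fs)
      p <- psd_from_cube(cubes[[b]], epoch$fs, wlen,
                         window_s = bands$welch_window_s[b], overlap = 0.5)
      per_ch <- apply(p$power, 2, trapz_band, freqs = p$freqs_hz,
                      lo = bands$lo_hz[b], hi = bands$hi_hz[b])
      absp[b] <- mean(per_ch)
    }
    names(absp) <- bands$name
    bp <- if (all(absp == 0)) {
      list(absPower = absp, relPower = absp, flag = TRUE)
    } else {
      list(absPower = absp, relPower = absp / sum(absp), flag = FALSE)
    }
    wlen <- round(bands$welch_window_s[1] * epoch$fs)
    psd <- psd_from_cube(cubes[[1]], epoch$fs, wlen,
                         window_s = bands$welch_window_s[1], overlap = 0.5)
  }
  pr <- power_ratios(bp$absPower)
  keep <- psd$freqs_hz >= 0.5 & psd$freqs_hz <= 45
  mean_psd <- list(freqs_hz = psd$freqs_hz[keep],
                   power = rowMeans(psd$power)[keep])
  if (bp$flag) {
    sef50 <- 0; sef95 <- 0
  } else {
    sef50 <- spectral_edge(mean_psd, 0.5)
    sef95 <- spectral_edge(mean_psd, 0.95)
  }
  out <- c(stats::setNames(bp$absPower, paste0("specAbs_", names(bp$absPower))),
           stats::setNames(bp$relPower, paste0("specRel_", names(bp$relPower))),
           ratio_theta_alpha = pr$ratio_theta_alpha,
           ratio_delta_theta = pr$ratio_delta_theta,
           ratio_beta_alpha = pr$ratio_beta_alpha,
           sef50 = sef50, sef95 = sef95)
  attr(out, "flag") <- bp$flag || pr$flag
  out
}
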
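#' Simulation configuration for a synthetic two-session EEG cohort
#'
#' Defines the study conditions emulated by the simulator: a within-subject
#' two-session design (condition 0 = well-rested, 1 = acutely sleep-deprived)
#' on a 61-channel montage. Condition effects mirror the physiology the
#' pipeline is meant to detect: a multiplicative gain on the frontal
#' theta-band envelope, a shift of shared beta-source coupling (raising
#' beta-band coherence/PLV), and an attenuation of posterior alpha power.
#' Per-subject spectral "fingerprints" (log-normal per channel x band
#' amplitude gains) create the inter-subject variability that makes
#' epoch-level cross-validation optimistic.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param channel_names Ordered channel labels (default [montage_61()]).
#' @param fs Sampling rate in Hz (> 90, i.e. above twice the 45 Hz low-pass).
#' @param duration_s Seconds per session (>= 20, one epoch).
#' @param theta_am_effect Multiplicative gain (>= 1) on the frontal theta
#'   envelope under condition 1.
#' @param beta_coh_effect Signed shift of shared beta-source coupling under
#'   condition 1 (0 = none).
#' @param alpha_power_effect Multiplicative gain (<= 1) on posterior alpha
#'   amplitude under condition 1.
#' @param fingerprint_sd SD of the per-subject log-gain per (channel, band).
#' @param noise_sd Broadband white-noise amplitude in microvolts.
#' @param seed Master integer seed; all per-subject/per-operation streams are
#'   derived from it by stable hashing.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10,
                       channel_names = montage_61(),
                       fs = 256,
                       duration_s = 300,
                       theta_am_effect = 1.4,
                       beta_coh_effect = 0.3,
                       alpha_power_effect = 0.8,
                       fingerprint_sd = 0.25,
                       noise_sd = 5,
                       seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (fs <= 90) stop("fs must exceed 90 Hz (2 x 45 Hz)")
  if (duration_s < 20) stop("duration_s must be >= 20 (one epoch)")
  if (fingerprint_sd < 0) stop("fingerprint_sd must be >= 0")
  if (theta_am_effect <= 0 || alpha_power_effect <= 0) stop("gains must be > 0")
  if (theta_am_effect < 1) stop("theta_am_effect must be >= 1")
  if (alpha_power_effect > 1) stop("alpha_power_effect must be <= 1")
  if (length(channel_names) != 61) stop("channel_names must have length 61")
  structure(list(
    n_subjects = as.integer(n_subjects), channel_names = channel_names,
    fs = fs, duration_s = duration_s, theta_am_effect = theta_am_effect,
    beta_coh_effect = beta_coh_effect, alpha_power_effect = alpha_power_effect,
    fingerprint_sd = fingerprint_sd, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Stable 31-bit stream seed from (seed, subject_id, role): reproducible across
# platforms and independent of cohort size.
stream_seed <- function(seed, subject_id, role) {
  key <- paste0(subject_id, "|", role)
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

subject_ids_for <- function(config) sprintf("S%02d", seq_len(config$n_subjects))

#' Draw a subject's spectral fingerprint
#'
#' Per (channel, band) multiplicative amplitude gains, i.i.d. log-normal:
#' `exp(Normal(0, fingerprint_sd^2))`. Deterministic given
#' `(config$seed, subject_id)`.
#'
#' @param config A [sim_config()].
#' @param subject_id Subject identifier (string).
#' @return Object of class `subject_fingerprint` with a 61 x 4 `gains` matrix
#'   (rows = channels, columns = bands).
#' @export
make_fingerprint <- function(config, subject_id) {
  stopifnot(inherits(config, "sim_config"))
  bands <- canonical_bands()$name
  rng <- local({
    set.seed(stream_seed(config$seed, subject_id, "fingerprint"))
    stats::rnorm(length(config$channel_names) * length(bands),
                 0, config$fingerprint_sd)
  })
  gains <- matrix(exp(rng), nrow = length(config$channel_names),
                  dimnames = list(config$channel_names, bands))
  structure(list(subject_id = subject_id, gains = gains),
            class = "subject_fingerprint")
}

# Base band amplitudes (microvolts, roughly physiological at rest): alpha
# dominates posteriorly, slow activity is moderate, beta is low.
base_band_amplitudes <- function(channel_names) {
  amp <- cbind(delta = rep(6, length(channel_names)),
               theta = rep(5, length(channel_names)),
               alpha = rep(8, length(channel_names)),
               beta  = rep(3, length(channel_names)))
  rownames(amp) <- channel_names
  amp[rownames(amp) %in% posterior_channels(), "alpha"] <-
    amp[rownames(amp) %in% posterior_channels(), "alpha"] * 1.5
  amp
}

# Smooth band mask on a frequency grid (Gaussian-edged, ~0.3 Hz roll-off).
band_mask <- function(freqs, lo, hi) {
  stats::pnorm((freqs - lo) / 0.3) * stats::pnorm((hi - freqs) / 0.3)
}

# Positive-frequency bin indices and mask values for band-limited noise on
# an n-point grid; sdfac converts unit-variance complex bin draws to
# time-domain SD 1 after Hermitian mirroring.
band_noise_bins <- function(n, fs, lo, hi) {
  freqs <- (seq_len(n) - 1) * fs / n
  k <- which(freqs > max(0, lo - 2) & freqs < min(fs / 2, hi + 2))
  m <- band_mask(freqs[k], lo, hi)
  list(k = k, m = m, sdfac = 2 * sqrt(sum(m^2)) / n)
}

complex_noise <- function(nk, ncol = 1) {
  matrix(complex(real = stats::rnorm(nk * ncol),
                 imaginary = stats::rnorm(nk * ncol)), nk, ncol)
}

#' Synthesize one subject-session recording
#'
#' Each channel is a sum of band-limited stochastic oscillations (one per
#' canonical band, amplitude = base x fingerprint gain x condition effect),
#' a shared beta-band source mixed into every channel (coupling scaled by
#' `1 + beta_coh_effect` under condition 1), and broadband white noise.
#' Output is in microvolts, channels x samples.
#'
#' @param fingerprint A [make_fingerprint()] result.
#' @param condition 0 (well-rested) or 1 (sleep-deprived).
#' @param config The [sim_config()] used for the cohort.
#' @return Object of class `eeg_recording`.
#' @export
synthesize_recording <- function(fingerprint, condition, config) {
  stopifnot(inherits(fingerprint, "subject_fingerprint"),
            inherits(config, "sim_config"))
  if (!condition %in% c(0, 1)) stop("condition must be 0 or 1")
  n <- round(config$fs * config$duration_s)
  if (n < 20 * config$fs) stop("duration too short for one 20-s epoch")
  bands <- canonical_bands()
  chans <- config$channel_names
  base <- base_band_amplitudes(chans)

  # condition-dependent amplitude multipliers per (channel, band)
  mult <- matrix(1, nrow(base), ncol(base), dimnames = dimnames(base))
  if (condition == 1) {
    mult[rownames(mult) %in% frontal_channels(), "theta"] <- config$theta_am_effect
    mult[rownames(mult) %in% posterior_channels(), "alpha"] <- config$alpha_power_effect
  }
  amp <- base * fingerprint$gains * mult

  set.seed(stream_seed(config$seed, fingerprint$subject_id,
                       paste0("recording", condition)))
  nch <- length(chans)
  bins <- lapply(seq_len(nrow(bands)), function(bi)
    band_noise_bins(n, config$fs, bands$lo_hz[bi], bands$hi_hz[bi]))

  # positive-frequency spectrum, all channels at once
  X <- matrix(0 + 0i, n, nch)
  for (bi in seq_len(nrow(bands))) {
    b <- bins[[bi]]
    Z <- complex_noise(length(b$k), nch)
    X[b$k, ] <- X[b$k, ] + Z * (b$m %o% (amp[, bi] / b$sdfac))
  }
  # Shared beta source, one realization mixed into all channels through a
  # subject-specific heterogeneous topography (zero-mean across channels, so
  # it survives the common average reference; drawn once per subject so
  # baseline coupling differs between subjects like the spectral
  # fingerprints do); condition 1 scales every mixing weight by
  # 1 + beta_coh_effect.
  bshared <- band_noise_bins(n, config$fs, 12, 30)
  mixing <- local({
    set.seed(stream_seed(config$seed, fingerprint$subject_id, "beta-mixing"))
    w <- stats::rnorm(nch)
    # subject-level coupling gain: between-subject connectivity variability
    # on the same scale as the spectral fingerprints
    g <- exp(stats::rnorm(1, 0, config$fingerprint_sd))
    g * (w - mean(w))
  })
  couple <- 0.6 * base[, "beta"] * mixing *
    (1 + if (condition == 1) config$beta_coh_effect else 0)
  set.seed(stream_seed(config$seed, fingerprint$subject_id,
                       paste0("shared", condition)))
  zs <- complex_noise(length(bshared$k)) * bshared$m
  X[bshared$k, ] <- X[bshared$k, ] + zs %*% t(couple / bshared$sdfac)
  # Hermitian mirror across all occupied bins
  kall <- sort(unique(unlist(lapply(c(bins, list(bshared)), `[[`, "k"))))
  X[n - kall + 2, ] <- Conj(X[kall, ])

  data <- t(Re(cpp_fft_cols(X, TRUE))) +
    matrix(stats::rnorm(nch * n, 0, config$noise_sd), nch, n)
  dimnames(data) <- list(chans, NULL)
  structure(list(subject_id = fingerprint$subject_id,
                 condition = as.integer(condition),
                 channel_names = chans, fs = config$fs, data = data,
                 artifacts = NULL),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, condition %d: %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Synthesize a full two-session cohort
#'
#' Exactly two recordings per subject (conditions 0 and 1) sharing one
#' fingerprint; fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List of `eeg_recording` objects (length `2 * n_subjects`).
#' @export
synthesize_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- list()
  for (sid in subject_ids_for(config)) {
    fp <- make_fingerprint(config, sid)
    out[[length(out) + 1L]] <- synthesize_recording(fp, 0, config)
    out[[length(out) + 1L]] <- synthesize_recording(fp, 1, config)
  }
  out
}

#' Inject high-amplitude artifact bursts into a recording
#'
#' Adds `n_bursts` 0.5-s windowed 5 Hz bursts at seeded positions (at most one
#' per 20-s epoch, on a seeded channel each), for testing the amplitude-based
#' epoch rejection rule. Burst positions are recorded in the returned
#' recording's `artifacts` data.frame (`epoch` is the 0-based 20-s epoch
#' index).
#'
#' @param recording An `eeg_recording`.
#' @param n_bursts Number of bursts (0 allowed).
#' @param amplitude_uV Burst amplitude in microvolts (> 0).
#' @param seed Integer seed for placement.
#' @return The recording with bursts added and `artifacts` metadata set.
#' @export
inject_artifacts <- function(recording, n_bursts, amplitude_uV, seed = 1L) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (amplitude_uV <= 0) stop("amplitude_uV must be > 0")
  n_epochs <- floor(ncol(recording$data) / (20 * recording$fs))
  if (n_bursts > n_epochs) {
    stop("n_bursts (", n_bursts, ") exceeds available 20-s epochs (", n_epochs, ")")
  }
  if (n_bursts == 0) {
    recording$artifacts <- data.frame(epoch = integer(0), channel = character(0),
                                      start_sample = integer(0), n_samples = integer(0))
    return(recording)
  }
  set.seed(as.integer(seed))
  epochs <- sort(sample.int(n_epochs, n_bursts) - 1L)
  burst_len <- round(2 * recording$fs) # 2-s bursts move the epoch SD decisively
  win <- 0.5 * (1 - cos(2 * pi * seq_len(burst_len) / (burst_len + 1)))
  t <- seq_len(burst_len) / recording$fs
  shape <- sin(2 * pi * 5 * t) * win
  meta <- data.frame(epoch = epochs, channel = character(n_bursts),
                     start_sample = integer(n_bursts), n_samples = burst_len)
  ep_len <- 20 * recording$fs
  for (i in seq_len(n_bursts)) {
    ch <- sample.int(nrow(recording$data), 1)
    off <- sample.int(ep_len - burst_len, 1)
    start <- epochs[i] * ep_len + off
    idx <- start + seq_len(burst_len)
    recording$data[ch, idx] <- recording$data[ch, idx] + amplitude_uV * shape
    meta$channel[i] <- recording$channel_names[ch]
    meta$start_sample[i] <- start
  }
  recording$artifacts <- meta
  recording
}
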
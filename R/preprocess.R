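#' Preprocessing configuration
#'
#' Deterministic conditioning pipeline applied to every recording, in fixed
#' order: resample -> zero-phase FIR band-pass -> common average reference ->
#' fixed-length epoching -> amplitude-based rejection.
#'
#' @param target_fs Target sampling rate (Hz), default 256.
#' @param hp_hz High-pass edge (Hz), default 0.2.
#' @param lp_hz Low-pass edge (Hz), default 45.
#' @param epoch_s Epoch length (s), default 20 (non-overlapping, contiguous).
#' @param reject_sd_uV Per-channel SD rejection threshold (microvolts),
#'   default 50: an epoch is dropped if any channel's SD exceeds it.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 256, hp_hz = 0.2, lp_hz = 45,
                              epoch_s = 20, reject_sd_uV = 50) {
  if (!(hp_hz > 0 && hp_hz < lp_hz && lp_hz < target_fs / 2)) {
    stop("need 0 < hp_hz < lp_hz < target_fs/2")
  }
  if (epoch_s <= 0 || reject_sd_uV <= 0) stop("epoch_s and reject_sd_uV must be > 0")
  structure(list(target_fs = target_fs, hp_hz = hp_hz, lp_hz = lp_hz,
                 epoch_s = epoch_s, reject_sd_uV = reject_sd_uV),
            class = "preprocess_config")
}

rational_rate <- function(target_fs, fs, max_den = 4096) {
  r <- target_fs / fs
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(p / q - r)
    if (e < err - 1e-15) { err <- e; best <- c(p, q) }
    if (err == 0) break
  }
  best
}

#' Resample a recording to a target rate
#'
#' Polyphase anti-aliased rational-rate conversion (via `signal::resample`);
#' the output length is forced to `round(duration * target_fs)` and the
#' stored sampling rate updated. If the rates already match, the data pass
#' through untouched.
#'
#' @param recording An `eeg_recording`.
#' @param target_fs Target sampling rate (Hz, > 0).
#' @return The resampled `eeg_recording`.
#' @export
resample_recording <- function(recording, target_fs) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (target_fs <= 0) stop("target_fs must be > 0")
  if (target_fs == recording$fs) return(recording)
  pq <- rational_rate(target_fs, recording$fs)
  n_in <- ncol(recording$data)
  n_out <- round(n_in * target_fs / recording$fs)
  out <- matrix(0, nrow(recording$data), n_out,
                dimnames = list(rownames(recording$data), NULL))
  for (ci in seq_len(nrow(recording$data))) {
    y <- signal::resample(recording$data[ci, ], pq[1], pq[2])
    if (length(y) >= n_out) out[ci, ] <- y[seq_len(n_out)]
    else out[ci, seq_along(y)] <- y
  }
  recording$data <- out
  recording$fs <- target_fs
  recording
}

#' Zero-phase FIR band-pass filter a recording
#'
#' Hamming windowed-sinc design with transition widths
#' `max(0.2 * edge, 0.1 Hz)` applied forward-backward (zero phase) via
#' [zero_phase_filter()]. Errors if the recording is shorter than the kernel.
#'
#' @param recording An `eeg_recording`.
#' @param hp_hz,lp_hz Band edges (Hz).
#' @return The filtered `eeg_recording`.
#' @export
bandpass_recording <- function(recording, hp_hz = 0.2, lp_hz = 45) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!(hp_hz > 0 && hp_hz < lp_hz && lp_hz < recording$fs / 2)) {
    stop("band invalid versus Nyquist")
  }
  if (ncol(recording$data) < 10 * recording$fs) {
    stop("recording shorter than the minimum supportable filter kernel (10 s)")
  }
  # transition floor keeps the kernel no longer than the recording
  min_trans <- 3.3 * recording$fs / (ncol(recording$data) - 2)
  h <- fir_bandpass_kernel(recording$fs, hp_hz, lp_hz,
                           trans_lo = max(0.2 * hp_hz, 0.1, min_trans),
                           trans_hi = max(0.2 * lp_hz, 0.1, min_trans))
  recording$data <- t(cpp_zero_phase_filter(t(recording$data), h))
  recording
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel;
#' idempotent and invariant for pairwise channel differences.
#'
#' @param recording An `eeg_recording` (>= 2 channels).
#' @return The re-referenced `eeg_recording`.
#' @export
average_reference <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"), nrow(recording$data) >= 2)
  recording$data <- sweep(recording$data, 2, colMeans(recording$data))
  recording
}

#' Segment a recording into contiguous non-overlapping epochs
#'
#' Epoch `k` (0-based) covers samples `[k*L, (k+1)*L)` with
#' `L = epoch_s * fs`; the trailing remainder is discarded, never padded.
#'
#' @param recording An `eeg_recording`.
#' @param epoch_s Epoch length in seconds.
#' @return List of `eeg_epoch` objects (possibly empty, with a warning).
#' @export
segment_epochs <- function(recording, epoch_s = 20) {
  stopifnot(inherits(recording, "eeg_epoch") || inherits(recording, "eeg_recording"))
  L <- round(epoch_s * recording$fs)
  n_ep <- floor(ncol(recording$data) / L)
  if (n_ep == 0) {
    warning("recording shorter than one epoch; returning no epochs")
    return(list())
  }
  lapply(seq_len(n_ep) - 1L, function(k) {
    structure(list(subject_id = recording$subject_id,
                   condition = recording$condition,
                   epoch_index = k,
                   fs = recording$fs,
                   data = recording$data[, k * L + seq_len(L), drop = FALSE]),
              class = "eeg_epoch")
  })
}

epoch_channel_sd <- function(epoch) {
  d <- epoch$data
  sqrt(pmax(rowMeans(d * d) - rowMeans(d)^2, 0)) # population SD, denominator N
}

#' Reject epochs by per-channel amplitude criterion
#'
#' An epoch is kept iff the population SD of every channel over the epoch is
#' at or below `reject_sd_uV`.
#'
#' @param epochs Non-empty list of `eeg_epoch` objects.
#' @param reject_sd_uV SD threshold in microvolts.
#' @return List with `kept` (epochs), `rejected_fraction`
#'   (`rejected / total`, exact), and `rejected_index` (0-based epoch
#'   indices of the rejected epochs).
#' @export
reject_epochs <- function(epochs, reject_sd_uV = 50) {
  if (length(epochs) == 0) stop("empty epoch list")
  bad <- vapply(epochs, function(e) any(epoch_channel_sd(e) > reject_sd_uV),
                logical(1))
  list(kept = epochs[!bad],
       rejected_fraction = sum(bad) / length(epochs),
       rejected_index = vapply(epochs[bad], function(e) e$epoch_index, integer(1)))
}

#' Run the full preprocessing pipeline on one recording
#'
#' Fixed order: resample -> band-pass -> common average reference ->
#' segment -> reject. Bit-identical across repeated runs on the same input.
#'
#' @param recording An `eeg_recording`.
#' @param config A [preprocess_config()].
#' @return List with `epochs` (kept), `rejected_fraction`, `n_total`,
#'   and `rejected_index`.
#' @export
preprocess_recording <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  r <- resample_recording(recording, config$target_fs)
  r <- bandpass_recording(r, config$hp_hz, config$lp_hz)
  r <- average_reference(r)
  eps <- segment_epochs(r, config$epoch_s)
  if (length(eps) == 0) {
    return(list(epochs = list(), rejected_fraction = NA_real_, n_total = 0L,
                rejected_index = integer(0)))
  }
  rej <- reject_epochs(eps, config$reject_sd_uV)
  list(epochs = rej$kept, rejected_fraction = rej$rejected_fraction,
       n_total = length(eps), rejected_index = rej$rejected_index)
}

#' Preprocess an entire cohort
#'
#' @param recordings List of `eeg_recording` objects.
#' @param config A [preprocess_config()].
#' @return List with `epochs` (flat list of kept epochs across recordings)
#'   and `rejected_fraction` (overall exact fraction).
#' @export
preprocess_cohort <- function(recordings, config = preprocess_config()) {
  all_eps <- list(); n_tot <- 0L; n_rej <- 0L
  for (r in recordings) {
    res <- preprocess_recording(r, config)
    all_eps <- c(all_eps, res$epochs)
    n_tot <- n_tot + res$n_total
    n_rej <- n_rej + (res$n_total - length(res$epochs))
  }
  list(epochs = all_eps, rejected_fraction = if (n_tot) n_rej / n_tot else NA_real_)
}
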
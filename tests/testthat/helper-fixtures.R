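# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# a bare epoch object from a channels x samples matrix
make_epoch <- function(data, fs = 256, condition = 0L, subject_id = "S01",
                       epoch_index = 0L) {
  if (is.null(rownames(data))) {
    rownames(data) <- montage_61()[seq_len(nrow(data))]
  }
  structure(list(subject_id = subject_id, condition = condition,
                 epoch_index = epoch_index, fs = fs, data = data),
            class = "eeg_epoch")
}

# a bare recording object
make_recording <- function(data, fs = 256, condition = 0L, subject_id = "S01") {
  if (is.null(rownames(data))) {
    rownames(data) <- montage_61()[seq_len(nrow(data))]
  }
  structure(list(subject_id = subject_id, condition = as.integer(condition),
                 channel_names = rownames(data), fs = fs, data = data,
                 artifacts = NULL),
            class = "eeg_recording")
}

# 61-channel white-noise epoch (20 s @ 256 Hz)
noise_epoch <- function(seed = 1, n = 5120, sd = 10, fs = 256) {
  set.seed(seed)
  make_epoch(matrix(rnorm(61 * n, 0, sd), 61, n), fs = fs)
}

# single-channel pure tone
tone <- function(freq, fs = 256, dur_s = 20, amp = 1, phase = 0) {
  amp * cos(2 * pi * freq * seq(0, dur_s - 1 / fs, by = 1 / fs) + phase)
}

# small strongly-separable cohort with no subject fingerprints, used by
# several modeling / selection / acceptance checks; built once
fixture_strong <- function() {
  fixture("strong", function() {
    cfg <- sim_config(n_subjects = 8, duration_s = 100,
                      theta_am_effect = 1.6, beta_coh_effect = 0.5,
                      alpha_power_effect = 0.8, fingerprint_sd = 0,
                      noise_sd = 5, seed = 11)
    pp <- preprocess_cohort(synthesize_cohort(cfg))
    list(config = cfg, fm = extract_feature_matrix(pp$epochs),
         epochs = pp$epochs)
  })
}

# synthetic (non-EEG) feature matrix with one informative feature
toy_feature_matrix <- function(seed = 1, n = 80, p = 120, shift = 2) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  colnames(X) <- sprintf("f%03d", seq_len(p))
  y <- rep(c(0L, 1L), each = n / 2)
  X[, 1] <- y + rnorm(n, 0, 1 / shift)
  subj <- rep(sprintf("S%02d", seq_len(n / 4)), each = 2)[seq_len(n)]
  structure(list(X = X,
                 meta = data.frame(label = y,
                                   subject_id = rep_len(subj, n),
                                   epoch_index = seq_len(n) - 1L,
                                   stringsAsFactors = FALSE)),
            class = "feature_matrix")
}
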
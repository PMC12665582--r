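tf_feature_names <- function() {
  c("meanAM", "meanBM", "spectralEntropy", "frequencyCentroid",
    "meanPeakAmplitude", "peakFrequency", "skewness", "kurtosis",
    "hjorthMobility", "hjorthComplexity")
}

# per-session caches for derived constants (kernels, name vectors)
.sleepdep_cache <- new.env(parent = emptyenv())

cached_band_kernels <- function(fs) {
  key <- paste0("kernels_", fs)
  if (is.null(.sleepdep_cache[[key]])) {
    bands <- canonical_bands()
    .sleepdep_cache[[key]] <- lapply(seq_len(nrow(bands)),
                                     function(b) band_kernel(fs, bands[b, ]))
  }
  .sleepdep_cache[[key]]
}

cached_feature_names <- function(channel_names) {
  key <- paste0("names_", paste(channel_names, collapse = ""))
  if (is.null(.sleepdep_cache[[key]])) {
    .sleepdep_cache[[key]] <- feature_names(channel_names)
  }
  .sleepdep_cache[[key]]
}

#' Canonical ordering of the 2481 feature names
#'
#' 2440 time-frequency features (channel-major, band-minor, feature
#' innermost, named `{Channel}_{band}_{feature}`), 13 channel-averaged
#' spectral features, 8 connectivity features (`plv_{band}`, `coh_{band}`),
#' and 20 graph metrics (5 metrics x 4 bands).
#'
#' @param channel_names Channel labels (default [montage_61()]).
#' @return Character vector of length 2481.
#' @export
feature_names <- function(channel_names = montage_61()) {
  bands <- canonical_bands()$name
  tf <- as.vector(vapply(channel_names, function(ch) {
    as.vector(vapply(bands, function(b) paste(ch, b, tf_feature_names(), sep = "_"),
                     character(10)))
  }, character(40)))
  spectral <- c(paste0("specAbs_", bands), paste0("specRel_", bands),
                "ratio_theta_alpha", "ratio_delta_theta", "ratio_beta_alpha",
                "sef50", "sef95")
  conn <- c(paste0("plv_", bands), paste0("coh_", bands))
  graph <- c(paste0("strength_", bands), paste0("clustering_", bands),
             paste0("efficiency_", bands), paste0("pathLength_", bands),
             paste0("modularity_", bands))
  c(tf, spectral, conn, graph)
}

#' Assemble the ordered 2481-entry feature vector
#'
#' Concatenates the per-(channel, band) time-frequency block, the spectral
#' block, per-band mean PLV and coherence, and per-band graph metrics in
#' the fixed canonical order, attaching label and identifiers.
#'
#' @param tf Matrix 61 x 40 (channels x (4 bands x 10 features)), rows named
#'   by channel.
#' @param spectral Named numeric vector of the 13 spectral features.
#' @param conn Named numeric vector of the 8 connectivity features.
#' @param graph Named numeric vector of the 20 graph features.
#' @param label Condition label (0/1).
#' @param subject_id,epoch_index Epoch identifiers.
#' @return Named numeric vector of length 2481 with attributes `label`,
#'   `subject_id`, `epoch_index`.
#' @export
assemble_feature_vector <- function(tf, spectral, conn, graph,
                                    label, subject_id, epoch_index) {
  parts <- list(tf = tf, spectral = spectral, conn = conn, graph = graph)
  absent <- names(parts)[vapply(parts, is.null, logical(1))]
  if (length(absent)) stop("missing feature parts: ", paste(absent, collapse = ", "))
  nm <- cached_feature_names(rownames(tf))
  vals <- c(as.vector(t(tf)), spectral, conn, graph)
  names(vals) <- NULL
  expected <- 61 * 40 + 13 + 8 + 20
  if (length(vals) != expected) {
    stop("feature vector has ", length(vals), " entries, expected ", expected)
  }
  out <- stats::setNames(vals, nm)
  attr(out, "label") <- as.integer(label)
  attr(out, "subject_id") <- subject_id
  attr(out, "epoch_index") <- as.integer(epoch_index)
  out
}

#' Extract the full 2481-dimensional feature vector of one epoch
#'
#' Fast batch path: a single padded FFT per channel feeds the decimated
#' Morlet-CWT band descriptors, zero-phase analytic band signals (Hjorth,
#' PLV), Welch band/broadband spectra, coherence, and weighted graph metrics
#' of the PLV adjacencies. Numerically consistent with the reference
#' operations ([morlet_scalogram()] + [tf_band_features()],
#' [plv_matrix()], [spectral_features()], [graph_metrics()]).
#'
#' @param epoch An `eeg_epoch` (61 x 5120 at the default configuration).
#' @param louvain_seed Seed pinning the Louvain modularity runs.
#' @return Named numeric feature vector (see [assemble_feature_vector()]).
#' @export
extract_features <- function(epoch, louvain_seed = 42L) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  bands <- canonical_bands()
  fs <- epoch$fs
  X <- t(epoch$data)
  freqs <- cwt_frequency_grid()
  bid <- integer(length(freqs))
  for (b in seq_len(nrow(bands))) {
    bid[freqs >= bands$lo_hz[b] & freqs < bands$hi_hz[b]] <- b
  }
  kernels <- cached_band_kernels(fs)
  plv_fs <- vapply(bands$name, band_phasor_fs, numeric(1))
  kit <- cpp_epoch_band_kit(X, fs, kernels, freqs, bid, nrow(bands),
                            unname(cwt_trim_s()[bands$name]), 1, 6, plv_fs)

  # interleave CWT block (8 per band) with the two Hjorth columns -> 10/band
  tf <- matrix(0, nrow(epoch$data), 40,
               dimnames = list(rownames(epoch$data), NULL))
  for (b in seq_len(4)) {
    tf[, (b - 1) * 10 + 1:8] <- kit$tf[, (b - 1) * 8 + 1:8]
    tf[, (b - 1) * 10 + 9:10] <- kit$hjorth[, (b - 1) * 2 + 1:2]
  }
  if (is.null(rownames(tf))) rownames(tf) <- montage_61()[seq_len(nrow(tf))]

  cubes <- lapply(seq_len(4), function(b) {
    wlen <- round(bands$welch_window_s[b] * fs)
    cpp_segment_ffts(X, as.integer(wlen), as.integer(wlen / 2))
  })
  spectral <- spectral_features(epoch, cubes = cubes)

  plv <- vapply(kit$plv, function(W) mean(W[upper.tri(W)]), numeric(1))
  coh <- vapply(seq_len(4), function(b) {
    wlen <- round(bands$welch_window_s[b] * fs)
    cpp_msc_mean(cubes[[b]], fs, as.integer(wlen), bands$lo_hz[b], bands$hi_hz[b])
  }, numeric(1))
  conn <- stats::setNames(c(plv, coh),
                          c(paste0("plv_", bands$name), paste0("coh_", bands$name)))

  gm <- lapply(kit$plv, function(W) {
    dimnames(W) <- list(rownames(epoch$data), rownames(epoch$data))
    graph_metrics(structure(list(band = "", weights = W, flag = FALSE),
                            class = "connectivity_matrix"),
                  louvain_seed = louvain_seed)
  })
  graph <- stats::setNames(
    c(vapply(gm, `[[`, numeric(1), "meanNodeStrength"),
      vapply(gm, `[[`, numeric(1), "weightedClustering"),
      vapply(gm, `[[`, numeric(1), "globalEfficiency"),
      vapply(gm, `[[`, numeric(1), "charPathLength"),
      vapply(gm, `[[`, numeric(1), "modularity")),
    c(paste0("strength_", bands$name), paste0("clustering_", bands$name),
      paste0("efficiency_", bands$name), paste0("pathLength_", bands$name),
      paste0("modularity_", bands$name)))

  assemble_feature_vector(tf, spectral, conn, graph,
                          label = epoch$condition,
                          subject_id = epoch$subject_id,
                          epoch_index = epoch$epoch_index)
}

#' Extract the feature matrix of a list of epochs
#'
#' @param epochs List of `eeg_epoch` objects.
#' @param louvain_seed Seed for the modularity runs.
#' @return Object of class `feature_matrix`: list with `X` (epochs x 2481
#'   named matrix) and `meta` (data.frame: `label`, `subject_id`,
#'   `epoch_index`).
#' @export
extract_feature_matrix <- function(epochs, louvain_seed = 42L) {
  stopifnot(length(epochs) > 0)
  rows <- lapply(epochs, extract_features, louvain_seed = louvain_seed)
  X <- do.call(rbind, rows)
  rownames(X) <- NULL
  meta <- data.frame(
    label = vapply(epochs, function(e) as.integer(e$condition), integer(1)),
    subject_id = vapply(epochs, function(e) e$subject_id, character(1)),
    epoch_index = vapply(epochs, function(e) as.integer(e$epoch_index), integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(X = X, meta = meta), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features (%d subjects)\n",
              nrow(x$X), ncol(x$X), length(unique(x$meta$subject_id))))
  invisible(x)
}
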
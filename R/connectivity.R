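# Phasor sampling rate (Hz) per band for PLV estimation: comfortably above
# each band's envelope/phase-difference bandwidth; subsampling the unit
# phasors leaves the PLV time-average unbiased and only trades estimator
# variance for speed.
band_phasor_fs <- function(band_name) {
  c(delta = 16, theta = 32, alpha = 32, beta = 64)[[band_name]]
}

#' Phase-locking value matrix of an epoch in one band
#'
#' Channels are band-filtered with the module's zero-phase FIR
#' ([band_kernel()]), instantaneous phases taken from the analytic signal,
#' the first and last second trimmed (filter transients), phases sampled at
#' a per-band rate (16-64 Hz), and
#' `PLV(i,j) = |mean_t exp(i (phi_i - phi_j))|`. A constant
#' (zero-amplitude) channel yields 0 for its pairs and sets the `flag`
#' attribute.
#'
#' @param epoch An `eeg_epoch`.
#' @param band Band name or row from [canonical_bands()].
#' @return Object of class `connectivity_matrix`: list with `band`,
#'   `weights` (symmetric in `[0,1]`, zero diagonal).
#' @export
plv_matrix <- function(epoch, band) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (is.character(band)) band <- get_band(band)
  Z <- cpp_band_analytic(t(epoch$data), band_kernel(epoch$fs, band))
  n <- nrow(Z)
  i0 <- round(epoch$fs)
  idx <- seq(i0 + 1, n - i0, by = max(1, round(epoch$fs / band_phasor_fs(band$name))))
  Z <- Z[idx, , drop = FALSE]
  a <- Mod(Z)
  dead <- colSums(a > 1e-300) == 0
  U <- Z / ifelse(a > 1e-300, a, 1)
  U[, dead] <- 0
  G <- crossprod(Conj(U), U)
  W <- Mod(G) / nrow(U)
  diag(W) <- 0
  W <- (W + t(W)) / 2
  dimnames(W) <- list(rownames(epoch$data), rownames(epoch$data))
  structure(list(band = band$name, weights = W, flag = any(dead)),
            class = "connectivity_matrix")
}

#' Mean PLV over all unique channel pairs
#' @param cm A `connectivity_matrix`.
#' @return Scalar mean over the upper-triangle entries.
#' @export
mean_plv <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  mean(cm$weights[upper.tri(cm$weights)])
}

# magnitude-squared coherence averaged over in-band frequencies, full matrix
msc_matrix <- function(cube, fs, wlen, lo, hi) {
  freqs <- (seq_len(dim(cube)[1]) - 1) * fs / wlen
  bins <- which(freqs >= lo & freqs < hi)
  C <- dim(cube)[2]
  acc <- matrix(0, C, C)
  for (f in bins) {
    Xf <- matrix(cube[f, , ], nrow = C) # channels x segments
    S <- Xf %*% Conj(t(Xf))             # cross-spectral matrix (segment sum)
    d <- Re(diag(S))
    d[d <= 0] <- Inf
    acc <- acc + (Re(S)^2 + Im(S)^2) / outer(d, d)
  }
  acc / length(bins)
}

#' Mean magnitude-squared coherence of an epoch in one band
#'
#' Welch auto-/cross-spectra with the band's window settings (Hamming, 50%
#' overlap), coherence averaged over in-band frequencies and then over the
#' 1830 unique channel pairs.
#'
#' @param epoch An `eeg_epoch`.
#' @param band Band name or row.
#' @return Scalar in `[0, 1]`.
#' @export
mean_coherence <- function(epoch, band) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (is.character(band)) band <- get_band(band)
  wlen <- round(band$welch_window_s * epoch$fs)
  cube <- cpp_segment_ffts(t(epoch$data), as.integer(wlen), as.integer(wlen / 2))
  M <- msc_matrix(cube, epoch$fs, wlen, band$lo_hz, band$hi_hz)
  mean(M[upper.tri(M)])
}

#' Weighted graph metrics of a connectivity matrix
#'
#' From the full weighted PLV adjacency (no thresholding):
#' `meanNodeStrength` (mean row sum), `weightedClustering` (mean Onnela
#' geometric-mean triangle intensity, no max-weight renormalisation since
#' PLV is already in `[0,1]`), `globalEfficiency` and `charPathLength`
#' (shortest paths on distances `d = 1/w`; efficiency averages `1/d` over
#' ordered pairs, path length averages `d` over reachable pairs), and
#' `modularity` (Q of the partition found by seeded weighted Louvain at
#' resolution 1).
#'
#' @param cm A `connectivity_matrix` (or a plain symmetric matrix).
#' @param louvain_seed RNG seed pinning the Louvain run (default 42).
#' @return Named list of the five metrics plus logical `flag` (set when the
#'   graph is disconnected; `charPathLength` then covers reachable pairs
#'   only, or 0 if there are none).
#' @export
graph_metrics <- function(cm, louvain_seed = 42L) {
  W <- if (inherits(cm, "connectivity_matrix")) cm$weights else unname(cm)
  n <- nrow(W)
  stopifnot(n >= 2, isTRUE(all.equal(W, t(W), tolerance = 1e-10)))
  diag(W) <- 0

  strength <- rowSums(W)
  k <- rowSums(W > 0)
  A <- W^(1 / 3)
  tri <- diag(A %*% A %*% A)
  cc <- ifelse(k >= 2, tri / (k * (k - 1)), 0)

  D <- cpp_shortest_dists(W)
  off <- D[row(D) != col(D)]
  eff <- mean(ifelse(is.finite(off), 1 / off, 0))
  reach <- off[is.finite(off)]
  disconnected <- length(reach) < length(off)
  cpl <- if (length(reach)) mean(reach) else 0

  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) {
    comm <- local({
      set.seed(louvain_seed)
      igraph::cluster_louvain(g, weights = igraph::E(g)$weight, resolution = 1)
    })
    Q <- igraph::modularity(g, igraph::membership(comm),
                            weights = igraph::E(g)$weight)
  } else {
    Q <- 0
  }
  list(meanNodeStrength = mean(strength),
       weightedClustering = mean(cc),
       globalEfficiency = eff,
       charPathLength = cpl,
       modularity = Q,
       flag = disconnected)
}
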
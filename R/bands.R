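#' Canonical EEG frequency bands
#'
#' The four canonical bands used throughout the pipeline, each carrying the
#' Welch window length used for its spectral estimates: delta 0.5-4 Hz (10 s
#' window), theta 4-8 Hz (8 s), alpha 8-12 Hz (4 s), beta 12-30 Hz (2 s).
#' Band intervals are half-open `[lo, hi)` so the shared edges at 4, 8 and
#' 12 Hz are never double-counted.
#'
#' @return A data.frame with columns `name`, `lo_hz`, `hi_hz`, `welch_window_s`.
#' @export
canonical_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta"),
    lo_hz = c(0.5, 4, 8, 12),
    hi_hz = c(4, 8, 12, 30),
    welch_window_s = c(10, 8, 4, 2),
    stringsAsFactors = FALSE
  )
}

#' Look up one canonical band by name
#' @param name One of `"delta"`, `"theta"`, `"alpha"`, `"beta"`.
#' @return A one-row data.frame (see [canonical_bands()]).
#' @export
get_band <- function(name) {
  b <- canonical_bands()
  row <- b[b$name == name, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown band: ", name)
  row
}

#' Morlet scalogram frequency grid
#'
#' Geometric grid of analysis frequencies spanning 0.5-45 Hz at (nominally)
#' 10 voices per octave: `floor(10 * log2(45/0.5)) + 1 = 65` points, both
#' endpoints included.
#'
#' @return Numeric vector of strictly increasing frequencies in Hz.
#' @export
cwt_frequency_grid <- function() {
  n <- floor(10 * log2(45 / 0.5)) + 1L
  exp(seq(log(0.5), log(45), length.out = n))
}

#' Indices of grid frequencies falling in a band
#'
#' Half-open membership `lo <= f < hi`, consistent with the band partition.
#'
#' @param freqs Frequency grid (Hz).
#' @param band A band row from [canonical_bands()] or a band name.
#' @return Integer indices into `freqs`.
#' @export
band_grid_indices <- function(freqs, band) {
  if (is.character(band)) band <- get_band(band)
  which(freqs >= band$lo_hz & freqs < band$hi_hz)
}
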
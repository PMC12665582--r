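test_that("the analysis grid spans 0.5-45 Hz with the pinned point count", {
  g <- cwt_frequency_grid()
  expect_length(g, floor(10 * log2(45 / 0.5)) + 1)
  expect_equal(g[1], 0.5)
  expect_equal(g[length(g)], 45)
  expect_true(all(diff(g) > 0))
  # ~10 voices per octave
  expect_equal(length(g) - 1, 64)
})

test_that("scalogram is linear in amplitude and localises tones", {
  x <- tone(10, dur_s = 4)
  s1 <- morlet_scalogram(x, 256)
  s2 <- morlet_scalogram(2 * x, 256)
  expect_lt(max(abs(s2$amplitude - 2 * s1$amplitude)) /
              max(s1$amplitude), 1e-9)
  expect_true(all(s1$amplitude >= 0))

  avg <- rowMeans(s1$amplitude)
  f_peak <- s1$freqs_hz[which.max(avg)]
  f_near <- s1$freqs_hz[which.min(abs(s1$freqs_hz - 10))]
  expect_equal(f_peak, f_near)

  expect_error(morlet_scalogram(x[1:100], 256), "shorter")
})

test_that("band envelopes concentrate on tones", {
  s <- morlet_scalogram(tone(9.8, dur_s = 8), 256)
  env <- band_envelope(s, "alpha")
  mid <- 512:(8 * 256 - 512)
  band <- get_band("alpha")
  # For a pure tone the bandwidth-modulation series is limited by the
  # wavelet's own spectral width (sd f/omega0, so BM <= f/(omega0*sqrt(2)))
  expect_lt(mean(env$BM[mid]), 9.8 / (6 * sqrt(2)))
  # steady envelope away from edges
  expect_lt(sd(env$AM[mid]) / mean(env$AM[mid]), 0.1)
  # centroid within one grid step of the tone frequency
  g <- s$freqs_hz
  step <- max(diff(g[band_grid_indices(g, band)]))
  expect_lt(abs(median(env$centroid_t[mid]) - 9.8), step + 1e-9)
})

test_that("tf band features match their definitions on canonical signals", {
  fs <- 256
  g <- cwt_frequency_grid()
  f_star <- g[which.min(abs(g - 10))] # an exact grid frequency in alpha
  x <- tone(f_star, fs, 20)
  s <- morlet_scalogram(x, fs)
  feats <- tf_band_features(s, "alpha", x_raw = x)
  expect_equal(unname(feats["peakFrequency"]), f_star)
  expect_named(feats, c("meanAM", "meanBM", "spectralEntropy",
                        "frequencyCentroid", "meanPeakAmplitude",
                        "peakFrequency", "skewness", "kurtosis",
                        "hjorthMobility", "hjorthComplexity"))
  expect_true(feats["spectralEntropy"] >= 0 && feats["spectralEntropy"] <= 1)
  b <- get_band("alpha")
  expect_true(feats["frequencyCentroid"] >= b$lo_hz &&
                feats["frequencyCentroid"] < b$hi_hz)

  # white noise has higher normalised entropy than a tone
  wins <- vapply(1:40, function(seed) {
    set.seed(seed)
    xn <- rnorm(4 * fs)
    sn <- morlet_scalogram(xn, fs)
    st <- morlet_scalogram(tone(f_star, fs, 4) + 0.01 * rnorm(4 * fs), fs)
    en <- tf_band_features(sn, "alpha", x_raw = xn)["spectralEntropy"]
    et <- tf_band_features(st, "alpha", x_raw = xn)["spectralEntropy"]
    en > et
  }, logical(1))
  expect_gte(sum(wins), 38)

  # degenerate constant-envelope input: moments fall back to 0
  xz <- rep(0, 5120)
  sz <- morlet_scalogram(xz, fs)
  fz <- tf_band_features(sz, "alpha", x_raw = xz)
  expect_equal(unname(fz[c("skewness", "kurtosis")]), c(0, 0))
  expect_equal(unname(fz["spectralEntropy"]), 0)
})

test_that("Hjorth parameters recover sinusoid frequency and unit complexity", {
  fs <- 256
  x <- tone(10, fs, 20)
  hp <- hjorth_params(x, fs)
  # discrete-difference correction: f * sin(pi f / fs) / (pi f / fs)
  expected <- 10 * sin(pi * 10 / fs) / (pi * 10 / fs)
  expect_lt(abs(hp$mobility_hz - expected) / expected, 1e-3)
  expect_lt(abs(hp$mobility_hz - 10) / 10, 0.005)
  expect_lt(abs(hp$complexity - 1), 0.005)

  # white noise: complexity > 1 essentially always
  highc <- vapply(1:50, function(s) {
    set.seed(s)
    hjorth_params(rnorm(2000), fs)$complexity > 1
  }, logical(1))
  expect_gte(sum(highc), 49)

  z <- hjorth_params(rep(3, 100), fs)
  expect_true(z$flag)
  expect_equal(c(z$mobility_hz, z$complexity), c(0, 0))
  expect_error(hjorth_params(c(1, 2), fs), "3 samples")
})

test_that("feature scale relations hold: meanAM linear, shape features invariant", {
  set.seed(31)
  fs <- 256
  x <- rnorm(5120)
  s1 <- morlet_scalogram(x, fs)
  s2 <- morlet_scalogram(3 * x, fs)
  f1 <- tf_band_features(s1, "beta", x_raw = x)
  f2 <- tf_band_features(s2, "beta", x_raw = 3 * x)
  expect_lt(abs(f2["meanAM"] - 3 * f1["meanAM"]) / (3 * f1["meanAM"]), 1e-6)
  for (nm in c("spectralEntropy", "frequencyCentroid", "peakFrequency",
               "hjorthComplexity")) {
    expect_lt(abs(f2[nm] - f1[nm]) / max(abs(f1[nm]), 1e-12), 1e-6)
  }
})

test_that("batch kit agrees with the reference path", {
  e <- noise_epoch(seed = 77)
  fv <- extract_features(e)
  for (band in c("delta", "alpha", "beta")) {
    ch <- "C3"
    x <- e$data[ch, ]
    s <- morlet_scalogram(x, e$fs)
    ref <- tf_band_features(s, band, x_raw = x)
    got <- fv[paste(ch, band, names(ref), sep = "_")]
    # Hjorth and peakFrequency are exact; envelope statistics agree to the
    # decimated-grid resolution
    expect_equal(unname(got[6]), unname(ref[["peakFrequency"]]))
    expect_lt(abs(got[9] - ref["hjorthMobility"]) / ref["hjorthMobility"], 1e-9)
    expect_lt(abs(got[10] - ref["hjorthComplexity"]) / ref["hjorthComplexity"], 1e-9)
    for (i in 1:5) {
      expect_lt(abs(got[i] - ref[i]) / max(abs(ref[i]), 1e-9), 0.02)
    }
  }
  # PLV reference operation matches the batch matrix summary
  cmx <- plv_matrix(e, "alpha")
  expect_equal(unname(fv["plv_alpha"]), mean_plv(cmx), tolerance = 1e-9)
  # coherence reference matches batch
  expect_equal(unname(fv["coh_beta"]), mean_coherence(e, "beta"), tolerance = 1e-9)
})
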
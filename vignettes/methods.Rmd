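---
title: "Methods: an EEG feature pipeline for detecting acute sleep deprivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an EEG feature pipeline for detecting acute sleep deprivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`sleepdepEEG` implements a complete analysis chain for discriminating acute
sleep deprivation (label 1) from well-rested wakefulness (label 0) in
61-channel eyes-open resting-state EEG, using a within-subject two-session
design: deterministic preprocessing, a 2481-dimensional feature vector per
20-s epoch, leakage-safe two-stage feature selection, nested stratified
(group) cross-validation over three classifier families, confusion-matrix /
ROC evaluation with Friedman–Dunn model comparison, and fold-aligned
SHAP-style attribution. Because the pipeline is meant to be testable end to
end without any data download, the package ships a first-class synthetic
cohort generator that emulates the statistical structure such a study
produces; everything downstream is agnostic to whether recordings are
simulated or real (any channels x samples matrix in microvolts with a known
sampling rate can be wrapped into a recording object).

# The synthetic cohort generator

Each subject owns a spectral *fingerprint*: multiplicative amplitude gains
per (channel, band), i.i.d. log-normal with log-SD `fingerprint_sd`. A
session signal per channel is a sum of band-limited stochastic oscillations
(delta/theta/alpha/beta), built in the frequency domain as Gaussian-edged
band-shaped complex noise and inverse-transformed — *not* pure sinusoids, so
envelopes fluctuate and the amplitude-modulation features are nondegenerate.
Base amplitudes are roughly physiological (a few to ~12 µV per band, alpha
boosted posteriorly); broadband white noise (`noise_sd`) is added in the
time domain. A single shared beta-band source is mixed into all channels
through a per-subject topography that is zero-mean across channels (so the
source survives common average referencing), scaled by a per-subject
log-normal coupling gain with SD `fingerprint_sd` — a connectivity
fingerprint mirroring the spectral one, so baseline beta coherence/PLV
varies between subjects just as band amplitudes do.

Condition 1 modifies the generative process in exactly three ways:

* frontal (Fp1/Fpz/Fp2/AF3/AF4) theta amplitude is multiplied by
  `theta_am_effect` (>= 1),
* the shared-source coupling is scaled by `1 + beta_coh_effect`,
* posterior alpha amplitude is multiplied by `alpha_power_effect` (<= 1).

These are the directions reported for acute sleep loss — frontal theta
up-modulation, altered large-scale beta coupling, posterior alpha
suppression — and they make the "ground truth" discriminative features known
in advance (`*_theta_meanAM` frontally, `coh_beta`), which the selection and
interpretability tests exploit. Defaults (`theta_am_effect = 1.4`,
`beta_coh_effect = 0.3`, `alpha_power_effect = 0.8`, `fingerprint_sd =
0.25`, `noise_sd = 5`) produce cohorts that are clearly but not trivially
separable at the epoch level.

Determinism: one master seed; each (subject, role) stream — fingerprint,
session-0 noise, session-1 noise, artifact placement — derives its own
31-bit seed by stable hashing, so cohorts are bit-reproducible and adding
subjects never perturbs existing ones. `inject_artifacts()` adds seeded
2-s, user-amplitude windowed 5 Hz bursts (at most one per 20-s epoch) and
records their epoch positions, providing ground truth for the rejection
rule. What the generator does *not* emulate — ocular/muscle artifact
topographies, electrode drift, session-timing (circadian) effects,
nonstationarity within a session — bounds what green tests mean: they
validate the pipeline's mechanics and its behaviour under known effects,
not clinical performance on real EEG.

# Preprocessing

Fixed order, bit-deterministic: resample to 256 Hz (polyphase, rational
ratio) → zero-phase FIR band-pass 0.2–45 Hz → common average reference →
contiguous non-overlapping 20-s epochs (trailing remainder discarded,
epoch k covers samples `[kL, (k+1)L)`, 0-based) → rejection of any epoch in
which any channel's population SD (denominator N) exceeds 50 µV.

Filters are Hamming windowed-sinc designs with unit-DC-gain low-pass
prototypes; band-pass kernels are differences of two low-pass kernels, so
gain is ~0.5 at each nominal edge. Zero phase is obtained by applying the
squared magnitude response in the frequency domain (equivalent to
forward–backward filtering) with zero-padded, 5-smooth FFT lengths.
Transition widths are `max(0.2 * edge, 0.1 Hz)` for the broadband filter —
giving the 0.2 Hz high-pass edge a ~33-s kernel, which is why an additional
floor caps the kernel at the recording length (effective only below ~35 s of
data) — and `max(0.2 * edge, 0.5 Hz)` for the per-band decomposition filters
used by the connectivity and Hjorth features, because a 20-s epoch cannot
support a 33-s kernel; the delta kernel is then ~6.6 s. ICA-based artifact
correction is deliberately out of scope (the simulator produces no ocular
components); the amplitude rule is the only artifact control.

# The 2481-feature vector

Per epoch: 61 channels x 4 bands x 10 time-frequency descriptors (2440),
13 channel-averaged spectral features, 8 connectivity features, 20 graph
metrics. Names follow `{Channel}_{band}_{feature}` for the TF block and are
emitted in a fixed canonical order.

**Time-frequency block.** A complex Morlet transform (centre frequency 6
cycles; analytic Gaussian frequency window of SD `f/6`, peak gain 2 so a
tone of amplitude A has envelope ~A) is evaluated on 65 geometrically spaced
frequencies spanning 0.5–45 Hz (both endpoints included, ~10 voices per
octave). Within each band (half-open intervals, so 4, 8, 12 Hz are never
counted twice): `AM(t)` is the band-mean amplitude, the instantaneous
centroid and bandwidth are amplitude²-weighted mean/SD of frequency, and the
10 features are the temporal means of AM and BM, normalised spectral entropy
of the time-averaged band power, power-weighted frequency centroid, mean
over time of the peak amplitude, the grid frequency of maximal time-summed
power, skewness and excess kurtosis of the AM series (0 with a flag when the
series is constant), and Hjorth mobility (reported in Hz via
`(fs/2π)·sqrt(var(Δx)/var(x))`) and complexity computed on the FIR
band-filtered time series. Time-averaged statistics exclude the first and
last second of the epoch as a cone-of-influence proxy, except in delta,
whose wavelet is longer than any affordable trim; Hjorth and PLV use a
uniform 1-s trim against filter transients. The batch extractor computes the
wavelet coefficients exactly but decimated: per analysis frequency only the
FFT bins inside ±5 SD of the Gaussian are kept and folded modulo a per-band
power-of-two length covering the support, which returns exact samples of the
band-limited analytic coefficient at 8–64 Hz; unit tests pin the batch path
to the full-rate reference implementation.

**Spectral block.** Welch PSDs with Hamming windows and 50% overlap, window
lengths tailored per band (10/8/4/2 s), density scaling with window power
correction. Absolute band power is the trapezoid integral over the half-open
band, computed per channel and then averaged over the 61 channels (the
channel-averaging, rather than per-channel spectral features, is what makes
the total dimension 2481 = 61·40 + 13 + 8 + 20); relative powers normalise
by the sum of the four band powers and hence sum to 1 by construction;
ratios theta/alpha, delta/theta, beta/alpha use a 1e-12 µV² denominator
floor; spectral edge frequencies (50%, 95%) come from the broadband
channel-mean PSD at the 10-s window, the finest of the configured
resolutions, with linear interpolation between bins.

**Connectivity and graph blocks.** Per band, instantaneous phases come from
the zero-phase analytic band signal; unit phasors are sampled at a per-band
rate (16/32/32/64 Hz — subsampling leaves the PLV time-average unbiased and
only trades estimator variance) and `PLV(i,j) = |mean exp(i(φ_i − φ_j))|`.
Magnitude-squared coherence uses Welch auto-/cross-spectra with the band's
window settings, averaged over in-band bins and the 1830 unique pairs. The
five graph metrics are computed on the full weighted PLV adjacency (no
thresholding): mean node strength; Onnela-form weighted clustering without
max-weight renormalisation (PLV is already in [0,1]); global efficiency and
characteristic path length on distances `d = 1/w` (efficiency averages `1/d`
over ordered pairs with unreachable pairs contributing 0; path length
averages over reachable pairs and flags disconnection); and modularity Q of
the partition found by weighted Louvain at resolution 1 under a pinned seed,
so runs are reproducible. Coherence does not enter the graphs.

# Selection, models, evaluation

Scaling to [0,1] and both selection stages are fitted on each outer
*training* partition only; test rows may scale outside [0,1] and are not
clipped. The χ² filter scores each nonnegative feature by comparing
class-wise sums with the class-prior expectation and keeps the top 50 (ties
break by canonical name order). Neighbourhood component analysis is then fit
on the *complement*, so the additional 50 are disjoint by construction: a
diagonal (per-feature) NCA maximising the leave-one-out soft-nearest-
neighbour objective with weighted L1 distances `Σ_j w_j²|x_ij − x_kj|` minus
an L2 penalty (λ = 1/n), by adaptive gradient ascent from w = 1 with at most
200 steps and early stopping at a 1e-4 relative objective change. Because
the objective is quadratic in rows and linear in features, the LOO objective
is evaluated on a seeded stratified subsample of at most 128 rows; features
are ranked by |w|.

Two fold plans: epoch-level stratified shuffled 5-fold, and subject-level
stratified *group* 5-fold in which whole subjects are assigned greedily (by
descending epoch count) to the fold minimising squared deviation of class
counts from the ideal per-fold counts — deterministic, never splitting a
subject across train and test, and filling every fold even with unequal
epochs per subject. Hyperparameters are tuned by randomised search —
uniform draws without replacement from the grid's Cartesian product, 25
candidates by default (capped at grid size) — scored by mean accuracy over
an inner stratified 3-fold on the outer-training rows; ties keep the first
draw. The winner is refit on the full outer-training partition (restricted
to the 100 selected features) and evaluated on the held-out fold with the
0.5 probability cutoff. Three learner families run through one harness:
random forest (ranger; `criterion` candidates are gini/hellinger since
entropy is not exposed), gradient boosting (xgboost), and an RBF/linear SVC
(e1071, Platt-calibrated probabilities with a pinned seed). Accuracy,
precision, recall, F1 follow their confusion-matrix definitions (zero
denominators yield flagged 0s); AUC is the trapezoid area under the
tie-aware threshold sweep and is unit-tested against the pairwise-ordering
oracle. Fold summaries report mean ± SD (n−1). Model comparison uses the
tie-corrected Friedman statistic (χ² reference with k−1 df; an exact
enumeration mode over all within-fold orderings exists for small problems
and is oracle-tested) and Dunn-style pairwise rank-sum differences with the
tie-corrected normal SE; multiplicity adjustment is Holm by default
(Bonferroni available) since Holm is uniformly more powerful.

# Interpretability

SHAP values are computed on each outer fold's held-out rows only, on the
probability scale for every model family. For xgboost, exact tree-path
attributions (margin scale) are rescaled linearly to the probability scale —
`φ_prob = φ_margin · (σ(m) − σ(b))/(m − b)` — preserving exact additivity
(per-row sum + base = predicted probability). For non-tree models a
permutation-sampling estimator walks feature permutations from background
rows to the test row; the telescoping sum makes it exactly locally accurate
with base value `mean f(background)`. The background is a seeded subsample
of at most 200 training rows; the model-call budget is `2·p + 2048` per row
(split into ~2 permutations x ~11 background rows at p = 100). Global
importance restricts to the intersection of the per-fold selected feature
sets (a feature selected in 4 of 5 folds is excluded) and pools mean |SHAP|
over all test rows of all folds; the top-10 features feed a Spearman
correlation matrix on raw feature values across all epochs.

# Numerical choices and problem sizes

Degenerate inputs are contract-tested: constant channels give flagged zero
PLV pairs; zero-power bands give entropy 0 and mid-band centroids; zero
variance gives flagged zero Hjorth values; empty fold intersections raise an
error naming per-fold set sizes. All FFT work is double precision through
FFTW. The acceptance suite exercises the full pipeline at desk scale, chosen
so the whole test run stays comfortably reproducible on a single CPU: the
leakage-inflation experiment uses 14 subjects x 5 epochs/session x 10 seeded
cohorts with a reduced RF grid (2 candidates), and the marker-recovery
experiment 8 subjects x 4 epochs/session x 10 seeds with a reduced xgboost
grid. For the leakage experiment the generator is set to a regime where the
condition effect is detectable within subject but small against the
between-subject fingerprint spread (`theta_am_effect = 1.25`,
`fingerprint_sd = 0.5`): within a subject the theta-power shift (~x1.56) far
exceeds the per-epoch estimation noise, while across subjects it is less
than half the fingerprint-induced log-power SD (~1.0), which is precisely
the regime in which epoch-level cross-validation can exploit subject
identity and subject-level cross-validation cannot. Under these conditions
epoch-level accuracy exceeds subject-level accuracy by ~0.15–0.29 per
cohort (mean ~0.20 over ten seeded cohorts).

# Known limitations

The generator's stationary Gaussian band model lacks real EEG's 1/f
continuum, transients, and artifact topographies; channel-averaged spectral
features are an interpretation pinned by the dimension arithmetic; the NCA
row cap trades objective fidelity for runtime on large folds; Louvain finds
a local modularity optimum (exhaustive enumeration confirms it only at toy
sizes); and the SVC probability calibration is itself cross-validated
internally, so its probabilities (and hence model-agnostic SHAP values)
carry extra seed-pinned variability.
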
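---
title: "Wavelet-based brain-function analysis for walking fNIRS studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-based brain-function analysis for walking fNIRS studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nirsflow` implements an end-to-end analysis of multichannel fNIRS
recordings acquired during rest and free walking: signal cleaning from raw
dual-wavelength intensities to band-limited hemoglobin concentration
changes, Morlet-wavelet activation and lateralization measures,
wavelet-coherence functional connectivity with binarized graph topology,
directed information flow via phase transfer entropy, and sliding-window
phase-locking-value (PLV) dynamics with K-means state clustering. Because
clinical gait recordings are typically private, the package ships a seeded
synthetic generator (`sim_config()`, `simulate_hb()`, `simulate_raw()`)
whose ground truth exercises every stage; all validation claims below are
asserted by the test suite on that generator.

# Data model

A montage is a `probe_layout()`: channels formed by source-detector pairs at
3 cm separation, each assigned to one of four cortical patches
(left/right prefrontal cortex, left/right motor cortex). The packaged
default (`default_layout()`) has 34 channels: 14 prefrontal and 20 motor.
The 20-channel motor set produces 190 upper-triangle channel pairs, the
feature dimension of the dynamic-state analysis. Published descriptions of
such montages are sometimes internally inconsistent about optode counts, so
the channel-to-region map is ordinary configuration, not a hard-coded fact.

Per subject, `assign_dominance()` relabels the anatomical regions by the
dominant hemisphere (for cerebral palsy, the hemisphere ipsilateral to the
affected side): DPFC/DMC on the dominant side, NPFC/NMC on the other. The
relabeling is an involution, and the dominant side always comes from the
subject metadata table rather than being inferred.

Recordings travel as plain-text bundles (samples-by-channels CSV matrices
plus a JSON sidecar with sampling rate, condition and the channel validity
mask). An HDF5-based container was considered and rejected: plain text keeps
the recordings inspectable and the package's I/O dependency-free.

# Preprocessing

The cleaning chain (in `preprocess()`) runs in a fixed order: channel
quality control on raw intensities, conversion to optical density,
motion repair, modified Beer-Lambert conversion, quadratic detrending,
removal of the first principal component, and band selection.

* **Quality control** (`qc_channels()`): a channel is excluded when its mean
  intensity at either wavelength exceeds 1000 or falls below 0.5 device
  units, or when the mean/SD quotient falls below 2. The statistic is the
  per-channel mean over the recording; both thresholds and the statistic are
  configurable because device units vary. Excluded channels are carried
  through but masked from every average and statistic.
* **Optical density** (`intensity_to_od()`): `OD = -ln(I / mean(I))`,
  invariant to constant gain.
* **Motion repair** (`tddr()`, `hampel_highfreq()`, `motion_repair()`): the
  signal is split at 0.5 Hz; the low band's temporal derivative is robustly
  reweighted and re-integrated (suppressing baseline steps and slow motion
  transients, and removing linear drift by construction), while the high
  band is despiked with a Hampel filter (window half-width 50 samples,
  threshold 4 scaled MADs). One deliberate choice: the location/scale
  iteration uses the standard Tukey biweight, but the *applied* weights keep
  unit weight for residuals below half the rejection point and redescend to
  zero at the rejection point. A literal soft biweight shrinks the 3-4 sigma
  tail of perfectly ordinary band-limited derivatives, and re-integration
  accumulates that shrinkage into a low-frequency error that visibly
  distorts artifact-free channels; the deadband keeps sub-threshold
  physiology untouched while gross artifacts are still fully rejected.
* **Beer-Lambert conversion** (`mbll_convert()`): per channel and sample the
  2x2 system over the two wavelengths is solved for (dHbO2, dHbR) in
  micromol/L, using shipped Prahl-style extinction coefficients at
  730/850 nm and a differential pathlength factor from the general
  age-and-wavelength equation
  `DPF = 223.3 + 0.05624 age^0.8493 - 5.723e-7 wl^3 + 0.001245 wl^2 -
  0.9025 wl`; both tables are overridable.
* **Detrending and global-signal removal**: least-squares quadratic removal
  per channel, then removal of the leading principal component across the
  valid channels (channels as variables, per subject and condition) as the
  systemic physiological component. The montage has no short-separation
  channels, so PCA is the only systemic-noise defense.
* **Band selection**: a zero-phase Fourier-domain band-pass to 0.01-0.2 Hz.
  The analysis measures average over in-band wavelet scales anyway, so this
  stage only needs to confine broadband power; a brick-wall zero-phase mask
  is exact for offline data and introduces no filter transient.

# Wavelet measures

`cwt_morlet()` computes an FFT-based continuous wavelet transform with the
analytic Morlet mother wavelet, central frequency `omega0 = 6` (the
conventional trade-off between time and frequency localization), on 64
logarithmic voices spanning 0.005-0.25 Hz so the 0.01-0.2 Hz averaging band
sits strictly inside the grid. Samples inside the cone of influence
(e-folding time `sqrt(2) s`) are excluded from all band averages by default
(`coi_policy`), avoiding edge bias on 6-minute epochs.

* **Wavelet amplitude** (`wavelet_amplitude()`, `wa_by_region()`): mean
  coefficient magnitude over in-band scales and the epoch; a region's
  activation is the mean over its valid channels. WA is linear in signal
  amplitude.
* **Lateralization index** (`lateralization_index()`):
  `LI = (WAi - WAo) / (WAi + WAo)` in [-1, 1]; +1 is complete ipsilateral
  (dominant-side) activation. Both-zero input is undefined and returns `NA`.
* **Wavelet coherence** (`wavelet_coherence()`, `wco_matrix()`): per
  frequency, the squared magnitude of the time-averaged cross-spectrum over
  the time-averaged powers. Time averaging is the smoothing operator — with
  no smoothing coherence would be identically 1 — and guarantees the value
  lies in [0, 1] by Cauchy-Schwarz. The band value is the mean over in-band
  frequencies; region connectivity is the mean over cross-region channel
  pairs (within-region blocks use distinct pairs only).

# Graph topology

`threshold_by_sparsity()` binarizes the coherence matrix by keeping the
strongest `s` fraction of off-diagonal weights, with a fixed total order
(weight, then pair index) so edge sets are deterministic under ties. Metrics
are computed on the binary graph at sparsity 0.10-0.50 in steps of 0.05,
summarized by the trapezoid area under each curve (`metric_curves()`):

* clustering coefficient (node-wise neighbor-edge density, 0 for degree < 2),
* global efficiency (mean inverse shortest path; disconnected pairs
  contribute 0),
* local efficiency (global efficiency of each node's induced neighborhood
  subgraph — note this is *not* the variant that routes paths through the
  rest of the graph),
* modularity of the partition found by greedy agglomerative Q-maximization.

Shortest paths, transitivity and community detection are delegated to
igraph; the test suite checks every metric against brute-force enumeration
oracles on hundreds of small random graphs, and the greedy partition against
exhaustive set-partition search on tiny graphs. Networks are built at
channel level (valid channels as nodes); region-level graphs are a
configuration away, not a different code path.

# Directed information flow

Instantaneous phase per channel (`band_phase()`) is the argument of the mean
in-band complex wavelet coefficient. `phase_transfer_entropy()` estimates
`PTE_xy = H(Y+, Y) + H(Y, X) - H(Y) - H(Y+, Y, X)` from joint histograms on
uniform bins over (-pi, pi], entropies in bits (the base cancels in dPTE).
The bin width follows Scott's rule, `3.49 mean(sd(theta)) Ns^(-1/3)`,
converted to a count by the ceiling; the prediction delay defaults to the
phase-reversal heuristic, `round(samples x channels / phase sign changes)`
with a floor of one sample. The directional index
`dPTE_xy = PTE_xy / (PTE_xy + PTE_yx)` is antisymmetric by construction
(`dPTE_xy + dPTE_yx = 1`), with values above 0.5 marking preferential flow
X to Y. Channel summaries: out-degree counts targets above 0.5; outflow
strength sums the dPTE over those targets by default (an excess-over-0.5 sum
is available behind a flag, since the literature prints no formula for
"strength of information flow").

A documented limitation: for 0.01-0.2 Hz hemodynamics the phase-reversal
heuristic returns roughly half the dominant phase period (~6 s at 10 Hz),
which is far longer than plausible neurovascular lags. At that horizon the
directional asymmetry of a 1 s lag is washed out, so the package's
direction-recovery validation fixes the prediction delay at the planted lag,
while the heuristic remains the default for recordings whose lag is unknown.
Group-level flow patterns, which average many edges, are less sensitive to
this choice than single-pair recovery.

# Dynamic connectivity states

The walking epoch is divided by a 20 s rectangular window sliding in 1 s
steps; the window count is `floor((N - W) / step)` — for a 6-minute epoch at
10 Hz exactly 340 windows (the convention drops a window flush against the
recording end). Per window, the PLV matrix of the 20 motor channels (phases
from the analytic signal of the 0.01-0.2 Hz band-passed data) supplies 190
upper-triangle features; the implementation computes the pairwise phasor
series once and reads each window off cumulative sums, so cost is linear in
recording length.

Features are compressed 190 to 64 by a symmetric autoencoder (tanh encoder,
linear decoder, full-batch Adam, 200 epochs, fixed seed) written in plain
matrix algebra — the model is small enough that a bespoke deterministic
trainer is the honest implementation; `method = "pca"` substitutes principal
component scores to isolate clustering behavior from training dynamics.
K-means with 500 random restarts per candidate k (1-10) keeps the lowest
within-cluster sum of squares; the number of states is the elbow of the WCSS
curve, operationalized as the point of maximum perpendicular distance from
the chord joining the first and last grid points (computed on the normalized
curve; the argmax is invariant to that normalization). Dynamics summaries
per subject (`state_dynamics()`): state frequency, mean dwell (mean run
length times the window step), the row-stochastic transition matrix of
consecutive windows, and the off-diagonal transition-share matrix.

Two operationalizations deserve emphasis. First, with 20 s windows sliding
over 30 s dwells, roughly two thirds of windows straddle a state switch;
such windows have no well-defined planted state, so recovery is scored
(adjusted Rand index) on windows lying wholly inside one dwell
(`window_state_labels()` flags them). Second, a maximum-distance-to-chord
elbow on a smooth convex WCSS curve lands mid-grid even for structureless
data, so "no pronounced structure" manifests as a shallow elbow depth rather
than k = 1; the tests compare elbow depths rather than asserting a
particular k for unstructured input.

# Group statistics

`choose_and_run_test()` reproduces the standard two-sample decision chain:
Shapiro-Wilk on each sample and Levene's test across samples at 0.05; if all
pass, a pooled-variance two-sample t-test, otherwise the Mann-Whitney U
test, both two-sided. Pooled rather than Welch variance is coherent because
the t-branch is only reached when Levene passes. Family-wise error across
the four group-by-condition cells uses Bonferroni: 0.05 / 4 = 0.0125
(`bonferroni_threshold()`). `type_i_error_check()` verifies the empirical
false-positive rate of the full decision chain by simulation.

# The synthetic generator

`simulate_hb()` mixes band-limited (0.01-0.2 Hz) unit-variance latent
oscillators through the symmetric square root of a target coupling matrix,
then adds independent in-band noise (default SD 0.3 of signal amplitude).
This latent-mixing construction (rather than autoregressive dynamics) keeps
in-band phase relations directly controllable, which is what the coherence,
PLV and PTE validations need. Directed pairs rebuild the receiver as
`strength` times the lagged driver plus `sqrt(1 - strength^2)` times its own
signal. dHbR is -0.3 times the dHbO2 signal lagged 0.8 s plus noise — the
sign convention is what matters; the magnitude is immaterial to any test.
`simulate_raw()` maps concentrations through the forward Beer-Lambert model
to dual-wavelength intensities, with optional motion spikes, baseline
steps, quadratic drift, a shared ~0.1 Hz physiological component, and 0.5%
multiplicative detector noise (a realistic noise floor for any photodiode
front end).

Markov-switching connectivity uses one coupling graph per state. The default
four-state set (`state_graphs_default()`) locks a different channel subset
per state (first half, second half, odd, even channels; coupling 0.9 against
a 0.1 background) — balanced patterns whose pairwise distances are equal, so
recovery quality reflects the estimation chain rather than ground-truth
ambiguity between nested states. Dwell control: `state_dwell_min = 0` gives
the literal first-order Markov chain (geometric dwells);
the state-recovery study uses fixed 30 s dwells
(`state_dwell_min = state_dwell_mean = 30`) over 360 s recordings, keeping
every dwell at or above the analysis window width — with geometric dwells
half the segments would be shorter than one window and no window-based
method could label them.

What the generator does *not* emulate: neurovascular coupling dynamics
(balloon-model nonlinearity), cardiac/respiratory bands and their aliasing,
1/f background spectra, optode-scalp coupling drift, or spatially continuous
anatomy. Passing recovery tests on this generator therefore demonstrates the
estimators' correctness under their own assumptions, not clinical validity
on real cohorts.

# Numerical choices and problem sizes

Validation problem sizes are chosen to finish quickly on a single CPU while
leaving the statistics meaningful: 360 s recordings at 10 Hz for
calibration/recovery runs, 100 replicates for dPTE calibration and direction
recovery, 20 seeded runs for state recovery, 200 random graphs for the
brute-force metric equivalence. Tie-breaks (edge thresholding), seeds
(encoder initialization, K-means restarts, all generators) and degenerate
inputs (zero signals, constant channels, all-invalid QC masks, zero-power
frequencies, both-zero transfer entropies) have defined, tested behavior.
All randomness flows from explicit integer seeds; repeated runs are
bit-identical.

# Known limitations

* The phase-reversal delay heuristic is mismatched to slow hemodynamic
  phases (above); single-edge direction estimates at the heuristic delay
  should be treated with caution.
* PLV in a 20 s window of 0.01-0.2 Hz signals rests on only a few
  oscillation cycles; single-pair window PLV is high-variance, and only the
  joint geometry across 190 pairs makes state clustering work.
* The elbow criterion resolves the state count reliably only when state
  patterns are well separated; on the package's own generator roughly one
  run in six picks 3 or 5 states instead of 4 under the default conditions.
* Group statistics implement two-group univariate comparisons only — no
  mixed models, no FDR alternatives to Bonferroni.
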
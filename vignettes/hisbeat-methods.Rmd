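---
title: "Beat-by-beat His bundle signal extraction: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat-by-beat His bundle signal extraction: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hisbeat)
```

## The signal model

A PR-interval epoch `b_PR(t)` — the window ending at the QRS onset — is
modeled as the sum of two source-separable components,

```
b_PR(t) = b_HB(t) + b_A(t),
```

where `b_A(t)` is the atrial activity (the P wave plus the slow, ramp-like
atrial-repolarization waveform that extends across the PR segment) and
`b_HB(t)` is the His bundle deflection: a compact ~100 Hz bi/triphasic
spike whose onset precedes the QRS onset by the HV interval. The additivity
assumption is physiologically motivated — atrial repolarization and His
depolarization are generated by different structures — and it is what makes
a projection method meaningful: if the atrial component lives in a
low-dimensional subspace, removing that subspace removes `b_A` from every
beat at once.

Two further working assumptions matter:

- **HV stability.** The HV interval is nearly constant across beats under
  normal conditions, so one template annotation (one preserve window) is
  valid for the whole recording. Recordings with marked beat-to-beat HV
  variation violate this and are outside the method's scope.
- **Spectral separation.** The atrial content is slow (P wave roughly below
  30 Hz, ramps quasi-linear) while the His deflection is fast (~75–100 Hz).
  Both pipeline stages exploit this: the wavelet stage through its level
  structure, the projection stage through over-smoothing.

## Stage 1: interval-dependent wavelet thresholding

Each epoch is decomposed with the orthonormal `coif5` wavelet in five
levels. At 1 kHz the detail levels d1–d5 cover roughly 250–500, 125–250,
62.5–125, 31–62.5, and 16–31 Hz; a ~100 Hz deflection lives mostly in d3
with spillover into d2 and d1.

Detail coefficients are soft-thresholded, `sign(x)·max(|x|−t, 0)`, at the
per-level fixed-form (universal) threshold `t_j = σ_j √(2 ln N_j)`, where
`N_j` is the per-epoch coefficient count and `σ_j` is the robust MAD
estimate `median(|d_j|)/0.6745`. Coefficients whose time support intersects
the annotated preserve interval(s) around the His deflection pass through
untouched; levels d4 and d5 are removed entirely (they carry only
very-low-frequency content at this rate — the zeroed set is configurable
because at other sampling rates the His band lands in different levels).
The deepest approximation is never touched: thresholding applies to detail
coefficients only, and the surviving low-frequency content (P wave, ramps)
is the next stage's business. The compiled object — wavelet, thresholds,
per-level preserve masks, zeroed levels — is serializable and is applied
verbatim to every raw epoch of a recording, which is what makes the
extraction consistent across beats.

Numerical choices in this stage:

- **Periodized transform + edge detrending.** The multilevel transform uses
  circular convolution, which is orthogonal for any even length and inverts
  to machine precision (epochs whose length is not a multiple of 2^5 are
  reflection-extended and truncated after reconstruction). Because a PR
  epoch ends on the atrial ramp far from its starting baseline, the
  circular wrap-around would otherwise look like a step edge and leak
  spurious detail energy near both ends; each epoch is therefore detrended
  by the straight line joining its end baselines (mean of 5 samples each)
  before the transform and retrended afterwards. The line is pure ramp
  content and is removed later by the projection like any other ramp.
- **Time-to-coefficient mapping.** A preserve interval is given in ms; the
  mask marks the level-`j` coefficients whose empirical time centroid falls
  inside the interval dilated by one median circular time-SD of that
  level's coefficients. Centroids and SDs are computed once per geometry by
  transforming an identity matrix, so filter delay and wrap-around are
  accounted for exactly rather than by a nominal `k·2^j` rule (the `coif5`
  filters are 30 taps long; their accumulated delay at level 3 is on the
  order of 100 samples and cannot be ignored).
- **Which signal sets the noise scale.** Estimating `σ_j` from the
  signal-averaged template would underestimate the single-beat noise by
  `√m` (averaging `m` beats attenuates noise by `√m`), leaving the stored
  thresholds far too small to clean raw epochs. When the raw epoch stack is
  available, `build_threshold_spec(..., epochs = stack)` estimates `σ_j`
  from the pooled detail coefficients of the raw epochs instead — the
  automated counterpart of choosing per-level magnitude limits that
  visibly clean the individual beats. The template-only path remains for
  workflows where only the averaged trace exists.
- **Per-level thresholds.** One threshold per level rather than one global
  threshold: detail-coefficient noise scales differ across levels once any
  colored noise or residual signal is present, and the per-level universal
  rule is the standard form.

The practical annotation convention of flanking the bump with markers T1
and T2 and keeping 4–5 intervals in total is supported by
`template_annotation()`; the template's HV is the distance from T1 to the
QRS onset.

## Stage 2: signal space projection

The thresholded epochs are over-smoothed with a cubic Savitzky–Golay filter
of 23 ms frame (23 samples at 1 kHz; at other rates the frame is converted
from ms and rounded to odd). The filter is exact on cubic polynomials and
attenuates a 100 Hz tone to well under half its amplitude, so the smoothed
epochs approximate the atrial component of each beat. Their time × beats
matrix is decomposed by SVD; the left singular vectors are retained until
the cumulative squared singular values reach the energy rule (default
0.99), capped at `m − 1` so the basis is always strictly smaller than the
number of epochs. The orthogonal-complement projector `P⊥ = I − U_n U_nᵀ`
is then applied to every thresholded epoch. `P⊥` is applied in the
factored form `x − U_n(U_nᵀ x)`, which agrees with the materialized T × T
operator to machine precision without forming it.

Design choices here:

- **Project the thresholded, not the raw, epochs.** The stage order is
  threshold → smooth → basis → project: the projection's input is the
  current PR estimate after wavelet cleaning, which is also the signal the
  smoothing stage can most reliably reduce to atrial content.
- **Energy rule as the "significant basis vectors" criterion.** The rank
  needed to span the atrial subspace is not known a priori; retained
  energy is a simple, monotone criterion and is exposed as a parameter. In
  high-SNR simulations the rule selects rank 1 (the shared atrial shape);
  as noise grows the rank grows and the projection becomes more aggressive,
  which is the main mechanism behind the correlation loss at low SNR.

## The synthetic study conditions

`sim_config()` defaults encode the evaluation conditions: 1 kHz sampling,
350 ms epochs ending at the QRS onset, a unit-amplitude Gaussian P wave
(peak at 80 ms, SD 20 ms), a piecewise-linear PTa ramp from the P-wave
offset (taken as peak + 2 SD) to the QRS onset, a His deflection at
HV = 60 ms, and additive white Gaussian noise whose RMS is set by the
stated SNR with the P-wave *peak* as the signal reference
(`σ = p_amp / 10^(SNR/20)`; RMS rather than peak noise is the standard
convention). The three PTa types fix the ramp extreme relative to the P
peak: −1/3 (opposite polarity), +1/2, and above +1/2 (default +0.6). The
epoch length and sampling rate are this package's choices — 350 ms covers
PR intervals up to the longest HV discussed (120 ms) with the full P wave
included — as the source conditions do not pin them down; both are
configurable.

The His deflection is a windowed sinusoid at 100 Hz with 15 ms support. The
window is flat-topped with 3 ms raised-cosine edges rather than a full
Hann taper: the measurement convention defines the His onset as the onset
of the deflection's *first downward limb*, and under a full-length taper
that limb is ~15% of the peak — an essentially invisible feature that no
onset detector could be expected to find at beat level. The short-edged
window gives the spike the sharp attack of the "M"-shaped deflections seen
in averaged recordings while keeping it compact and band-limited. Amplitude
defaults to 0.2 of the P peak.

The multi-beat generator appends a stylized high-amplitude R–S complex
after each epoch at (optionally jittered) RR spacing and, in multichannel
mode, flips the atrial polarity across channels while keeping the His
timing identical — the structure exercised by the fourth identification
criterion. What the generator does **not** emulate: realistic torso/volume
conductor physics, T waves and baseline wander, ectopic or arrhythmic
beats, channel-correlated sensor noise, and beat-to-beat HV variability.
Passing tests on these simulations therefore demonstrate the pipeline's
algebraic and statistical behavior under the stated model, not clinical
performance on measured MCG/BSPM.

## Measurement conventions

- **QRS onset index.** The onset is the final sample of each epoch row, and
  ground truth HV satisfies `hv = (T − onset_idx)/fs` exactly; the
  epoch extractor, the stack class, and `measure_hv()` all share this
  convention.
- **HV measurement.** `measure_hv()` finds the last supra-threshold complex
  before the QRS onset (threshold `k = 2` times a caller-supplied noise
  floor; samples within 10 ms merge into one complex), takes its first
  downward limb — the first negative excursion reaching at least 30% of the
  complex peak, a guard that prevents sub-noise dips just ahead of the
  deflection from masquerading as its onset — and backtracks to the
  preceding zero crossing. On noiseless epochs this recovers the generated
  HV to the sample across the 35–120 ms grid.
- **Correlation window.** Extraction quality is scored as the Pearson
  correlation between the extracted beat and the clean reference over the
  His window (support dilated by 5 ms), not the full epoch: the full-epoch
  score would be dominated by the empty baseline. The full-epoch option is
  exposed.
- **SER.** Band powers come from a Hann-windowed, 50%-overlap Welch
  periodogram integrated over the stated bands (P wave 5–30 Hz, His
  75–100 Hz, noise 150–200 Hz), and `SER = P_ext/(P_raw − P_ext)`.
- **Spearman's ρ** uses the rank-difference formula with average ranks for
  ties; for tie-free data this equals Pearson correlation of the ranks
  exactly, and the tie-handling divergence from the textbook formula is
  deliberate. **Bland–Altman** limits use the sample (n−1) SD and ±1.96.

## What the simulations show

At the evaluation's study conditions (Type 1, 100 replicates per SNR
point), the mean extraction correlation rises monotonically over 5–28 dB
and plateaus above 0.9 at the top of the range; the median per-beat HV at
28 dB is recovered within a millisecond of the true 60 ms. Useful beat-level
extraction requires roughly 15–20 dB. One honest caveat on the PTa-type
comparison: because the simulated ramp is exactly linear and both the edge
detrending and the SVD basis remove linear ramps essentially perfectly, the
three PTa types yield nearly identical correlations here — the ordering
"Type 1 at least as good as Types 2 and 3" holds, but only weakly, as
near-equality. Ramp shapes with curvature or beat-to-beat variation would
be needed to separate the types, and real atrial repolarization is not
exactly linear.

Problem sizes used by the test suite and the acceptance script — stacks of
30–200 epochs of 350 samples, SNR sweeps of 5–9 points with 30–100
replicates — were chosen so the whole evaluation reruns from scratch in
seconds while keeping Monte-Carlo error well below the decision margins.

## Known limitations

- The preserve intervals are manual (or, in simulations, derived from
  ground truth); automating their selection is an open refinement.
- The atrial-subspace rank rule is a heuristic; an adversarial noise
  spectrum could inflate the rank and erode the His signal.
- Beats are assumed regular: the only beat-rejection mechanism is the
  detector's refractory rule, and arrhythmic morphologies are out of scope.
- EDF ingestion is not implemented; the delimited CSV-with-header format is
  the supported interchange for series and stacks.
- Thresholding with one stored spec assumes stationary noise across the
  recording; slow noise drift would call for re-estimation per analysis
  bin.
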
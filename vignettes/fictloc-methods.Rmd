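---
title: "Quantifying spinal locomotor output: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spinal locomotor output: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(fictloc)
```

fictloc analyzes three kinds of data produced in studies of the spinal
locomotor network: drug-evoked fictive locomotion recorded from lumbar
ventral roots of the isolated neonatal spinal cord, the spatial distribution
of identified interneuron somata in transverse sections, and neonatal
swimming / vestibulospinal reflex behavior. This vignette explains the
models and procedures behind each stage, the parameters that matter, and
the design decisions taken where more than one reasonable choice existed.

## From raw trace to discharge envelope

A ventral-root recording is an extracellular voltage series dominated by
summed motor-axon discharge. During fictive locomotion the discharge arrives
in bursts, one per locomotor cycle: the left and right L2 roots alternate,
the ipsilateral L2 and L5 roots alternate (flexor versus extensor phase),
and the diagonal pairs are synchronous.

The preprocessing chain in `envelope()` is:

1. **Median detrend** (optional, default on): subtracting the channel median
   is a minimal digital stand-in for baseline drift removal. Recordings are
   assumed already band-limited by the acquisition chain, so no digital
   bandpass is applied.
2. **Full-wave rectification**, `rectify()`.
3. **Weighted central moving average** with a Hamming window,
   `smooth_wcma()`. Near the trace edges the weights are renormalized over
   the available samples; zero padding would instead bend the envelope
   toward zero exactly where short test traces are most scrutinized.
4. **Resampling** to an analysis rate, `resample_uniform()`, with a
   zero-phase Hamming-windowed FIR low-pass (cutoff 90% of the new Nyquist,
   unit DC gain) before decimation.

Two parameters matter and neither follows from first principles, so both are
declared defaults rather than inferred values: the smoothing window duration
(0.25 s) and the envelope rate (200 Hz). A 0.25 s window is roughly 1/15 of
the slowest locomotor cycle considered here (6.25 s) and preserves bursts of
0.5 s and longer while suppressing within-burst carrier structure. 200 Hz
keeps burst edges resolved to 5 ms, an order of magnitude finer than any
timing tolerance used downstream.

## Burst detection

`detect_bursts()` uses a two-threshold hysteresis rule on the envelope's
elevation above its baseline median: open at `median + 3 * MAD`, close when
the elevation falls below half the opening elevation. Robust statistics make
the thresholds insensitive to the burst fraction of the record and to
uniform amplitude scaling; the hysteresis prevents chatter on the falling
flank. Two post-rules clean up the event list: gaps shorter than 0.3 s are
merged (bursts briefly dipping under threshold), then events shorter than
0.2 s are dropped (transients). For a strictly noiseless envelope the MAD
can collapse to zero even though bursts are present (a clean gate at duty
below 50%); the detector then falls back to half-maximum thresholding.

Cycle period is defined onset-to-onset. This is the common convention in
fictive-locomotion work and makes the phase definition below unambiguous;
peak-to-peak periods are noisier because the peak position inside a burst is
arbitrary. Events whose following period is shorter than half the median
period are flagged (`short_cycle`) as candidate non-locomotor "extra"
bursts, which in this preparation appear preferentially in the right L5
root; they are retained, not deleted, and the per-cycle phase estimator
tolerates them naturally.

## Coordination statistics

**Phases.** For an ordered root pair, each reference cycle
`[onset_k, onset_{k+1})` contributes one phase,
`360 * (t_target - onset_k) / period_k` degrees, where `t_target` is the
first target-root onset in the cycle. Cycles without a target onset are
skipped and counted. The estimator is onset-anchored rather than
correlogram-based because onsets are the quantity the burst detector
actually certifies; the correlogram peak lag is exposed alongside for
cross-checking.

**Circular summary.** `circular_stats()` reports the circular mean
direction, the resultant length R, the circular standard deviation
`sqrt(-2 log R)`, and the Rayleigh non-uniformity test using the standard
series approximation with the second-order small-sample correction. Below
about n = 10 that approximation frays; a Monte Carlo p-value under
uniformity is available (`method = "simulation"`).

**Cross-correlation and CCC.** The correlogram is the exact Pearson
correlation of the overlapping segments at every lag, so coefficients are
bounded in [-1, 1] by construction and equal 1 at lag zero for a trace with
itself. The rhythm-strength index (CCC) is the signed mean of the
correlogram over lags within a quarter cycle of zero, i.e. a window of half
a mean cycle period centered on lag 0. The window choice is deliberate: over
a *full* period the correlogram of any strongly rhythmic pair integrates to
approximately zero (the positive and negative half-waves cancel), which
would make the index blind to exactly the property it is meant to measure.
Over the half-period window a synchronous pair scores strongly positive, an
alternating pair strongly negative, and an arrhythmic pair near zero.

**Rhythmicity.** The autocorrelation rhythmicity index is the height of the
first positive-lag local maximum of the envelope autocorrelogram, and its
lag estimates the cycle period. Local maxima whose topographic prominence is
below 5% of the correlogram's range are treated as ripple and skipped; an
envelope is called rhythmic above an index of 0.2.

**Frequency modes.** Instantaneous cycle frequencies (reciprocal
onset-to-onset periods) are pooled and smoothed with a Gaussian kernel
density (default bandwidth 0.02 Hz, Silverman fallback when unset), plotted
peak-normalized to 1. Modes are local maxima with topographic prominence of
at least 20% of the peak, which separates genuine slow/fast locomotor modes
from sampling ripple. Distributions are compared between genotype groups
with the two-sample Kolmogorov-Smirnov test (asymptotic p). Because the KS
statistic is lattice-valued at moderate n, its null p distribution is
slightly lumpy; the test suite checks calibration through rejection rates
rather than strict uniformity of p.

## Soma position analysis

Each soma is measured in a transverse section by a distance `d` and angle
`alpha` from the ventral limit of the central canal, together with the
section height `H` (canal to dorsal edge) and hemicord width `W` (canal to
lateral edge). Normalized coordinates are `DV = d sin(alpha) / H` and
`ML = d cos(alpha) / W`, reported as percentages. Cells measured in the
opposite hemicord (`alpha > 90` degrees) are mirrored onto one side before
analysis, and values pushed slightly outside [0, 1] by measurement noise
are clamped with a warning rather than dropped — dropping would bias the
edges of the distribution, which is exactly where the lateral cluster sits.

Density maps use a Gaussian kernel (default bandwidth 0.05 in fraction
units, 50 x 50 grid) with an explicit boundary correction: each grid point
is reweighted by the kernel mass falling inside the unit square, then the
map is renormalized to integrate to 1. Without the correction a uniform
sample would appear to lose up to three quarters of its density at corners,
corrupting any visual comparison of edge-hugging clusters.

Groups are compared with the two-sample Hotelling's T² test on the (ML, DV)
pairs — the two-dimensional generalization of the two-sample t-test — with
`T² (n1+n2-3) / (2 (n1+n2-2))` referred to an F(2, n1+n2-3) distribution.
By default cells pool across sections and embryos within a group, which
treats cells as the experimental unit; `per_embryo = TRUE` aggregates to
embryo means first, the conservative alternative when embryo effects are
suspected. Axial levels are tested separately; no multiplicity correction
is applied by default (a `p_adjust` method can be supplied), matching the
per-level reporting convention of this literature.

## Neonatal behavior

**Swimming.** Per hindlimb, the times of full flexion define the cycle
(flexion-to-flexion; configurable). Left-right coordination reuses the same
phase estimator as the root-pair analysis — literally the same function, so
the two code paths cannot drift apart. A cycle is a missed alternation when
its phase falls outside the symmetric half-cycle window [90°, 270°]; the
miss ratio divides the missed count by the mean cycle period. The window is
a declared operationalization of "failed alternation": any narrower window
would start scoring ordinary phase jitter as failure.

**Vestibulospinal reflex.** The paw-displacement measurement reproduces the
rotate-overlay procedure: the end frame is rotated 90° counterclockwise
about the image center (`(x, y) -> (-y, x)` in centered coordinates), an
optional manual alignment translation is applied, and the Euclidean distance
between start and end paw positions is returned. When no extension occurs
the end point is taken at 200 ms and the result is flagged.

## The synthetic-data generators

The generators in `simulate_ventral_roots()`, `simulate_positions()` and
`simulate_swim()` are phenomenological: they reproduce the statistical
structure the analyses assume, not the biophysics that produces it.

* **Ventral roots.** A reference onset train comes from either a
  fixed-period process or a two-state Markov process (slow/fast mean
  periods, per-cycle switching probability), with multiplicative period
  jitter (CV 0.05 by default). Channel onsets are shifted by per-channel
  phase offsets — defaults RL2 = 0°, LL2 = 180°, RL5 = 180°, LL5 = 0°,
  giving left-right and flexor-extensor alternation with diagonal
  synchrony. Bursts are rendered as 50-450 Hz band-limited noise carriers
  under a raised-cosine-edged gate of duration `duty x period` (duty 0.35),
  over Gaussian baseline noise (SNR about 10 at the defaults). The default
  simulation rate is 1 kHz — enough to carry the band-limited carrier —
  rather than full acquisition fidelity, keeping a four-root, ~60-cycle
  simulation around a quarter of a million samples per channel; rate and
  carrier band are configurable upward. Optional extra bursts are injected
  between locomotor bursts, preferentially into RL5 and at half that rate
  into LL5. The slow/fast mode periods used in the two-state examples
  (6.25 s and about 3.7 s, i.e. 0.16 and 0.27 Hz) and the single
  intermediate mode (0.22 Hz) are the canonical slow/fast/intermediate
  locomotor frequencies for this preparation.
* **Somata.** (ML, DV) pairs are drawn from a two-component Gaussian
  mixture truncated to the unit square: a major central cluster (mean
  (0.50, 0.35), weight 0.75) and a minor medial cluster (mean (0.15, 0.40),
  weight 0.25), SD 0.08 — invented fixture values chosen to look like a
  ventral interneuron population, not measurements. Raw `(d, alpha, H, W)`
  records are produced by inverting the normalization for section sizes
  drawn uniformly from plausible neonatal ranges (H 380-480 µm, W
  280-380 µm), so normalization round-trips to machine precision.
* **Swimming.** Left-limb flexions follow the configured period (0.5 s
  default, CV 0.05); the right limb is antiphase except during lapse runs
  (entered per cycle with `lapse_prob`, geometric run length) where it
  moves nearly in phase. Per-cycle phase jitter is 10° SD — far enough from
  both the 90° and 270° window edges that ground-truth lapse labels and
  detected misses agree exactly.

Every generator is fully reproducible from the config seed and restores the
caller's RNG state. Ground truth (onsets, regimes, cluster labels, lapse
labels) is always returned, so each downstream metric can be checked
against the generating process rather than against another estimate.

What the generators do *not* emulate — and therefore what passing tests do
not certify about real data: slow electrode drift and movement artifacts,
burst-amplitude asymmetries between roots, within-burst unit structure,
deleted or split bursts from failing preparations, optical distortion in
section measurements, and tracking error in behavioral coordinates. The
analyses are designed to be robust to mild versions of these (robust
thresholds, skipped-cycle accounting, clamping) but the simulations make no
claim to reproduce them.

## Numerical choices and degenerate inputs

* Envelopes are clamped at zero after smoothing to absorb FIR roundoff.
* A flat envelope yields an empty burst train plus a warning, not an error;
  downstream pair statistics then report empty samples.
* Circular means are flagged undefined when the resultant length falls
  below 1e-8 (e.g. perfectly balanced 0°/180° samples).
* The Rayleigh p is clamped to [0, 1]; the series approximation can
  overshoot marginally at extreme concentrations.
* The pooled covariance in Hotelling's T² must be nonsingular; collinear
  inputs raise an error suggesting jitter or an exact test rather than
  returning a misleading p.
* Lag-domain quantities (correlograms) are computed with one FFT
  cross-product plus prefix sums; agreement with the direct per-lag loop is
  at machine precision and is tested.
* Problem sizes in the test suite are chosen to exercise each property at
  the smallest scale where the property is meaningful: e.g. 60-cycle
  recordings for phase recovery, 600 s of regime-switching rhythm for mode
  structure, 2000 replicates for the T² calibration.

## Known limitations

* The burst detector uses a single global threshold per record; it does not
  track slow amplitude drift within a recording. Analyze the stable portion
  of a recording (the `window` argument of `analyze_fl()`).
* The CCC index depends on the cycle-period estimate used for its window;
  an arrhythmic reference channel makes that estimate noisy. The estimate
  and the full correlogram are both reported so this is auditable.
* KS p-values are asymptotic; at very small pooled samples prefer exact
  tests.
* The Hotelling test assumes a common covariance across groups; with
  strongly different cluster structures interpret T² as a location contrast
  only.
* `analyze_swim()` compares groups with rank-based tests on per-animal
  summaries; it does not model within-animal bout correlation.
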
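---
title: "Detecting atrial fibrillation in short single-lead ECG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting atrial fibrillation in short single-lead ECG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afusion)
```

## The problem

Wearable and handheld ECG devices produce short (9–61 s), single-lead
recordings with low signal-to-noise ratio. A screening pipeline must decide,
per recording, between four classes: normal sinus rhythm (N), atrial
fibrillation (A), some other rhythm (O), and recordings too noisy to
interpret (~). AF is recognizable by two hallmarks — irregular RR intervals
and absent P waves — but both are also mimicked by noise, which is why the
noisy class must be modelled explicitly rather than discarded.

`afusion` implements a fusion pipeline: recordings are unified to exactly
30-s segments, 24 *artificial* (formula-defined) features and 38 *abstract*
(CNN-learned) features are extracted per segment, concatenated into a 62-dim
vector $[R_1 \ldots R_{24}, S_1 \ldots S_{38}]^\top$, and classified with a
300-tree random forest. Scoring follows the CinC-2017 convention: per-class
$F_1 = 2 \cdot \mathit{Nn} / (\Sigma N + \Sigma n)$ from reference and
predicted totals, with the headline macro $F_1$ averaged over N, A and O
only.

## Segment unification

Recordings longer than 30 s are cropped at a seeded uniformly random offset
(drawn once, not per epoch). Shorter recordings are tiled: QRS complexes are
located with the Pan–Tompkins detector, the span from the first QRS onset to
the last QRS onset is excised and copied head-to-tail until 9000 samples are
reached. The final partial copy is a truncated head of the span by default.
A mirrored variant (`pad_mode = "mirror"`) exists, but mirroring reverses
waveform asymmetry (a mirrored PQRST is not physiological), so it is not the
default. The "QRS starting point" is defined operationally: walk backward
from the steepest pre-R upstroke sample until the derivative magnitude falls
below 10% of its window maximum inside a 60-ms window.

## Fiducial detection

*R peaks.* The classic Pan–Tompkins chain — band-pass 5–15 Hz, five-point
derivative, squaring, 150-ms moving-window integration, adaptive dual
thresholds with search-back, 200-ms refractory period. Filters are applied
forward–backward (zero phase), so no lag bookkeeping is needed and
integration peaks sit over their QRS complexes; detections are then refined
to the band-passed extremum and finally to the local extremum of the raw
trace. Every threshold is relative to signal statistics, making detection
invariant to positive amplitude rescaling. On noise-free synthetic normal
rhythm the median localization error is ≤ 1 sample.

*P onsets.* A dyadic à-trous wavelet transform with quadratic-spline-like
filters (lowpass $[1,3,3,1]/8$, highpass $[2,-2]$) is computed; the detail
signal at scale $2^4$ (at 300 Hz, sensitive to the 40–120 ms P deflection)
is searched in the window [QRS onset − 250 ms, onset − 50 ms]. A P wave is a
modulus-maxima pair of opposite sign; the onset is the sample left of the
first maximum where the modulus falls below half that maximum. The cascade's
group delay per scale is calibrated numerically on a symmetric bump and
compensated, so the pair midpoint sits at the deflection centre.

Two relative criteria make the pair test selective. The pair magnitude must
exceed 6× the segment's noise floor, estimated from the scale-$2^1$ detail
and transferred across scales through the cascade's white-noise gains — on
noise-dominated segments the floor rises and P detection correctly shuts
off. And the window peak must exceed 1.8× the window's median modulus: a
genuine P deflection is localized, whereas AF fibrillatory waves oscillate
across the entire window (a sinusoid's peak-to-median-modulus ratio is
$\approx 1.4$), so sustained 4–9 Hz activity is rejected. With the
generator's defaults this recovers ≈ 99% of true P onsets within ±30 ms on
normal rhythm while marking < 10% of AF beats. Both constants are exposed as
arguments (`k_noise`, `peak_ratio`).

Missing P waves are represented as absence (`NA` in the beat-aligned
vector), not as placeholder values; downstream PR statistics then apply the
degenerate policy below.

## The 24 artificial features

In reporting order: beat count and R-amplitude statistics
(`n_R, r_max, r_min, r_mean, r_median, S`), sample-series shape (`SK, KU`),
RR-interval statistics and heart rate
(`rr_max, rr_min, rr_mean, rr_median, rr_std, HR` with $HR = 60/\bar{RR}$,
RR in seconds), PR-interval statistics (`pr_*`), spectral moments
(`FC, MSF, RMSF, FV`) and the permutation ratio entropy (`PRE`).

Numerical conventions worth stating:

* **Mixed denominators, kept literally.** The standard deviation uses the
  population form $S = \sqrt{\sum_i (X_i - \bar X)^2 / N}$, while skewness
  and kurtosis divide third and fourth central moment sums by $(N-1)S^3$ and
  $(N-1)S^4$ (kurtosis minus 3). This mixed $N/(N-1)$ convention is retained
  deliberately rather than replaced by a textbook estimator; at segment
  lengths of 9000 samples the difference is negligible anyway.
* **Which series feeds which formula.** The feature `S` is the standard
  deviation of the detected R-peak *amplitudes* (it sits among the
  amplitude features); `SK` and `KU` are computed over the full sample
  series. Both choices are the defaults of `waveform_features()`.
* **All interval statistics use /N** for consistency with the above, and
  `HR` uses the mean RR in seconds, yielding beats per minute.
* **Spectral moments** treat the one-sided periodogram of the mean-removed
  segment as a distribution over frequency: centre of gravity FC, mean
  square MSF, $RMSF = \sqrt{MSF}$, and variance FV about FC. The identity
  $MSF = FV + FC^2$ holds algebraically and is enforced in tests at 1e-9
  relative tolerance. A single periodogram (no Welch averaging) is the
  default estimator; averaging is available but off.
* **Degenerate policy: 0 + flag, never NaN.** A segment with no detected
  beats, no P waves, or constant samples yields zeros with a named
  `degenerate` attribute, so the forest never sees non-finite inputs and
  "absence of physiology" remains encoded (always jointly with informative
  features such as `n_R = 0`).

### Permutation ratio entropy

Classical permutation entropy ranks samples within embedded windows and
discards amplitude differences between neighbours. The ratio-entropy variant
used here encodes, for each window of $m+1$ consecutive samples, the
*relations between adjacent elements*: the ternary sign of each of the $m$
adjacent differences, with a dead-band $\delta$ around zero ($\delta = 0$ by
default). The $n - m - 1$ encoded rows form a relation matrix; rows share a
pattern iff element-wise equal, and the entropy (in nats) of the pattern
multiplicities is returned. A constant or strictly monotone series has one
pattern and zero entropy; white noise populates many patterns. This makes
PRE a randomness detector that separates noise-dominated traces from
structured-but-irregular rhythms such as AF — the reason it is the one
nonlinear feature in the set.

The row count $n - m - 1$ (one fewer than the number of available windows)
follows the source description of the statistic literally. The encoding rule
sits behind a single argument so alternative quantizations are a one-line
change; $m = 3$ is the default order. Exactness is guarded by a test
comparing against a brute-force enumeration oracle on hundreds of short
random series.

## The CNN and the 38 abstract features

The 13-layer 1-D CNN: six (convolution, max-pool) pairs with kernel sizes
5, 5, 7, 7, 9, 11 and channel counts 4, 8, 16, 16, 32, 32 — convolution
stride 1 with no padding ($L \to L - k + 1$), pooling width 2 stride 2 with
floor division (forced by the printed odd-to-even transitions 741→370 and
77→38) — followed by a fully-connected layer to 38 units. A length-3000
input traverses temporal lengths 2996, 1498, 1494, 747, 741, 370, 364, 182,
174, 87, 77, 38. The 38 FC activations are the abstract features; a 4-way
softmax head is attached only during training and discarded afterwards.

A 30-s segment at 300 Hz has 9000 samples while the input layer expects
3000; the architecture table's arithmetic is the only bit-checkable
statement, so it is preserved literally and the segment is decimated by 3
(anti-alias low-pass, then subsampling — an effective 100 Hz, ample for the
5–15 Hz QRS band and P/T morphology) and z-normalized per segment.

Training details left open by the architecture are fixed as: ReLU after
each convolution, no batch normalization, Adam at 1e-3, batch 32,
cross-entropy through the softmax head, all randomness seeded. The network
is implemented natively in R — valid convolutions as im2col matrix
products, hand-derived backpropagation — which keeps the package dependency-
light and is fast enough for the desk scales used here (a few hundred
segments, tens of epochs, minutes on one CPU). An analytic-vs-numeric
gradient check on a truncated architecture guards the backward pass at 1e-4
relative tolerance.

## Fusion and the random forest

Fusion is plain ordered concatenation; no scaling, since trees are invariant
to monotone per-feature transforms (a property the tests assert). The forest
uses 300 trees, Gini splits, per-split feature subsampling with
$\lfloor\sqrt{62}\rfloor = 7$ candidates, depth cap 40, minimum split size
2, bootstrap resampling, and soft-vote averaging of per-tree class
fractions; ties go to the earlier class in (N, A, O, ~) order. The ensemble
is fitted by `ranger` behind the package's `train_forest()` surface. No
class weighting is applied by default.

## The synthetic generator: what it emulates, and what it does not

Each class renders PQRST morphology as Gaussian bumps (default widths: P
25 ms, QRS 12 ms, T 60 ms standard deviation) on a lognormal beat train:

* **N** — RR mean 0.8 s, CV 3%, P amplitude 0.15 mV, noise 0.02 mV.
* **A** — RR CV 25% (always more irregular than N), P amplitude 0,
  plus a 6 Hz, 0.05 mV sinusoidal fibrillatory baseline; RR mean 0.7 s.
* **O** — N-like with 20% premature beats (RR halved) and ±40 ms uniform
  PR-interval jitter, separable from N by interval features.
* **~** — white Gaussian noise at 0.8 mV (several times the RMS contribution
  of the QRS train, enough that beat detection fails on a large fraction of
  beats) plus a 0.3 Hz, 0.3 mV baseline-wander sinusoid, over an otherwise
  normal beat train.

Record durations are drawn uniformly from 9–61 s so that both the cropping
and the tiling branch of unification are exercised. Ground truth (R-peak,
QRS-onset and P-onset times) is recorded exactly, which is what makes every
detector testable without any external data.

These defaults produce *cleanly separated* classes: the canonical phenotypes
with modest within-class variability. Passing tests therefore demonstrate
that the machinery is correct and that the feature design separates the
canonical phenotypes — they do not demonstrate clinical-grade accuracy on
real Holter or handheld data, which contains borderline rhythms, electrode
artefacts, polarity inversions and pathologies the generator does not model.
End-to-end accuracies on synthetic data (near 1.0 at a few hundred
recordings) must be read in that light. The directional results — fusion
never hurting, entropy helping the noisy class — are the transferable
claims, and they match what the method reports on real challenge data.

## Problem sizes used in the checks

The test suite and acceptance script run entirely on synthetic data at desk
scale, chosen as the smallest sizes at which the properties are stable: the
end-to-end run uses 300 recordings (150/50/70/30 per class) with 10 CNN
epochs; the feature-scheme ablation uses 110 recordings per seed across 10
seeds with 5 epochs; detector quality checks aggregate 5–15 seeded
recordings per class. The entropy oracle comparison covers 200 random series
of length ≤ 50 at orders 2–4, exactly.

## Known limitations

* The P-onset delineator is re-specified rather than reproduced from the
  wavelet-delineation literature (window, scales, thresholds are this
  package's choices, config-exposed), because no parameter set is published
  for the method the pipeline calls for.
* QRS "onset" and P "onset" are operational definitions; absolute PR values
  carry a systematic offset of a few samples, which cancels in the
  statistics the classifier uses.
* Segment tiling duplicates beats; interval statistics on tiled segments
  include one artificial boundary interval per copy. This mirrors the
  method's own unification and is not corrected.
* The CNN trains at desk scale; its abstract features are deterministic
  given a seed but not expected to match any externally trained network
  weight-for-weight.
* Only 300 Hz single-lead input is exercised; other sampling rates are
  read and processed but not validated.
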
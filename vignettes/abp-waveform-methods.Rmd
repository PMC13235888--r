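---
title: "Methods: synthetic ABP cohorts, waveform imaging, and notch-centered features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic ABP cohorts, waveform imaging, and notch-centered features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abpwave)
```

## Scope and rationale

`abpwave` implements an end-to-end analysis of continuous arterial blood
pressure (ABP) waveforms for a binary patient-level outcome: pulse
segmentation, construction of normalized multi-pulse instances, five
signal-to-image encodings, a convolutional classifier with patient-level
evaluation and Grad-CAM saliency, instance-to-patient aggregation, and a
dicrotic-notch-centered derivative-feature battery with two-group
statistics. The clinical recordings that motivated this design are not
publicly available, so the package is organized around a synthetic
cohort generator whose records carry ground-truth beat landmarks. Every
downstream stage can therefore be validated against a known answer —
which is exactly what the test suite does.

## The beat model

A single pulse is an additive model over a beat of period $T$:

$$p(t) = b + A_s e^{-(t-t_s)^2/2w_s^2} + A_d e^{-(t-t_d)^2/2w_d^2}
       + \tfrac{1}{2}A_s\, r(t),$$

where the runoff term $r(t)$ ramps linearly from 0 at beat onset to 1 at
the systolic bump center $t_s$ and decays as
$\exp(-(t-t_s)/\tau)$ afterwards. The two Gaussian bumps create the
systolic peak and the dicrotic (reflected) wave; the local minimum
between them is the dicrotic notch, and the local maximum after it the
diastolic peak. The exponential term models diastolic runoff — the drain
of arterial pressure into the periphery — and its time constant $\tau$
(`runoff_tau`) is the generator's principal group-difference dial:
a shorter $\tau$ gives a steeper diastolic decay.

Defaults are conventional rather than fitted: baseline 70 mmHg, systolic
amplitude 40 mmHg (peak pressures ≈ 130 mmHg), systolic center at 13% of
the beat, dicrotic center at 42%, heart period 0.8 s at 100 Hz sampling.
`runoff_tau` defaults to 1.0 s for the non-event group — in the range of
arterial Windkessel time constants — and 0.7 s (30% shorter) for the
event group, which also receives a slightly smaller dicrotic bump
(8 vs 10 mmHg). The 0.691 event prevalence mirrors the class imbalance
typical of this surgical population (125 events among 181 patients).
Records add
sinusoidal baseline drift (default 3 mmHg at 0.1 Hz, always below the
0.5 Hz detrending cutoff), beat-period jitter (CV 4%), per-patient shape
variability (CV 5% per field), and white measurement noise (1 mmHg SD).

Two numerical details matter. Consecutive beats are joined with a
5-sample linear cross-fade so concatenation cannot create spurious local
extrema; the first beat is faded against its own tail, which makes a
zero-variability record exactly periodic (a property the tests exploit).
And one master seed drives per-patient sub-seeds through stable integer
mixing, so a patient's trace does not depend on cohort membership order.

What the generator does **not** emulate: reflected-wave physiology
beyond a single fixed bump, respiratory modulation, arrhythmia or
ectopy, transducer artifacts other than white noise and slow drift, and
any pressure–flow coupling (no Windkessel ODE is solved). Passing tests
on these cohorts therefore demonstrate that the pipeline's machinery is
correct and sensitive to diastolic-decay differences of the modeled
kind — not that the classifier would attain any particular performance
on clinical data.

## Preprocessing choices

*Detrending* is a zero-phase 2nd-order Butterworth high-pass at 0.5 Hz
(applied forward–backward, with mean subtraction and reflection padding
to suppress edge transients). The stated purpose of the filter in this
kind of pipeline is removal of sub-pulse-rate drift, so a high-pass —
rather than a band-pass with an arbitrary upper edge — realizes it.

*Segmentation* runs two independent detectors. The rule-based detector
finds local maxima subject to a 0.3 s minimum distance and a prominence
floor of 20% of the rolling 2-s amplitude range, takes the onset as the
minimum of the 30 samples preceding each peak, and the offset as the
following trough. The alternative detector thresholds the first
difference at 40% of its rolling maximum to find systolic upstrokes and
anchors onset/peak/offset around them. Both smooth with a 50 ms
zero-lag moving average before detection; at the default 1 mmHg noise
this step is what keeps spurious local maxima out of the peak set.
Detections are reconciled by matching peaks within 0.05 s (5 samples at
100 Hz); matched beats keep the rule-based indices, unmatched beats are
dropped and counted. Tolerance and precedence are package choices — in
clinical workflows such discrepancies are resolved by visual inspection,
which an automated pipeline must replace with a fixed policy.

*Clean-segment selection* replaces visual inspection with three rules:
no flatline (range < 1 mmHg over any 2 s window), absolute pressure
within 20–250 mmHg, detected beat rate within 40–220 /min, and a
10-minute minimum length by default.

*Instances* group 3 consecutive pulses (onset of the first to offset of
the last), resample to 300 points and min-max scale to [0, 1]. Scaling
is applied after resampling so stored instances attain 0 and 1 exactly.
Instances are non-overlapping by default (stride = pulses per
instance); overlap is configurable.

## Image encodings

Standard definitions are used: GASF as $\cos(\phi_i+\phi_j)$ over
angular coordinates $\phi=\arccos(2x-1)$; MTF as quantile-bin
first-order transition probabilities (8 bins by default, empty rows set
uniform); RP as the thresholded pairwise distance matrix (threshold 10%
of the maximum distance, or unthresholded); SPEC as a Hann-window STFT
magnitude (window 64, hop 16); DRP as a deterministic, axis-free
rasterization of the polyline onto a square monochrome grid. All
encoders are pure functions, and the tests hold GASF/MTF/RP to exact
(< 1e−12) agreement with brute-force constructions. DRP rasters are
rendered at 64 px for classifier work in this package — large enough to
resolve the pulse geometry, small enough for CPU training.

## Classifier

No deep-learning framework is assumed: the classifier is a compact CNN
written in vectorised base R. Convolutions are 3×3 im2col matrix
products with precomputed gather indices; the architecture is
conv(8)–pool–conv(16)–pool–conv(16)–GAP–logistic. "Penultimate
convolutional layer" refers to the second block, the stage before the
final one. Training follows the protocol this pipeline models —
Adam at learning rate 0.001, early stopping on validation loss with
patience 10 and best-epoch restoration, class weights inverse to class
frequency, optional horizontal-flip/rotation/jitter augmentation — and
package defaults elsewhere (batch 32, He initialization, max 50
epochs). Splits are stratified at the patient level (70/15/15 by
largest-remainder rounding, five repeats under derived sub-seeds), and
an explicit leakage check asserts that no patient appears in two sets.
Deeper published architectures (ResNet/DenseNet/VGG variants) are out
of scope: the protocol, not the backbone, is what this package
verifies. Grad-CAM follows the standard recipe — spatial means of the
class-score gradient as channel weights, rectified weighted activation
sum, bilinear upsampling, max normalization — using the predicted
class's logit by default.

## Aggregation, evaluation, baselines

Patient scores are the mean of the first $m$ instance probabilities
(default), the fraction above 0.5 (majority voting), or the mean of the
top-$k$ (default $k=5$) — the latter implementing multiple-instance
top-k pooling at inference time; a trained MIL objective is
deliberately not claimed. AUROC uses the rank (Mann–Whitney)
formulation with ties counted one half; it is tested against an
all-pairs brute force for exact equality. Calibration uses 10
equal-width bins with the Brier score as summary. The classical
baselines fit logistic regression, random forest, SVM and k-NN on the
63-feature battery at pulse level with selection (RFE on standardized
logistic coefficients, F-value ranking, or quantile-binned mutual
information) fit on training patients only. Model-to-model AUROC
comparison is a paired patient bootstrap — a generic surrogate, since
the original test is unspecified.

## Notch-centered features

Each pulse is normalized by min-max over its peak-to-offset segment
(pre-peak samples may leave [0, 1]) and split at the dicrotic notch
(DN) and diastolic peak (DP). The DN is the first local minimum after
the peak on a lightly smoothed copy; when no interior minimum exists
the maximum of the second derivative between peak and offset serves as
fallback (DP = DN, method recorded), and a decay with flat curvature is
flagged and excluded. Derivatives use central differences with
second-order one-sided ends — exact for polynomials to degree 2 — and
features are computed on the *raw* (Savitzky–Golay denoised, order 3,
window 9) pressure pulses rather than the detrended signal, because
high-passing at 0.5 Hz strips precisely the slow diastolic-runoff
component the features quantify. The "area" statistic is the
trapezoidal integral of the (derivative-order) series over the segment.
Outliers are removed per feature and group by the 1.5·IQR rule with
linear-interpolation quartiles; groups are compared with Student's
t-test when both pass Shapiro–Wilk normality (p ≥ 0.05) and the
Mann–Whitney U-test otherwise, two-sided, deliberately without
multiplicity correction, treating each feature as its own pre-specified
hypothesis (a correction option exists). The point-by-point comparison averages pulses within
patient first — avoiding pseudo-replication across a patient's beats —
then applies the same gated test at each of 300 aligned positions.

## What separates, and what does not

Under the default group gap (30% shorter event `runoff_tau`), the
normalized first-derivative features behave exactly as the design
intends: the peak→DN mean slope and the DN→DP and DP→offset minimum
slopes differ strongly and with a stable sign (higher in the
steeper-runoff group, because per-pulse normalization by the
peak-to-offset range rescales the earlier, steeper decay). The
second-derivative *area* features do not separate reliably on these
cohorts, and the reason is structural: the trapezoidal area of the
second derivative over a segment telescopes to the difference of first
derivatives at the segment's endpoints, and both endpoints of the
peak→DN segment (a true local maximum and a true local minimum in this
beat model) have near-zero slope by construction. What remains is
dominated by sub-sample peak-phase effects and notch-detection jitter,
which are symmetric across groups. On clinical pulses — where the notch
is often a deceleration shoulder rather than a clean minimum — the
endpoint slopes need not vanish, which plausibly explains why such a
feature can be informative on real data while being near-null on these
idealized cohorts. The package reports the feature faithfully and the
tests document the discrepancy rather than masking it.

A related caveat applies to saliency localization. When only the
diastolic decay differs between groups, the pixel-level evidence in
min-max-normalized DRP images concentrates near the pulse onset and
upstroke: rescaling by the peak-to-trough range converts a steeper
diastolic decay into a shifted rendering of the *early* pulse, and the
classifier attends wherever the evidence is easiest. Grad-CAM maps on
these synthetic cohorts therefore need not concentrate over the
diastolic third of the image even though diastole is the generative
source of the difference — an instructive divergence from the
real-data observation that motivated the visualization.

## Problem sizes and tolerances

The suite and the acceptance script favor sizes that exercise every
code path at desk scale: 60-second records (≈75 beats) for feature
work, 120-patient cohorts for the 20-seed parameter-recovery sweep,
30-patient cohorts at 64 px DRP with a (8, 16, 16)-channel CNN and 25
epochs for learnability runs, and a 181-patient, 3-second cohort where
only composition arithmetic matters. Exact-arithmetic oracles (encoder
constructions, rank AUROC, aggregation) are held to identical or
< 1e−12 agreement; detection against generator truth to ±2–3 samples;
stochastic end-points (power sweeps, CNN AUROC, null behavior) to the
bands stated in the tests.

## Known limitations

Beyond the generator's scope (above): the CNN is intentionally small
and CPU-bound; no pretrained weights or GPU-scale searches are
provided. Landmark detection assumes a single systolic peak per beat.
The 30-sample onset window follows the 100 Hz convention and is kept as
a sample count (the sampling rate is recorded alongside), since whether
it should scale with rate is deliberately left configurable.
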
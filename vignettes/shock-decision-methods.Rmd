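---
title: "Shock-decision methods: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shock-decision methods: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfdetect)
```

## The problem

An automated external defibrillator (AED) must decide, from a few seconds of
single-channel ECG, whether the rhythm is *shockable* — ventricular
fibrillation (VF), pulseless ventricular tachycardia (VT), or ventricular
flutter — or *nonshockable*. The American Heart Association sets the minimum
bar at 90% sensitivity for shockable rhythms and 95% specificity for
nonshockable arrhythmia. `vfdetect` implements a complete experimental
pipeline for this decision: signal conditioning, rhythm segmentation with
clinical exclusion rules, a mixed convolutional/recurrent classifier with
CNN-only and SVM baselines, and the statistics used to compare them — all
exercisable on synthetic cohorts so the full pipeline runs on a laptop with
no data downloads.

## Signal conditioning

Records are resampled to 250 Hz (polyphase rational resampling with a
linear-phase FIR anti-alias filter cut at 0.45 of the lower Nyquist rate)
and conditioned by the typical AED monitoring chain:

1. mean subtraction,
2. a 5-point (20 ms) moving average with reflect padding, and
3. a 1–30 Hz 4th-order Butterworth bandpass applied forward–backward, so
   ECG morphology is not phase-distorted.

The moving-average order, the Butterworth order, and zero-phase operation
are exposed in `preprocess_config()`; the literature that motivates the
chain specifies only the 1–30 Hz band, so these are deliberate, documented
defaults rather than reproductions. Two numerical details matter. The
bandpass is applied over a reflect-padded copy of the record to suppress
start-up transients at the edges. And because a bandpass annihilates the
asymptotic DC response but not the finite-sample mean of a noisy record,
the chain subtracts the residual mean after filtering — the conditioning
contract is a strictly zero-DC output.

## Segmentation and labeling

Segments of `L` seconds (2, 3, 4 and 8 by default) tile each annotated
rhythm interval *from the interval's start*; the tail shorter than `L` is
dropped. Tiling per interval, rather than per record, guarantees every
emitted segment carries a unique rhythm label; windows overlapping noise or
saturation intervals are discarded. The binary mapping is: VF, VT and
ventricular flutter are shockable; organized rhythms (sinus, SVT, AF,
blocks, ectopy, pulsed rhythms, PEA) are nonshockable; asystole, fine VF,
slow VT, noise and saturation are excluded from the decision entirely.

The borderline-rhythm rules are applied with strict inequalities: any
rhythm with rate under 12 bpm or peak-to-peak amplitude under 100 µV is
asystole (this rule takes precedence); VF with peak amplitude
(`max|x − median(x)|`) under 200 µV is fine VF; VT under 150 bpm is slow
VT. Rate is estimated by local-maxima detection with an adaptive threshold
of half the peak amplitude and a 200 ms refractory period; it is used only
for synthetic or self-measured data, since real records carry expert
annotations.

## The classifier

The proposed network stacks two convolutional sub-blocks (each J = 32
filters of width M = 3, ReLU, followed by non-overlapping max-pooling of
size K = 7), an LSTM with Q = 20 output features, and a single sigmoid
unit producing `p_Sh`, the shock likelihood. The temporal length after each
stage follows `floor((N + 2p − M)/s) + 1` with no padding; for an 8-s
segment at 250 Hz the chain is 2000 → 1998 → 285 → 283 → 40, so the LSTM
consumes a 40-step sequence of 32-dimensional feature vectors (9, 14 and 20
steps for 2, 3 and 4-s segments).

Training minimizes the class-weighted binary cross-entropy. Each instance
of class *k* is weighted `n/(2 n_k)`, so both classes carry equal total
weight under the roughly 4:1 nonshockable:shockable imbalance. The
optimizer is stochastic gradient descent with Nesterov momentum 0.9,
learning rate 1e-3 decayed per update as `lr/(1 + 1e-6 t)`, 600 epochs in
batches of 256 at full scale. Probabilities are clipped to
`[1e-7, 1 − 1e-7]` inside the loss. After training, the decision threshold
θ is the value maximizing balanced accuracy on the *training* predictions
(candidates are midpoints between consecutive sorted unique probabilities
plus 0 and 1, ties resolved to the smallest θ); the decision is shock iff
`p_Sh ≥ θ`, deliberately failing toward sensitivity on ties.

Choices the architecture description leaves open, resolved here once:

* **Initialization** — fan-in-scaled uniform weights for convolutional and
  dense layers, orthogonal LSTM recurrence matrices, zero biases except the
  LSTM forget gate (1). All seed-controlled; identical seeds give
  bit-identical models.
* **Dense head** — a single sigmoid unit on the final LSTM hidden state
  `h_{N4}`; no hidden layer, since none is specified. Only the last hidden
  state feeds the head.
* **Gradient scaling** — batch updates use the weight-scaled mean gradient
  (the exposed loss is the weighted sum; a constant factor only rescales
  the learning rate).
* **CNN-only baselines** — the three published comparison architectures are
  reproduced from their layer tables (filters/kernels/pools); activations
  (ReLU), stride (1), padding (none) and the hidden dense width (32, where
  two dense layers are listed) are not specified there and are fixed here.

The whole network — forward passes and backpropagation through the dense
head, the LSTM (backpropagation through time), max-pooling and the
convolutions — is implemented in vectorized base R. Every forward primitive
is verified in the test suite against naive nested-loop oracles to 1e-10.

## SVM baselines

The classical baseline computes a registry of nine classical VF-detection
features per segment (mean absolute slope, dominant frequency, spectral
flatness, 0.5–9/9–30 Hz band-power ratio, threshold-crossing rate,
peak-to-peak amplitude, excess kurtosis, sample entropy, mean absolute
value) and fits a Gaussian-kernel SVM. The soft-margin dual is solved by
libsvm (via `e1071`); the package stores the support-vector expansion
explicitly and its test suite re-evaluates the decision function by direct
summation, checks the box constraints `0 ≤ α_i ≤ C·w_class`, and checks
`Σ α_i y_i = 0`. Feature standardization constants come from training data
only. The registry is a documented, versioned stand-in for the larger
feature sets of the classical literature — exact parity with any particular
published 30-feature set is out of scope; sample entropy is computed on the
segment decimated to at most 500 samples to keep the quadratic template
count affordable.

Hyperparameters are searched by Gaussian-process Bayesian optimization
(expected improvement, log-uniform over `10^-3 ≤ C, γ ≤ 2·10^2`, Latin
hypercube initial design, 60 evaluations by default) with patient-grouped
5-fold cross-validated balanced accuracy as the objective; the fold scheme
and objective are this package's choices, since only the search box is
prescribed by the source material. Class imbalance scales the box
constraint per class. Optionally, at most 0.5% of training instances are
discarded as outliers: one screening fit, then the instances with the
largest margin violations `ξ_i = max(0, 1 − y_i f(x_i))` are dropped
(one-shot, not iterative — a config switch, since either reading is
defensible).

The learned-feature experiment feeds the trained LSTM's 20 features to the
same SVM machinery. The best `k`-feature subset is chosen on training data
with a linear discriminant criterion by greedy forward selection —
exhaustive best-subset search over 2^20 subsets is computationally
pointless at desk scale, and greedy selection preserves the experiment's
intent (how few learned features suffice).

## Evaluation statistics

Balanced accuracy `BAC = (Se + Sp)/2` is the ranking criterion, as it is
insensitive to the 4:1 class imbalance. Classifiers are compared pairwise
with the McNemar test on discordant decisions: an exact one-sided binomial
tail for fewer than 25 discordant pairs, a continuity-corrected chi-square
(halved) otherwise. The conventional one-sided test of "B better than A" is
implemented; feature AUCs are rank-based (Mann–Whitney, ties averaged).

Separability of learned versus classical features is measured by embedding
each feature matrix to 2-D with t-SNE and computing the Davies–Bouldin
index of the two classes over paired bootstrap resamples (1000 by default);
the comparison p-value is the fraction of replicas where the learned
features' index is not lower. The t-SNE here is an exact-gradient
implementation (perplexity 30, 1000 iterations, early exaggeration,
adaptive gains, seed-controlled): at the cohort sizes this package targets
(hundreds of instances) the exact O(n²) gradient is affordable, so no
tree-based approximation is used.

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes, not
clinical truth. Each synthetic patient record is a sequence of 10–14 s
rhythm intervals drawn from a mix calibrated so that usable segments show a
4:1 nonshockable:shockable imbalance, with a small share (5%) of
borderline rhythms — fine VF, slow VT, asystole — that the exclusion rules
must catch, and occasional broadband noise intervals. Organized rhythms are
Gaussian-bump PQRST trains (rate, amplitude and RR jitter varied per
interval); VF is an amplitude- and frequency-modulated oscillation whose
instantaneous frequency random-walks around 4–6.5 Hz. An OHCA-like mode
lowers VF amplitude and frequency and widens QRS complexes, mimicking the
harder rhythms seen minutes after collapse; an optional 1.031 µV/LSB
quantization emulates defibrillation-pad acquisition. All randomness flows
from one cohort seed through per-record derived seeds.

What passing tests on this cohort do **not** show: robustness to CPR
artifact, electrode motion, real morphological diversity, or the
public-database/OHCA performance gap. The generator's role is to verify the
pipeline's mechanics and learning dynamics end to end, not to certify
clinical accuracy.

## Desk-scale study sizes

The default experiment profile (`experiment_config()`) trains for 50 epochs
in batches of 32 on a 20-patient, 120 s/record synthetic cohort (about 500
four-second segments), which the end-to-end test requires to reach held-out
balanced accuracy ≥ 0.95. The full-scale recipe (600 epochs, batches of
256) remains the `train_control()` default for real-data runs. Unit tests
use smaller cohorts still; all sizes are stated in the tests themselves.

## Known limitations

* The WFDB reader covers the dialect needed here: formats 212 and 16,
  first channel only, rhythm-change annotations with standard aux strings.
* Training is single-threaded R; full-scale 600-epoch training on the real
  databases is out of scope.
* The original studies' random patient partition cannot be reproduced (no
  published seed), so real-data results can only be matched in
  distribution, never segment for segment.
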
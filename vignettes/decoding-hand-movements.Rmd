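---
title: "Decoding sequential finger-grip movements: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding sequential finger-grip movements: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gripdecode classifies trials of an exoskeleton data glove — 15 flexion
channels (joints J1–J3 of digits D1–D5) sampled at 100 Hz — into six
movement tasks, each a sequence of four thumb-opposition grips performed
with the index through little finger. This vignette explains the models
and the design decisions behind them; the README shows the worked
end-to-end example.

## The decoding problem

A trial is a time-by-channel matrix of angular sensor values whose length
varies across repetitions, subjects and age groups. Two decoders are
provided:

* **DTW + one-vs-rest linear SVM** (`cv_spec(classifier = "svm_dtw")`):
  trials are warp-resampled to a data-driven template so that every trial
  occupies a fixed-length feature space, then classified with six binary
  linear SVMs.
* **Stacked bidirectional LSTM** (`classifier = "lstm"`): a recurrent
  network consumes the variable-length velocity series directly. A third
  mode, `lstm_dtw`, feeds the DTW-aligned trials to the same network.

## Preprocessing

Raw device angles depend on hand geometry and on how the exoskeleton is
mounted, so each channel is first mapped affinely so that its calibration
minimum (flat hand) becomes 0 and its maximum (fist) becomes 1. Values
beyond the calibration range pass through the same map and may leave
[0, 1]. The pipeline is then: centered moving average (100 ms window,
shrinking at the edges so length is preserved), forward-difference
temporal derivative scaled to units of s⁻¹, and linear-interpolation
downsampling to 16 Hz. Working on angular *velocity* rather than posture
removes most residual dependence on hand geometry: applying any per-subject
affine gain to the raw data and its calibration leaves the preprocessed
output bit-identical, a property the test suite asserts.

Two orderings are defensible for the derivative relative to smoothing and
downsampling; we smooth first (to keep difference noise down) and
downsample last (to preserve derivative fidelity). The resampler uses
linear interpolation rather than a polyphase decimator because the signals
are already band-limited far below the 8 Hz output Nyquist by the moving
average and by the movements themselves. An even moving-average window `w`
spans `[i - w/2, i + w/2 - 1]`.

## DTW alignment and template selection

Trials are aligned with multivariate (dependent) dynamic time warping:
the cumulative cost is the sum of *Euclidean* (not squared) distances
between 15-dimensional samples, with steps {(1,0), (0,1), (1,1)} and fixed
endpoints. Ties in the traceback prefer the diagonal, so paths are
deterministic.

The template is chosen from the training trials only. With `n` training
trials, pairs `(i, i + floor(n/2))` for `i = 1 … floor(n/2) − 1` are
aligned — a deliberately small subset of all pairs that is sufficient to
find a trial that is not an outlier. Each pairing gets a score
`s_i = rho_i (1 − d_i)`, where `d_i` is the pair's DTW distance normalized
so the largest pairing distance equals 1, and `rho_i` is the Pearson
correlation between the two path-expanded series flattened across channels
(a per-channel mean correlation is a documented alternative; the flattened
form gives a single well-defined scalar). The first trial of the
best-scoring pair becomes the template; ties break to the lowest pairing
index, and if every pairing distance is zero the distances are all set to
zero so the scores reduce to the correlations.

Every trial is then warp-resampled to the template length: all trial
samples that the optimal path maps to one template index are averaged, and
a template-index stretch against a single trial sample replicates that
sample. The result always has exactly the template's length — the
fixed-size feature contract the SVM requires — and warping a trial to
itself is the identity. Choosing the template per training fold (rather
than once globally) is the strict no-leakage reading; the provenance of
every fold's template is recorded and asserted in the tests.

## The SVM

Each class is separated from the rest by a soft-margin linear SVM on the
flattened aligned trials; prediction takes the class with the largest
decision value (ties break by the fixed class order). No parameter search
is performed: the box constraint defaults to the SVM-light heuristic
`C = n / Σᵢ xᵢ·xᵢ`, the reciprocal mean squared feature norm. No feature
scaling is applied. The binary problems are solved by libsvm (through
e1071) at tolerance 1e-6; being convex, the fits are deterministic up to
that tolerance. Scaling all features by `a` scales the default `C` by
`a⁻²` and leaves the decision signs unchanged.

## The LSTM

The sequence classifier is two stacked bidirectional LSTM layers — 100
hidden units per direction by default, configurable — each followed by
layer normalization and a ReLU block. The encoder output concatenates the
final forward and backward hidden states of the second layer; a 30-unit
rectified hidden layer and a 6-unit softmax head produce class
probabilities, and the label is their argmax. Training uses cross-entropy
loss and Adam (learning rate 0.001) for a fixed 64 epochs with mini-batches
of 16 — no early stopping, no dropout, no gradient clipping. Ragged
batches are formed by sorting trials by length, right-padding, and
masking; hidden and cell states hold their previous value at padded steps,
so a trial's prediction is identical whether it is padded inside a batch
or presented alone (asserted to 1e-5 in the tests).

The network is implemented in base R matrix code within the package, with
analytic backpropagation through the LSTM cells, the layer norms and the
dense head; the gradients are verified against central finite differences
to 1e-7 in the test suite. An optional `lstm_grid_search()` utility scans
epochs, batch size and hidden width but is never run by default; the
recipe above is fixed.

## Cross-validation and metrics

* `loro` (within-subject): folds are subject-run pairs; the classifier is
  trained on a subject's remaining runs.
* `loso` (across-subject): one fold per left-out subject.
* `two_fold`: subjects are split in half by one of three rules — `matched`
  (within each age group, sort by hand size and alternate fold
  assignment; requires even group sizes), `hand_size` (smaller half vs
  larger half at the median), `age` (young vs old).

Decoding accuracy (DA) is the percentage of correctly labeled test trials;
per-class sensitivity is the per-task recall; standard errors are computed
across per-subject DAs. `sensitivity_table()` assembles per-class
sensitivities across analyses; `compare_conditions()` applies a two-sided
Wilcoxon signed-rank test to paired per-subject DAs (exact null for
n ≤ 25 without ties or zeros, normal approximation otherwise) with a
caller-supplied Bonferroni family size, since the family is an analysis
choice, not a property of one comparison.

## Permutation chance level

`permutation_test()` shuffles the task labels over all trials (preserving
class counts), reruns the entire cross-validation, and records the DA;
the 2.5th/97.5th percentiles of the resulting distribution form the 95%
CI and the upper bound is the significance threshold. For the SVM+DTW
pipeline, template selection, alignment and the default box constraint
depend only on the signals — never the labels — so they are computed once
per fold and reused across permutations, and each fold's feature matrix is
replaced by an exact Gram factor `G` with `G Gᵀ = F Fᵀ` before the
per-permutation refits. Both steps are mathematically identical to
rerunning the full pipeline (template re-selection under permuted labels
returns the same template) and make 300 permutations a minutes-scale
computation on one CPU.

A finite-sample caveat that matters when reading chance levels: under a
*global* label shuffle, a fold's permuted training labels are slightly
anti-correlated with its held-out labels (what is over-represented in
training is under-represented in the test fold), so the permutation mean
falls slightly *below* the theoretical 1/6 at small trial counts. On the
240-trial benchmark design used in the acceptance script the mean sits
near 15.8%; a label-blind classifier in the same harness gives exactly
16.67%, confirming the offset is a property of the procedure, not the
implementation. The bias shrinks roughly as 1/n and is negligible at
full-study scale (thousands of trials).

## The synthetic simulator

`generate_dataset()` emulates the study structure so that every stage is
testable without hardware: per subject, `runs` runs of six blocks of
`trials_per_block` repetitions, block *k* carrying task *k* in the fixed
order clothes-peg, fingertip touching, cube cw/ccw, small cube cw/ccw.
Each grip is a raised-cosine flexion–extension pulse (smooth and
band-limited, like natural movement) on the channels that the task
recruits; the four grips run in fixed D2→D5 order with short gaps.

Tasks differ in the *direction* of their channel-activation pattern —
thumb/finger balance, co-activation of the non-gripping fingers, proximal
vs distal joint emphasis, and the amplitude profile across the four
grips — not merely in overall scale, because a subject's tempo rescales
all velocity magnitudes and would wash out purely scalar differences in
across-subject decoding. The cw/ccw variants of each cube share one
pattern and differ only in a small waveform asymmetry (pulse peak at 0.42
vs 0.58 of the grip for the large cube, 0.45 vs 0.55 for the small one),
making them the deliberately hardest pairs. Setting
`equalize_classes = TRUE` gives all six tasks one pattern, which removes
class information entirely and drives every decoder to chance — the
negative control used in the tests.

Subject idiosyncrasy: hand size is drawn uniformly per group (16–22 cm),
full-flexion amplitude is proportional to hand size (2 device units per
cm), resting offsets are montage-like uniform draws, and per-subject tempo
varies by 5% with an extra ×1.2 slowdown and larger per-grip amplitude
jitter (8% vs 3%) in the old group, reflecting slower and less precise
movements in older adults; these magnitudes are simulator choices, not
measured values. Trial durations jitter with a CV of 0.1 around the 8 s
base (2 s per grip), and Gaussian sensor noise with sd equal to 2% of the
subject's amplitude is added. Calibration records the noise-free envelope:
minimum = resting offset, maximum = offset + amplitude. All draws flow
from one seeded Mersenne-Twister generator, so datasets are reproducible
across platforms given the seed.

What the simulator does *not* model: biomechanical coupling between
joints, the abduction sensors and IMU, sensor drift or dropouts, and any
measured kinematic distributions — its magnitudes are plausible, not
fitted. Passing tests on synthetic data therefore demonstrate that the
pipeline recovers structure *of the kind the study describes*, not
performance on real gloves.

## Numerical choices and degenerate inputs

* DTW traceback tie-break: diagonal, then the step consuming a trial
  sample; paths are unique and deterministic.
* Template score with all-zero pairing distances: distances set to 0,
  scores = correlations; all-constant trials are an error (undefined
  correlation).
* SVM decision ties: fixed class order. Single-class training folds warn
  and predict the majority class.
* LSTM: Glorot-uniform initialization, forget-gate biases start at 1;
  non-finite losses abort with a diagnostic rather than propagate NaNs.
* Wilcoxon comparisons with all-zero differences return p = 1 with a
  warning; Bonferroni-adjusted p-values cap at 1.

## Problem sizes used by the tests and the acceptance script

The packaged analyses run at desk scale: the across-subject benchmark uses
4 subjects × 60 trials (240 trials, 300 permutations in the acceptance
script), the within-subject comparisons use 2 subjects × 2 runs × 18
trials, and the LSTM checks run the fixed 64-epoch recipe at reduced
hidden width (16–24 units). The structural checks of the full design
(34 subjects × 300 trials) shorten the trial duration so the count
contracts stay cheap to verify. Full-scale runs are a matter of larger
configs, not different code paths.

## Known limitations

Warping to a common template cancels timing differences between trials;
if duration itself is the discriminative feature of a class, the SVM+DTW
route will not see it (the cw/ccw tasks remain separable because the
asymmetry survives as a value difference after warping). The LSTM is
CPU-bound in this implementation and is therefore the slower route at
realistic hidden widths. The two-fold `matched` split requires even group
sizes; the `hand_size` split puts the median subject in the larger-hand
fold when counts are odd.
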
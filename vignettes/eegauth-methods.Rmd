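---
title: "EEG authentication and channel reduction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG authentication and channel reduction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`eegauth` implements a verification-style EEG biometric pipeline: given
multichannel scalp recordings from a cohort of subjects, decide whether a
0.5 s sample belongs to one claimed *genuine* user or to an *imposter*, and
determine how few electrodes suffice to keep that decision accurate. The
pipeline mirrors a standard design: band-pass filtering into the canonical
EEG sub-bands, overlapping-window feature extraction, SMOTE-rebalanced
random-forest classification, impurity-based channel ranking, and a
sequential ablation that removes the weakest channel, retrains, and tracks
accuracy until it falls more than one percentage point below the
full-montage benchmark.

The montage-reduction question is a subset-selection problem: an
`n`-channel headset admits `sum_k C(n, k) = 2^n` unordered channel subsets
(`search_space_size(32)` is 4,294,967,296), which rules out exhaustive
evaluation and motivates the ranked, one-channel-at-a-time ablation.

## Filtering

All filtering is zero-phase Butterworth band-pass. Cutoffs are expressed as
normalized frequencies `Wn = fcutoff / (fs/2)`. The overall band is
0.2–50 Hz at order 4; the sub-bands are delta 0.2–4 Hz (order 2), theta
4–8 Hz, alpha 8–12 Hz, beta 12–26 Hz, and gamma 26–50 Hz (order 4). The
delta band drops to order 2 because a 0.2 Hz edge at 500 Hz is far below
the stable range of higher-order IIR designs. Adjacent bands deliberately
share their common edge; no gap/overlap correction is attempted.

Numerics: transfer-function (b, a) coefficients of an 8-pole band-pass with
a normalized edge of 0.0008 are severely ill-conditioned, so filters are
designed in zero-pole-gain form and applied as cascaded second-order
sections. Zero-phase behaviour comes from forward–backward application with
odd-reflection padding (pad length `3 * (taps of the equivalent transfer
function)`), which squares the magnitude response and cancels phase. The
test suite verifies the squared passband response against an independent
transfer-function design on a well-conditioned band, unit-amplitude
passband behaviour, stopband rejection, linearity, and zero lag.

## Windowing and features

Each band recording is cut into 0.5 s rectangular windows advanced by
0.25 s (half-overlap); a trailing partial window is dropped, so a recording
of `N` samples yields `floor((N - L)/S) + 1` windows. Eleven named features
are computed per window and channel: mean, population standard deviation,
mean absolute value, RMS, skewness (`m3/m2^1.5`), non-excess kurtosis
(`m4/m2^2`), Hjorth activity/mobility/complexity (variance ratios of the
signal and its first differences, without sampling-rate scaling — the
ratios cancel it), Shannon entropy of a 16-bin amplitude histogram (bits),
and spectral entropy of the DC-excluded periodogram normalized to [0, 1]
by `log2` of the number of spectral bins. Zero-variance windows take 0 for
the moment and Hjorth ratios, and a constant window has zero entropy;
these guards keep every feature finite for any finite input.

Two deliberate substitutions are documented here. First, the feature set is
the eleven features named above; the surrounding literature sometimes
counts twelve, but no twelfth definition is available, and inventing one
would be worse than shipping the named eleven (the set size is
configuration-visible, not hard-coded). Second, both entropies are often
computed with wavelet-based estimators; `eegauth` uses the
amplitude-histogram and periodogram versions because they are
deterministic, parameter-light, and exactly testable (broadband noise gives
normalized spectral entropy near 1, a pure tone near 0).

Feature tables are tibbles with channel-major columns named
`<channel>_<feature>`; `feature_column_index()` recovers the
`(channel, feature)` provenance that channel ranking and ablation rely on.

## Splitting, binarization, SMOTE

Windows are split 80/10/10 into train/validation/test, stratified per
subject, with floor counts for the two small splits and the remainder in
training. The split is window-level and random: overlapping neighbours can
straddle splits, which reproduces the common (leakage-prone) practice; a
contiguous block splitter (`method = "blocks"`) is available for
leakage-controlled experiments but is off by default.

For one genuine-user hypothesis the labels binarize to 1 (genuine) versus
0 (imposter); with 12 balanced subjects that is a 1:11 imbalance. The
training split only is rebalanced to exactly 50/50 with SMOTE: each
synthetic row is `x + u (x_nn - x)` for a minority row `x`, one of its
`k = 5` nearest minority neighbours `x_nn` (Euclidean), and `u ~ U[0, 1]`.
Validation and test remain imbalanced — only enrolment data can be
augmented in a deployed verifier. Neighbour search runs in raw feature
space by default (trees are scale-invariant downstream); a z-scoring flag
exists as a sensitivity knob. `k = 5` is the canonical SMOTE setting.

## Classifier, ranking, ablation

The verifier is a Gini random forest (via `ranger`, single-threaded and
seed-deterministic); decisions are ensemble majority votes at 0.5, and
accuracy is the fraction of correctly classified 0.5 s test windows.
Hyperparameters come from an exhaustive grid search scored on the
validation split (default grids: 50/100/200 trees, depth 8/16/unlimited,
node size 2/8), with ties broken to the first-encountered grid point; the
winning parameters are then frozen for every ablation retrain so that
accuracy changes are attributable to channel removal alone. Wall-clock
training and classification times are recorded in the results bundle but
carry no acceptance semantics — they are hardware noise.

Channel ranking fits a gradient-boosted tree classifier (via `xgboost`) on
the balanced training set and sums per-column impurity-gain importances
within each channel's column group, renormalized to fractions summing
to 1. Summation is chosen because gain is additive over columns. The
booster subsamples columns (`colsample_bytree = 0.25`): with fully
separable training data a greedy booster otherwise credits only the first
separating channels and assigns zero gain to equally informative but
redundant ones, which would make the ranking of correlated channels
arbitrary. A forest-impurity ranking (`method = "forest"`) is available
for comparison. Ranking happens once, before ablation — the results file
stores a single impurity score list — and a `rerank` flag enables the
per-step variant as an experiment.

Ablation walks from the full montage down to one channel, at each step
dropping every feature column of the lowest-ranked remaining channel from
both training and test, retraining with the frozen parameters, and
recording accuracy. `min_channels_before_drop()` scans this trace from the
full count downward and returns the smallest count for which all larger
montages stay within the tolerance (1 percentage point of accuracy by
default) of the full-montage benchmark.

## The synthetic cohort generator

No raw recordings ship with the package; `generate_cohort()` produces a
seeded stand-in cohort whose defaults emulate the target recording
campaign: 12 subjects, 32 channels at 500 Hz with 10-10 labels, 20 s per
subject (about 79 windows each — enough for stable split sizes while
keeping a full test-suite run cheap; longer recordings simply sharpen the
same structure).

Each band contributes one narrowband sinusoid at a seeded frequency drawn
in the central 80% of the band (shared by all subjects and channels, so
frequency is never an identity cue), with per-(subject, channel) random
phases. Identity is carried entirely by band amplitudes on a planted set
of *informative* channels (default: the first five). On those channels
each subject holds a binary high/low amplitude profile
(`signature_levels`); all other
channels sit at the shared baseline. The low/high levels default to
0.75/1.25 of baseline with background noise at twice the oscillation
baseline, so single-window, single-channel readout of a subject's level is
deliberately imperfect — identity is reliable only by pooling channels,
as with real scalp signatures. Background noise is 1/f with a
*fixed* amplitude spectrum and random phases (a random-phase surrogate):
every realization has exactly the same power spectrum, so the noise floor
is EEG-like yet contributes no subject-identifying fingerprint.

The per-band amplitude profiles form a balanced binary code. For the
canonical 12-subject cohort the codewords are rows of a Plackett–Burman
12-run orthogonal array (strength 2): every informative channel splits the
cohort 6/6, every *pair* of informative channels leaves each subject
indistinguishable from exactly two others, and the full five-channel set
identifies every subject uniquely. This gives the generator a structural
property that the pipeline is designed to detect: authentication is
near-perfect while the informative montage survives, stays flat while
redundant (noise) channels are ablated, and collapses once the informative
set is cut below about three channels — the discriminative signal is
distributed across channels rather than concentrated in any one. For other
cohort sizes the codewords fall back to seeded balanced columns with
distinct rows whenever the code space allows.

What the generator does *not* emulate: event/trial structure, evoked
potentials, artifacts, electrode drift, volume-conduction correlations
between neighbouring electrodes, or non-stationarity. Passing tests
therefore demonstrate that the pipeline recovers planted, stationary,
amplitude-coded structure — they say nothing about accuracy on real EEG,
where signatures are weaker and confounded. Real-data headline numbers
(for example, per-band accuracies in the low 80% range and 13–17 minimum
channels by band) require the original recordings and are deliberately out
of scope here.

## Determinism and numerical conventions

Every source of randomness flows from explicit integer seeds through
small derived child seeds (kept inside the 32-bit range); no function
touches the global RNG state without restoring it. Two identical runs
serialize to byte-identical results JSON once timing fields are excluded.
Other fixed conventions: window sample counts round half away from zero;
rankings renormalize to sum 1 and degenerate all-zero importances fall
back to uniform; SMOTE preserves original rows verbatim ahead of synthetic
ones; ties in the hyperparameter grid resolve to the first-encountered
point; subject and channel indices are 1-based throughout.

## Problem sizes used by the checks

The package's own verification runs use deliberately small problem sizes:
cohort fixtures of 4 subjects x 8 channels for plumbing and ranking tests,
and the full 12 x 32 default cohort (20 s per subject, 50-tree forests,
gamma band) for the end-to-end parameter-recovery study, with a handful of
seeds where a property is stated over repeated runs. The recovery study
caps tree depth at 8: with half-overlapping windows split at random,
unlimited-depth trees can partially memorize the noise content of windows
that straddle train and test, and shallow trees both generalize better
and keep the 32 ablation retrains cheap. These sizes are the
package's chosen verification conditions; the pipeline itself has no
built-in limits beyond memory.

## Known limitations

- The delta band's 0.5 s windows cover less than one full cycle of its
  slowest components; delta-band features are correspondingly noisy (true
  of the pipeline design, not only of this implementation).
- Random window-level splitting lets half-overlapping windows straddle
  train and test; authentication accuracy on real data is optimistic under
  this protocol. The block splitter exists precisely to quantify that
  optimism.
- The SMOTE neighbour search is exact (`stats::dist`), which is quadratic
  in the minority count — fine at these scales, slow for very long
  enrolment recordings.
- Wall-clock timing fields are recorded for completeness and reported
  descriptively; they are not comparable across machines.
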
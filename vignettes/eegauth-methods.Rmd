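---
title: "EEG-based single-trial authentication: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG-based single-trial authentication: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegauth)
```

## The problem

Biometric authentication verifies a *claimed* identity: the system holds
a per-user model, a sample arrives, and a binary decision is made. EEG
is an attractive credential because brain responses are subject-specific
and hard to replay. `eegauth` implements a complete decoder for this
setting, built around simple motor tasks (clenching the left or the
right hand): per-user models are trained on single 2 s windows of
multichannel EEG and evaluated by the standard biometric error rates,
the false acceptance rate (FAR, imposters admitted) and the false
rejection rate (FRR, genuine users denied).

The pipeline is: ingestion and windowing, an 18-feature bank per
channel, reduction of the channel dimension to a fixed 36-element
vector, greedy beam selection of 10 features, a per-user RBF-SVM per
task, and a two-task AND gate. Every stage that learns anything is
fitted on training folds only.

## Ingestion and windowing

Recordings arrive either as classic EDF (16-bit; a plain-CSV sidecar
`<file>.annotations.csv` carries task epochs) or as the package's exact
RDS "array bundle". Channel labels are normalised to canonical 10-20
spellings (`"FCZ.."` becomes `"FCz"`), since common motor-imagery
exports pad and upper-case labels. Three electrode presets are
supported: a frontocentral 8-channel montage
{Fz, FCz, C3, C4, F1, F2, AF3, AF4}, a 16-channel extension adding
{F4, Fp1, Fp2, C1, C2, FC1, FC2, F3}, and the full 64-channel montage.

Signals are band-passed 1–50 Hz with a 4th-order Butterworth filter run
forward and backward (`signal::filtfilt`), i.e. zero net phase — the
standard choice when later features depend on waveform shape. Each
annotated task epoch is then cut into 2 s windows with 75% overlap;
windows never span epochs, so their task label is unambiguous. A 4 s
trial yields 5 windows (`floor((4-2)/0.5)+1`), hence 21 trials per task
yield 105 windows. The epoch length before windowing is a parameter
(`trial_len_s`, default 4 s).

## Empirical mode decomposition

Each window and channel is decomposed into intrinsic mode functions
(IMFs) by cubic-spline sifting: envelopes through the local maxima and
minima (natural cubic splines, with the two outermost extrema mirrored
beyond each end to control edge swings on 2 s windows), subtraction of
the envelope mean, repeat. Two decibel thresholds terminate the
process:

* *resolution* (default 40 dB): a candidate mode is accepted when its
  energy exceeds the energy of its envelope mean by this factor,
  i.e. `10*log10(E_mode / E_envmean) >= 40`;
* *residual energy* (default 60 dB): decomposition stops when the
  residue has dropped this far below the input energy, or the residue
  is effectively monotone.

A candidate is additionally required to be an admissible IMF (extrema
and zero-crossing counts differing by at most one) before sifting
stops, and a safeguard (`max_sift_iters = 200`) guarantees termination.
The sifting core is compiled (C++) because it runs tens of thousands of
times per cohort. Only the first 4 IMFs are used downstream — on 2 s
motor windows they carry nearly all of the band-limited structure; if a
decomposition yields fewer, the missing modes are zero vectors (with a
warning) so feature shapes stay fixed.

Plain EMD on broadband noise shows occasional intermittency-driven mode
mixing in the deeper modes: the zero-crossing count of IMF4 can
sporadically exceed IMF3's on an individual draw, though the ordering
holds on average. The tests assert strict per-draw ordering only for
the first three modes. Ensemble variants that suppress this are out of
scope.

## The 18-feature bank

Per channel: four entropy measures of each of the first four IMFs, plus
two band powers of the channel signal — 18 features, in the fixed row
order `shannon_imf1..4, logenergy_imf1..4, sampen_imf1..4,
apen_imf1..4, mu_power, beta_power`.

Shannon entropy `S = -Σ q_i log q_i` and log-energy entropy
`L = Σ log q_i` use the normalised sample energies
`q_i = x_i² / Σ x_j²` as the "probability" of a sample — the convention
of the classic wavelet toolboxes, and the natural reading when the
features are computed on continuous-valued modes (a histogram-based
estimator would need an arbitrary binning choice). Zero-energy samples
are skipped in `L` (counted in a warning); both are invariant to
amplitude scaling. Natural logarithms throughout.

Approximate entropy (ApEn) and sample entropy (SampEn) use embedding
length `m = 2` and tolerance `r = 0.15 · sd(x)`, Chebyshev distance;
ApEn includes self-matches, SampEn excludes them. Degenerate SampEn
counts follow documented conventions: equal match counts at both
template lengths (including constant series) give 0; a zero extended
count returns the finite cap `log(B·(N-m))` with a warning, keeping the
feature bounded. Both statistics are verified against independent
brute-force double-loop implementations to 1e-10.

Band powers are the mean multitaper PSD over the mu (7.5–12.5 Hz) and
beta (16–31 Hz) sensorimotor bands, computed on the filtered channel
signal (not on an IMF — they are *channel* features complementing the
per-IMF entropies). Slepian tapers come from the symmetric tridiagonal
eigenproblem with time–bandwidth product 3 and 5 tapers on the 2 s
window; both are configurable. Tapers are cached per window length.

## Channel reduction to 36 features

Two interchangeable reducers compress the 18×C matrix to 18×2 and
concatenate the two columns into the 36-element SVM input:

* **Cluster reducer.** For each window, the Pearson correlation of the
  18-feature profiles of every channel pair; mean and SD across windows
  give C×C summary matrices. Average-linkage hierarchical clustering on
  `1 - mean correlation`, cut at k = 2, partitions the channels (EEG
  feature profiles typically split into two spatial groups). The
  feature matrix is averaged within each cluster. Perfectly flat
  correlation structure falls back to a deterministic
  {first channel} vs rest split.
* **PCA reducer.** For each of the 18 feature rows, a PCA over channels
  is fitted on the training windows ([windows × C]) and each window's
  C channel values are projected onto the top-2 components. This
  orientation (compressing *channels* to 2 per feature) matches the
  18×2 → 36 input contract; component signs are fixed deterministically
  (largest loading positive).

Both fits are estimated per training fold only and frozen before any
held-out window is transformed. The reducer interface
(`feature_matrix` in, 36-vector out) is the plug-in point for other
reducers.

## Feature selection

From the 36 candidates, a greedy beam forward selection picks 10: score
every single feature, keep the best 5; extend every retained set with
every unused candidate, score, keep the best 5 sets; repeat to size 10
and return the best final set. The score is the stratified 5-fold
cross-validated accuracy of an RBF-SVM restricted to the candidate
columns, computed *within the training fold*. One fold assignment (from
a per-selection seed) is shared by all candidate sets, scores are
cached by set, and ties break lexicographically on the sorted index
tuple, so the search is fully deterministic given its seed. Selection
runs independently per task and per outer fold. A fixed final size of
10 is used (no early stop): the beam already guards against weak
additions, and a fixed size keeps all decoder variants comparable.

## The authenticator

Per user and task, training assembles the user's 105 windows (label
genuine) with 105 imposter windows sampled uniformly without
replacement from all other subjects' windows (seeded). Features are
min–max normalised with the training minima/maxima; held-out values may
fall outside [0, 1] and are deliberately not clipped. The SVM uses an
RBF kernel on standardised features with the kernel scale set by the
median pairwise Euclidean distance of the (standardised) training rows
(`gamma = 1/median²`) — a deterministic, widely used stand-in for
automatic kernel scaling — and box constraint C = 1 (configurable).

Evaluation is a 5-fold cross-validation with *sequential* contiguous
blocks per class (no shuffling): fold j tests the j-th fifth of the
user's windows and the j-th fifth of the sampled imposters. Sequential
blocks also limit leakage between overlapping windows of the same
trial, which a shuffled split would scatter across folds; the residual
overlap at block borders is inherent to 75% overlapping windows and is
shared by any windowed single-session design. Within each training
fold, the reducer fit, normalisation, selection and SVM see only the
training 80%; an index audit in the tests verifies no test window
enters any fit.

False acceptances are estimated against an *expanded imposter pool*:
every window of every other subject that was not used for training in
that fold (the held-out imposter block plus all never-sampled windows)
is scored as an imposter attempt. Finally, the two-task gate: an
attempt supplies one trial per task and is granted only if both
per-task SVMs vote genuine. Gated genuine attempts pair the user's test
windows of the two tasks by position; gated imposter attempts pair, per
subject, the windows available in both tasks; the gate score of an
attempt is the smaller of the two decision values (an AND gate passes
at threshold t iff min of the scores exceeds t).

## Error rates and comparisons

FRR and FAR are pooled ratios over users and folds
(`Σ FN / Σ (TP+FN)` and `Σ FP / Σ (TN+FP)`); accuracy is the pooled
fraction of correct decisions, algebraically consistent with the two
rates under attempt-count weights. Because the expanded pool makes
imposter attempts outnumber genuine ones, the report also carries
`cv_accuracy`, the mean balanced accuracy on the 42-window test folds —
the quantity to look at when asking "does this decoder discriminate at
all?". Per-user FARs (pooled over folds within a user) feed the FAR
box-plots and the paired two-sided Wilcoxon signed-rank comparison of
two systems, Bonferroni-corrected for 3 planned contrasts
(alpha = 0.05/3). ROC curves sweep a threshold over the decision values
(gate scores for the gated system), with AUC by the trapezoidal rule;
the default operating point is the SVM's native zero decision boundary
(reported rates are at that threshold; a Youden-J style threshold can
be read off the ROC but is not claimed as anyone's canonical choice).

## The synthetic cohort generator

Real motor-imagery EEG cannot ship with the package, so the generator
emulates the properties the decoder exploits, per channel:

* an AR(2) background with a low-frequency resonance
  (pole modulus 0.95 at 2 Hz, innovation SD 0.5 µV) producing the
  drifting rhythmic floor of EEG while leaving the high-frequency range
  to the terms below;
* a mu (~10 Hz) and a beta (~22 Hz) oscillator, amplitude-modulated at
  0.7 Hz, *shared within each of two channel groups* (left/right
  hemisphere by electrode number, midline channels alternating) with
  distinct group gains (1.3 vs 0.7) — this plants the 2-cluster channel
  structure the cluster reducer looks for;
* white noise with SD `complexity` (default 2 µV), the knob that
  controls the irregularity (SampEn/ApEn) of the fast modes;
* a task effect: the motor task attenuates the mu oscillator of the
  contralateral channel group (factor 0.45), so left- and right-hand
  windows differ and the AND gate is meaningful.

Per-subject parameters are drawn around this base with a spread
proportional to the cohort's `separation`: log-normal band-amplitude
gains (SD 0.4·separation), oscillator frequency jitter within their
bands, background pole and innovation jitter, and log-normal complexity
(SD 0.5·separation). At `separation = 0` all subjects share identical
generative parameters, so decoders can only reach chance — the null
condition used in the tests. Defaults (21 trials/task, 4 s trials,
160 Hz, preset 8) mirror a typical public motor-task recording setup.

What the generator does *not* emulate: volume conduction and realistic
spatial mixing, artifacts (EOG/EMG), non-stationarity across sessions
or days, and 1/f broadband structure beyond the AR(2) background.
Passing the end-to-end tests therefore shows the pipeline recovers
known subject structure of this kind — not that any particular accuracy
will be attained on real recordings.

A note on the complexity knob: the entropy of the first IMF has a
noise floor caused by mu–beta mode mixing on 2 s windows, so small
complexity contrasts (0 vs 1) are not reliably ordered on single
windows. The tests assert the ordering for a contrast spanning the
spread that a separated cohort actually draws (0 vs 4), averaged over a
trial's five windows, as the feature bank effectively does.

## Numerical and design choices

* EMD envelopes: natural cubic splines, mirror extension of two
  extrema; plateau extrema use the plateau midpoint.
* SampEn caps and zero-handling as described above; all 18 features are
  checked finite, and a padded (all-zero) IMF contributes 0 entropy by
  convention.
* SVM decision values are oriented so positive always means genuine,
  regardless of internal class ordering.
* All randomness flows through private seeded RNG streams
  (`local_rng`) that restore the caller's RNG state; derived seeds
  (per subject, per task, per fold) come from the parent stream. Two
  runs with the same seed produce byte-identical JSON reports.
* Default problem sizes in the tests and the acceptance script: the
  separable condition uses 5 subjects at separation 1.5 (21 trials per
  task, preset 8); the null condition uses the generator minimum of
  3 subjects, which is sufficient for a chance-level check; the
  determinism check uses a reduced beam (width 2, size 3) since
  determinism does not depend on the search width.

## Known limitations

* Single-session data only; cross-day robustness is untested.
* The NN-based reducers this design anticipates are not implemented;
  the reducer interface is where they would plug in.
* EDF support is classic EDF (identical per-channel rates, 16-bit);
  EDF+ annotations are handled via the CSV sidecar instead.
* Plain EMD mode mixing on noise, as discussed above.
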
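---
title: "Brain-region-aware domain adaptation for EEG emotion recognition: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-region-aware domain adaptation for EEG emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brada)
```

## The problem

Affective brain-computer interfaces try to infer a person's emotional state
(here: binary high/low valence or arousal, derived from 1–9 self-ratings)
from multichannel scalp EEG. The obstacle is covariate shift: feature
distributions differ sharply between subjects (anatomy, skull conductivity,
cap placement, mood) and between recording campaigns (equipment, stimuli,
protocol). A classifier trained on a pool of subjects degrades badly on an
unseen subject, and worse across databases.

`brada` implements a brain-region-aware answer: restrict features to the
electrode groups over the cortical regions actually driven by audiovisual
stimulation, learn a domain-invariant subspace *per region* with a
kernelized maximum-independence criterion, concatenate the two projections,
and classify with a linear SVM. Everything is exercised end-to-end on
synthetic studies generated in-package, so the full pipeline is testable
without access-restricted recordings.

## Channel regions

The 32-electrode 10-20 montage (`biosemi32_montage`) is split into

* **visual** — the five occipital electrodes `PO3, PO4, O1, Oz, O2`;
* **auditory** — twelve electrodes over temporal cortex:
  `F7, F8, F3, F4, FC5, FC6, T7, T8, CP5, CP6, P7, P8`.

The auditory list follows the method's grouping, not a textbook atlas:
`F3/F4/F7/F8` are conventionally frontal, but the method assigns them to
the auditory set and the implementation follows that list verbatim — the
grouping is part of the method under test, so "fixing" it would change the
method. Other lobes are deliberately unused. Channel matching is
case-insensitive with canonical capitalization on output, because file
dialects disagree about case.

## Features

Per trial and channel, ten features: differential entropy (DE) and mean
Welch power density (PSD) in five bands — theta (4–8 Hz), slow alpha
(8–10 Hz), alpha (8–12 Hz), beta (12–30 Hz), gamma (30 Hz up). Slow alpha
overlaps alpha by construction; both are kept, as the five-band arithmetic
requires. Hence m = 320 features for 32 channels, 120 for the auditory set,
50 for the visual set.

Numerical choices, each made once and fixed:

* **DE formula.** DE is computed as ½·ln(2πeσ²) of the band-filtered
  epoch — the Gaussian-assumption form that the DE literature for EEG uses.
  A zero-variance epoch is an error, not −∞.
* **Band filter.** Zero-phase Butterworth, realised as a 5th-order
  high-pass followed by a 5th-order low-pass, each run forward–backward.
  The cascade keeps the recursion stable for narrow low bands at high
  sampling rates, where a single order-5 transfer-function band-pass
  diverges in double precision. Signals are demeaned before filtering so a
  DC offset cannot leak into the band variance through edge transients.
* **Gamma's upper edge** is open in the band scheme; it is capped at
  `min(45, 0.45·fs)` Hz to stay clear of mains interference and the
  Nyquist limit.
* **PSD estimator.** Welch with 1-s Hann windows and 50 % overlap,
  one-sided density scaling (the spectrum integrates to the signal power;
  verified against Parseval and flat-spectrum oracles in the tests); band
  PSD is the mean density over bins in `[low, high)`.
* **Epoching.** One feature row per trial, computed over the whole trial,
  which absorbs the differing trial lengths of the two benchmark layouts.
  The sampling rate is taken as given.

Min–max normalization maps every feature column onto [0, 1] using the
minimum and maximum over **all samples passed in jointly** — source and
target together, consistent with the transductive protocol in which the
subspace is learned from all samples of both domains. Constant columns map
to 0.

## The adaptation model

Let X̄ be the normalized region features with the one-hot domain matrix D
stacked underneath (`augment_features()`): each distinct (database,
subject) pair is one domain row. The augmented rows are what allow the
projection to express — and thereby cancel — per-domain offsets. No scaling
is applied to the D rows relative to the feature rows.

With K the kernel Gram matrix of the augmented samples, K_D = D′D, and
H = I − (1/n)11′ the centering matrix, the empirical HSIC between the
projected features and the domain identity is (n−1)⁻²·tr(K_Z H K_D H). The
subspace maximizes projected variance minus domain dependence; its solution
is the top-h eigenvectors of

&nbsp;&nbsp;&nbsp;&nbsp;M = K(−H·K_D·H + μ·H)K,

with trade-off μ = 1 by default. Projection of (possibly new) samples is
Z = W′K_cross. Numerical policy: M is explicitly symmetrized before the
eigendecomposition (floating-point asymmetry otherwise yields complex
pairs); eigenvector signs are fixed so each column's largest-magnitude
entry is positive, making output reproducible across BLAS builds; ties are
left in solver order. An optional trace-scaled ridge on the kernel diagonal
is available but off by default. With a single domain, −H·K_D·H vanishes
and the solver reduces to kernelized variance maximization — asserted
numerically in the tests.

The flagship configuration uses a polynomial kernel; the method fixes
neither degree nor offset, so degree 2 with coef0 = 1 is the default — the
lowest-degree strictly nonlinear choice — with both exposed in
`kernel_spec()`. The Gaussian kernel's width defaults to `1/(p·var(X̄))`.
The linear-kernel variant of the same solver is `brada_mida`.

Two classical baselines are re-implemented from their original
formulations: transfer component analysis (`fit_tca`: generalized
eigenproblem of `(K L K + μI)⁻¹ K H K` with the MMD matrix L) and subspace
alignment (`fit_sa`: per-domain PCA bases, source mapped through
V_s(V_s′V_t)). The `brada_tca` / `brada_sa` variants keep region separation
and joint normalization but not domain-feature augmentation, which is the
maximum-independence solver's own mechanism; TCA and SA have no
domain-feature concept in their sources. For SA the subspace dimension is
capped at `min(m, n_s, n_t)` — with 50 visual features the cap binds before
the default grid ends.

## Region concatenation

The two region projections are concatenated into a 2h-dimensional
embedding. Kernel magnitudes grow with the number of feature rows entering
the kernel, so the 120-channel-feature auditory block arrives on a much
larger scale than the 50-feature visual block; each block is therefore
rescaled to unit average variance before concatenation, letting both
regions contribute comparably to the classifier. For the same reason the
SVM wrapper centers the embedding and divides by one global training-set
scale factor — a single factor, not per-column standardization, which would
re-weight trailing noise components up and destroy the eigenvalue ordering
the subspace provides.

## Evaluation protocols

* **Cross-subject:** leave-one-subject-out. By default the protocol is
  transductive — the held-out subject's (unlabeled) samples participate in
  subspace learning, consistent with the method's unsupervised design — but
  the subject's labels never reach the SVM, which trains only on the
  remaining subjects' rows. Because no labels enter subspace learning, the
  transductive embedding is identical across folds and is computed once.
  `transductive = FALSE` switches to strict out-of-sample projection
  through the stored cross-kernel; both modes are tested.
* **Cross-database:** both tables are pooled, normalized jointly, and one
  subspace per region is learned from all samples with (database, subject)
  domains — multi-source, multi-target. The SVM trains on the source
  database's rows and is scored on the target database's rows, reported
  per target subject.
* Mean accuracy is the unweighted mean over folds (each subject counts
  equally); the pooled per-sample accuracy is also reported.
* Ratings binarize as high iff rating > 5; the threshold is configurable
  and ties go to the low class.
* `search_h()` sweeps h over {10, …, 100} using the evaluation protocol
  itself — an oracle-style sweep, as such curves are usually produced; the
  curve is the honest output, and `detect_plateau()` checks the
  rise-then-flat signature. `significance_test()` is a paired two-sided
  t-test over fold accuracies; identical reports return p = 1 by
  convention.

## The synthetic-data generator

`generate_feature_dataset()` emulates a multi-subject affective-EEG study
at the feature level. Its defaults are the packaged study conditions, fixed
once:

* residual noise sd 1.0 (the scale unit);
* per-column class gap `effect_size` (default 0.8) injected **only** into
  auditory- and visual-region columns, with random per-column sign;
* per-subject additive offsets of sd `subject_offset_sd` (default 1.0),
  of which a fraction `shift_align = 0.6` lies along the class-discriminant
  direction — drawn independently per brain region. The aligned component
  is what makes pooled cross-subject training degrade; its per-region
  independence means the two regions carry independent residual error, so
  combining them can average it down (regional drift is also the more
  realistic model). The rest is isotropic;
* per-subject multiplicative jitter (log-sd 0.1) and an optional
  cross-database offset (0.5) for paired studies
  (`generate_cross_study()`);
* ratings drawn consistently with the latent binary state except for 10 %
  label noise, so threshold-5 binarization recovers the state at ~90 % —
  which also sets the accuracy ceiling any classifier can reach;
* optional `column_scale_sd` multiplies columns by log-normal scales
  (heterogeneous units; exercises the normalization ablation), and
  `latent_dim` routes the informative-column structure through a factor
  model: a quarter of the factors are high-variance signal-free background,
  the rest carry the class signal evenly, so projections recover the signal
  progressively and downstream accuracy rises until h reaches the intrinsic
  dimension, then plateaus.

`generate_raw_epochs()` produces signal-level data: per channel a sum of
five band-centered oscillations with log-normal amplitudes plus 1/f-shaped
background; the latent state modulates the alpha amplitude multiplicatively
in region channels, so the injected effect reappears after feature
extraction as a DE gap in nats. Packaged profiles mirror the two benchmark
layouts (27 subjects × 20 trials at 256 Hz; 32 × 40 at 128 Hz).

What the generator does **not** emulate: volume conduction and channel
correlation structure, artifacts (ocular, muscle), non-stationarity within
a trial, realistic spectral shapes beyond 1/f, or rating idiosyncrasies.
Passing tests therefore demonstrate that the pipeline recovers a known
injected structure under subject and database shift — not that any
particular accuracy will be reached on real recordings.

## Problem sizes used by the checks

The end-to-end property checks run on the full 27 × 20 profile
(540 samples, 27 folds) for the transfer-gain and region-synergy
properties, a 9 × 12 miniature for quick protocol plumbing, a 12 × 30
study for the dimension sweep, and a 6 × 10 study at 3-s trials for the
raw-signal round trip — sizes at which fold granularity is fine enough for
the margins being asserted while a full suite run stays around a minute.
The split-signal study uses effect 0.45: at 0.8 either region alone already
sits at the label-noise ceiling, leaving region combination nothing to
add; at 0.45 neither region saturates and the combined embedding's
advantage is observable.

## Known limitations

* The transductive default means the reported LOSO numbers assume the test
  subject's unlabeled data were available at subspace-learning time; use
  `transductive = FALSE` for the stricter claim.
* `search_h()`'s argmax is optimistically biased (the sweep reuses the
  evaluation folds); nested selection must be built from
  `loso_cv()` primitives by the user if needed.
* The SA baseline aligns global PCA bases; it is known to underperform when
  domains differ by more than a rotation — visible in its results here.
* Kernel matrices are dense `n × n`; studies beyond a few thousand samples
  would need low-rank approximation, which is out of scope.
* Reading vendor EEG formats (BDF/EDF) is an extension point:
  `eeg_epochs()` accepts any trials × channels × samples array.

## A worked call

```{r example, eval = FALSE}
study <- generate_feature_dataset("mahnob_like",
                                  shift_spec(effect_size = 0.8,
                                             subject_offset_sd = 1.0),
                                  seed = 0)
baseline <- loso_cv(study, brada_config("baseline", seed = 0))
adapted  <- loso_cv(study, brada_config("brada", h = 40, seed = 0))
glance(baseline)
glance(adapted)
significance_test(adapted, baseline)
```
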
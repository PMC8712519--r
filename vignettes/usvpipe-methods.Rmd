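---
title: "Methods: detection, classification and clustering of mouse lemur vocalizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection, classification and clustering of mouse lemur vocalizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(usvpipe)
```

usvpipe is a seeded, fully reproducible pipeline for analysing
high-frequency/ultrasonic vocalizations (USVs) of the gray mouse lemur in the
5–50 kHz band, together with the validation protocol needed to decide how far
the automated stages can be trusted. This vignette explains the models, the
parameters that matter, what the synthetic material does and does not
emulate, and the design decisions taken where the problem was genuinely open.

## The measurement core

Every stage consumes a short-time Fourier magnitude spectrogram
(`compute_spectrogram()`): Hann window of 512 samples at the 192 kHz default
rate (≈ 2.7 ms, 375 Hz bins), 50% overlap. The window is a compromise: zips
last as little as 8–10 ms and need several frames of temporal support, while
the 375 Hz bin width keeps frequency measurements well inside a 500 Hz error
budget. Any rate ≥ 100 kHz (twice the upper band edge) is accepted.

**Tonality.** Frames are scored by how line-like their in-band spectrum is:
`1 − GM(P)/AM(P)`, one minus the spectral flatness of the in-band power
spectrum. Raw single-frame periodogram bins are exponentially distributed,
which makes the geometric mean noisy enough that pure white-noise frames
would occasionally score above 0.5; the power spectrum is therefore
Bartlett-smoothed over three adjacent bins before the ratio is taken. This
variance stabilisation leaves the limits untouched (exactly 0 for a flat
spectrum, → 1 for a line) and keeps white noise reliably below ≈ 0.3.
Tonality over a band of only a few bins is degenerate — a pure tone looks
"flat" inside its own 2-bin band — so contour cleaning always evaluates
tonality over a band of at least 6 kHz centred on the box.

**Contours and features.** Within a detection box the contour is the
frequency at maximum amplitude per frame, restricted to the box band (ties
break to the lowest bin). Cleaning removes frames that are non-tonal
(tonality below `tonality_floor`, default 0.3) or more than 25 dB below the
contour peak; the amplitude gate matters because detection smoothing widens
boxes slightly into the noise bed, and noise peak-picks at the box edges
would otherwise corrupt the start/end frequency measurements.
`extract_features()` condenses a contour into: duration; mean, min, max,
start and end peak frequency; bandwidth; ordinary-least-squares slope
(Hz/s); sinuosity (path length over straight-line length in frame/bin
units, ≥ 1); mean tonality; and a syllable-count estimate from amplitude
gaps. A single-frame contour has duration = hop, slope 0, sinuosity 1.

## Detection

The detector is a deterministic spectrogram segmenter with three
duration-stratified profiles, mirroring the long / short / very-short
split of the repertoire (long whistle & trill; short whistle & tsak; zip).
Per profile: in-band energy per frame is smoothed by a moving average
(40 / 8 / 3 ms), the noise floor is the per-file median frame energy, and a
frame is active if smoothed energy ≥ floor + 8 dB and full-band tonality
≥ 0.35. Active runs separated by gaps shorter than one smoothing window are
fused (so trill syllable gaps of 10–30 ms fuse under the long profile while
series intercall intervals of 90–180 ms do not), then gated by duration:
long 0.15–3 s, short 20–200 ms, very short 4–30 ms. Box frequency bounds are
tightened to the bins within 20 dB of the strongest bin; the score is the
mean tonality of the segment.

The tonality gate is deliberately permissive (0.35): loud band-limited noise
transients *should* be detected — removing them is the trainable denoiser's
job, and the validation protocol needs those noise false positives to
exercise it. Only the flat separator/bed noise is below the gate.

Running all three profiles simultaneously (`multi_detect()`) deliberately
produces doublets (a zip found by both the short and very-short profile;
trill syllables re-boxed by the short profile) and fragments. Two cleanup
stages follow:

* `rds_filter()` first merges same-profile boxes separated by less than
  `merge_gap` (15 ms), then deletes any box at least `containment_frac`
  (90%) contained inside a longer-duration-profile box. Merging must precede
  deletion: in the other order two partially-contained fragments could merge
  into a fully-contained box that a second pass would delete, violating
  idempotence. The exact rules of the original R cleanup script are not
  published; these two are a reconstruction of its described behaviour
  (deleting doublet syllables, merging fragments) and are flagged as such.
* the **denoiser** (`train_denoiser()`) is a binary random forest on the
  acoustic features, trained from a seeded 8:2 stratified learning/testing
  split. Its training examples are measured through *detected* boxes (the
  detector is run on each rendered training clip and the best-overlapping
  box is measured), not through ground-truth boxes: narrowband noise
  measured through its detected, frequency-tightened box genuinely looks
  more tonal than through its wide true box, and the model must live in the
  measurement domain of the boxes it will judge. Rejected boxes keep status
  `rejected` rather than being deleted, preserving the reviewer audit trail.

## Classification and clustering

`train_classifier()` fits a multiclass random forest on the same features
(8:2 seeded stratified split; classes under 10 examples warn but proceed).
Each tree draws a class-balanced bootstrap: the rarest natural class, the
zip, is highly stereotyped, and the balanced bootstrap keeps its recall at 1
against the much more frequent short whistle whose steep, short variants
grade into zip space — reproducing the asymmetric confusion regime (short
whistles misclassified as zips, never the reverse) that drives zip precision
far below 1 when zips are rare in a scene.

`weighted_feature_matrix()` standardizes each column to zero mean and unit
variance and then applies the group weights (frequency / duration / contour,
default all 1). Standardizing before weighting is our choice — without it a
unit weight would mean nothing across Hz, seconds and dimensionless columns.
Zero-variance columns stay at 0. `choose_k_elbow()` runs best-of-`replicates`
k-means for k = 1..max and picks the k with maximal perpendicular distance
of the inertia curve to its endpoint chord — a standard concretization of
the elbow criterion, which is otherwise only a name. An extra warm start
(previous centroids plus the worst-fit point) guarantees the inertia curve
is non-increasing in k. `match_clusters_to_types()` maps clusters to their
majority call type; merging by majority is how the unsupervised categories
are compared with the human-made repertoire.

## Validation protocol

`match_detections()` categorizes every box: temporal IoU ≥ 0.5 with exactly
one annotation (greedy one-to-one, descending overlap) is a true positive;
a box covering ≥ 50% of two or more annotations is an overlaid false
positive when those annotations are cross-linked as overlaid in the ground
truth, otherwise a cluster false positive; remaining boxes with any overlap
are fragments; the rest are noise. The overlaid category is keyed to the
ground-truth cross-links rather than to "different call types" because
standardized overlaid scenes contain a single call type. Noise-event
annotations are not targets: they never count toward `tt`.

`semi_automated_adjust()` simulates the reviewer: fragments are extended to
their annotation (duplicates of one call merge into a single corrected box),
clusters are split at annotation boundaries, and overlaid boxes are credited
to each spanned call; noise boxes stay. Corrected boxes are true positives
by construction, so the adjusted result is assembled directly rather than
re-matched — re-matching would re-flag the corrected box of a heavily
overlapped pair as spanning its partner again. Precision is defined as 1.0
when there are no detections at all (no claim, no mistake); recall is
undefined (an error) when `tt = 0`. Against exact synthetic ground truth
recall cannot exceed 1; against a manually screened reference it can, which
is why synthetic and field recall values are not comparable level-to-level.
Scenario comparisons use across-type means; session-level reports use
medians with interquartile ranges.

## What the synthesizer emulates — and what it does not

`build_standardized_file()` reproduces the standardized evaluation layout:
alternating 3 s white-noise separators and call units over a continuous
noise bed, one call type per file, 50 units per type in good quality and 10
in each degraded scenario by default; tsak and short-whistle units are
series of three calls with 90–180 ms intercall intervals. The archive's
"28 dB" separator amplitude has no stated reference level; here the bed is
an explicit parameter (`noise_level_db`, default −33 dBFS RMS) calibrated so
good-quality calls sit near 30 dB peak SNR. Degradations: clipping hard-limits
at 0.5 full scale; the low-amplitude scenario attenuates by −15 dB, chosen so
attenuated calls remain *partially* detectable (the fragment regime the
semi-automated protocol exists to repair) rather than disappearing below the
energy gate entirely; overlaid scenes superimpose unit pairs at half-unit
offset and cross-link the annotations. Zips appear only in good quality, as
in the archive material. Per-type acoustic parameters (durations, bands,
sweeps, modulation) are this package's own reconstruction from the
repertoire's qualitative descriptions and are fully configurable; the short
whistle's sweep distribution is given a steep tail so its extreme variants
grade into the zip, as natural transitional calls do.

The synthetic material is *not* acoustically realistic beyond what the
pipeline contracts need: no vocal-tract model, no reverberation or room
acoustics, no harmonics, no animal movement, and noise events are a single
family of band-limited bursts rather than the zoo of real disturbances.
Green tests therefore demonstrate that the algorithms implement the intended
behaviours and orderings (profile specialisation, degradation ordering,
cleanup monotonicity, the rare-class regime), not that any particular field
recall would be achieved on real recordings. Low-frequency call types
(Grunt, Croak) fall below the 5 kHz analysis band and are out of scope.

## Problem sizes

The defaults of `pipeline_config()` are the study conditions themselves
(50/10/10/10 standardized units, 10 experimental sessions, 891/598 denoiser
examples, a classifier training set shaped like the archive's table,
k-means with max 50 clusters and 100 restarts). The test suite and
`scripts/acceptance.R` run the same studies at desk scale as the package's
own choice of demonstration size: 8 good / 5–6 degraded units per type, 10
experimental sessions of 18 calls and 5 noise events, 140/90 denoiser and
328 classifier examples, elbow search to k = 15 with 20 restarts. All
qualitative regimes asserted by the tests are stable across seeds at these
sizes.

## Known limitations

* The detector is a deterministic energy/tonality segmenter standing in for
  a learned image detector; it shares the observable failure modes
  (fragments, clusters, noise hits) but none of a learned detector's
  generalisation behaviour, so cross-profile recall of a *non-intended*
  profile is essentially zero here rather than merely lower.
* Features describe the peak-amplitude contour only; there is no harmonic
  or fundamental-frequency tracking.
* The reviewer simulation corrects fragment/cluster/overlaid boxes
  perfectly; a human corrects "if possible". Semi-automated scores are
  therefore an upper bound on reviewer repair.
* Dynamic-time-warping clustering is out of scope.

```{r example}
cfg <- pipeline_config(seed = 1)
m1 <- run_model1(cfg, verbose = TRUE)
m1$scenario_summary
m2 <- run_model2(cfg, model1 = m1)
m3 <- run_model3(cfg, model1 = m1)
autoplot(m3$kmeans)
```
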
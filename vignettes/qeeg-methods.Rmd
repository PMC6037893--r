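---
title: "Quantitative EEG features, PLI networks and OOB classification: methods"
author: "qeegtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG features, PLI networks and OOB classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegtools)
```

## The problem

Resting-state EEG separates dementia with Lewy bodies (DLB) from
Alzheimer's disease (AD) better than most inexpensive tests: DLB shows
diffuse slowing (more delta/theta power, a lower dominant rhythm), weaker
alpha-band functional connectivity, and a less hub-dominated network
backbone. `qeegtools` implements the complete quantitative pipeline behind
that comparison — from a 21-channel 10-20 recording to an ordered
25-feature vector per subject and an out-of-bag random-forest
classification with variable-importance scores — together with a synthetic
cohort generator that provides ground truth for every stage.

## Pipeline and conventions

**Units and geometry.** Samples are microvolts, channels in rows, time in
seconds; the default montage is the 21-electrode 10-20 set (Fp2, Fp1, F8,
F7, F4, F3, A2, A1, T4, T3, C4, C3, T6, T5, P4, P3, O2, O1, Fz, Cz, Pz) at
500 Hz. All 21 recorded channels stay in the analysis by default (the
lowest/mean/highest feature reductions run over 21 channels);
`montage1020(exclude = c("A1","A2"))` restricts to the 19 scalp positions.

**Source derivation.** `applySourceDerivation()` re-references each channel
to the unweighted mean of its montage neighbors, computed from the original
signals (a Hjorth-style local Laplacian). The neighbor table is a
nearest-neighbor adjacency on the 10-20 grid, shipped both in code and as
editable YAML (`inst/extdata/montage_1020.yaml`). The classical source
derivation admits distance weights; since no canonical weight set exists
for the 21-channel clinical montage we use the unweighted mean, the
simplest defensible reading, and make the whole table configurable. Any
spatially uniform component is removed exactly — the property the tests
assert.

**Bands and filtering.** Six bands partition 0.5–48 Hz: delta (0.5–4),
theta (4–8), alpha-1 (8–10), alpha-2 (10–13), beta (13–30), gamma
(30–48 Hz). Filtering is a zero-phase forward–backward Butterworth
band-pass (order 4 each way). The filter contract, not the realization, is
normative: unit gain (±5%) at band centers, at least 20 dB one octave
outside either edge; both hold with margin for every band at 500 Hz.
Spectral-bin membership is `lo < f <= hi`, so adjacent bands share no bin
and a line component exactly at a printed band edge (e.g. 10 Hz, the
alpha-1/alpha-2 boundary) counts toward the band whose range ends there.

**Epochs.** Quantitative analysis runs on four artifact-free epochs per
subject. Visual epoch selection is replaced by explicit offsets (evenly
spaced by default). The default epoch length is 8 s: four 8-s epochs cut
into 2-s pieces give exactly the sixteen sub-epochs the peak-frequency
variability is defined over, which is the arithmetic that reconciles
"approximately 10 s" epochs with sixteen pieces. Epoch operations never
touch sample values, only boundaries; a trailing remainder shorter than one
piece is discarded.

**Spectra.** `powerSpectrum()` is a Welch average: 2-s segments, 50%
overlap, mean periodogram over all segments of all epochs, normalized so
integrated density equals time-domain variance (Parseval, tested at ±5%).
The 2-s segment fixes the 0.5 Hz resolution. The default taper is
rectangular: the band edges are commensurate with the 0.5 Hz grid, so
on-grid lines land in a single bin and never leak across a band boundary,
whereas any cosine taper smears a band-edge line into the neighboring band
(about 13% of its power for Hamming). For signals dominated by strong
off-grid lines, `window = "hamming"` or `"hann"` is available. Relative
band power divides by the 0.5–48 Hz broadband total by default —
published five-band fractions sum to ≈0.89, implying gamma sat in the
denominator even though gamma itself is not analyzed further —
configurable to 0.5–30 Hz.

**Peak frequency.** Per channel, the argmax of the density inside a search
range; the global value is the argmax of the channel-averaged spectrum
(one of two defensible readings of a "global" peak; averaging per-channel
argmaxes is the other, and the choice is documented rather than silent).
The default range is 4–13 Hz: dementia cohorts place the dominant rhythm
in the theta–alpha range, and a full-range argmax would lock onto delta in
slowed records. Ties break toward the lower frequency, deterministically.
Variability is the standard deviation of the global peak over the sixteen
2-s pieces, with the population divisor n (the sample divisor is a flag;
nothing in the definition of "SD over 16 epochs" fixes one, so the choice
is explicit).

**Theta/alpha ratio.** `theta / (theta + alpha1 + alpha2)` on channel-mean
relative powers — a bounded index of slowing in [0,1].

**Phase Lag Index.** For two phase series, `PLI = |mean sign sin(Δφ)|`;
`sign(0) = 0`, which is forced by the requirement that a strictly zero-lag
relation scores exactly 0 (this is what makes the PLI insensitive to
volume conduction). Phases come from the FFT-based analytic signal after
filtering to 8–13 Hz (alpha-1 and alpha-2 as one band, as printed for the
connectivity analysis). The first and last 0.25 s of every epoch are
excluded from the sign average to suppress filter and Hilbert edge
transients; the margin is configurable. PLI is computed per epoch and the
matrix averaged over epochs — per-epoch averaging matches standard
practice, and for stationary couplings the two orders agree. The estimator
is tested against a literal sample-by-sample loop at 1e-12.

**Spanning tree.** The network backbone is the *maximum*-weight spanning
tree over PLI weights (equivalently the minimum spanning tree over
`1 - PLI`): the backbone must retain the strongest connections, which is
the established convention in this literature — minimizing raw PLI would
keep the weakest links and invert the meaning of every topology metric.
Kruskal's greedy algorithm with ties broken by ascending node-index order
makes results platform-independent; an all-equal matrix still returns a
tree (pure tie-break order) flagged `degenerate`. With N nodes, M = N−1
edges, L leaves, diameter d (in edges) and maximum normalized betweenness
BC_max, the four metrics are `max degree / M`, `L / M`, `d / M` and
`L / (2 M BC_max)`. These normalizations reproduce the magnitude of
published group values (leaf fraction ≈ 0.55, highest degree ≈ 0.2) and
give closed forms the tests pin down: a 21-node star scores 1, 1, 0.1,
0.5; a path scores 0.1, 0.1, 1. The two-node tree is degenerate under
these formulas (every node is a leaf, no betweenness) and is defined to
score 1 throughout. The diameter is computed and reported but is not a
classifier feature.

**Feature vector.** 25 features in a fixed order: lowest/mean/highest
relative power (delta, theta, alpha-1, alpha-2, beta), lowest/mean/highest
peak frequency, theta/alpha ratio, lowest/mean/highest PLI, then the
tree's highest degree, leaf number and hierarchy. Gamma power never enters
the classifier.

**Classifier.** `randomForestOOB()` wraps `randomForest` with a bootstrap
of size ⌈2n/3⌉ drawn *with replacement* — the explicit, if unusual,
description of the published procedure; `conventionalBootstrap = TRUE`
restores the standard size-n bootstrap, since the published wording may
simply paraphrase it. Defaults: 1000 trees, `mTry = floor(sqrt(p)) = 5`
for 25 features (the published analysis names nTree and mTry without
values), Gini splits, trees grown to purity. Each subject is predicted by
the trees whose bootstrap excluded it (out-of-bag), so the error estimate
needs no held-out set; VIMP is permutation importance, the unscaled mean
decrease in OOB accuracy. Subjects never out of bag (pathological at tiny
n) are flagged and excluded from the metrics. Runs are deterministic given
the seed.

**Group statistics.** One-way ANOVA and Kruskal–Wallis per feature, with
Bonferroni-multiplied pairwise post-hoc tests (capped at 1). All-constant
input returns F = 0, p = 1 rather than the 0/0 indeterminate.

## The synthetic generator

No patient EEG accompanies the method, so validation runs on generated
cohorts with known ground truth. Each channel is the sum of

1. a sinusoid at the dominant frequency carrying `rhythmShare` (default
   0.5) of its band's variance fraction — enough line power to define a
   peak, enough surrounding noise that phases wander and PLI stays
   informative;
2. per-band Gaussian noise, built by passing white noise through the *same*
   zero-phase band-pass filters the analysis uses (generator and analyzer
   agree on band edges by construction) and scaled so the per-band variance
   fractions meet the requested budget exactly;
3. white observation noise of the requested SD (the structured variance is
   normalized to 1, so `noiseSd` reads as a relative level).

Coupled pairs share the dominant-rhythm source: the target channel mixes
in the source channel's sinusoid with a constant phase offset (`lag`) and
weight `strength`, then is rescaled to keep its variance budget.
Implementing the lag as a phase offset rather than a whole-signal delay
makes the PLI oracle analytic: constant lag with `sin(lag) != 0` gives
PLI exactly 1 in the noise-free case, zero lag exactly 0. The coupling
source sits at the subject's dominant frequency — one consequence is that
theta-dominant subjects contribute little alpha-band PLI even when
nominally coupled, which matches the clinical direction of the
DLB-versus-AD contrast.

Seeding is hierarchical and counter-based: subject k of a cohort draws its
seed as `cohortSeed + 104729·k` (jitter uses a parallel offset stream), so
adding subjects never perturbs existing ones, and generation is
bit-identical across runs and platforms given the spec (R's default
Mersenne-Twister).

**Archetypes.** `dlbTemplate()`, `adTemplate()` and `mixedTemplate()`
encode the published group means as generator defaults: DLB-like
(dominant 6.9 Hz; fractions delta 0.41, theta 0.34, alpha-1 0.07, alpha-2
0.04, beta 0.06; weak coupling 0.15), AD-like (8.4 Hz; 0.32 / 0.18 /
0.15 / 0.09 / 0.15; coupling 0.4) and mixed (6.9 Hz, intermediate). The
remainder of each budget goes to gamma, closing the variance sum. These
are emulations of group-level statistical structure, not reproductions of
patient data. Cohort defaults jitter the dominant frequency (SD 0.5 Hz),
band fractions (SD 0.02, renormalized), coupling strength (SD 0.05) and
noise level (SD 0.05) — moderate between-subject spreads chosen once to
keep cohorts heterogeneous but separable at n = 20 per group.

**What the generator does not emulate:** eye/muscle artifacts, FIRDA
morphology, sleep-stage drift, nonstationarity, volume conduction through
a head model, or 1/f broadband structure. Passing tests therefore
demonstrate correctness of the estimators and the direction of group
contrasts under controlled conditions — not clinical performance. The
published classification accuracies (85% pure-DLB vs AD, 74% mixed vs AD,
52% DLB/AD+ vs DLB/AD−) derive from unavailable patient recordings and
are intentionally not reproduction targets; what the synthetic analogue
mirrors is their *structure* — near-ceiling accuracy on a genuinely
separated contrast, chance-level accuracy on exchangeable cohorts.

## Numerical choices and degenerate inputs

* Filters: Butterworth order 4, forward–backward; stable in double
  precision down to the delta band at 500 Hz (verified numerically).
* A second pass of the same band-pass changes *in-band* RMS by under 5%;
  total RMS drops slightly more because transition-skirt energy is
  removed, which is why the idempotence check integrates the PSD over the
  band.
* Analytic-signal phases are undefined for constant signals — error, not
  NaN. Zero total spectral power in the denominator range is likewise an
  error.
* PLI edge margin 0.25 s per epoch end; at 8-s epochs this discards 6% of
  samples.
* The finite-sample PLI null is not zero: 21 independent white-noise
  channels at 4 × 8-s epochs average ≈ 0.109 in the alpha band (frozen as
  a regression reference); uncorrelated-phase nulls at n = 1e5 samples sit
  below 0.02.
* Tie-breaks: spectral peak ties go to the lower frequency; spanning-tree
  weight ties to the lower node-index pair.
* EDF output is 16-bit with a symmetric per-channel physical range; the
  header's ASCII physical-range fields are re-parsed before scaling so the
  writer and any reader use bit-identical calibration. Round-trip error is
  at most one quantization step.

## Problem sizes used in validation

The test suite and the acceptance script regenerate everything from code:
cohorts of 20 subjects per archetype (21 channels, 4 × 8-s epochs),
20-seed averages for stochastic properties (band-fraction recovery,
coupling monotonicity, classifier contrasts), 100 random 6-node matrices
against exhaustive spanning-tree enumeration, and 1e5-sample phase nulls.
These sizes give stable Monte-Carlo estimates at a few minutes of total
runtime on one core.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
co <- archetypeCohort("dlb", nSubjects = 3, seed = 7)
subjects <- generateCohort(co)
res <- analyzeSubject(subjects[[1]]$recording)
res$spectral
res$tree
round(res$features[c("theta_power_mean", "theta_alpha_ratio",
                     "pli_mean", "mst_degree_highest")], 3)
```

## Known limitations

* The Hjorth neighbor sets and the original software's exact MST
  normalizations are not published; ours are documented conventions that
  reproduce the printed magnitudes, not certified re-implementations.
* Whether the original "global peak frequency" averaged spectra or
  argmaxes, and whether PLI pooled phases across epochs, is unknown; both
  alternatives are implemented or noted above.
* The generator's stationary narrowband-plus-noise model is far simpler
  than cortical dynamics; directional group results on synthetic cohorts
  are a necessary, not sufficient, check of clinical validity.
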
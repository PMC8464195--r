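---
title: "Methods: HPTLC chemometrics for honey adulteration detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HPTLC chemometrics for honey adulteration detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hptlcauth)
```

## The problem and the data model

A honey diluted with sugar syrup keeps a plausible HPTLC organic-extract
fingerprint — dilution only scales band intensities down — so fingerprints
alone cannot prove adulteration. The workable signal is compositional:
rice, corn and glucose syrups carry quantifiable maltose, golden, treacle
and maple syrups carry quantifiable sucrose, and pure honeys carry
essentially neither. This package models a sample as

* four sugar quantities (fructose, glucose, maltose, sucrose) on the
  quantification scale of the study data (dynamic range 0 to ~2,000), and
* a set of organic-extract bands, each a `(channel, Rf, AU)` triple, where
  the channel is one of four imaging conditions (254 nm and 366 nm before
  derivatisation, transmittance white light and 366 nm after), Rf in
  `[0, 1]` and AU a normalised peak-height intensity in `[0, 1]`.

The full design is 68 samples: 2 honeys, 6 syrups, and 60 blends (every
honey x syrup pair at 10, 20, 30, 40, 50% w/w).

## Synthetic study generator

`generate_study()` exists so every downstream stage is testable without
instrument data. Its defaults are fixed, documented stand-ins chosen for
realism, not fits to any measurement:

* Honeys are fructose/glucose dominant with trace maltose and zero
  sucrose. Jarrah is given a markedly higher fructose/glucose ratio
  (1050/520) than Manuka (820/700), mirroring the documented compositional
  contrast between the two honeys; this is what gives the sugars-only
  classifier its honey-identity signal.
* Maltose-rich syrups carry 420–700 units of maltose (GLU additionally
  glucose-heavy), sucrose-rich syrups 650–1,450 units of sucrose (maple
  by far the highest, as real maple syrup is predominantly sucrose).
* Each honey has six organic bands per channel (24 total) with AU 0.3–0.9
  and band sets that overlap only partially between the honeys. Syrups
  show at most faint traces (AU ≤ 0.15), except maple's signifying band at
  Rf 0.41 (AU 0.8 at 366 nm). This reproduces the qualitative finding that
  most syrups present no major bands.
* Blends follow the exact linear mass-fraction mixing rule for both sugars
  and band intensities over the union of parent band positions, so honey
  bands dilute monotonically with the adulterant fraction.
* Measurement noise is multiplicative truncated-Gaussian with a 5% CV on
  sugars and band intensities (`noise_scale` rescales it; 0 gives the
  noiseless mixing rule exactly).

What the generator deliberately does **not** emulate: continuous
densitogram peak shapes (each band is one point at one Rf, where real
chromatogram exports spread a band over many correlated columns), baseline
drift, and inter-batch effects. Consequences of the single-point band
representation are discussed under *Known limitations*.

## Feature matrix

Only bands with Rf in the closed window `[0.05, 0.60]` are modelled — the
published convention for these plates; closure at the boundaries was chosen
because "between" is ambiguous and dropping boundary bands would be the
more surprising behaviour. Bands are then assigned to the nearest point of
a per-channel Rf grid; two bands landing on one grid point keep the
maximum AU (a band cannot shadow a stronger co-migrating band upward).
The default grid step of 0.005 over the window gives 111 points per
channel, 448 columns with the four sugars — a desk-scale default; the
deposited study matrix had 1,253 features whose composition is not
documented, so the step is a first-class knob.

Standardisation is per-column min–max to `[0, 1]` (constant columns map to
0), with the scaling parameters retained for exact inversion. `[0, 1]` was
preferred over `[-1, 1]` because the intensity features already live there
naturally and a single range keeps the combined matrix homogeneous.

## Augmentation

`augment()` simulates plate-to-plate variability, the study's published
recipe, applied per copied row:

* every band Rf shifts by an independent draw from `Uniform(-b, +b)` with
  `b = 0.0173` Rf and is re-assigned to the nearest grid point (a uniform
  distribution is the maximum-entropy reading of a stated bound; a
  truncated Gaussian is available);
* every organic cell receives Gaussian noise with SD `1.25 x` the SD of
  that channel's values over the whole input matrix — the per-channel SD is
  the only SD the recipe describes computing;
* every sugar receives Gaussian noise with SD 5% of its value;
* negative draws are truncated to 0 rather than resampled, preserving
  independence and non-negativity.

Each input row yields `outer_repeats x inner_repeats` copies (defaults
50 x 21; the factor 21 is exposed as a parameter because only the product
`50 x 21 x 68 + 68 = 71,468` is documented, not what 21 denotes). Labels
are copied, so classes stay exactly balanced. Whether augmentation precedes
or follows standardisation is not documented either; the pipeline default
augments the raw matrix and standardises afterwards, and both orders are
supported. The order matters more than it looks: standardising *after*
augmentation stretches band-free grid columns (pure noise) to full
`[0, 1]` range, which measurably dilutes distance-based analyses — see
*Known limitations*.

## Unsupervised suite

Hierarchical clustering is average-linkage on Euclidean distances of the
standardised matrix (`stats::hclust`), reported as the full merge tree with
a cut utility. k-means (`stats::kmeans`) uses 25 random restarts by default
— the published analyses report single solutions without initialisation
detail, and restarts stabilise the `between_SS/total_SS` ratio. The elbow
criterion is operationalised as maximum perpendicular distance from the
within-SS curve to its endpoint chord, ties toward smaller k (an exactly
linear curve therefore selects k = 1). DBSCAN is implemented in the package
(no suitable dependency is installed here): a core point has at least
`min_pts` neighbours within `eps` (itself included); clusters are maximal
density-connected sets; border points join the first claiming cluster in a
canonical coordinate-sorted order, which makes results independent of input
row order — the classic formulation is not. PCA is `stats::prcomp` on the
column-centred matrix, reported as loadings, scores and explained-variance
fractions.

## Regression

Each sugar is predicted from all other columns (the other three sugars
included by default, excludable by flag). PLS1 is a NIPALS iteration with
deflation; PCR regresses the response on leading principal-component
scores. Component counts are selected by 10-fold RMSECV — pooled
out-of-fold squared residuals, fold assignment a deterministic shuffle
under the run seed, ties toward fewer components (too many components
destabilise the model). Hold-out evaluation refits on a 70/30 split
(stratified over class labels when every class has at least two samples,
otherwise simple random — with 68 singleton classes stratification is
impossible, and the original 45/23 split construction is undocumented),
with centring learned on the training partition only; a dedicated test
verifies the absence of preprocessing leakage. RMSE is reported on the
training split and RMSEP/R² on the held-out split, since which of the two
the published table reports is not stated.

## Classifier

The 68-class network is a feed-forward stack (default two ReLU hidden
layers of 128 and 64 units) with inverted dropout (0.2), softmax
cross-entropy, mini-batch Adam, and early stopping on a stratified
held-back slice of the training fold. L2 weight decay (default `1e-3`) is
part of the configuration because augmented data consist of many noisy
copies of few prototypes — exactly the regime where an unregularised
network memorises per-copy noise (we observed 99% training / 58% test
accuracy without decay, against a linear-baseline 86%). Evaluation is
stratified k-fold (default 6): accuracy on each held-out fold, their mean,
and a pooled confusion matrix. Feature-set selectors mirror the three
published comparisons: the 4 sugar columns, all organic columns, or both.

Training is deterministic given the config seed. The original network's
topology, optimiser, batch size and epochs are all undocumented, so
published accuracies are reproduction targets in pattern, not bit-exactly.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on synthetic data:
the full 71,468-row augmentation is exercised for its row arithmetic, and
model evaluations use the reduced `outer_repeats = 10` augmentation
(14,348 rows), a 64/32 network, batch 512 and a 30-epoch budget — sizes
chosen so the whole suite completes in minutes on a single CPU while
leaving the measured quantities stable across seeds. Oracle checks
(exhaustive k-means partitions, brute-force average linkage, reachability
closure DBSCAN, eigendecomposition PCA) run at 6–12 points where
enumeration is exact.

## Known limitations

* **Single-point bands cap what the organic features can carry.** With AU
  noise at 1.25 x the per-channel SD, a 10-percentage-point change in
  adulteration level shifts a band by far less than one noise SD, and the
  band-poor maltose-rich syrups are nearly indistinguishable from each
  other in the organic channels. On the synthetic study the sugars-only
  classifier therefore *outperforms* the organics-only one (~74% vs ~15%
  mean 6-fold accuracy at the default noise), and the combined set (~62%)
  does not reach the near-perfect accuracy reported for the original
  dense-chromatogram data, where hundreds of correlated columns per band
  average the noise down. The ordering reported for the original study
  (sugars < organics < combined) is a property of dense fingerprints, not
  of gridded band lists; tests assert it only where the data support it.
* **Standardisation order.** Min–max scaling after augmentation amplifies
  band-free columns to full range; with low-noise augmentation the
  standardise-then-augment order preserves separability essentially
  perfectly (the package's separable-surface tests reach 100% 6-fold
  accuracy). Users comparing feature sets should be deliberate about this
  order.
* The synthetic templates are stand-ins: passing tests demonstrate the
  pipeline's correctness and the qualitative published patterns
  (marker-sugar structure, cluster structure, PCR needing more components
  than PLS), not quantitative agreement with any instrument.
* DBSCAN is O(n²) and intended for study-scale matrices, not for the
  71,468-row augmented data.
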
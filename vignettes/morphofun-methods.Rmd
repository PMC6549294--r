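---
title: "Morphofunctional profiling of neuronal cultures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphofunctional profiling of neuronal cultures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`morphofun` quantifies how connected a primary neuronal culture is, from two
kinds of high-content recordings:

* **fixed-culture fields** — 4-channel, multi-z fluorescence images
  (nuclear stain, dendrite marker, presynaptic and postsynaptic markers),
  from which morphological descriptors are extracted per field;
* **calcium time-lapse recordings** — a nuclear-reporter reference stack
  plus an activity movie (2 frames/s for 3 min by default), from which
  functional descriptors are extracted per recording.

Descriptors are merged with the plate layout, filtered, well-averaged
(morphology only), z-scored within experiment and replicate, and combined
into a single **connectivity score** whose weights are each descriptor's
average correlation with culture age (days in vitro, DIV). A random-forest
or LDA classifier predicts culture age from the descriptors. Because real
microscope data of this kind are rarely shareable, the package ships a
synthetic generator with complete ground truth; every stage of the pipeline
is validated against that truth.

# The morphological pipeline

Per field, on max projections of the nuclear and dendrite channels:

1. **Nuclei** are connected components above a user-set intensity
   threshold; touching nuclei are split by marker-controlled watershed on
   the distance transform, and components below a minimum area are
   discarded.
2. **Dendrites** combine a rough supra-threshold mask with a fine mask from
   multi-scale Frangi vesselness (scales 1–3 px by default); the union is
   thinned to a skeleton. Skeleton length uses unit weight for orthogonal
   steps and $\sqrt 2$ for diagonal steps; because thinning erodes each
   tube end by roughly the tube radius, the measured length adds the mean
   mask half-width back per skeleton endpoint (tip-loss compensation).
   Branch nodes are skeleton pixels whose *crossing number* (0→1
   transitions around the 8-neighborhood ring) is at least 3 — a raw
   neighbor count misreads thinning staircases as junctions — clustered so
   adjacent junction pixels count once.
3. **Neuronal vs non-neuronal nuclei**: a nucleus is neuronal when its
   projected area is at most `max_nucleus_area_um2`, its circularity
   ($4\pi A/P^2$) at least `min_circularity`, and the dendrite mask covers
   at least `min_occupancy` of its 2-px-dilated footprint. The perimeter
   $P$ is the boundary-step count scaled by $\pi/4$; without this isotropic
   correction a digitized disc has circularity $\approx 0.62$ instead of 1,
   which would put round nuclei below any sensible circularity threshold.
   A texture score (variance of the Laplacian-of-Gaussian response inside
   the nucleus, normalized by squared mean intensity) captures chromocenter
   spottiness: neuronal nuclei are small and spotty, glial nuclei large and
   flat.
4. **Search region** = dendrite mask dilated by 3 px minus neuronal-nuclei
   mask dilated by 2 px. Synaptic spots are only detected there.
5. **Spots**: on the sharpest z-slice (highest intensity sd) of the
   presynaptic channel and the *same* slice of the postsynaptic channel,
   a difference-of-Gaussians filter ($\sigma$ = 1 and 3 px) is thresholded;
   8-connected components of 4 pixels or fewer are removed (only spots
   larger than 4 px are kept).
6. **Synapses**: every (pre, post) spot pair whose footprints share at
   least 1 pixel. The synapse *count* is the number of distinct pre spots
   in at least one pair, so one pre spot overlapping two post spots is not
   double-counted. Pearson correlation of the two channels over the search
   region is reported as an intensity-based colocalization complement.

Densities are reported per 100 µm of skeleton and per µm² of dendrite
area. Descriptors computed from raw intensities carry `intensity` in their
name; they are excluded from score fitting as outlier-sensitive.

# The functional pipeline

Somata are segmented on the max projection of the nuclear-reporter
reference with the same machinery as nuclei. Raw traces are per-soma mean
intensities per frame, normalized as $\Delta F/F_0$ with $F_0$ the 10th
percentile of the raw trace — a robust choice when bursts inflate the mean.
The burst detector is a documented stand-in (the upstream assay defers to
an unpublished script): onsets are upward crossings of
$\mathrm{median} + k \cdot 1.4826\,\mathrm{MAD}$ ($k = 3$), merged within
2 s; when a sparse train has MAD 0 the sd is used as the scale. A neuron is
active with ≥ 1 burst. Network bursts are runs of 1-s bins in which at
least 50% of active neurons burst (threshold configurable). The **burst
correlation** — the headline synchrony readout — is the mean off-diagonal
entry of the pairwise Pearson correlation matrix of the normalized traces;
pairs with a constant trace contribute 0, and it is computed on continuous
traces rather than binarized trains.

# Data integration and the connectivity score

Morphology rows lacking nuclei or dendrites are dropped; nucleus records
whose projected area exceeds the per-plate mean by more than 5 sd are
debris and removed before well averaging. Morphology is averaged per well
(the technical replicate); functional rows pass through unaveraged.
Z-scores are computed within experiment × replicate; groups of one row or
zero variance yield missing values rather than fabricated z-scores.

The score model is fitted in four steps: (1) per experiment, the Pearson
correlation of each descriptor with DIV on control rows, averaged across
experiments; (2) pairwise inter-correlation on the merged control + treated
data; (3) ranking by |average DIV correlation|; (4) top-down retention
skipping any descriptor with |inter-correlation| > 0.75 to an already
retained one. Intensity descriptors are excluded up front. The score of a
row is $\sum_i w_i z_i / \sum_i |w_i|$ over the selected descriptors
present in that row; renormalizing by the weights actually present keeps
missing values from biasing the scale, and ranking by |r| while weights
keep their sign lets anti-correlated descriptors (neuronal count falls
with age) pull the score in the right direction. Inter-correlations are
computed on z-scores for scale invariance; whether the upstream procedure
used raw or standardized values is not documented, and Pearson is used for
both correlation types to match the z-score framework.

PCA runs on the z-score matrix (`stats::prcomp`). Group comparisons use
pairwise two-sided Wilcoxon rank-sum tests with Bonferroni correction
(family = one descriptor's pairwise comparisons), with Shapiro–Wilk and
Bartlett checks reported alongside.

# Culture-age classification

Rows are split into a stratified 2/3 training and 1/3 test set. The random
forest is a compact CART forest (gini splits, bootstrap resampling, `mtry`
features per split, majority vote) implemented in the package's compiled
code because no forest package is available in the target environment; the
number of trees ({100, 250, 500, 1000}) and `mtry` are chosen by stratified
10-fold cross-validation on the training set, growing the largest forest
once per fold and evaluating nested sub-forests. The ambiguous "number of
descriptors" hyperparameter is implemented as features-per-split. LDA
(`MASS::lda`) uses the same split; descriptors constant within every class
are excluded from it. Classification uses raw descriptor values, matching
the upstream choice. The seed is recorded in the fitted object.

# The synthetic world

The generator states a down-scaled but structurally faithful culture on a
256 × 256 px lattice (0.149 µm/px bookkeeping retained for unit
conversions; geometry is down-scaled relative to a real 40× field so a
small field holds a workable network):

* **Nuclei**: neuronal nuclei are small discs (radius 6 px) with 3–5
  chromocenter blobs (high texture); glial nuclei are larger (11 px) and
  flat. Placement keeps nuclei disjoint so truth counts are unambiguous.
* **Dendrites**: random binary trees grown from each neuronal soma with
  curvature-perturbed unit steps, branch spread 0.7–1.2 rad, rendered as
  tubes of Gaussian cross-section (σ = 2 px). Trees near the border can
  exit early, so growth restarts from random somata until the stated total
  length budget is rendered. The **truth length** is the centerline length
  of the *union* tube network at its FWHM half-width: where tubes merge at
  bifurcations or crossings the rendered network really has one
  centerline, so a summed path length would overstate what any observer of
  the image could measure.
* **Puncta**: 2-D Gaussians (σ = 1.4 px) anchored on dendrite centerlines,
  so typical segmented areas are 5–15 px — above the 4-px filter. True
  synapses place a post punctum within 1 px of a pre punctum; same-channel
  puncta keep ≥ 6 px separation (synapse sites ≥ 8 px, absorbing the ±1 px
  jitter of their post partners) and non-synaptic puncta stay ≥ 5 px from
  the opposite channel, making the ≥ 1 px overlap truth unambiguous.
* **Stack and noise**: ≥ 3 z-slices; the middle slice is in focus and
  neighbors are blurred and dimmed. Poisson shot noise plus Gaussian read
  noise (sd 15 a.u. against amplitudes of 500–900 over background 50), a
  standard fluorescence model. `noiseless()` switches both off.
* **Calcium**: a Poisson network event train; each neuron adopts each
  network event with probability `synchrony_fraction` and fires
  independent bursts at the complementary rate, so the per-neuron rate is
  synchrony-invariant, `synchrony_fraction = 1` gives identical trains and
  0 gives independence. Transients rise instantaneously and decay with
  τ = 1.5 s (fast indicator regime). Movies render somata as discs whose
  intensity follows baseline × (1 + ΔF/F).
* **Maturation ramps** (`maturation_model()`, default DIV 3–18): dendrite
  length rises strictly; puncta counts scale with dendrite length times a
  ramped linear density (presynaptic rises early then plateaus,
  postsynaptic gradually, synapses rise and plateau late); neuron count
  declines slowly; synchrony rises after an onset near DIV 8. All ramps
  are deterministic.
* **Descriptor-table simulator** (`simulate_descriptor_table()`) bypasses
  rendering: well-level descriptors are the ramp-implied expectations with
  multiplicative noise (CV 0.12 for morphology), per-experiment batch
  factors, and deliberately noisier functional descriptors (CV 0.25–0.4) —
  live recordings of a few neurons are far more variable well-to-well than
  fixed-field morphology, which is also why several functional descriptors
  survive the 0.75 inter-correlation filter instead of being shadowed by
  dendrite density. Intensity descriptors are age-independent with
  occasional 4× outliers, the behavior that motivates their exclusion.

What a green test does **not** establish: the generator has no optical PSF,
no chromatic aberration (a 1-px shift applied in tests stands in for it),
no spatially varying background, no overlapping nuclei at real plating
densities, and its SNR is chosen for testability; recovery rates on real
microscope data will be worse and threshold defaults must be retuned per
assay (every threshold is a config key).

`degrade_descriptors()` shifts one descriptor class toward its mean at the
youngest age in the table — the immature, less-connected phenotype — which
is the directionality the score is designed to detect; sensitivity is
assessed by appending a degraded copy of the table as a treated arm and
z-scoring jointly (a whole-table affine shift would cancel in the
z-scores).

# Numerical choices and degenerate inputs

* 8-connectivity throughout (components, skeleton analysis), the common
  high-content convention.
* Chamfer (1, √2) distance transform; watershed markers are its local
  maxima within a 4-px radius.
* Sharpest-slice ties resolve to the lowest index; Pearson correlation of
  a constant channel is defined as 0; an empty colocalization region is an
  error.
* Nuclei touching the image border are counted but excluded from shape
  statistics (their area and perimeter are truncated).
* Fields with zero dendrite emit missing densities and are dropped by
  `filter_fields()` rather than producing infinities.
* Second-derivative Gaussian kernels are DC-normalized so constant images
  produce exactly zero vesselness.
* All generators draw from one seeded RNG per call and restore the
  caller's RNG state; identical (parameters, seed) give bit-identical
  output, including the written TIFFs.

# Known limitations

The burst detector and ΔF/F₀ normalization are documented stand-ins for an
unpublished upstream analysis; both are config-exposed. The descriptor set
covers every descriptor named in the assay's text and figures but not an
exhaustive vendor list; the table format is extensible (any numeric
non-metadata column is a descriptor). The minimal TIFF codec handles only
uncompressed little-endian grayscale baseline files — sufficient for the
package's own interchange format, not arbitrary microscope exports.
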
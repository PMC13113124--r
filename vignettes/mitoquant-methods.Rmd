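---
title: "Methods: mitochondrial morphometry, mitophagy colocalization and expansion-microscopy quantification"
author: "mitoquant"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mitoquant)
```

# Scope and model

`mitoquant` implements three image-quantification pipelines and their
supporting statistics:

1. **Per-cell mitochondrial morphometry** from thin confocal z-stacks
   (3 planes, 0.1 µm z-step): membrane-potential-dependent intensity,
   object count, per-object area, and a fragmented / fused phenotype
   call.
2. **Object-based mitophagy colocalization**: the percentage of
   mitochondria positive for LC3 inside a 30 µm neurite segment.
3. **3D expansion-microscopy (ExM) quantification** of protein
   clusters (acquired at a 1 µm z-step on the expanded gel) and their
   association with the TOM20-defined mitochondrial network, reported
   at biological scale after gel-expansion calibration.

All containers are S4 classes carrying physical calibration
(`ImageStack`, `BinaryMask`, `LabeledObjects`, ...); every measurement
is in micrometres. A synthetic-scene generator with exact ground truth
(`generateMitoScene`, `generateColocScene`, `generateExmScene`,
`generateNeuronScene`) drives all validation.

# The confocal measurement sequence

For each cell, `mitoPipeline` applies, in order: a median z-projection
of the mitochondrial channel; a disk median filter of radius 1 px; a
white top-hat of radius 5 px (image minus its grayscale opening with a
discrete Euclidean disk), which removes slowly varying background while
preserving the thin, bright mitochondrial structures; Triangle
auto-thresholding of the filtered image; and connected-component
particle analysis at 8-connectivity. The binary mask is defined on the
*filtered* image, while mean fluorescence intensity is measured on the
*unfiltered* projection within that mask — the potential-dependent
quantity must not be distorted by background normalization. Objects
smaller than `min_size_vox` (default 4 px) are discarded as shot-noise
specks; this size filter is an artifact-level default, not part of the
original protocol, and can be set to 0.

## Triangle thresholding

The variant is fixed precisely so results are reproducible: a 256-bin
histogram over the image's min–max range; counts normalized by the
peak count (making the choice invariant to uniform count rescaling);
the chord drawn from the peak bin to the farthest nonzero bin on the
longer-tail side; the threshold taken at the bin with maximum
perpendicular distance to that chord, ties resolving to the lowest
bin, and the returned intensity at the bin center. Foreground is
strictly greater than the threshold. A constant image has no
threshold and raises a "degenerate histogram" error rather than
guessing.

Triangle assumes a dominant background mode with a decaying tail. On
top-hat images whose background noise lobe is wide relative to the
zero-intensity atom, the algorithm can lock onto the cliff right after
the zero bin and threshold far too low — a property of the algorithm,
not of this implementation (verified bin-for-bin against an exhaustive
distance-maximization oracle). This matters for how the synthetic
scenes are parameterized (below), and it is why `exmPipeline` accepts
explicit numeric thresholds standing in for the interactive threshold
selection of the original ExM workflow.

## Fragmentation phenotyping

The published phenotype call was a blinded visual classification. The
automated surrogate scores each cell by the fraction of total
mitochondrial area held in objects smaller than `area_cut` (default
1.0 µm²) and calls the cell *fragmented* when the score exceeds
`frac_cut` (default 0.5). Both cuts are artifact-defined: 1 µm²
separates sub-micron puncta from multi-micron tubular networks at the
0.1 µm pixel size, and 0.5 makes the call by area majority. The score
is monotone nonincreasing under object merging, so fusing
sub-threshold fragments can never make a cell look more fragmented.

## Colocalization

Signals are discrete, so colocalization is object-based: every
connected object of `mito ∧ segment` is one mitochondrion, and it is
LC3-positive when it shares at least one voxel with the LC3 mask
(`coloc_min_overlap_vox`, configurable) — the least-assumptive rule
consistent with masked object overlap. The 30 µm segment is built by
walking a supplied neurite centerline and dilating to the neurite
width (2 µm default). A segment containing no mitochondria reports an
`empty_denominator` flag with NA percent, never a silent 0.

# Expansion microscopy

The gel's expansion factor is measured as an *area* ratio
(post-expansion gel over coverslip), but calibration applies to
lengths, so the linear factor is `sqrt(area_ratio)`;
`calibrateExpansion(..., interpretation = "linear")` covers
measurements already taken as linear ratios. `applyCalibration`
divides voxel dimensions by the linear factor and leaves intensities
untouched. After 3D Gaussian smoothing (sigma 1 voxel, configurable)
and per-channel thresholding, 26-connected components of the protein
mask are the clusters, and the mask algebra defines:

- cluster density = N / analyzed biological volume (full stack by
  default; a cell-mask restriction is a straightforward variant);
- mean cluster volume = mean per-cluster voxel volume;
- association ratio = vol(cabl ∧ mito) / vol(cabl ∧ ¬mito), a
  signal-volume reading of mitochondrial enrichment (a count-based
  reading would discard cluster size; volumes match the "ratio of
  mitochondrial to non-mitochondrial" phrasing);
- occupancy = 100 · vol(cabl ∧ mito) / vol(mito).

Degenerate cases are flagged, not silently coerced: an empty protein
mask gives density 0 with undefined volume; fully mitochondrial signal
gives an `Inf` association ratio with a flag.

# The synthetic scenes

The generator renders what each experiment needs and records exact
truth (counts, centroids, voxel supports, positive-object identities,
per-cluster volumes, soma mask, neurite centerline):

- **Punctate vs tubular mitochondria**: solid blobs (0.5 ± 0.1 µm
  diameter) or dilated random-walk polylines (4 ± 1 µm long, 0.3 µm
  wide), placed without overlap under a bounded retry budget
  (100 × n attempts, then a "scene overcrowded" error). In the thin
  3-plane fixture, objects span the stack depth so the median
  projection keeps their footprint.
- **Camera model**: optional Gaussian PSF surrogate (σ 0.1 µm), then
  Poisson photon noise plus Gaussian read noise. Peak SNR is defined
  as `A / sqrt(A + background + read²)`; `amplitudeForSNR` inverts it.
  The canonical noisy conditions (`morphologyParamsSNR`) use a dark,
  offset-subtracted background of 1 count with 0.5-count read noise —
  the regime of photon-counting confocal detection, and the regime in
  which Triangle thresholding of top-hat images has a decisive margin
  between its background cliff and the true elbow. A smooth zero-mean
  illumination relief (20% of background) keeps histograms realistic.
- **Colocalization scenes** force exactly `round(fraction · n)`
  positive mitochondria by centering an LC3 punctum on each positive
  mitochondrion; decoy puncta touch nothing. Mitochondria are placed
  within the first 30 µm of the strip so the standard segment captures
  all of them.
- **ExM scenes** are defined at biological scale (a 10 × 12.8 ×
  12.8 µm field with a central mitochondrial ellipsoid) and rendered
  at the expanded scale, so the same seed gives the *same biological
  scene* at any expansion factor — the basis of the cross-factor
  consistency checks. Clusters are solid spheres around 4 µm³; this is
  large for a protein cluster, deliberately so: at a 1 µm z-step even
  expanded nanodomains would be sub-voxel, and the recovery tests
  validate the metric definitions, not instrument resolution.

What the scenes do *not* emulate: realistic optics (vector PSF,
spherical aberration, depth-dependent blur), gel distortion fields,
autofluorescence texture, touching or branching organelles, and
cell-to-cell variability. Passing recovery tests therefore shows the
pipelines measure what they claim on resolvable, well-separated
structures — not that segmentation is robust to every real-world
artifact.

# Statistics

Biological replicates are the statistical unit: technical values are
averaged within each (condition, replicate) pair before testing.
`welchAnova` (unequal variances), `kruskalWallis` and `rmAnova`
(complete blocks required) wrap the standard R implementations;
`postHoc` provides:

- **Dunnett** against a named control. The default follows the
  Welch-ANOVA pairing: unpooled per-group standard errors with
  Satterthwaite degrees of freedom, using the minimum df across
  comparisons for the multivariate-t adjustment (conservative);
  `varEqual = TRUE` gives the classical pooled procedure, which
  cross-checks against `multcomp`.
- **Dunn** rank-based z statistics with tie correction (Bonferroni
  adjustment by default), the Kruskal–Wallis companion.
- **Tukey** HSD on a one-way fit, and **Bonferroni**-adjusted pairwise
  t tests (paired on complete blocks), for repeated-measures designs.

Normality is reported per group (Shapiro–Wilk at α = 0.05) but never
used to switch tests silently. The normalization helpers are exact
arithmetic: percent-of-vehicle anchors the vehicle mean at 100% after
background subtraction, densitometry anchors the control sample at 1
after loading-control (or total-protein) division, and the autophagic
index is the Baf A1 / untreated p62 ratio.

# Numerical choices and edge cases

- Intensities are double precision throughout; TIFF storage is 32-bit
  with a power-of-two intensity scale recorded in the JSON sidecar, so
  integer photon-count data round-trips exactly.
- Median filtering reflects at borders; grayscale opening (top-hat)
  clips its window at borders; Gaussian smoothing reflects and
  renormalizes its truncated (3σ) kernel to unit sum.
- Labels are assigned in array order of each component's first voxel,
  making labeling deterministic; all summary statistics are invariant
  to label permutation.
- Empty masks, empty denominators, degenerate histograms and
  incomplete blocks raise errors or set explicit flags; no silent
  defaults.
- Problem sizes in the tests and the acceptance script (256² × 3
  confocal fixtures, 10–50 objects, 10–20 seeds per recovery
  experiment, 1000 null simulations for the type-I calibration) are
  desk-scale choices that keep each experiment's sampling error well
  inside its decision margin.

# Known limitations

- Triangle thresholding fails on bright, flat, noisy backgrounds (the
  zero-bin cliff, above); use the threshold overrides there.
- Touching mitochondria are merged (no watershed splitting), so counts
  under-report in dense networks — the fragmentation score is designed
  to be robust to this direction of error.
- The fragmentation surrogate is calibrated on the synthetic
  phenotypes; applying it to new cell types warrants re-examining
  `area_cut` against a blinded visual sample.
- Anisotropic voxels are handled in physical measurements but
  connectivity is topological: a 26-connected diagonal step across a
  1 µm z-gap counts as connected just like a 0.1 µm xy step.
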
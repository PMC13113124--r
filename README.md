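# mitoquant

Quantitative image analysis of mitochondrial biology for fluorescence
microscopy, written for studies of mitochondrial dysfunction and
mitophagy (e.g. in Gaucher-disease cell models): per-cell mitochondrial
morphometry with automatic fragmentation phenotyping, object-based
LC3–mitochondria colocalization in neurite segments, and 3D
quantification of protein clusters and their mitochondrial association
in expansion microscopy. A synthetic-scene generator with exact ground
truth makes every pipeline testable without microscope data, and the
statistics layer provides the normalization arithmetic and
group-comparison tests such studies report.

## Who it is for

Cell biologists and imaging analysts who quantify:

- **ΔΨm and mitochondrial morphology** from MitoTracker / TOM20
  confocal stacks — mean intensity within the mitochondrial mask,
  mitochondria per cell, per-object area (µm²), and the percentage of
  cells with a fragmented network;
- **mitophagy** — the percentage of mitochondria positive for LC3
  within a 30 µm neurite segment, scored per object (≥ 1 shared voxel),
  not by pixel correlation;
- **nanoscale protein clustering** in expansion microscopy (ExM) —
  cluster density (µm⁻³), mean cluster volume (µm³), the ratio of
  mitochondrial to non-mitochondrial signal, and the percentage of
  mitochondrial volume occupied, all at biological scale after
  gel-expansion calibration.

## The pipelines

**Confocal morphometry** (`mitoPipeline`), per cell:

    median z-projection → disk median filter (r = 1 px)
    → white top-hat (r = 5 px) → Triangle auto-threshold → binary mask
    → connected components (8-connectivity) → physical measurements

The mask is built on the filtered image; intensity is measured on the
unfiltered projection inside that mask. The fragmentation score is the
fraction of mitochondrial area held in objects smaller than 1 µm²; a
cell is *fragmented* when the score exceeds 0.5.

**Expansion microscopy** (`exmPipeline`): the linear expansion factor
is `sqrt(area_post / area_pre)` of the gel; voxel dimensions are
divided by it, both channels are 3D-smoothed and thresholded (Triangle
default, explicit overrides supported), and the AND-mask splits the
protein signal into mitochondrial and non-mitochondrial parts:

    association ratio = vol(cabl ∧ mito) / vol(cabl ∧ ¬mito)
    occupancy %       = 100 · vol(cabl ∧ mito) / vol(mito)

**Statistics** (`welchAnova`, `kruskalWallis`, `rmAnova`, `postHoc`):
Welch's ANOVA with Dunnett's post hoc, Kruskal–Wallis with Dunn's post
hoc, and one-way repeated-measures ANOVA with Tukey or Bonferroni post
hoc, operating on biological replicates (technical values are averaged
first). Normalization helpers express ATP luminescence as percent of
vehicle, densitometry relative to a loading control, and the autophagic
index as the Baf A1 / untreated p62 ratio.

## Worked example

```r
library(mitoquant)

# a synthetic field of 50 punctate mitochondria with known truth
sc <- generateMitoScene(morphologyParams(nObjects = 50L), seed = 1)
m  <- mitoPipeline(sc$stack, "mito")
m
#> MitoMorphometry [cell]
#>   n = 50 | mean area = 0.711 um^2 | mean intensity = 39.32
#>   fragmentation: fragmented (score 0.943 )
```

The pipeline recovers all 50 objects. With the default 0.1 µm blur the
Triangle threshold sits low, so each mask object includes the blur
skirt around its 0.5 µm blob (hence mean areas of ~0.7 µm² rather than
the nominal ~0.2 µm²); 94% of the mitochondrial area still lies in
sub-µm² objects, so the cell is scored fragmented.

```r
# mitophagy: 4 of 10 mitochondria carry an LC3 punctum
cc <- generateColocScene(10, 0.4, seed = 7)
pM <- projectZ(cc$stack, "mito"); pL <- projectZ(cc$stack, "lc3")
seg <- segmentMask(cc$truth@extras$centerlineVox,
                   dim(getChannel(cc$stack, 1)), voxelSize(cc$stack))
colocFraction(binarize(pM, triangleThreshold(pM)),
              binarize(pL, triangleThreshold(pL)),
              BinaryMask(seg$mask@voxels[2, , ], voxelSize(cc$stack)[2:3]),
              segmentLengthUm = 30)
#> ColocResult: 4 / 10 mitochondria LC3-positive = 40 % in a 30 um segment

# expansion microscopy at a gel area ratio of 16 (linear factor 4)
ex <- generateExmScene(0.006, 4, 0.5, 4, seed = 3)
exmPipeline(ex$stack, calibrateExpansion(1, 16), thresholds = c(55, 55))
#> ExMQuant (biological scale):
#>   cluster density : 0.0061035 per um^3 ( 10 clusters in 1638.4 um^3 )
#>   mean volume     : 3.9014 um^3
#>   association     : 0.97657
#>   occupancy       : 3.9002 %
```

The recovered density (0.0061 µm⁻³) and mean cluster volume (~4 µm³)
match the generating parameters, and with half the clusters placed
inside mitochondria the association ratio sits near 1.

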
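#' @import methods
#' @importFrom stats median rnorm rpois runif aggregate oneway.test
#'   kruskal.test aov TukeyHSD t.test shapiro.test p.adjust pnorm var
#' @importFrom utils head tail combn
#' @useDynLib mitoquant, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Calibrated multi-channel z-stack
#'
#' The universal input container of the pipelines: a voxel grid indexed
#' \code{(z, y, x, channel)} together with the physical voxel size in
#' micrometres and ordered channel names. All arithmetic is done in
#' double precision regardless of the on-disk bit depth.
#'
#' @slot voxels 4D numeric array, dim \code{(nz, ny, nx, nchannel)};
#'   finite, nonnegative intensities.
#' @slot voxelSize numeric(3), \code{(dz, dy, dx)} in micrometres, all > 0.
#' @slot channelNames character, one per channel.
#'
#' @examples
#' s <- ImageStack(array(0, c(3, 8, 8, 1)), voxelSize = c(0.1, 0.1, 0.1))
#' dim(voxels(s))
#' @export
setClass("ImageStack",
  representation(voxels = "array", voxelSize = "numeric",
                 channelNames = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 4L)
      msg <- c(msg, "voxels must be a 4D array (z, y, x, channel)")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive finite values (dz, dy, dx)")
    if (length(dim(object@voxels)) == 4L &&
        length(object@channelNames) != dim(object@voxels)[4L])
      msg <- c(msg, "channelNames length must equal the channel count")
    if (any(!is.finite(object@voxels)))
      msg <- c(msg, "voxel intensities must be finite")
    if (length(msg)) msg else TRUE
  })

#' Single-plane image with pixel calibration
#'
#' Product of z-projection; carries the in-plane pixel size so that
#' downstream measurements stay physical.
#'
#' @slot pixels numeric matrix indexed (y, x).
#' @slot pixelSize numeric(2), \code{(dy, dx)} in micrometres.
#' @export
setClass("Image2D",
  representation(pixels = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0))
      msg <- c(msg, "pixelSize must be 2 positive values (dy, dx)")
    if (any(!is.finite(object@pixels)))
      msg <- c(msg, "pixel intensities must be finite")
    if (length(msg)) msg else TRUE
  })

#' Binary mask over a 2D or 3D grid
#'
#' @slot voxels logical array (y, x) or (z, y, x).
#' @slot spacing numeric physical size per axis (micrometres), matching
#'   the array dimensionality.
#' @export
setClass("BinaryMask",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    nd <- length(dim(object@voxels))
    if (!nd %in% c(2L, 3L))
      msg <- c(msg, "mask must be 2D or 3D")
    if (!is.logical(object@voxels))
      msg <- c(msg, "mask voxels must be logical")
    if (length(object@spacing) != nd || any(object@spacing <= 0))
      msg <- c(msg, "spacing must match mask dimensionality and be positive")
    if (length(msg)) msg else TRUE
  })

#' Auto-threshold result
#'
#' @slot threshold numeric intensity value.
#' @slot histogram integer 256-bin counts used by the algorithm.
#' @slot binCenters numeric intensity at each bin center.
#' @slot binIndex integer index (1-based) of the selected bin.
#' @slot method character label, e.g. "triangle".
#' @export
setClass("ThresholdResult",
  representation(threshold = "numeric", histogram = "numeric",
                 binCenters = "numeric", binIndex = "integer",
                 method = "character"),
  validity = function(object) {
    rng <- range(object@binCenters)
    if (object@threshold < rng[1] - 1e-9 || object@threshold > rng[2] + 1e-9)
      "threshold must lie within the histogram's intensity range" else TRUE
  })

#' Labeled connected components with physical measurements
#'
#' @slot labelMap integer array (2D or 3D), 0 = background, objects
#'   labeled 1..N with no gaps, ordered by first voxel in array order.
#' @slot table data.frame with one row per object: label, voxel_count,
#'   physical measure (area_um2 or volume_um3), centroid in physical
#'   coordinates, bounding box, and mean_intensity when an intensity
#'   image was supplied.
#' @slot spacing numeric physical voxel size per axis (micrometres).
#' @slot connectivity integer connectivity used (4/8 in 2D, 6/26 in 3D).
#' @export
setClass("LabeledObjects",
  representation(labelMap = "array", table = "data.frame",
                 spacing = "numeric", connectivity = "integer"))

#' Per-cell mitochondrial morphometry
#'
#' @slot cellId character identifier.
#' @slot meanMitoIntensity mean fluorescence over the mitochondrial mask,
#'   measured on the unfiltered z-projection (a.u.); NA when flagged.
#' @slot nMitochondria object count.
#' @slot perObjectAreas numeric vector of per-object areas (um^2).
#' @slot meanMitoArea mean of perObjectAreas (um^2).
#' @slot fragmentationScore fraction in [0,1] of mitochondrial area held
#'   in sub-threshold objects; NA when unclassifiable.
#' @slot fragmentationClass "fragmented", "fused_intermediate" or
#'   "unclassifiable".
#' @slot flags character vector of quality flags (e.g. "empty_mask").
#' @export
setClass("MitoMorphometry",
  representation(cellId = "character", meanMitoIntensity = "numeric",
                 nMitochondria = "integer", perObjectAreas = "numeric",
                 meanMitoArea = "numeric", fragmentationScore = "numeric",
                 fragmentationClass = "character", flags = "character"),
  validity = function(object) {
    msg <- character()
    if (object@nMitochondria != length(object@perObjectAreas))
      msg <- c(msg, "nMitochondria must equal length(perObjectAreas)")
    if (!is.na(object@fragmentationScore) &&
        (object@fragmentationScore < 0 || object@fragmentationScore > 1))
      msg <- c(msg, "fragmentationScore must be in [0,1]")
    if (length(msg)) msg else TRUE
  })

#' Object-based colocalization result
#'
#' @slot segmentLength physical length of the analyzed neurite segment (um).
#' @slot nMitoInSegment mitochondria (connected objects) in the segment.
#' @slot nLc3Positive mitochondria sharing >= 1 voxel with the LC3 mask.
#' @slot percentPositive 100 * nLc3Positive / nMitoInSegment.
#' @slot flags character quality flags ("empty_denominator" when no
#'   mitochondria fall in the segment; percent is then NA, never 0).
#' @export
setClass("ColocResult",
  representation(segmentLength = "numeric", nMitoInSegment = "integer",
                 nLc3Positive = "integer", percentPositive = "numeric",
                 flags = "character"),
  validity = function(object) {
    if (object@nLc3Positive > object@nMitoInSegment)
      "nLc3Positive cannot exceed nMitoInSegment" else TRUE
  })

#' Gel expansion calibration
#'
#' The gel's expansion factor is determined as the total area after
#' expansion relative to the area of the coverslip; the linear factor
#' applied to voxel dimensions is the square root of that area ratio.
#'
#' @slot areaPre pre-expansion area (mm^2).
#' @slot areaPost post-expansion area (mm^2).
#' @slot areaRatio areaPost / areaPre.
#' @slot linearFactor sqrt(areaRatio) by default; equal to areaRatio when
#'   the ratio is declared already-linear at calibration time.
#' @export
setClass("ExpansionCalibration",
  representation(areaPre = "numeric", areaPost = "numeric",
                 areaRatio = "numeric", linearFactor = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@areaPre <= 0) msg <- c(msg, "areaPre must be > 0")
    if (object@areaPost < object@areaPre)
      msg <- c(msg, "gel shrank: areaPost must be >= areaPre")
    if (object@linearFactor < 1) msg <- c(msg, "linearFactor must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Expansion-microscopy quantification
#'
#' The four 3D metrics, all at biological scale: cluster density
#' (clusters per um^3), mean cluster volume (um^3), the ratio of
#' mitochondrial to non-mitochondrial signal volume, and the percentage
#' of the mitochondrial volume occupied by the clustered protein.
#'
#' @slot clusterDensity clusters per um^3 of analyzed biological volume.
#' @slot meanClusterVolume mean per-cluster biological volume (um^3);
#'   NA when no clusters were detected.
#' @slot associationRatio volume(cabl AND mito) / volume(cabl AND NOT mito);
#'   Inf (with flag) when all signal is mitochondrial.
#' @slot occupancyPercent 100 * volume(cabl AND mito) / volume(mito).
#' @slot nClusters detected cluster count.
#' @slot analyzedVolume biological volume analyzed (um^3).
#' @slot flags character quality flags.
#' @export
setClass("ExMQuant",
  representation(clusterDensity = "numeric", meanClusterVolume = "numeric",
                 associationRatio = "numeric", occupancyPercent = "numeric",
                 nClusters = "integer", analyzedVolume = "numeric",
                 flags = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.na(object@occupancyPercent) &&
        (object@occupancyPercent < 0 || object@occupancyPercent > 100 + 1e-9))
      msg <- c(msg, "occupancyPercent must be in [0, 100]")
    if (object@clusterDensity < 0) msg <- c(msg, "clusterDensity must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Ground truth of a synthetic scene
#'
#' Bookkeeping recorded by the scene generators while placing objects,
#' enabling parameter-recovery tests of every downstream pipeline.
#' Voxel indices are linear indices into the (z, y, x) spatial grid.
#'
#' @slot counts named integer vector, objects per channel.
#' @slot centroidsUm list (per channel) of matrices with columns z, y, x
#'   in micrometres, biological scale.
#' @slot voxelSets list (per channel) of lists of integer voxel-index
#'   vectors, one per object (nominal support before blur/noise).
#' @slot colocFraction requested colocalizing fraction (NA when n/a).
#' @slot clusterVolumesUm3 per-cluster nominal biological volumes (um^3).
#' @slot expansionFactor linear expansion factor used for rendering (1
#'   for confocal scenes).
#' @slot phenotype per-cell phenotype label ("fragmented"/"tubular").
#' @slot noiseParams list: poisson flag, readSd, background, amplitude.
#' @slot extras list of scene-specific truth (soma mask, neurite
#'   centerline, positive-object indices, ...).
#' @export
setClass("SceneTruth",
  representation(counts = "integer", centroidsUm = "list",
                 voxelSets = "list", colocFraction = "numeric",
                 clusterVolumesUm3 = "numeric", expansionFactor = "numeric",
                 phenotype = "character", noiseParams = "list",
                 extras = "list"))

#' Parameters of the mitochondrial morphology generator
#'
#' Describes the two phenotypes the morphometry pipeline must tell
#' apart: \code{punctate} scenes are fields of small discontinuous
#' blobs (fragmented networks), \code{tubular} scenes contain long
#' interconnected tubules (fused networks).
#'
#' @slot mode "punctate" or "tubular".
#' @slot nObjects number of objects to place (>= 0).
#' @slot tubuleLength mean and SD of tubule length (um), tubular mode.
#' @slot tubuleWidth tubule diameter (um).
#' @slot blobDiameter mean and SD of blob FWHM diameter (um), punctate mode.
#' @slot intensityAmplitude peak amplitude above background (a.u.).
#' @slot backgroundLevel mean background (a.u.).
#' @slot backgroundRelief relative amplitude of a smooth zero-mean
#'   spatial background modulation (uneven illumination /
#'   autofluorescence); 0 gives a perfectly flat background.
#' @slot psfSigma isotropic Gaussian blur sigma (um); 0 disables.
#' @slot voxelSize (dz, dy, dx) in um.
#' @slot stackShape (nz, ny, nx) voxels.
#' @slot minSeparation minimum center-to-center distance (um) enforced
#'   during placement.
#' @slot poissonNoise logical, apply Poisson photon noise.
#' @slot readSd Gaussian read-noise SD (a.u.).
#' @export
setClass("MorphologyParams",
  representation(mode = "character", nObjects = "integer",
                 tubuleLength = "numeric", tubuleWidth = "numeric",
                 blobDiameter = "numeric", intensityAmplitude = "numeric",
                 backgroundLevel = "numeric", backgroundRelief = "numeric",
                 psfSigma = "numeric",
                 voxelSize = "numeric", stackShape = "integer",
                 minSeparation = "numeric", poissonNoise = "logical",
                 readSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("punctate", "tubular"))
      msg <- c(msg, "mode must be 'punctate' or 'tubular'")
    if (object@nObjects < 0) msg <- c(msg, "nObjects must be >= 0")
    if (any(object@voxelSize <= 0) || any(object@stackShape <= 0))
      msg <- c(msg, "voxelSize and stackShape must be positive")
    if (object@psfSigma < 0) msg <- c(msg, "psfSigma must be >= 0")
    if (any(c(object@tubuleLength[1], object@tubuleWidth,
              object@blobDiameter[1], object@intensityAmplitude) <= 0))
      msg <- c(msg, "physical dimensions and amplitude must be > 0")
    if (object@backgroundLevel < 0 || object@readSd < 0)
      msg <- c(msg, "backgroundLevel and readSd must be >= 0")
    if (object@backgroundRelief < 0 || object@backgroundRelief > 1)
      msg <- c(msg, "backgroundRelief must be in [0,1]")
    if (length(msg)) msg else TRUE
  })

#' Group-comparison test result
#'
#' @slot statistic test statistic (Welch F, Kruskal-Wallis H, RM-ANOVA F).
#' @slot parameter named numeric degrees of freedom.
#' @slot pValue p-value in [0,1].
#' @slot method character description.
#' @slot posthoc data.frame of pairwise comparisons (may be empty).
#' @slot nGroups number of groups compared.
#' @export
setClass("TestResult",
  representation(statistic = "numeric", parameter = "numeric",
                 pValue = "numeric", method = "character",
                 posthoc = "data.frame", nGroups = "integer"),
  validity = function(object) {
    if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
      "pValue must be in [0,1]" else TRUE
  })
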
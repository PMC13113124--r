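#' Calibrate a gel's expansion factor
#'
#' The expansion factor of a gel is determined as its total area after
#' expansion relative to the area of the coverslip. Because voxel
#' dimensions are lengths, the factor applied to them is the square
#' root of that area ratio; set \code{interpretation = "linear"} when
#' the supplied ratio has already been measured as a linear (diameter)
#' ratio.
#'
#' @param areaPre coverslip area before expansion (mm^2)
#' @param areaPost gel area after expansion (mm^2); must be >= areaPre
#' @param interpretation "area" (default; linear factor = sqrt(ratio))
#'   or "linear" (ratio used as-is)
#' @return an \linkS4class{ExpansionCalibration}
#' @examples
#' calibrateExpansion(4, 64)     # area ratio 16 -> linear factor 4
#' @export
calibrateExpansion <- function(areaPre, areaPost,
                               interpretation = c("area", "linear")) {
  interpretation <- match.arg(interpretation)
  if (areaPre <= 0 || areaPost <= 0) stop("areas must be positive")
  if (areaPost < areaPre)
    stop("gel shrank: post-expansion area is smaller than pre-expansion area")
  ratio <- areaPost / areaPre
  lf <- if (interpretation == "area") sqrt(ratio) else ratio
  new("ExpansionCalibration", areaPre = areaPre, areaPost = areaPost,
      areaRatio = ratio, linearFactor = lf)
}

#' Rescale a stack's voxel dimensions to biological scale
#'
#' Divides each voxel dimension by the calibration's linear expansion
#' factor, leaving intensities untouched, so that all downstream
#' physical measurements (volumes, densities) are reported at the
#' biological (pre-expansion) scale.
#'
#' @param stack an \linkS4class{ImageStack} acquired on the expanded gel
#' @param cal an \linkS4class{ExpansionCalibration}
#' @return the stack with calibrated voxel size
#' @export
applyCalibration <- function(stack, cal) {
  stopifnot(is(stack, "ImageStack"), is(cal, "ExpansionCalibration"))
  ImageStack(stack@voxels, stack@voxelSize / cal@linearFactor,
             stack@channelNames)
}

#' 3D expansion-microscopy quantification pipeline
#'
#' Applies the expansion calibration, smooths both channels in 3D,
#' thresholds each channel (Triangle by default, or explicit numeric
#' overrides standing in for interactive threshold selection), builds
#' binary masks, and computes the four metrics at biological scale:
#' \itemize{
#'   \item cluster density: clusters / analyzed biological volume
#'     (26-connected components of the protein mask);
#'   \item mean cluster volume;
#'   \item association ratio: volume(cabl AND mito) /
#'     volume(cabl AND NOT mito), the enrichment of the protein within
#'     mitochondrial regions relative to the rest of the cell;
#'   \item occupancy: 100 * volume(cabl AND mito) / volume(mito), the
#'     proportion of mitochondrial volume covered by the protein.
#' }
#' An empty protein mask yields density 0 with undefined cluster
#' volume (flag "empty_cabl_mask"); when all protein is mitochondrial
#' the association ratio is reported as \code{Inf} with the flag
#' "no_non_mito_cabl".
#'
#' @param stack two-channel \linkS4class{ImageStack} (protein, mito)
#' @param cal optional \linkS4class{ExpansionCalibration}; omit when
#'   the stack is already at biological scale
#' @param cablChannel,mitoChannel channel selectors
#' @param thresholds optional numeric(2) explicit thresholds
#'   (protein, mito) overriding the Triangle default
#' @param config processing constants, see \code{\link{defaultConfig}}
#' @param minSizeVox minimum cluster size in voxels
#'   (default \code{config$min_size_vox})
#' @return an \linkS4class{ExMQuant}
#' @export
exmPipeline <- function(stack, cal = NULL, cablChannel = 1L,
                        mitoChannel = 2L, thresholds = NULL,
                        config = defaultConfig(), minSizeVox = NULL) {
  stopifnot(is(stack, "ImageStack"))
  if (!is.null(cal)) stack <- applyCalibration(stack, cal)
  if (is.null(minSizeVox)) minSizeVox <- config$min_size_vox
  sm <- smooth3D(stack, config$smooth_sigma_vox)
  cabl <- getChannel(sm, cablChannel)
  mito <- getChannel(sm, mitoChannel)
  sp <- voxelSize(stack)

  thrOf <- function(a, override) {
    if (!is.null(override) && is.finite(override)) override
    else triangleThreshold(a)@threshold
  }
  tC <- thrOf(cabl, thresholds[1])
  tM <- thrOf(mito, if (length(thresholds) >= 2) thresholds[2] else NULL)
  mC <- binarize(cabl, tC, spacing = sp)
  mM <- binarize(mito, tM, spacing = sp)

  lab <- measureObjects(labelComponents(mC, config$connectivity_3d),
                        minSizeVox = minSizeVox)
  tab <- labelTable(lab)
  # clusters below the size cut are dropped from the volume masks too
  mC <- BinaryMask(voxels(lab) > 0L, sp)
  vol <- maskVolume(mC)
  analyzed <- prod(dim(cabl)) * prod(sp)
  flags <- character(0)

  n <- nrow(tab)
  if (n == 0L) flags <- c(flags, "empty_cabl_mask")
  inMito <- maskVolume(maskAnd(mC, mM))
  outMito <- maskVolume(maskAndNot(mC, mM))
  assoc <- if (outMito == 0) {
    if (inMito > 0) flags <- c(flags, "no_non_mito_cabl")
    if (inMito > 0) Inf else NA_real_
  } else inMito / outMito
  occ <- if (maskVolume(mM) == 0) {
    flags <- c(flags, "empty_mito_mask"); NA_real_
  } else 100 * inMito / maskVolume(mM)

  new("ExMQuant",
      clusterDensity = n / analyzed,
      meanClusterVolume = if (n > 0) mean(tab$volume_um3) else NA_real_,
      associationRatio = assoc,
      occupancyPercent = occ,
      nClusters = as.integer(n),
      analyzedVolume = analyzed,
      flags = flags)
}
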
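#' Per-cell mitochondrial morphometry pipeline
#'
#' The full measurement sequence applied to one cell: median
#' z-projection of the mitochondrial channel, 1-pixel-radius disk
#' median filter, 5-pixel-radius white top-hat to normalize labeling,
#' Triangle auto-threshold, particle analysis under 8-connectivity.
#' The mask is generated on the filtered image; the mean fluorescence
#' intensity is measured on the unfiltered projection within that mask.
#' Objects smaller than \code{config$min_size_vox} voxels are dropped.
#'
#' An empty post-threshold mask yields a zero-count morphometry with
#' undefined intensity and the flag \code{"empty_mask"} rather than an
#' error. Fragmentation is classified with
#' \code{\link{classifyFragmentation}} at the configured cuts.
#'
#' @param stack a calibrated \linkS4class{ImageStack}
#' @param channel mitochondrial channel index or name
#' @param cellRoi optional \linkS4class{BinaryMask} (2D, projection
#'   geometry) restricting the analysis to one cell
#' @param config list of processing constants, see
#'   \code{\link{defaultConfig}}
#' @param cellId identifier stored in the result
#' @return a \linkS4class{MitoMorphometry}
#' @examples
#' sc <- generateMitoScene(morphologyParams(nObjects = 8L), seed = 2)
#' mitoPipeline(sc$stack, "mito")
#' @export
mitoPipeline <- function(stack, channel = 1L, cellRoi = NULL,
                         config = defaultConfig(), cellId = "cell") {
  proj <- projectZ(stack, channel, "median")
  filt <- medianFilterDisk(proj, config$median_radius_px)
  toph <- topHatWhite(filt, config$tophat_radius_px)
  thr <- triangleThreshold(toph)
  mask <- binarize(toph, thr)
  if (!is.null(cellRoi)) {
    stopifnot(is(cellRoi, "BinaryMask"))
    if (!identical(dim(cellRoi@voxels), dim(mask@voxels)))
      stop("cellRoi geometry does not match the projection")
    if (!any(cellRoi@voxels)) stop("cellRoi is empty")
    mask <- maskAnd(mask, cellRoi)
  }
  lab <- labelComponents(mask, config$connectivity_2d)
  meas <- measureObjects(lab, intensity = proj,
                         minSizeVox = config$min_size_vox)
  tab <- labelTable(meas)
  n <- nrow(tab)
  flags <- character(0)
  if (n == 0L) {
    m <- new("MitoMorphometry", cellId = cellId,
             meanMitoIntensity = NA_real_, nMitochondria = 0L,
             perObjectAreas = numeric(0), meanMitoArea = NA_real_,
             fragmentationScore = NA_real_,
             fragmentationClass = "unclassifiable",
             flags = "empty_mask")
    return(m)
  }
  finalMask <- BinaryMask(voxels(meas) > 0L, mask@spacing)
  m <- new("MitoMorphometry", cellId = cellId,
           meanMitoIntensity = maskMeanIntensity(proj, finalMask),
           nMitochondria = n,
           perObjectAreas = tab$area_um2,
           meanMitoArea = mean(tab$area_um2),
           fragmentationScore = NA_real_,
           fragmentationClass = "unclassifiable",
           flags = flags)
  classifyFragmentation(m, areaCut = config$area_cut_um2,
                        fracCut = config$frac_cut)
}

#' Classify a cell's mitochondrial network as fragmented or fused
#'
#' Automatic surrogate for the blinded visual call: the fragmentation
#' score is the fraction of total mitochondrial area held in objects
#' smaller than \code{areaCut}; the cell is "fragmented" when the score
#' exceeds \code{fracCut}, else "fused_intermediate". The defaults
#' (1 um^2, 0.5) separate punctate from tubular synthetic phenotypes
#' and are artifact-defined, not a published criterion.
#'
#' The score is monotone nonincreasing under object merging: merging
#' two sub-cut objects into one object above the cut can only lower it.
#'
#' @param m a \linkS4class{MitoMorphometry} with >= 1 object
#' @param areaCut area threshold in um^2 (default 1.0)
#' @param fracCut score threshold in (0,1) (default 0.5)
#' @return \code{m} with fragmentation slots filled
#' @export
classifyFragmentation <- function(m, areaCut = defaultConfig()$area_cut_um2,
                                  fracCut = defaultConfig()$frac_cut) {
  stopifnot(is(m, "MitoMorphometry"))
  if (m@nMitochondria < 1L)
    stop("unclassifiable: cell has zero mitochondrial objects")
  score <- sum(m@perObjectAreas[m@perObjectAreas < areaCut]) /
    sum(m@perObjectAreas)
  m@fragmentationScore <- score
  m@fragmentationClass <- if (score > fracCut) "fragmented"
                          else "fused_intermediate"
  validObject(m)
  m
}

#' Percentage of cells with a fragmented mitochondrial phenotype
#'
#' @param cells list of \linkS4class{MitoMorphometry} objects
#' @return 100 * (# fragmented) / (# classifiable); cells flagged
#'   "unclassifiable" are excluded from the denominator
#' @export
percentFragmented <- function(cells) {
  cls <- vapply(cells, function(m) m@fragmentationClass, character(1))
  classifiable <- cls %in% c("fragmented", "fused_intermediate")
  if (!any(classifiable)) stop("no classifiable cells")
  100 * sum(cls == "fragmented") / sum(classifiable)
}

#' Soma mask from the beta-III-tubulin channel
#'
#' Triangle-thresholds the median projection of the tubulin channel,
#' keeps the largest connected component and fills its holes. When two
#' disjoint somas are present only the larger is kept (documented
#' behavior; supply a manual ROI for multi-cell fields).
#'
#' @param stack an \linkS4class{ImageStack}
#' @param tubulinChannel channel index or name
#' @return a 2D \linkS4class{BinaryMask} in projection geometry
#' @export
somaMask <- function(stack, tubulinChannel = "tubulin") {
  proj <- projectZ(stack, tubulinChannel, "median")
  thr <- triangleThreshold(proj)
  mask <- binarize(proj, thr)
  lab <- labelComponents(mask, defaultConfig()$connectivity_2d)
  tab <- labelTable(lab)
  if (nrow(tab) == 0L) stop("no foreground in tubulin channel")
  biggest <- tab$label[which.max(tab$voxel_count)]
  m <- voxels(lab) == biggest
  filled <- EBImage::imageData(EBImage::fillHull(m * 1)) > 0
  BinaryMask(matrix(filled, nrow(m), ncol(m)), mask@spacing)
}

#' Build a neurite analysis-segment mask from a centerline
#'
#' Walks the centerline until the requested physical length is covered
#' and dilates it to the neurite width, producing the binary segment
#' mask within which object-based colocalization is scored (30 um by
#' default). The mask spans all z-planes of the reference geometry.
#'
#' @param centerlineVox matrix of ordered voxel coordinates with
#'   columns (z, y, x), e.g. from a scene truth
#' @param referenceShape (nz, ny, nx) of the target grid
#' @param spacing voxel size (dz, dy, dx) um
#' @param lengthUm segment length (default 30)
#' @param widthUm full neurite width for dilation (default 2)
#' @param startOffsetUm distance along the centerline at which the
#'   segment starts (default 0)
#' @return list(mask = 3D \linkS4class{BinaryMask},
#'   lengthUm = realized length)
#' @export
segmentMask <- function(centerlineVox, referenceShape, spacing,
                        lengthUm = defaultConfig()$segment_length_um,
                        widthUm = defaultConfig()$segment_width_um,
                        startOffsetUm = 0) {
  cl <- as.matrix(centerlineVox)
  if (ncol(cl) != 3L) stop("centerline must have columns (z, y, x)")
  pos <- sweep(cl, 2, spacing, "*")
  step <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                        pos[-nrow(pos), , drop = FALSE])^2))
  cum <- c(0, cumsum(step))
  keep <- cum >= startOffsetUm & cum <= startOffsetUm + lengthUm
  if (sum(keep) < 2L) stop("centerline shorter than requested segment")
  pts <- cl[keep, , drop = FALSE]
  realized <- max(cum[keep]) - min(cum[keep])

  plane <- matrix(FALSE, referenceShape[2], referenceShape[3])
  ry <- ceiling(widthUm / 2 / spacing[2])
  rx <- ceiling(widthUm / 2 / spacing[3])
  off <- expand.grid(dy = -ry:ry, dx = -rx:rx)
  off <- off[(off$dy * spacing[2])^2 + (off$dx * spacing[3])^2 <=
               (widthUm / 2)^2 + 1e-9, ]
  for (i in seq_len(nrow(pts))) {
    yy <- pts[i, 2] + off$dy; xx <- pts[i, 3] + off$dx
    ok <- yy >= 1 & yy <= referenceShape[2] & xx >= 1 & xx <= referenceShape[3]
    plane[cbind(yy[ok], xx[ok])] <- TRUE
  }
  vol <- array(rep(plane, each = referenceShape[1]), referenceShape)
  list(mask = BinaryMask(vol, spacing), lengthUm = realized)
}

#' Object-based LC3-mitochondria colocalization in a neurite segment
#'
#' A mitochondrion is each connected object of
#' \code{mito AND segment}; it is LC3-positive when it shares at least
#' \code{minOverlapVox} voxels with the LC3 mask. The result reports
#' the percentage of positive mitochondria. Zero mitochondria in the
#' segment is reported as an \code{"empty_denominator"} flag with NA
#' percent, never silently as 0.
#'
#' @param mitoMask,lc3Mask co-registered \linkS4class{BinaryMask}s
#' @param segment \linkS4class{BinaryMask} of the analysis segment
#'   (e.g. from \code{\link{segmentMask}})
#' @param segmentLengthUm physical segment length to record
#' @param minOverlapVox positivity criterion in shared voxels
#'   (default 1, the least-assumptive object-based rule)
#' @param connectivity labeling connectivity (default by dimension)
#' @return a \linkS4class{ColocResult}
#' @export
colocFraction <- function(mitoMask, lc3Mask, segment,
                          segmentLengthUm = NA_real_,
                          minOverlapVox = defaultConfig()$coloc_min_overlap_vox,
                          connectivity = NULL) {
  checkSameGeometry(mitoMask, lc3Mask)
  checkSameGeometry(mitoMask, segment)
  inSeg <- maskAnd(mitoMask, segment)
  lab <- labelComponents(inSeg, connectivity)
  n <- nrow(labelTable(lab))
  if (n == 0L)
    return(new("ColocResult", segmentLength = segmentLengthUm,
               nMitoInSegment = 0L, nLc3Positive = 0L,
               percentPositive = NA_real_, flags = "empty_denominator"))
  lm <- voxels(lab)
  overlapLabs <- lm[lm > 0L & lc3Mask@voxels]
  counts <- tabulate(overlapLabs, nbins = n)
  pos <- sum(counts >= minOverlapVox)
  new("ColocResult", segmentLength = segmentLengthUm,
      nMitoInSegment = as.integer(n), nLc3Positive = as.integer(pos),
      percentPositive = 100 * pos / n, flags = character(0))
}
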
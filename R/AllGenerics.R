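#' Access the voxel (or pixel) data of a container
#' @param x an ImageStack, Image2D, BinaryMask or LabeledObjects object
#' @return the underlying numeric/logical/integer array
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Physical voxel size in micrometres
#' @param x a calibrated container
#' @return numeric vector of per-axis physical sizes (um)
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Channel names of a stack
#' @param x an ImageStack
#' @return character vector
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Replace channel names
#' @param x an ImageStack
#' @param value character vector, one name per channel
#' @return the modified object
#' @export
setGeneric("channelNames<-",
           function(x, value) standardGeneric("channelNames<-"))

#' Per-object measurement table
#' @param x a LabeledObjects object
#' @return data.frame, one row per labeled object
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))

#' Number of labeled objects
#' @param x a LabeledObjects object
#' @return integer count
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

setMethod("voxels", "ImageStack", function(x) x@voxels)
setMethod("voxels", "Image2D", function(x) x@pixels)
setMethod("voxels", "BinaryMask", function(x) x@voxels)
setMethod("voxels", "LabeledObjects", function(x) x@labelMap)

setMethod("voxelSize", "ImageStack", function(x) x@voxelSize)
setMethod("voxelSize", "Image2D", function(x) x@pixelSize)
setMethod("voxelSize", "BinaryMask", function(x) x@spacing)
setMethod("voxelSize", "LabeledObjects", function(x) x@spacing)

setMethod("channelNames", "ImageStack", function(x) x@channelNames)
setMethod("channelNames<-", "ImageStack", function(x, value) {
  x@channelNames <- as.character(value)
  validObject(x)
  x
})

setMethod("labelTable", "LabeledObjects", function(x) x@table)
setMethod("nObjects", "LabeledObjects", function(x) nrow(x@table))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat("ImageStack:", d[4], "channel(s),",
      sprintf("%d x %d x %d (z,y,x) voxels\n", d[1], d[2], d[3]))
  cat("  voxel size (um):",
      paste(signif(object@voxelSize, 4), collapse = " x "), "\n")
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
})

setMethod("show", "BinaryMask", function(object) {
  cat("BinaryMask:", paste(dim(object@voxels), collapse = " x "),
      "-", sum(object@voxels), "foreground voxels\n")
})

setMethod("show", "LabeledObjects", function(object) {
  cat("LabeledObjects:", nrow(object@table), "object(s), connectivity",
      object@connectivity, "\n")
  if (nrow(object@table)) print(head(object@table, 5))
})

setMethod("show", "MitoMorphometry", function(object) {
  cat("MitoMorphometry [", object@cellId, "]\n", sep = "")
  cat("  n =", object@nMitochondria,
      "| mean area =", signif(object@meanMitoArea, 4), "um^2",
      "| mean intensity =", signif(object@meanMitoIntensity, 4), "\n")
  cat("  fragmentation:", object@fragmentationClass,
      "(score", signif(object@fragmentationScore, 3), ")\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "ColocResult", function(object) {
  cat("ColocResult:", object@nLc3Positive, "/", object@nMitoInSegment,
      "mitochondria LC3-positive =",
      signif(object@percentPositive, 4), "% in a",
      object@segmentLength, "um segment\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "ExpansionCalibration", function(object) {
  cat("ExpansionCalibration: area ratio", signif(object@areaRatio, 5),
      "-> linear factor", signif(object@linearFactor, 5), "\n")
})

setMethod("show", "ExMQuant", function(object) {
  cat("ExMQuant (biological scale):\n")
  cat("  cluster density :", signif(object@clusterDensity, 5), "per um^3",
      "(", object@nClusters, "clusters in",
      signif(object@analyzedVolume, 5), "um^3 )\n")
  cat("  mean volume     :", signif(object@meanClusterVolume, 5), "um^3\n")
  cat("  association     :", signif(object@associationRatio, 5), "\n")
  cat("  occupancy       :", signif(object@occupancyPercent, 5), "%\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "TestResult", function(object) {
  cat(object@method, "\n")
  cat("  statistic =", signif(object@statistic, 6),
      "| p =", signif(object@pValue, 4), "\n")
  if (nrow(object@posthoc)) {
    cat("  post hoc:\n")
    print(object@posthoc)
  }
})

setMethod("show", "SceneTruth", function(object) {
  cat("SceneTruth:", paste(names(object@counts), object@counts,
                           sep = "=", collapse = ", "), "\n")
})
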
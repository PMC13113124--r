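#' Construct an ImageStack
#'
#' @param voxels numeric array: (z, y, x) for a single channel or
#'   (z, y, x, channel).
#' @param voxelSize numeric(3) physical voxel size (dz, dy, dx) in um.
#' @param channelNames optional character vector; defaults to
#'   "ch1", "ch2", ...
#' @return an \linkS4class{ImageStack}
#' @examples
#' s <- ImageStack(array(1, c(3, 16, 16)), c(0.1, 0.1, 0.1))
#' voxelSize(s)
#' @export
ImageStack <- function(voxels, voxelSize, channelNames = NULL) {
  if (length(dim(voxels)) == 3L)
    dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 4L)
    stop("voxels must be a 3D (z,y,x) or 4D (z,y,x,channel) array")
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(dim(voxels)[4L]))
  new("ImageStack", voxels = voxels * 1.0,
      voxelSize = as.numeric(voxelSize),
      channelNames = as.character(channelNames))
}

#' Extract one channel of a stack as a (z, y, x) array
#'
#' @param stack an ImageStack
#' @param channel integer index or channel name
#' @return 3D numeric array
#' @export
getChannel <- function(stack, channel) {
  stopifnot(is(stack, "ImageStack"))
  ch <- resolveChannel(stack, channel)
  out <- stack@voxels[, , , ch, drop = FALSE]
  dim(out) <- dim(stack@voxels)[1:3]
  out
}

resolveChannel <- function(stack, channel) {
  if (is.character(channel)) {
    ch <- match(channel, stack@channelNames)
    if (is.na(ch)) stop("unknown channel: ", channel)
    return(ch)
  }
  ch <- as.integer(channel)
  if (ch < 1L || ch > dim(stack@voxels)[4L])
    stop("unknown channel: ", channel)
  ch
}

#' Construct an Image2D
#' @param pixels numeric matrix (y, x)
#' @param pixelSize numeric(2) (dy, dx) in um
#' @return an \linkS4class{Image2D}
#' @export
Image2D <- function(pixels, pixelSize) {
  new("Image2D", pixels = as.matrix(pixels) * 1.0,
      pixelSize = as.numeric(pixelSize))
}

#' Construct a BinaryMask
#' @param voxels logical array (y, x) or (z, y, x)
#' @param spacing physical size per axis (um)
#' @return a \linkS4class{BinaryMask}
#' @export
BinaryMask <- function(voxels, spacing) {
  storage.mode(voxels) <- "logical"
  new("BinaryMask", voxels = voxels, spacing = as.numeric(spacing))
}

#' Pipeline processing constants
#'
#' The default processing configuration of the confocal and
#' expansion-microscopy pipelines: a 1-pixel-radius median filter and a
#' 5-pixel-radius white top-hat on the median z-projection, Triangle
#' auto-thresholding, particle analysis at 8-connectivity in 2D and
#' 26-connectivity in 3D, a 30 um neurite segment for object-based
#' colocalization, and fixture calibrations of 0.1 um z-step (confocal,
#' 3 planes) and 1 um z-step (expansion microscopy).
#'
#' \code{min_size_vox} (default 4) suppresses shot-noise specks; set it
#' to 0 for unfiltered particle analysis.
#'
#' @return named list of configuration values
#' @examples
#' defaultConfig()$tophat_radius_px
#' @export
defaultConfig <- function() {
  list(
    median_radius_px   = 1L,
    tophat_radius_px   = 5L,
    smooth_sigma_vox   = 1,
    threshold_method   = "triangle",
    min_size_vox       = 4L,
    connectivity_2d    = 8L,
    connectivity_3d    = 26L,
    segment_length_um  = 30,
    segment_width_um   = 2,
    confocal_z_step_um = 0.1,
    confocal_xy_um     = 0.1,
    confocal_n_planes  = 3L,
    exm_z_step_um      = 1,
    exm_xy_um          = 0.2,
    area_cut_um2       = 1.0,
    frac_cut           = 0.5,
    coloc_min_overlap_vox = 1L
  )
}
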
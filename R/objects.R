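connectivityOffsets <- function(ndim, connectivity) {
  if (ndim == 2L) {
    if (!connectivity %in% c(4L, 8L))
      stop("2D connectivity must be 4 or 8")
    g <- expand.grid(dy = -1:1, dx = -1:1)
    g <- g[!(g$dy == 0 & g$dx == 0), ]
    if (connectivity == 4L) g <- g[abs(g$dy) + abs(g$dx) == 1L, ]
  } else if (ndim == 3L) {
    if (!connectivity %in% c(6L, 26L))
      stop("3D connectivity must be 6 or 26")
    g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
    g <- g[rowSums(abs(g)) > 0L, ]
    if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, ]
  } else stop("only 2D and 3D masks are supported")
  m <- as.matrix(g)
  storage.mode(m) <- "integer"
  m
}

#' Connected-component labeling
#'
#' Labels maximal connected foreground components of a binary mask
#' under the stated connectivity (4 or 8 in 2D, 6 or 26 in 3D; defaults
#' 8 and 26, matching common particle-analysis behavior). Label order
#' is deterministic: components are numbered 1..N by the position of
#' their first voxel in array (column-major) order.
#'
#' @param mask a \linkS4class{BinaryMask}
#' @param connectivity integer; default 8 (2D) or 26 (3D)
#' @return a \linkS4class{LabeledObjects} with an unmeasured table;
#'   call \code{\link{measureObjects}} to fill measurements
#' @export
labelComponents <- function(mask, connectivity = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  nd <- length(dim(mask@voxels))
  if (is.null(connectivity))
    connectivity <- if (nd == 2L) defaultConfig()$connectivity_2d
                    else defaultConfig()$connectivity_3d
  connectivity <- as.integer(connectivity)
  off <- connectivityOffsets(nd, connectivity)
  lm <- cpp_label_components(as.logical(mask@voxels),
                             as.integer(dim(mask@voxels)), off)
  n <- attr(lm, "n_labels")
  attr(lm, "n_labels") <- NULL
  lab <- array(as.integer(lm), dim(mask@voxels))
  counts <- if (n > 0) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  tab <- data.frame(label = seq_len(n), voxel_count = counts)
  new("LabeledObjects", labelMap = lab, table = tab,
      spacing = mask@spacing, connectivity = connectivity)
}

#' Measure labeled objects in physical units
#'
#' Fills the per-object table: voxel count, physical area (2D) or
#' volume (3D) as voxel count times the voxel area/volume, physical
#' centroid, bounding box, and mean intensity when an intensity image
#' of matching geometry is supplied. Objects smaller than
#' \code{minSizeVox} voxels are removed and labels recompacted to
#' 1..N with no gaps.
#'
#' @param labels a \linkS4class{LabeledObjects}
#' @param intensity optional \linkS4class{Image2D}, numeric array or
#'   matrix matching the label map geometry
#' @param minSizeVox minimum object size in voxels (default 0)
#' @return a \linkS4class{LabeledObjects} with completed table
#' @export
measureObjects <- function(labels, intensity = NULL, minSizeVox = 0L) {
  stopifnot(is(labels, "LabeledObjects"))
  lm <- labels@labelMap
  d <- dim(lm)
  nd <- length(d)
  if (!is.null(intensity)) {
    iv <- if (is(intensity, "Image2D")) intensity@pixels else intensity
    if (!identical(dim(iv), d))
      stop("intensity image shape does not match label map")
  }
  n0 <- max(0L, max(lm))
  if (n0 == 0L) {
    tab <- emptyMeasureTable(nd, !is.null(intensity))
    return(new("LabeledObjects", labelMap = lm, table = tab,
               spacing = labels@spacing, connectivity = labels@connectivity))
  }
  counts <- tabulate(lm[lm > 0L], nbins = n0)
  keep <- which(counts >= minSizeVox)
  remap <- integer(n0)
  remap[keep] <- seq_along(keep)
  if (length(keep) < n0) {
    pos <- lm > 0L
    lm[pos] <- remap[lm[pos]]
  }
  n <- length(keep)
  idx <- which(lm > 0L)
  labs <- lm[idx]
  coords <- arrayInd(idx, d)
  cnt <- counts[keep]
  cent <- rowsum(coords, labs) / cnt
  cent <- sweep(cent, 2, labels@spacing, "*")
  bbmin <- do.call(cbind, lapply(seq_len(nd), function(a)
    vapply(split(coords[, a], labs), min, 0)))
  bbmax <- do.call(cbind, lapply(seq_len(nd), function(a)
    vapply(split(coords[, a], labs), max, 0)))
  axn <- if (nd == 2L) c("y", "x") else c("z", "y", "x")
  tab <- data.frame(label = seq_len(n), voxel_count = cnt)
  physcol <- if (nd == 2L) "area_um2" else "volume_um3"
  tab[[physcol]] <- cnt * prod(labels@spacing)
  for (a in seq_len(nd)) tab[[paste0("centroid_", axn[a], "_um")]] <- cent[, a]
  for (a in seq_len(nd)) {
    tab[[paste0("bbox_", axn[a], "_min")]] <- as.integer(bbmin[, a])
    tab[[paste0("bbox_", axn[a], "_max")]] <- as.integer(bbmax[, a])
  }
  if (!is.null(intensity))
    tab$mean_intensity <- as.numeric(rowsum(iv[idx], labs) / cnt)
  rownames(tab) <- NULL
  new("LabeledObjects", labelMap = lm, table = tab,
      spacing = labels@spacing, connectivity = labels@connectivity)
}

emptyMeasureTable <- function(nd, withIntensity) {
  axn <- if (nd == 2L) c("y", "x") else c("z", "y", "x")
  tab <- data.frame(label = integer(0), voxel_count = integer(0))
  tab[[if (nd == 2L) "area_um2" else "volume_um3"]] <- numeric(0)
  for (a in axn) tab[[paste0("centroid_", a, "_um")]] <- numeric(0)
  for (a in axn) {
    tab[[paste0("bbox_", a, "_min")]] <- integer(0)
    tab[[paste0("bbox_", a, "_max")]] <- integer(0)
  }
  if (withIntensity) tab$mean_intensity <- numeric(0)
  tab
}

#' Mean intensity within a mask
#'
#' @param img an \linkS4class{Image2D}, matrix or array
#' @param mask a \linkS4class{BinaryMask} of matching geometry
#' @return arithmetic mean of \code{img} over the mask foreground
#' @export
maskMeanIntensity <- function(img, mask) {
  stopifnot(is(mask, "BinaryMask"))
  iv <- if (is(img, "Image2D")) img@pixels else img
  if (!identical(dim(iv), dim(mask@voxels)))
    stop("image and mask geometry differ")
  if (!any(mask@voxels)) stop("empty region: mask has no foreground")
  mean(iv[mask@voxels])
}

checkSameGeometry <- function(a, b) {
  if (!identical(dim(a@voxels), dim(b@voxels)))
    stop("mask geometries differ")
  if (!isTRUE(all.equal(a@spacing, b@spacing)))
    stop("mask spacings differ")
}

#' Voxelwise mask conjunction
#' @param a,b \linkS4class{BinaryMask} objects of identical geometry
#' @return a \linkS4class{BinaryMask}
#' @export
maskAnd <- function(a, b) {
  checkSameGeometry(a, b)
  BinaryMask(a@voxels & b@voxels, a@spacing)
}

#' Voxelwise conjunction with complement (a AND NOT b)
#'
#' Together with \code{\link{maskAnd}} this partitions \code{a} exactly:
#' \code{|a AND b| + |a AND NOT b| = |a|}. Used to split a protein mask
#' into its mitochondrial and non-mitochondrial parts.
#'
#' @param a,b \linkS4class{BinaryMask} objects of identical geometry
#' @return a \linkS4class{BinaryMask}
#' @export
maskAndNot <- function(a, b) {
  checkSameGeometry(a, b)
  BinaryMask(a@voxels & !b@voxels, a@spacing)
}

#' Foreground volume (or area) of a mask in physical units
#' @param mask a \linkS4class{BinaryMask}
#' @return foreground voxel count times the voxel volume/area
#' @export
maskVolume <- function(mask) {
  stopifnot(is(mask, "BinaryMask"))
  sum(mask@voxels) * prod(mask@spacing)
}
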
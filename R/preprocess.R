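#' Z-projection of one channel
#'
#' Collapses the z-axis with a per-pixel order statistic. The median
#' projection is the pipeline's standard input image; the maximum
#' projection is used for fragmentation phenotyping.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param channel channel index or name
#' @param statistic "median" or "max"
#' @return an \linkS4class{Image2D}
#' @export
projectZ <- function(stack, channel, statistic = c("median", "max")) {
  statistic <- match.arg(statistic)
  a <- getChannel(stack, channel)
  nz <- dim(a)[1]
  if (nz < 1L) stop("stack has no z-planes")
  planes <- lapply(seq_len(nz), function(z) matrix(a[z, , ], dim(a)[2], dim(a)[3]))
  px <- if (statistic == "max") {
    Reduce(pmax, planes)
  } else if (nz == 1L) {
    planes[[1]]
  } else if (nz == 2L) {
    (planes[[1]] + planes[[2]]) / 2
  } else if (nz == 3L) {
    # median-of-3 selection network, elementwise
    pmax(pmin(planes[[1]], planes[[2]]),
         pmin(pmax(planes[[1]], planes[[2]]), planes[[3]]))
  } else {
    m <- matrix(unlist(planes), nrow = nz, byrow = TRUE)
    matrix(apply(m, 2, median), dim(a)[2], dim(a)[3])
  }
  Image2D(px, voxelSize(stack)[2:3])
}

diskOffsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

diskKernel <- function(radius) {
  r <- as.integer(ceiling(radius))
  d <- outer((-r:r)^2, (-r:r)^2, "+")
  (d <= radius^2 + 1e-9) * 1
}

#' Disk median filter
#'
#' Median within the discrete Euclidean disk of the given pixel radius
#' (distance <= radius), with mirror reflection at the image border.
#' Radius 0 is the identity. Radius 1 gives the 5-pixel cross.
#'
#' @param img an \linkS4class{Image2D} or numeric matrix
#' @param radiusPx integer radius >= 0 in pixels
#' @return same type as \code{img}
#' @export
medianFilterDisk <- function(img, radiusPx) {
  if (radiusPx < 0) stop("radius must be >= 0")
  px <- if (is(img, "Image2D")) img@pixels else img
  if (radiusPx > 0) {
    off <- diskOffsets(radiusPx)
    storage.mode(off) <- "integer"
    px <- cpp_rank_filter_median(px, off)
  }
  if (is(img, "Image2D")) Image2D(px, img@pixelSize) else px
}

#' White top-hat filter
#'
#' Subtracts the grayscale morphological opening with a discrete
#' Euclidean disk of the given radius, removing background structures
#' larger than the disk while preserving small bright objects; used to
#' normalize mitochondrial labeling before thresholding. The window is
#' clipped at the image border. Output is pointwise nonnegative and
#' never exceeds the input.
#'
#' @param img an \linkS4class{Image2D} or numeric matrix
#' @param radiusPx integer radius >= 1 in pixels
#' @return same type as \code{img}
#' @export
topHatWhite <- function(img, radiusPx) {
  if (radiusPx < 1) stop("radius must be >= 1")
  px <- if (is(img, "Image2D")) img@pixels else img
  # grayscale morphology operates on [0,1]; opening commutes with
  # positive scaling, so normalize by the maximum and restore
  m <- max(px)
  opened <- if (m <= 0) px else
    EBImage::imageData(EBImage::opening(px / m, diskKernel(radiusPx))) * m
  out <- pmax(px - opened, 0)
  if (is(img, "Image2D")) Image2D(out, img@pixelSize) else out
}

reflectIdx <- function(idx, n) {
  # mirror reflection without border repetition: (a b c | b a)
  if (n == 1L) return(rep(1L, length(idx)))
  p <- (idx - 1L) %% (2L * (n - 1L))
  ifelse(p < n, p + 1L, 2L * n - 1L - p)
}

gaussKernel1d <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

convolveAxis3d <- function(a, kernel, axis) {
  h <- (length(kernel) - 1L) %/% 2L
  n <- dim(a)[axis]
  out <- array(0, dim(a))
  for (j in -h:h) {
    idx <- reflectIdx(seq_len(n) + j, n)
    shifted <- switch(axis,
                      a[idx, , , drop = FALSE],
                      a[, idx, , drop = FALSE],
                      a[, , idx, drop = FALSE])
    out <- out + kernel[j + h + 1L] * shifted
  }
  out
}

#' Separable 3D Gaussian smoothing
#'
#' Gaussian blur applied to every channel with mirror-reflected
#' borders; \code{sigmaVox} is expressed in voxels (scalar for
#' isotropic, or (z, y, x)). Sigma 0 is the identity. The kernel is
#' truncated at 3 sigma and renormalized to unit sum.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param sigmaVox numeric >= 0, length 1 or 3
#' @return a smoothed \linkS4class{ImageStack}
#' @export
smooth3D <- function(stack, sigmaVox) {
  stopifnot(is(stack, "ImageStack"))
  if (any(sigmaVox < 0)) stop("sigma must be >= 0")
  s <- rep(as.numeric(sigmaVox), length.out = 3)
  if (all(s == 0)) return(stack)
  vox <- stack@voxels
  for (ch in seq_len(dim(vox)[4])) {
    a <- getChannel(stack, ch)
    for (axis in 1:3) {
      if (s[axis] > 0 && dim(a)[axis] > 1L)
        a <- convolveAxis3d(a, gaussKernel1d(s[axis]), axis)
    }
    vox[, , , ch] <- a
  }
  ImageStack(vox, stack@voxelSize, stack@channelNames)
}

#' Triangle auto-threshold
#'
#' Builds a 256-bin histogram over the image's intensity range and
#' selects the bin maximizing the perpendicular distance between the
#' (peak-normalized) histogram and the straight line joining the peak
#' bin to the farthest nonzero tail bin, searching on the longer-tail
#' side of the peak; ties resolve to the lowest qualifying bin. Count
#' normalization makes the choice invariant to uniform rescaling of the
#' histogram.
#'
#' @param x an \linkS4class{Image2D}, numeric matrix or array
#' @param nBins histogram bin count (default 256)
#' @return a \linkS4class{ThresholdResult}; the threshold is the
#'   intensity at the selected bin center
#' @export
triangleThreshold <- function(x, nBins = 256L) {
  v <- if (is(x, "Image2D")) x@pixels else x
  v <- as.numeric(v)
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("degenerate histogram: image has fewer than 2 distinct intensities")
  w <- diff(rng) / nBins
  bins <- pmin(floor((v - rng[1]) / w) + 1L, nBins)
  counts <- tabulate(bins, nbins = nBins)
  idx <- triangleBinFromCounts(counts)
  centers <- rng[1] + (seq_len(nBins) - 0.5) * w
  new("ThresholdResult", threshold = centers[idx],
      histogram = as.numeric(counts), binCenters = centers,
      binIndex = idx, method = "triangle")
}

#' Triangle bin selection on a raw histogram
#'
#' The geometric core of \code{\link{triangleThreshold}}, operating
#' directly on bin counts; exported so that thresholds can be computed
#' on externally built histograms.
#'
#' @param counts nonnegative numeric vector of bin counts with >= 2
#'   nonzero bins or a nonzero bin away from the peak
#' @return integer index of the selected bin
#' @export
triangleBinFromCounts <- function(counts) {
  counts <- as.numeric(counts)
  if (all(counts <= 0)) stop("degenerate histogram: empty")
  cn <- counts / max(counts)      # scale invariance
  peak <- which.max(cn)           # lowest bin on ties
  nz <- which(counts > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  if (lo == hi) stop("degenerate histogram: single occupied bin")
  if ((hi - peak) >= (peak - lo)) {
    a <- peak; b <- hi
  } else {
    a <- lo; b <- peak
  }
  cand <- a:b
  # perpendicular distance from (i, cn[i]) to the line (a,cn[a])-(b,cn[b])
  dx <- b - a; dy <- cn[b] - cn[a]
  len <- sqrt(dx^2 + dy^2)
  d <- abs(dx * (cn[cand] - cn[a]) - dy * (cand - a)) / len
  cand[which.max(d)]               # lowest candidate on ties
}

#' Threshold an image into a binary mask
#'
#' Foreground is strictly greater than the threshold.
#'
#' @param x an \linkS4class{Image2D}, a single-channel
#'   \linkS4class{ImageStack}, or a numeric array with \code{spacing}
#' @param threshold finite intensity value, or a
#'   \linkS4class{ThresholdResult}
#' @param spacing physical per-axis size, required when \code{x} is a
#'   bare array
#' @return a \linkS4class{BinaryMask}
#' @export
binarize <- function(x, threshold, spacing = NULL) {
  if (is(threshold, "ThresholdResult")) threshold <- threshold@threshold
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (is(x, "Image2D")) {
    BinaryMask(x@pixels > threshold, x@pixelSize)
  } else if (is(x, "ImageStack")) {
    if (dim(x@voxels)[4] != 1L)
      stop("binarize expects a single-channel stack; use getChannel()")
    BinaryMask(getChannel(x, 1L) > threshold, x@voxelSize)
  } else {
    if (is.null(spacing)) stop("spacing is required for bare arrays")
    m <- x > threshold
    if (is.null(dim(m))) stop("x must have dimensions")
    BinaryMask(m, spacing)
  }
}
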
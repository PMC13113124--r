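#' Run an expression under a fixed RNG seed, restoring RNG state after
#' @noRd
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Construct morphology-generator parameters
#'
#' Defaults describe the confocal fixture: a 3-plane stack with 0.1 um
#' voxels in z and xy, punctate mitochondria of 0.5 um mean diameter or
#' tubules of 4 um mean length and 0.3 um width, noise off. Amplitudes
#' are photon counts above a constant background.
#'
#' @param mode "punctate" or "tubular"
#' @param nObjects objects to place (>= 0)
#' @param tubuleLength c(mean, sd) tubule length in um
#' @param tubuleWidth tubule diameter in um
#' @param blobDiameter c(mean, sd) blob diameter in um
#' @param intensityAmplitude peak amplitude above background (a.u.)
#' @param backgroundLevel mean background (a.u.)
#' @param backgroundRelief relative amplitude (0-1) of a smooth
#'   zero-mean background modulation emulating uneven illumination;
#'   the default 0.2 keeps auto-thresholding realistic, 0 gives a
#'   perfectly flat background
#' @param psfSigma isotropic Gaussian blur sigma in um (0 = off)
#' @param voxelSize c(dz, dy, dx) in um
#' @param stackShape c(nz, ny, nx) in voxels
#' @param minSeparation minimum center separation in um during placement
#' @param poissonNoise logical, Poisson photon noise
#' @param readSd Gaussian read-noise SD (a.u.)
#' @return a \linkS4class{MorphologyParams}
#' @export
morphologyParams <- function(mode = c("punctate", "tubular"),
                             nObjects = 50L,
                             tubuleLength = c(4, 1),
                             tubuleWidth = 0.3,
                             blobDiameter = c(0.5, 0.1),
                             intensityAmplitude = 100,
                             backgroundLevel = 10,
                             backgroundRelief = 0.2,
                             psfSigma = 0.1,
                             voxelSize = c(0.1, 0.1, 0.1),
                             stackShape = c(3L, 256L, 256L),
                             minSeparation = 1.6,
                             poissonNoise = FALSE,
                             readSd = 0) {
  mode <- match.arg(mode)
  new("MorphologyParams", mode = mode, nObjects = as.integer(nObjects),
      tubuleLength = as.numeric(tubuleLength),
      tubuleWidth = as.numeric(tubuleWidth),
      blobDiameter = as.numeric(blobDiameter),
      intensityAmplitude = as.numeric(intensityAmplitude),
      backgroundLevel = as.numeric(backgroundLevel),
      backgroundRelief = as.numeric(backgroundRelief),
      psfSigma = as.numeric(psfSigma),
      voxelSize = as.numeric(voxelSize),
      stackShape = as.integer(stackShape),
      minSeparation = as.numeric(minSeparation),
      poissonNoise = isTRUE(poissonNoise), readSd = as.numeric(readSd))
}

#' Amplitude needed for a target peak signal-to-noise ratio
#'
#' Under the camera model (Poisson photon noise plus additive Gaussian
#' read noise) the noise SD at an object peak is
#' \code{sqrt(A + background + readSd^2)}; this solves
#' \code{A = snr * sqrt(A + background + readSd^2)} for the amplitude A.
#'
#' @param snr target peak SNR
#' @param background constant background level (a.u.)
#' @param readSd read-noise SD (a.u.)
#' @return amplitude (a.u.)
#' @export
amplitudeForSNR <- function(snr, background, readSd = 0) {
  v <- background + readSd^2
  (snr^2 + snr * sqrt(snr^2 + 4 * v)) / 2
}

#' Morphology parameters at a target peak SNR
#'
#' Canonical noisy imaging conditions for recovery experiments: a dark,
#' offset-subtracted background (1 photon count) with 0.5-count read
#' noise, Poisson photon noise on, and the object amplitude solved from
#' the requested peak SNR via \code{\link{amplitudeForSNR}}.
#'
#' @param snr target peak signal-to-noise ratio
#' @param mode,nObjects passed to \code{\link{morphologyParams}}
#' @param backgroundLevel,readSd camera model (defaults 1 and 0.5)
#' @param ... further arguments to \code{\link{morphologyParams}}
#' @return a \linkS4class{MorphologyParams}
#' @export
morphologyParamsSNR <- function(snr, mode = "punctate", nObjects = 50L,
                                backgroundLevel = 1, readSd = 0.5, ...) {
  morphologyParams(mode = mode, nObjects = nObjects,
                   intensityAmplitude =
                     amplitudeForSNR(snr, backgroundLevel, readSd),
                   backgroundLevel = backgroundLevel,
                   readSd = readSd, poissonNoise = TRUE, ...)
}

# -- geometric rendering helpers (voxel coordinates are (z, y, x)) -----

# runif that treats an inverted interval as an infeasible draw (NA);
# proposals with NA coordinates are rejected, not errors
boundedUnif <- function(lo, hi) if (lo >= hi) NA_real_ else runif(1, lo, hi)

# linear indices of voxels whose centers lie inside the ellipsoid of
# per-axis radius `radUm` (um) centered at continuous position `cUm`
ellipsoidSupport <- function(shape, spacing, cUm, radUm) {
  rngs <- lapply(1:3, function(d) {
    lo <- max(1L, floor((cUm[d] - radUm[d]) / spacing[d] - 1))
    hi <- min(shape[d], ceiling((cUm[d] + radUm[d]) / spacing[d] + 1))
    if (lo > hi) integer(0) else seq.int(lo, hi)
  })
  if (!all(lengths(rngs) > 0)) return(integer(0))
  ctr <- lapply(1:3, function(d) ((rngs[[d]] - 0.5) * spacing[d] - cUm[d]) / radUm[d])
  g <- expand.grid(z = ctr[[1]], y = ctr[[2]], x = ctr[[3]])
  inside <- g$z^2 + g$y^2 + g$x^2 <= 1
  if (!any(inside)) return(integer(0))
  gi <- expand.grid(z = rngs[[1]], y = rngs[[2]], x = rngs[[3]])
  zi <- gi$z[inside]; yi <- gi$y[inside]; xi <- gi$x[inside]
  as.integer(zi + (yi - 1L) * shape[1] + (xi - 1L) * shape[1] * shape[2])
}

# union of sphere supports stamped along a polyline (rows = um coords)
polylineSupport <- function(shape, spacing, pointsUm, radiusUm) {
  segs <- lapply(seq_len(nrow(pointsUm)), function(i)
    ellipsoidSupport(shape, spacing, pointsUm[i, ], rep(radiusUm, 3)))
  unique(unlist(segs))
}

# random-walk polyline in the xy plane at fixed z, reflected at margins
tubulePolyline <- function(lengthUm, startUm, extentUm, marginUm, stepUm = 0.2,
                           kappa = 0.25) {
  n <- max(2L, ceiling(lengthUm / stepUm) + 1L)
  pts <- matrix(0, n, 3)
  pts[1, ] <- startUm
  theta <- runif(1, 0, 2 * pi)
  for (i in 2:n) {
    theta <- theta + rnorm(1, 0, kappa)
    p <- pts[i - 1, ] + stepUm * c(0, sin(theta), cos(theta))
    for (d in 2:3) {
      if (p[d] < marginUm[d]) { p[d] <- 2 * marginUm[d] - p[d]; theta <- theta + pi / 2 }
      if (p[d] > extentUm[d] - marginUm[d]) {
        p[d] <- 2 * (extentUm[d] - marginUm[d]) - p[d]; theta <- theta + pi / 2
      }
    }
    pts[i, ] <- p
  }
  pts
}

# smooth zero-mean background field: two full sine periods per axis,
# so the modulation integrates to exactly zero over the grid
backgroundField <- function(shape, level, relief) {
  if (relief <= 0 || level <= 0) return(array(level, shape))
  sy <- sin(4 * pi * (seq_len(shape[2]) - 0.5) / shape[2])
  sx <- sin(4 * pi * (seq_len(shape[3]) - 0.5) / shape[3])
  plane <- level * (1 + relief * outer(sy, sx))
  array(rep(plane, each = shape[1]), shape)
}

applyCameraNoise <- function(clean, poissonNoise, readSd) {
  v <- clean
  if (poissonNoise) v[] <- rpois(length(v), lambda = pmax(v, 0))
  if (readSd > 0) v <- v + rnorm(length(v), 0, readSd)
  pmax(v, 0)
}

applyPsf <- function(arr, psfSigma, spacing) {
  if (psfSigma <= 0) return(arr)
  s <- ImageStack(arr, spacing)
  getChannel(smooth3D(s, psfSigma / spacing), 1L)
}

newSceneTruth <- function(counts, centroids, voxelSets, params = NULL,
                          colocFraction = NA_real_,
                          clusterVolumes = numeric(0),
                          expansionFactor = 1,
                          phenotype = character(0),
                          noiseParams = list(), extras = list()) {
  new("SceneTruth", counts = counts, centroidsUm = centroids,
      voxelSets = voxelSets, colocFraction = colocFraction,
      clusterVolumesUm3 = clusterVolumes,
      expansionFactor = expansionFactor, phenotype = phenotype,
      noiseParams = noiseParams, extras = extras)
}

# place n objects without voxel overlap; draws a proposal via
# `propose()` returning list(centerUm, support); bounded retries
placeObjects <- function(n, shape, propose) {
  occupied <- logical(prod(shape))
  centers <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("z", "y", "x")))
  supports <- list()
  budget <- 100L * max(1L, n)
  attempts <- 0L
  while (length(supports) < n) {
    attempts <- attempts + 1L
    if (attempts > budget) stop("scene overcrowded: placement failed after ",
                                budget, " attempts")
    cand <- propose()
    sup <- cand$support
    if (!length(sup) || any(occupied[sup])) next
    occupied[sup] <- TRUE
    centers <- rbind(centers, cand$centerUm)
    supports[[length(supports) + 1L]] <- sort(sup)
  }
  list(centers = centers, supports = supports)
}

#' Generate a synthetic mitochondrial scene with ground truth
#'
#' Renders a field of mitochondria as either small discontinuous blobs
#' (punctate / fragmented phenotype) or long random-walk tubules
#' (tubular / fused phenotype) over a constant background, optionally
#' blurred by a Gaussian surrogate PSF and corrupted by
#' Poisson-Gaussian camera noise. Objects are placed without voxel
#' overlap (bounded retries, then a "scene overcrowded" error). With
#' \code{nChannels = 2} a second channel is rendered from the same
#' geometry with an independent per-object intensity scaling, emulating
#' a potential-dependent dye next to a structural marker.
#'
#' Identical \code{(params, seed)} give bit-identical output.
#'
#' @param params a \linkS4class{MorphologyParams}
#' @param seed integer RNG seed
#' @param nChannels 1 or 2
#' @return list(stack = \linkS4class{ImageStack},
#'   truth = \linkS4class{SceneTruth})
#' @examples
#' sc <- generateMitoScene(morphologyParams(nObjects = 5L), seed = 1)
#' sc$truth
#' @export
generateMitoScene <- function(params, seed, nChannels = 1L) {
  stopifnot(is(params, "MorphologyParams"))
  validObject(params)
  withSeed(seed, {
    shape <- params@stackShape
    sp <- params@voxelSize
    extent <- shape * sp
    n <- params@nObjects

    propose <- if (params@mode == "punctate") {
      function() {
        d <- max(0.1, rnorm(1, params@blobDiameter[1], params@blobDiameter[2]))
        margin <- d / 2 + params@minSeparation / 2
        # thin optical substack: objects span the depth, so the median
        # projection keeps their full footprint
        c_um <- c(extent[1] / 2,
                  boundedUnif(margin, extent[2] - margin),
                  boundedUnif(margin, extent[3] - margin))
        if (anyNA(c_um))
          return(list(centerUm = c_um, support = integer(0), guard = integer(0)))
        rad <- c(max(d / 2, extent[1]), d / 2, d / 2)
        sup <- ellipsoidSupport(shape, sp, c_um, rad)
        grown <- ellipsoidSupport(shape, sp, c_um,
                                  rad + params@minSeparation / 2)
        list(centerUm = c_um, support = sup, guard = grown)
      }
    } else {
      function() {
        len <- max(0.5, rnorm(1, params@tubuleLength[1], params@tubuleLength[2]))
        margin <- c(0, rep(params@tubuleWidth + 0.2, 2))
        start <- c(extent[1] / 2,
                   runif(1, margin[2], extent[2] - margin[2]),
                   runif(1, margin[3], extent[3] - margin[3]))
        pts <- tubulePolyline(len, start, extent, margin)
        sup <- polylineSupport(shape, sp, pts, params@tubuleWidth / 2)
        grown <- polylineSupport(shape, sp, pts,
                                 params@tubuleWidth / 2 + params@minSeparation / 4)
        list(centerUm = colMeans(pts), support = sup, guard = grown)
      }
    }
    # guard region keeps objects separated beyond mere non-overlap
    occupied <- logical(prod(shape))
    centers <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("z", "y", "x")))
    supports <- list()
    budget <- 100L * max(1L, n)
    attempts <- 0L
    while (length(supports) < n) {
      attempts <- attempts + 1L
      if (attempts > budget)
        stop("scene overcrowded: placement failed after ", budget, " attempts")
      cand <- propose()
      if (!length(cand$support) || any(occupied[cand$guard])) next
      occupied[cand$guard] <- TRUE
      centers <- rbind(centers, cand$centerUm)
      supports[[length(supports) + 1L]] <- sort(cand$support)
    }

    bg <- backgroundField(shape, params@backgroundLevel,
                          params@backgroundRelief)
    clean <- bg
    for (s in supports) clean[s] <- clean[s] + params@intensityAmplitude
    channels <- list(clean)
    if (nChannels == 2L) {
      scale2 <- if (n > 0) runif(n, 0.3, 1) else numeric(0)
      c2 <- bg
      for (i in seq_along(supports))
        c2[supports[[i]]] <- c2[supports[[i]]] +
          params@intensityAmplitude * scale2[i]
      channels <- c(channels, list(c2))
    }
    vox <- array(0, c(shape, length(channels)))
    for (ci in seq_along(channels)) {
      a <- applyPsf(channels[[ci]], params@psfSigma, sp)
      a <- applyCameraNoise(a, params@poissonNoise, params@readSd)
      vox[, , , ci] <- a
    }
    chn <- if (nChannels == 2L) c("structure", "potential") else "mito"
    stack <- ImageStack(vox, sp, chn)
    truth <- newSceneTruth(
      counts = c(mito = n),
      centroids = list(mito = centers),
      voxelSets = list(mito = supports),
      phenotype = if (params@mode == "punctate") "fragmented" else "tubular",
      noiseParams = list(poisson = params@poissonNoise, readSd = params@readSd,
                         background = params@backgroundLevel,
                         amplitude = params@intensityAmplitude))
    list(stack = stack, truth = truth)
  })
}

#' Generate a two-channel mitophagy colocalization scene
#'
#' Places \code{nMito} mitochondrial blobs along a simulated neurite
#' strip and overlays LC3 puncta so that exactly
#' \code{round(colocFraction * nMito)} mitochondria overlap an LC3
#' punctum by at least one voxel; the remaining LC3 puncta (decoys)
#' touch no mitochondrion. The truth records which mitochondria are
#' positive and the neurite centerline for segment construction.
#'
#' @param nMito number of mitochondria
#' @param colocFraction fraction in [0,1] of LC3-positive mitochondria
#' @param geometry a \linkS4class{MorphologyParams} (punctate settings
#'   are used; the strip spans the x-axis at mid-height)
#' @param seed integer RNG seed
#' @param nDecoys LC3 puncta overlapping nothing (default 5)
#' @param segmentLengthUm mitochondria are placed within this initial
#'   stretch of the strip so a segment of that length captures all of
#'   them (default 30); decoys may lie anywhere along the strip
#' @return list(stack, truth); channels are "mito" and "lc3"
#' @export
generateColocScene <- function(nMito, colocFraction,
                               geometry = morphologyParams(
                                 nObjects = nMito,
                                 stackShape = c(3L, 128L, 512L),
                                 minSeparation = 1.2),
                               seed = 1L, nDecoys = 5L,
                               segmentLengthUm = 30) {
  if (colocFraction < 0 || colocFraction > 1)
    stop("colocFraction must be in [0,1]")
  nMito <- as.integer(nMito)
  k <- as.integer(round(colocFraction * nMito))
  withSeed(seed, {
    shape <- geometry@stackShape
    sp <- geometry@voxelSize
    extent <- shape * sp
    stripHalf <- 1.0                      # neurite half-width, um
    yc <- extent[2] / 2

    xMax <- min(extent[3], segmentLengthUm)
    proposeMito <- function(withinSegment = TRUE) {
      d <- max(0.1, rnorm(1, geometry@blobDiameter[1], geometry@blobDiameter[2]))
      margin <- d / 2 + geometry@minSeparation / 2
      c_um <- c(extent[1] / 2,
                boundedUnif(yc - stripHalf + d / 2, yc + stripHalf - d / 2),
                if (withinSegment) boundedUnif(margin, xMax - margin)
                else boundedUnif(margin, extent[3] - margin))
      if (anyNA(c_um))
        return(list(centerUm = c_um, d = d,
                    support = integer(0), guard = integer(0)))
      rad <- c(max(d / 2, extent[1]), d / 2, d / 2)
      list(centerUm = c_um, d = d,
           support = ellipsoidSupport(shape, sp, c_um, rad),
           guard = ellipsoidSupport(shape, sp, c_um,
                                    rad + geometry@minSeparation / 2))
    }

    occupied <- logical(prod(shape))
    mito <- list(); mcent <- NULL; mdiam <- numeric(0)
    budget <- 100L * max(1L, nMito + nDecoys)
    attempts <- 0L
    while (length(mito) < nMito) {
      attempts <- attempts + 1L
      if (attempts > budget) stop("scene overcrowded")
      cand <- proposeMito()
      if (!length(cand$support) || any(occupied[cand$guard])) next
      occupied[cand$guard] <- TRUE
      mito[[length(mito) + 1L]] <- sort(cand$support)
      mcent <- rbind(mcent, cand$centerUm)
      mdiam <- c(mdiam, cand$d)
    }

    # positive LC3: centered on the first k mitochondria (>=1 shared voxel
    # by construction); decoys placed in free guard space
    lc3 <- list(); lcent <- NULL
    if (k > 0) for (i in seq_len(k)) {
      d <- 0.8 * mdiam[i]
      sup <- ellipsoidSupport(shape, sp, mcent[i, ],
                              c(max(d / 2, extent[1]), d / 2, d / 2))
      lc3[[length(lc3) + 1L]] <- sort(sup)
      lcent <- rbind(lcent, mcent[i, ])
    }
    placedDecoys <- 0L
    while (placedDecoys < nDecoys) {
      attempts <- attempts + 1L
      if (attempts > budget) stop("scene overcrowded")
      cand <- proposeMito(withinSegment = FALSE)
      if (!length(cand$support) || any(occupied[cand$guard])) next
      occupied[cand$guard] <- TRUE
      placedDecoys <- placedDecoys + 1L
      lc3[[length(lc3) + 1L]] <- sort(cand$support)
      lcent <- rbind(lcent, cand$centerUm)
    }

    render <- function(supports) {
      a <- backgroundField(shape, geometry@backgroundLevel,
                           geometry@backgroundRelief)
      for (s in supports) a[s] <- a[s] + geometry@intensityAmplitude
      a <- applyPsf(a, geometry@psfSigma, sp)
      applyCameraNoise(a, geometry@poissonNoise, geometry@readSd)
    }
    vox <- array(0, c(shape, 2))
    vox[, , , 1] <- render(mito)
    vox[, , , 2] <- render(lc3)
    stack <- ImageStack(vox, sp, c("mito", "lc3"))

    zc <- max(1L, round(shape[1] / 2))
    centerline <- cbind(z = zc, y = round(yc / sp[2]), x = seq_len(shape[3]))
    truth <- newSceneTruth(
      counts = c(mito = nMito, lc3 = length(lc3)),
      centroids = list(mito = mcent,
                       lc3 = if (is.null(lcent))
                         matrix(numeric(0), 0, 3) else lcent),
      voxelSets = list(mito = mito, lc3 = lc3),
      colocFraction = colocFraction,
      noiseParams = list(poisson = geometry@poissonNoise,
                         readSd = geometry@readSd,
                         background = geometry@backgroundLevel,
                         amplitude = geometry@intensityAmplitude),
      extras = list(positiveMito = seq_len(k),
                    centerlineVox = centerline,
                    stripHalfWidthUm = stripHalf))
    list(stack = stack, truth = truth)
  })
}

#' Generate a two-channel expansion-microscopy scene
#'
#' A biological-scale scene (a mitochondrial ellipsoid plus spherical
#' protein clusters) rendered at the physically expanded scale: all
#' coordinates and sizes are multiplied by
#' \code{expansionFactor} before voxelization onto a grid with the
#' acquisition voxel size, so the stack shape grows with the factor
#' while the truth stays at biological scale. A fraction
#' \code{assocFraction} of the clusters lies entirely inside the
#' mitochondrial region; the rest lie strictly outside with a clearance
#' that survives smoothing. Per-cluster nominal volumes vary uniformly
#' within +/-15% of \code{meanClusterVolume}.
#'
#' @param clusterDensity clusters per um^3 of biological volume
#' @param meanClusterVolume mean cluster volume (um^3, biological)
#' @param assocFraction fraction in [0,1] of mitochondria-associated clusters
#' @param expansionFactor linear expansion factor (> 1)
#' @param seed integer RNG seed
#' @param extentUm biological extent (z, y, x) in um
#' @param voxelSize acquisition voxel size (dz, dy, dx) um (expanded scale)
#' @param amplitude,background,poissonNoise,readSd camera model settings
#' @return list(stack, truth); channels are "cabl" and "mito"
#' @export
generateExmScene <- function(clusterDensity, meanClusterVolume,
                             assocFraction, expansionFactor, seed,
                             extentUm = c(10, 12.8, 12.8),
                             voxelSize = c(1, 0.2, 0.2),
                             amplitude = 100, background = 5,
                             poissonNoise = FALSE, readSd = 0) {
  if (expansionFactor <= 1) stop("expansionFactor must be > 1")
  if (assocFraction < 0 || assocFraction > 1)
    stop("assocFraction must be in [0,1]")
  withSeed(seed, {
    shape <- as.integer(round(extentUm * expansionFactor / voxelSize))
    bioVol <- prod(shape * voxelSize) / expansionFactor^3
    n <- as.integer(round(clusterDensity * bioVol))
    if (n < 1L) stop("density * volume must yield at least one expected cluster")
    k <- as.integer(round(assocFraction * n))

    # mitochondrial region: biological-scale ellipsoid at scene center
    mitoC <- extentUm / 2
    mitoSemi <- extentUm * c(0.45, 0.40, 0.40)
    # clearance so smoothed/thresholded masks stay disjoint from
    # outside clusters (2.5 voxels per axis, in biological um)
    clearance <- 2.5 * voxelSize / expansionFactor

    vols <- meanClusterVolume * runif(n, 0.85, 1.15)
    radii <- (3 * vols / (4 * pi))^(1 / 3)
    inEll <- function(p, semi) sum(((p - mitoC) / semi)^2) <= 1

    expandedSupport <- function(cBio, rBio) {
      ellipsoidSupport(shape, voxelSize, cBio * expansionFactor,
                       rep_len(rBio, 3) * expansionFactor)
    }
    occupied <- logical(prod(shape))
    centers <- NULL; supports <- list()
    budget <- 100L * n
    attempts <- 0L
    for (i in seq_len(n)) {
      r <- radii[i]
      wantIn <- i <= k
      semiInner <- pmax(mitoSemi - r - 0.05, 0.01)
      repeat {
        attempts <- attempts + 1L
        if (attempts > budget) stop("scene overcrowded")
        if (wantIn) {
          # uniform draw inside the shrunken ellipsoid
          u <- rnorm(3); u <- u / sqrt(sum(u^2)) * runif(1)^(1 / 3)
          p <- mitoC + semiInner * u
        } else {
          p <- c(runif(1, r, extentUm[1] - r),
                 runif(1, r, extentUm[2] - r),
                 runif(1, r, extentUm[3] - r))
          if (inEll(p, mitoSemi + r + clearance)) next
        }
        sup <- expandedSupport(p, r)
        guard <- expandedSupport(p, r + clearance)
        if (!length(sup) || any(occupied[guard])) next
        occupied[guard] <- TRUE
        centers <- rbind(centers, p)
        supports[[i]] <- sort(sup)
        break
      }
    }

    mitoSup <- ellipsoidSupport(shape, voxelSize, mitoC * expansionFactor,
                                mitoSemi * expansionFactor)
    cabl <- array(background, shape)
    for (s in supports) cabl[s] <- background + amplitude
    mito <- array(background, shape)
    mito[mitoSup] <- background + amplitude
    vox <- array(0, c(shape, 2))
    vox[, , , 1] <- applyCameraNoise(cabl, poissonNoise, readSd)
    vox[, , , 2] <- applyCameraNoise(mito, poissonNoise, readSd)
    stack <- ImageStack(vox, voxelSize, c("cabl", "mito"))

    colnames(centers) <- c("z", "y", "x")
    truth <- newSceneTruth(
      counts = c(cabl = n, mito = 1L),
      centroids = list(cabl = centers,
                       mito = matrix(mitoC, 1, 3,
                                     dimnames = list(NULL, c("z", "y", "x")))),
      voxelSets = list(cabl = supports, mito = list(sort(mitoSup))),
      colocFraction = assocFraction,
      clusterVolumes = vols,
      expansionFactor = expansionFactor,
      noiseParams = list(poisson = poissonNoise, readSd = readSd,
                         background = background, amplitude = amplitude),
      extras = list(associatedClusters = seq_len(k),
                    biologicalVolumeUm3 = bioVol,
                    mitoSemiAxesUm = mitoSemi))
    list(stack = stack, truth = truth)
  })
}

#' Generate a three-channel neuron scene (tubulin, mitochondria, LC3)
#'
#' A filled soma disc plus a straight neurite of the requested length
#' renders the beta-III-tubulin channel; mitochondria and LC3 puncta
#' are placed along the neurite (or restricted to the soma). The truth
#' carries the exact soma mask, the neurite centerline in voxel
#' coordinates, and the identity of LC3-positive mitochondria.
#'
#' @param somaRadius soma radius in um
#' @param neuriteLength neurite length in um (>= 30 so a full analysis
#'   segment exists)
#' @param seed integer RNG seed
#' @param nMito mitochondria to place
#' @param colocFraction fraction of LC3-positive mitochondria
#' @param mitoIn "neurite" (default) or "soma"
#' @param geometry a \linkS4class{MorphologyParams}; stackShape must
#'   accommodate soma plus neurite, else a "scene overcrowded" error
#' @return list(stack, truth); channels "tubulin", "mito", "lc3"
#' @export
generateNeuronScene <- function(somaRadius = 8, neuriteLength = 40, seed = 1L,
                                nMito = 12L, colocFraction = 0.4,
                                mitoIn = c("neurite", "soma"),
                                geometry = morphologyParams(
                                  nObjects = nMito,
                                  stackShape = c(3L, 256L, 640L))) {
  mitoIn <- match.arg(mitoIn)
  if (neuriteLength < 30)
    stop("neuriteLength must be >= 30 um so a full analysis segment exists")
  if (colocFraction < 0 || colocFraction > 1)
    stop("colocFraction must be in [0,1]")
  withSeed(seed, {
    shape <- geometry@stackShape
    sp <- geometry@voxelSize
    extent <- shape * sp
    yc <- extent[2] / 2
    somaX <- somaRadius + 1
    if (somaX + somaRadius > extent[3] ||
        somaX + somaRadius + neuriteLength > extent[3] ||
        2 * somaRadius > extent[2])
      stop("scene overcrowded: soma plus neurite do not fit the stack")
    neuriteHalf <- 0.5                      # um
    x0 <- somaX                              # soma center x
    x1 <- somaX + somaRadius + neuriteLength # neurite tip

    yIdx <- (seq_len(shape[2]) - 0.5) * sp[2]
    xIdx <- (seq_len(shape[3]) - 0.5) * sp[3]
    somaPlane <- outer((yIdx - yc)^2, (xIdx - x0)^2, "+") <= somaRadius^2
    neuritePlane <- outer(abs(yIdx - yc) <= neuriteHalf,
                          xIdx >= x0 & xIdx <= x1, "&")
    tubulinPlane <- somaPlane | neuritePlane
    tubulin <- backgroundField(shape, geometry@backgroundLevel,
                               geometry@backgroundRelief) +
      array(rep(tubulinPlane, each = shape[1]), shape) *
        geometry@intensityAmplitude

    nMito <- as.integer(nMito)
    k <- as.integer(round(colocFraction * nMito))
    proposeBlob <- function() {
      d <- max(0.1, rnorm(1, geometry@blobDiameter[1], geometry@blobDiameter[2]))
      if (mitoIn == "neurite") {
        c_um <- c(extent[1] / 2,
                  boundedUnif(yc - neuriteHalf + d / 2, yc + neuriteHalf - d / 2),
                  boundedUnif(x0 + somaRadius + d, x1 - d))
        if (anyNA(c_um))
          return(list(centerUm = c_um, d = d,
                      support = integer(0), guard = integer(0)))
      } else {
        ang <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1)) * (somaRadius - d)
        c_um <- c(extent[1] / 2, yc + rr * sin(ang), x0 + rr * cos(ang))
      }
      rad <- c(max(d / 2, extent[1]), d / 2, d / 2)
      list(centerUm = c_um, d = d,
           support = ellipsoidSupport(shape, sp, c_um, rad),
           guard = ellipsoidSupport(shape, sp, c_um,
                                    rad + geometry@minSeparation / 2))
    }
    occupied <- logical(prod(shape))
    mito <- list(); mcent <- NULL; mdiam <- numeric(0)
    budget <- 100L * max(1L, nMito)
    attempts <- 0L
    while (length(mito) < nMito) {
      attempts <- attempts + 1L
      if (attempts > budget) stop("scene overcrowded")
      cand <- proposeBlob()
      if (!length(cand$support) || any(occupied[cand$guard])) next
      occupied[cand$guard] <- TRUE
      mito[[length(mito) + 1L]] <- sort(cand$support)
      mcent <- rbind(mcent, cand$centerUm)
      mdiam <- c(mdiam, cand$d)
    }
    lc3 <- list(); lcent <- NULL
    if (k > 0) for (i in seq_len(k)) {
      d <- 0.8 * mdiam[i]
      sup <- ellipsoidSupport(shape, sp, mcent[i, ],
                              c(max(d / 2, extent[1]), d / 2, d / 2))
      lc3[[length(lc3) + 1L]] <- sort(sup)
      lcent <- rbind(lcent, mcent[i, ])
    }

    render <- function(clean) {
      a <- applyPsf(clean, geometry@psfSigma, sp)
      applyCameraNoise(a, geometry@poissonNoise, geometry@readSd)
    }
    paint <- function(supports) {
      a <- backgroundField(shape, geometry@backgroundLevel,
                           geometry@backgroundRelief)
      for (s in supports) a[s] <- a[s] + geometry@intensityAmplitude
      a
    }
    vox <- array(0, c(shape, 3))
    vox[, , , 1] <- render(tubulin)
    vox[, , , 2] <- render(paint(mito))
    vox[, , , 3] <- render(paint(lc3))
    stack <- ImageStack(vox, sp, c("tubulin", "mito", "lc3"))

    zc <- max(1L, round(shape[1] / 2))
    xlo <- ceiling((x0 + somaRadius) / sp[3])
    xhi <- floor(x1 / sp[3])
    centerline <- cbind(z = zc, y = round(yc / sp[2]), x = xlo:xhi)
    somaMask3d <- array(rep(somaPlane, each = shape[1]), shape)
    truth <- newSceneTruth(
      counts = c(tubulin = 1L, mito = nMito, lc3 = length(lc3)),
      centroids = list(tubulin = matrix(c(extent[1] / 2, yc, x0), 1, 3,
                                        dimnames = list(NULL, c("z", "y", "x"))),
                       mito = mcent,
                       lc3 = if (is.null(lcent))
                         matrix(numeric(0), 0, 3) else lcent),
      voxelSets = list(tubulin = list(which(somaMask3d |
                         array(rep(neuritePlane, each = shape[1]), shape))),
                       mito = mito, lc3 = lc3),
      colocFraction = colocFraction,
      noiseParams = list(poisson = geometry@poissonNoise,
                         readSd = geometry@readSd,
                         background = geometry@backgroundLevel,
                         amplitude = geometry@intensityAmplitude),
      extras = list(somaMask = somaMask3d, somaPlane = somaPlane,
                    neuritePlane = neuritePlane,
                    centerlineVox = centerline,
                    neuriteHalfWidthUm = neuriteHalf,
                    positiveMito = seq_len(k)))
    list(stack = stack, truth = truth)
  })
}
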
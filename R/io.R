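#' Read a calibrated z-stack from a multi-page TIFF
#'
#' Pages are expected in channel-major order (all z-planes of channel 1,
#' then channel 2, ...), the layout \code{\link{writeStack}} produces.
#' Calibration (voxel size, channel names, plane layout) is carried in a
#' plain-text JSON sidecar written next to the TIFF
#' (\code{<path>.meta.json}). A stack without calibration is refused
#' unless \code{voxelSizeOverride} is given: silent default pixel sizes
#' would corrupt every physical measurement downstream.
#'
#' @param path TIFF file path.
#' @param voxelSizeOverride optional numeric(3) (dz, dy, dx) in um,
#'   taking precedence over sidecar calibration.
#' @param nChannels optional channel count when no sidecar is present
#'   (default 1).
#' @return an \linkS4class{ImageStack}
#' @seealso \code{\link{writeStack}}
#' @export
readStack <- function(path, voxelSizeOverride = NULL, nChannels = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1L)
    stop("inconsistent page shapes in ", path)

  meta <- NULL
  sidecar <- sidecarPath(path)
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)

  if (!is.null(voxelSizeOverride)) {
    vs <- as.numeric(voxelSizeOverride)
  } else if (!is.null(meta) && !is.null(meta$voxel_size_um)) {
    vs <- as.numeric(meta$voxel_size_um)
  } else {
    stop("calibration missing for ", path,
         " (no sidecar and no voxelSizeOverride)")
  }
  if (length(vs) != 3L || any(vs <= 0))
    stop("voxel size must be 3 positive values (dz, dy, dx)")

  nch <- if (!is.null(meta) && !is.null(meta$n_channels))
    as.integer(meta$n_channels) else if (!is.null(nChannels))
    as.integer(nChannels) else 1L
  np <- length(pages)
  if (np %% nch != 0L)
    stop("page count ", np, " is not a multiple of channel count ", nch)
  nz <- np %/% nch
  d <- dim(pages[[1]])[1:2]

  vox <- array(0, c(nz, d[1], d[2], nch))
  for (p in seq_len(np)) {
    ch <- (p - 1L) %/% nz + 1L
    z <- (p - 1L) %% nz + 1L
    pg <- pages[[p]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    vox[z, , , ch] <- pg
  }
  if (!is.null(meta) && !is.null(meta$intensity_scale) &&
      meta$intensity_scale != 1)
    vox <- vox * as.numeric(meta$intensity_scale)
  # integer-valued (photon count) data round-trips exactly
  if (!is.null(meta) && isTRUE(meta$integer_data)) vox <- round(vox)
  chn <- if (!is.null(meta) && !is.null(meta$channel_names))
    as.character(meta$channel_names) else paste0("ch", seq_len(nch))
  ImageStack(vox, vs, chn)
}

#' Write a calibrated z-stack to a multi-page TIFF
#'
#' Voxels are stored as 32-bit floats, one page per (channel, z-plane)
#' in channel-major order, with calibration in a JSON sidecar
#' (\code{<path>.meta.json}). Round-trips are exact for values
#' representable in single precision (in particular all integer-valued
#' photon-count images below 2^24) and accurate to ~1e-7 relative
#' otherwise; calibration round-trips at full double precision.
#'
#' @param stack an \linkS4class{ImageStack}
#' @param path output TIFF path.
#' @return invisibly, the sidecar path
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  d <- dim(stack@voxels)
  if (d[4] < 1L || prod(d) == 0L) stop("empty stack cannot be written")
  pages <- vector("list", d[1] * d[4])
  p <- 0L
  for (ch in seq_len(d[4])) {
    for (z in seq_len(d[1])) {
      p <- p + 1L
      pages[[p]] <- matrix(stack@voxels[z, , , ch], d[2], d[3])
    }
  }
  # TIFF floats are stored in [0,1]; divide by a power of two >= max so
  # the scaling is exact in binary floating point and recorded for read
  mx <- max(vapply(pages, max, 0), 0)
  scale <- if (mx > 1) 2^ceiling(log2(mx)) else 1
  if (scale != 1) pages <- lapply(pages, function(p) p / scale)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                            reduce = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) stop("unwritable path: ", path)
  meta <- list(voxel_size_um = stack@voxelSize,
               channel_names = stack@channelNames,
               n_channels = d[4], n_z = d[1],
               intensity_scale = scale,
               integer_data = all(stack@voxels == round(stack@voxels)),
               axis_order = "zyx")
  jsonlite::write_json(meta, sidecarPath(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(sidecarPath(path))
}

sidecarPath <- function(path) paste0(path, ".meta.json")

#' Write scene ground truth to a JSON sidecar
#'
#' Voxel indices are serialized 0-based in (z, y, x) array order to keep
#' the sidecar language-neutral; \code{\link{readSceneTruth}} restores
#' R's 1-based linear indices.
#'
#' @param truth a \linkS4class{SceneTruth}
#' @param path output path (conventionally \code{<image>.truth.json})
#' @return invisibly, \code{path}
#' @export
writeSceneTruth <- function(truth, path) {
  stopifnot(is(truth, "SceneTruth"))
  payload <- list(
    counts = as.list(truth@counts),
    centroids_um = lapply(truth@centroidsUm, function(m)
      if (is.null(m)) list() else unname(apply(m, 1, as.numeric, simplify = FALSE))),
    voxel_sets_0based = lapply(truth@voxelSets, function(ch)
      lapply(ch, function(v) as.integer(v) - 1L)),
    coloc_fraction = truth@colocFraction,
    cluster_volumes_um3 = truth@clusterVolumesUm3,
    expansion_factor_linear = truth@expansionFactor,
    phenotype = truth@phenotype,
    noise_params = truth@noiseParams)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read scene ground truth written by \code{\link{writeSceneTruth}}
#' @param path sidecar path
#' @return a \linkS4class{SceneTruth} (the \code{extras} slot is not
#'   serialized and comes back empty)
#' @export
readSceneTruth <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  counts <- vapply(p$counts, function(x) as.integer(x), integer(1))
  centroids <- lapply(p$centroids_um, function(ch) {
    if (!length(ch)) return(matrix(numeric(0), 0, 3,
                                   dimnames = list(NULL, c("z", "y", "x"))))
    m <- do.call(rbind, lapply(ch, function(r) as.numeric(unlist(r))))
    colnames(m) <- c("z", "y", "x")
    m
  })
  vsets <- lapply(p$voxel_sets_0based, function(ch)
    lapply(ch, function(v) as.integer(unlist(v)) + 1L))
  new("SceneTruth", counts = counts, centroidsUm = centroids,
      voxelSets = vsets,
      colocFraction = nullToNa(p$coloc_fraction),
      clusterVolumesUm3 = as.numeric(unlist(p$cluster_volumes_um3)),
      expansionFactor = nullToNa(p$expansion_factor_linear),
      phenotype = as.character(unlist(p$phenotype)),
      noiseParams = p$noise_params, extras = list())
}

nullToNa <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
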
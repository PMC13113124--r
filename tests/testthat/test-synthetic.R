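test_that("empty scenes are pure background and deterministic", {
  p <- morphologyParams(nObjects = 0L, backgroundLevel = 10,
                        backgroundRelief = 0, psfSigma = 0,
                        stackShape = c(3L, 32L, 32L))
  sc <- generateMitoScene(p, seed = 123)
  expect_true(all(voxels(sc$stack) == 10))
  expect_identical(unname(sc$truth@counts["mito"]), 0L)
  expect_equal(nrow(sc$truth@centroidsUm$mito), 0)
})

test_that("identical seeds give identical scenes, different seeds differ", {
  p <- morphologyParams(nObjects = 12L, poissonNoise = TRUE,
                        stackShape = c(3L, 192L, 192L))
  a <- generateMitoScene(p, seed = 1)
  b <- generateMitoScene(p, seed = 1)
  c <- generateMitoScene(p, seed = 2)
  expect_identical(voxels(a$stack), voxels(b$stack))
  expect_identical(a$truth@voxelSets, b$truth@voxelSets)
  expect_false(identical(a$truth@centroidsUm$mito, c$truth@centroidsUm$mito))
})

test_that("noise-free intensity is conserved: objects plus background", {
  p <- morphologyParams(nObjects = 10L, psfSigma = 0, backgroundRelief = 0.2,
                        intensityAmplitude = 50, backgroundLevel = 8,
                        stackShape = c(3L, 96L, 96L))
  sc <- generateMitoScene(p, seed = 6)
  nvox <- prod(dim(getChannel(sc$stack, 1)))
  expected <- 8 * nvox +
    50 * sum(lengths(sc$truth@voxelSets$mito))
  expect_equal(sum(voxels(sc$stack)), expected, tolerance = 1e-9)
})

test_that("truth voxel sets are nonempty and disjoint", {
  sc <- generateMitoScene(morphologyParams(nObjects = 30L), seed = 14)
  sets <- sc$truth@voxelSets$mito
  expect_true(all(lengths(sets) > 0))
  all_idx <- unlist(sets)
  expect_equal(length(all_idx), length(unique(all_idx)))
})

test_that("overcrowded scenes fail with a bounded retry budget", {
  p <- morphologyParams(nObjects = 200L, stackShape = c(3L, 24L, 24L))
  expect_error(generateMitoScene(p, seed = 1), "overcrowded")
  expect_error(morphologyParams(nObjects = -1L), "nObjects")
  expect_error(morphologyParams(voxelSize = c(0, 0.1, 0.1)), "positive")
})

test_that("colocalization scenes force the exact positive count", {
  sc <- generateColocScene(10, 0.4, seed = 3)
  expect_length(sc$truth@extras$positiveMito, 4L)
  # positives share >= 1 voxel with an LC3 punctum, by truth masks
  mitoSets <- sc$truth@voxelSets$mito
  lc3All <- unlist(sc$truth@voxelSets$lc3)
  overlap <- vapply(mitoSets, function(s) any(s %in% lc3All), TRUE)
  expect_identical(which(overlap), 1:4)

  sc0 <- generateColocScene(8, 0, seed = 5)
  expect_false(any(unlist(sc0$truth@voxelSets$mito) %in%
                     unlist(sc0$truth@voxelSets$lc3)))
  expect_error(generateColocScene(5, 1.2, seed = 1), "colocFraction")
})

test_that("expansion scenes scale geometry by the linear factor", {
  e <- generateExmScene(0.006, 4, 1, 4, seed = 9)
  # every cluster's rendered voxel set lies inside the mito truth mask
  mitoSet <- e$truth@voxelSets$mito[[1]]
  for (s in e$truth@voxelSets$cabl) expect_true(all(s %in% mitoSet))

  # rendered centroid separations are factor x the biological ones
  e4 <- generateExmScene(0.006, 4, 0.5, 4, seed = 10)
  shape <- dim(getChannel(e4$stack, 1))
  vs <- voxelSize(e4$stack)
  cents <- t(vapply(e4$truth@voxelSets$cabl, function(s) {
    co <- arrayInd(s, shape)
    colMeans(sweep(co - 0.5, 2, vs, "*"))
  }, numeric(3)))
  bio <- e4$truth@centroidsUm$cabl
  dRend <- as.matrix(dist(cents))
  dBio <- as.matrix(dist(bio))
  expect_equal(dRend[upper.tri(dRend)], 4 * dBio[upper.tri(dBio)],
               tolerance = 0.05)

  # realized count recorded in truth equals round(density * volume)
  expect_identical(unname(e4$truth@counts["cabl"]),
                   as.integer(round(0.006 * e4$truth@extras$biologicalVolumeUm3)))
  expect_error(generateExmScene(0.006, 4, 0.5, 1, seed = 1), "expansionFactor")
  expect_error(generateExmScene(1e-9, 4, 0.5, 4, seed = 1), "at least one")
})

test_that("neuron scenes have exact tubulin truth and a measurable centerline", {
  g <- morphologyParams(nObjects = 12L, psfSigma = 0, backgroundRelief = 0,
                        stackShape = c(3L, 256L, 640L))
  nn <- generateNeuronScene(somaRadius = 8, neuriteLength = 40, seed = 4,
                            geometry = g)
  pT <- projectZ(nn$stack, "tubulin")
  mT <- binarize(pT, triangleThreshold(pT))
  expect_identical(voxels(mT),
                   nn$truth@extras$somaPlane | nn$truth@extras$neuritePlane)

  # centerline voxel count along x follows length / voxel size:
  # the neurite runs from the soma edge (somaX + radius = 17 um) to its
  # tip (17 + 40 um) at 0.1 um pixels
  cl <- nn$truth@extras$centerlineVox
  expect_equal(nrow(cl), floor(57 / 0.1) - ceiling(17 / 0.1) + 1)

  expect_error(generateNeuronScene(neuriteLength = 20, seed = 1), ">= 30")
  expect_error(generateNeuronScene(somaRadius = 8, neuriteLength = 80, seed = 1),
               "overcrowded")
})

test_that("mitochondria confined to the soma leave the segment empty", {
  nn <- generateNeuronScene(somaRadius = 8, neuriteLength = 40, seed = 6,
                            mitoIn = "soma")
  sp <- voxelSize(nn$stack)
  shape <- dim(getChannel(nn$stack, 1))
  seg <- segmentMask(nn$truth@extras$centerlineVox, shape, sp)
  pM <- projectZ(nn$stack, "mito")
  mM <- binarize(pM, triangleThreshold(pM))
  mito3 <- BinaryMask(array(rep(voxels(mM), each = shape[1]), shape), sp)
  r <- colocFraction(mito3, seg$mask, seg$mask)
  expect_identical(r@flags, "empty_denominator")
  expect_true(is.na(r@percentPositive))
})
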
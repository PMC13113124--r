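test_that("morphometry recovers counts and intensity on clean scenes", {
  p <- morphologyParams(nObjects = 25L, psfSigma = 0,
                        intensityAmplitude = 80, backgroundLevel = 5,
                        stackShape = c(3L, 192L, 192L))
  sc <- generateMitoScene(p, seed = 21)
  m <- mitoPipeline(sc$stack, "mito")
  expect_identical(m@nMitochondria, 25L)
  expect_length(m@perObjectAreas, 25L)
  expect_equal(m@meanMitoArea, mean(m@perObjectAreas))
  # without blur the mask equals the rendered support, so the mean
  # intensity on the unfiltered projection is amplitude + background
  expect_equal(m@meanMitoIntensity, 85, tolerance = 0.05 * 85)
})

test_that("an empty threshold result is flagged, not silently zeroed", {
  # structure in the histogram but nothing surviving the size filter:
  # a 2x2 block survives the median filter but falls below min_size 8
  a <- array(1, c(3, 32, 32)); a[, 16:17, 16:17] <- 10
  cfg <- defaultConfig(); cfg$min_size_vox <- 8L
  m <- mitoPipeline(ImageStack(a, c(0.1, 0.1, 0.1)), config = cfg)
  expect_identical(m@nMitochondria, 0L)
  expect_identical(m@fragmentationClass, "unclassifiable")
  expect_true(is.na(m@meanMitoIntensity))
  expect_identical(m@flags, "empty_mask")
})

test_that("fragmentation scoring follows the area-fraction definition", {
  mk <- function(areas) new("MitoMorphometry", cellId = "x",
                            meanMitoIntensity = 1,
                            nMitochondria = length(areas),
                            perObjectAreas = areas,
                            meanMitoArea = mean(areas),
                            fragmentationScore = NA_real_,
                            fragmentationClass = "unclassifiable",
                            flags = character(0))
  allSmall <- classifyFragmentation(mk(rep(0.3, 10)))
  expect_equal(allSmall@fragmentationScore, 1)
  expect_identical(allSmall@fragmentationClass, "fragmented")

  giant <- classifyFragmentation(mk(8))
  expect_equal(giant@fragmentationScore, 0)
  expect_identical(giant@fragmentationClass, "fused_intermediate")

  # merging two sub-cut objects into one supra-cut object cannot raise
  # the score
  before <- classifyFragmentation(mk(c(0.6, 0.6, 2)))
  after <- classifyFragmentation(mk(c(1.2, 2)))
  expect_lte(after@fragmentationScore, before@fragmentationScore)

  expect_error(classifyFragmentation(mk(numeric(0))), "unclassifiable")
})

test_that("synthetic phenotype cohorts classify correctly at defaults", {
  cls <- character(0)
  for (s in 1:5) {
    cls <- c(cls,
      mitoPipeline(generateMitoScene(morphologyParams("punctate",
        nObjects = 40L), seed = s)$stack)@fragmentationClass,
      mitoPipeline(generateMitoScene(morphologyParams("tubular",
        nObjects = 8L), seed = 50 + s)$stack)@fragmentationClass)
  }
  expect_identical(cls, rep(c("fragmented", "fused_intermediate"), 5))
})

test_that("percent fragmented is simple arithmetic, order-invariant", {
  mk <- function(cl) new("MitoMorphometry", cellId = "x",
                         meanMitoIntensity = 1, nMitochondria = 1L,
                         perObjectAreas = 0.5, meanMitoArea = 0.5,
                         fragmentationScore = 0.5,
                         fragmentationClass = cl, flags = character(0))
  cells <- c(replicate(3, mk("fragmented"), simplify = FALSE),
             replicate(9, mk("fused_intermediate"), simplify = FALSE))
  expect_equal(percentFragmented(cells), 25)
  expect_equal(percentFragmented(rev(cells)), 25)
  expect_equal(percentFragmented(cells[1:3]), 100)
  expect_equal(percentFragmented(cells[4:6]), 0)
  # unclassifiable cells drop out of the denominator
  cells2 <- c(cells, list(mk("unclassifiable")))
  expect_equal(percentFragmented(cells2), 25)
  expect_error(percentFragmented(list(mk("unclassifiable"))), "classifiable")
})

test_that("soma mask keeps the largest filled component", {
  g <- morphologyParams(nObjects = 6L, psfSigma = 0, backgroundRelief = 0,
                        stackShape = c(3L, 256L, 640L))
  nn <- generateNeuronScene(somaRadius = 8, neuriteLength = 40, seed = 11,
                            geometry = g)
  sm <- somaMask(nn$stack, "tubulin")
  expect_true(all(voxels(sm)[nn$truth@extras$somaPlane]))     # covers soma
  outside <- !(nn$truth@extras$somaPlane | nn$truth@extras$neuritePlane)
  expect_false(any(voxels(sm)[outside]))                      # no background
  blank <- ImageStack(array(3, c(3, 16, 16)), c(0.1, 0.1, 0.1), "tubulin")
  expect_error(somaMask(blank), "degenerate")
})

test_that("object-based colocalization counts overlap per object", {
  sc <- generateColocScene(10, 0.4, seed = 7)
  shape <- dim(getChannel(sc$stack, 1))
  sp <- voxelSize(sc$stack)
  pM <- projectZ(sc$stack, "mito"); pL <- projectZ(sc$stack, "lc3")
  mM <- binarize(pM, triangleThreshold(pM))
  mL <- binarize(pL, triangleThreshold(pL))
  seg2d <- BinaryMask(segmentMask(sc$truth@extras$centerlineVox, shape,
                                  sp)$mask@voxels[2, , ], sp[2:3])
  r <- colocFraction(mM, mL, seg2d, segmentLengthUm = 30)
  expect_identical(r@nMitoInSegment, 10L)
  expect_identical(r@nLc3Positive, 4L)
  expect_equal(r@percentPositive, 40)

  empty <- BinaryMask(matrix(FALSE, shape[2], shape[3]), sp[2:3])
  expect_equal(colocFraction(mM, empty, seg2d)@percentPositive, 0)
  expect_equal(colocFraction(mM, mM, seg2d)@percentPositive, 100)
})
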
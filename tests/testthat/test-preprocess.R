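test_that("z-projection computes per-pixel order statistics", {
  s <- ImageStack(array(7, c(3, 6, 6)), c(0.1, 0.1, 0.1))
  expect_equal(voxels(projectZ(s, 1, "median")), matrix(7, 6, 6))
  expect_equal(voxels(projectZ(s, 1, "max")), matrix(7, 6, 6))

  a <- array(0, c(3, 1, 1)); a[, 1, 1] <- c(1, 9, 2)
  s <- ImageStack(a, c(0.1, 0.1, 0.1))
  expect_equal(voxels(projectZ(s, 1, "median"))[1, 1], 2)
  expect_equal(voxels(projectZ(s, 1, "max"))[1, 1], 9)

  set.seed(11)
  a <- array(runif(3 * 8 * 8), c(3, 8, 8))
  s <- ImageStack(a, c(0.1, 0.1, 0.1))
  med <- apply(a, c(2, 3), median)
  mx <- apply(a, c(2, 3), max)
  expect_equal(voxels(projectZ(s, 1, "median")), med)
  expect_equal(voxels(projectZ(s, 1, "max")), mx)
  expect_error(projectZ(s, "nope"), "unknown channel")
})

test_that("disk median filter matches brute-force neighborhood median", {
  set.seed(4)
  img <- matrix(runif(256, 0, 50), 16, 16)
  expect_equal(medianFilterDisk(img, 0L), img)

  flat <- matrix(5, 9, 9); flat[5, 5] <- 99
  expect_equal(medianFilterDisk(flat, 1L), matrix(5, 9, 9))

  # brute force with mirror reflection, disk = Euclidean distance <= r
  refl <- function(i, n) { p <- (i - 1) %% (2 * (n - 1)); ifelse(p < n, p + 1, 2 * n - 1 - p) }
  for (r in c(1L, 2L)) {
    got <- medianFilterDisk(img, r)
    off <- expand.grid(dy = -r:r, dx = -r:r)
    off <- off[off$dy^2 + off$dx^2 <= r^2, ]
    exp_img <- img
    for (i in 1:16) for (j in 1:16) {
      vals <- mapply(function(dy, dx) img[refl(i + dy, 16), refl(j + dx, 16)],
                     off$dy, off$dx)
      exp_img[i, j] <- median(vals)
    }
    expect_equal(got, exp_img, info = paste("radius", r))
  }
  expect_error(medianFilterDisk(img, -1), "radius")
})

test_that("white top-hat removes background and preserves small peaks", {
  flat <- matrix(3.5, 12, 12)
  expect_equal(topHatWhite(flat, 5L), matrix(0, 12, 12))

  peak <- matrix(2, 15, 15); peak[8, 8] <- 2 + 7
  th <- topHatWhite(peak, 5L)
  expect_equal(th[8, 8], 7)
  expect_equal(max(th[-(7 * 15 + 8)]), 0)

  # equals clipped-window erosion-then-dilation subtracted from input
  set.seed(9)
  img <- matrix(runif(256, 0, 80), 16, 16)
  r <- 2
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= r^2, ]
  er <- img
  for (i in 1:16) for (j in 1:16) {
    ii <- i + off$dy; jj <- j + off$dx
    ok <- ii >= 1 & ii <= 16 & jj >= 1 & jj <= 16
    er[i, j] <- min(img[cbind(ii[ok], jj[ok])])
  }
  op <- er
  for (i in 1:16) for (j in 1:16) {
    ii <- i + off$dy; jj <- j + off$dx
    ok <- ii >= 1 & ii <= 16 & jj >= 1 & jj <= 16
    op[i, j] <- max(er[cbind(ii[ok], jj[ok])])
  }
  expect_equal(topHatWhite(img, r), pmax(img - op, 0))

  # pointwise bounded by input, nonnegative
  out <- topHatWhite(img, 5L)
  expect_true(all(out >= 0) && all(out <= img + 1e-12))
  expect_error(topHatWhite(img, 0), "radius")
})

test_that("3D Gaussian smoothing is normalized, separable and exact at sigma 0", {
  set.seed(2)
  a <- array(runif(8^3), c(8, 8, 8))
  s <- ImageStack(a, c(1, 1, 1))
  expect_identical(voxels(smooth3D(s, 0)), voxels(s))

  # impulse response sums to 1 (kernel normalization, away from borders)
  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  sm <- smooth3D(ImageStack(imp, c(1, 1, 1)), 1)
  expect_equal(sum(voxels(sm)), 1, tolerance = 1e-12)

  # separable result equals dense 3D convolution on an 8^3 stack
  sig <- 1
  h <- ceiling(3 * sig)
  k1 <- exp(-((-h:h)^2) / (2 * sig^2)); k1 <- k1 / sum(k1)
  k3 <- outer(outer(k1, k1), k1)
  dim(k3) <- c(length(k1), length(k1), length(k1))
  refl <- function(i, n) { p <- (i - 1) %% (2 * (n - 1)); ifelse(p < n, p + 1, 2 * n - 1 - p) }
  dense <- array(0, dim(a))
  for (z in 1:8) for (y in 1:8) for (x in 1:8) {
    acc <- 0
    for (dz in -h:h) for (dy in -h:h) for (dx in -h:h)
      acc <- acc + k3[dz + h + 1, dy + h + 1, dx + h + 1] *
        a[refl(z + dz, 8), refl(y + dy, 8), refl(x + dx, 8)]
    dense[z, y, x] <- acc
  }
  expect_equal(getChannel(smooth3D(ImageStack(a, c(1, 1, 1)), sig), 1),
               dense, tolerance = 1e-12)
})

test_that("Triangle threshold separates modes and rejects degenerate input", {
  h <- integer(256); h[10] <- 1000L; h[200] <- 50L
  bin <- triangleBinFromCounts(h)
  expect_gt(bin, 10); expect_lt(bin, 200)

  img <- matrix(c(rep(1, 90), rep(10, 10)), 10, 10)
  tr <- triangleThreshold(img)
  expect_s4_class(tr, "ThresholdResult")
  expect_gt(tr@threshold, 1); expect_lt(tr@threshold, 10)
  expect_true(tr@threshold >= min(img) && tr@threshold <= max(img))

  expect_error(triangleThreshold(matrix(3, 5, 5)), "degenerate histogram")

  # invariance to uniform rescaling of counts
  set.seed(21)
  for (i in 1:20) {
    h <- randomHistogram(i + 400)
    expect_identical(triangleBinFromCounts(h), triangleBinFromCounts(h * 37))
  }
})

test_that("binarize thresholds strictly above and keeps geometry", {
  img <- Image2D(matrix(1:9, 3, 3), c(0.1, 0.1))
  expect_false(any(voxels(binarize(img, 9))))
  expect_true(all(voxels(binarize(img, 0))))
  set.seed(5)
  m <- matrix(runif(64), 8, 8)
  thr <- 0.5
  expect_identical(voxels(binarize(Image2D(m, c(1, 1)), thr)), m > thr)
  expect_error(binarize(Image2D(m, c(1, 1)), NA_real_), "finite")
})

test_that("median projection and filter are idempotent on constant images", {
  c5 <- matrix(5, 10, 10)
  expect_equal(medianFilterDisk(medianFilterDisk(c5, 2L), 2L), c5)
  s <- ImageStack(array(5, c(3, 10, 10)), c(0.1, 0.1, 0.1))
  expect_equal(voxels(projectZ(s, 1, "median")), c5)
})
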
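# Independent oracles used across the suite. These deliberately share no
# code with the package: flood fill by frontier expansion, Triangle by
# exhaustive point-to-line distance, the test statistics by their
# textbook formulas.

# connected components by breadth-first frontier expansion
floodFillComponents <- function(maskArr, connectivity) {
  d <- dim(maskArr)
  nd <- length(d)
  g <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if ((nd == 2 && connectivity == 4) || (nd == 3 && connectivity == 6))
    g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  mult <- cumprod(c(1, d[-nd]))
  visited <- !maskArr
  comps <- list()
  for (start in which(maskArr)) {
    if (visited[start]) next
    visited[start] <- TRUE
    comp <- integer(0)
    frontier <- start
    while (length(frontier)) {
      comp <- c(comp, frontier)
      co <- arrayInd(frontier, d)
      cand <- integer(0)
      for (k in seq_len(nrow(g))) {
        nc <- sweep(co, 2, g[k, ], "+")
        ok <- rowSums(nc >= 1L) == nd &
          rowSums(sweep(nc, 2, d, "<=")) == nd
        if (!any(ok)) next
        cand <- c(cand, as.integer((nc[ok, , drop = FALSE] - 1L) %*% mult) + 1L)
      }
      cand <- unique(cand)
      cand <- cand[!visited[cand]]
      visited[cand] <- TRUE
      frontier <- cand
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, 0L))]
}

# components of a LabeledObjects map as a canonical list of index sets
componentsOfLabels <- function(lab) {
  lm <- voxels(lab)
  n <- max(0L, max(lm))
  if (n == 0L) return(list())
  sets <- split(which(lm > 0L), lm[lm > 0L])
  sets <- lapply(sets, sort)
  names(sets) <- NULL
  sets[order(vapply(sets, min, 0L))]
}

# exhaustive Triangle: distance of each bin to the peak-tail chord,
# computed in slope-intercept form on peak-normalized counts
triangleOracleBin <- function(counts) {
  cn <- counts / max(counts)
  peak <- which(cn == max(cn))[1]
  nz <- which(counts > 0)
  lo <- min(nz); hi <- max(nz)
  if ((hi - peak) >= (peak - lo)) { a <- peak; b <- hi } else { a <- lo; b <- peak }
  if (a == b) return(a)
  m <- (cn[b] - cn[a]) / (b - a)
  icpt <- cn[a] - m * a
  cand <- a:b
  d <- abs(cn[cand] - (m * cand + icpt)) / sqrt(1 + m^2)
  cand[which(d == max(d))[1]]
}

randomHistogram <- function(seed) {
  set.seed(seed)
  kind <- seed %% 4
  h <- switch(kind + 1,
    { # decaying background + bright tail mode
      x <- 1:256
      round(5000 * exp(-x / runif(1, 3, 30)) +
              300 * exp(-(x - runif(1, 120, 240))^2 / runif(1, 50, 800)) +
              rpois(256, 2))
    },
    round(runif(256, 0, 100)),                        # flat noise
    { h <- integer(256)                               # sparse spikes
      i <- sample(256, sample(3:20, 1)); h[i] <- rpois(length(i), 500) + 1L
      h },
    { # two clean modes
      x <- 1:256
      round(4000 * exp(-(x - 20)^2 / 60) + 600 * exp(-(x - 200)^2 / 400))
    })
  if (sum(h > 0) < 2) h[c(10, 200)] <- c(50L, 10L)
  h
}

# Welch's ANOVA by formula
welchOracle <- function(values, groups) {
  sp <- split(values, groups)
  k <- length(sp)
  n <- lengths(sp)
  m <- vapply(sp, mean, 0)
  v <- vapply(sp, var, 0)
  w <- n / v
  mw <- sum(w * m) / sum(w)
  A <- sum(w * (m - mw)^2) / (k - 1)
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * sum((1 - w / sum(w))^2 / (n - 1))
  Fv <- A / B
  df2 <- (k^2 - 1) / (3 * sum((1 - w / sum(w))^2 / (n - 1)))
  c(F = Fv, df2 = df2, p = pf(Fv, k - 1, df2, lower.tail = FALSE))
}

# Kruskal-Wallis H with tie correction, by formula
kruskalOracle <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  sp <- split(r, groups)
  H <- 12 / (N * (N + 1)) * sum(lengths(sp) * vapply(sp, mean, 0)^2) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# one-way repeated-measures ANOVA F by sums of squares
rmAnovaOracle <- function(value, condition, replicate) {
  gm <- mean(value)
  condM <- tapply(value, condition, mean)
  repM <- tapply(value, replicate, mean)
  a <- length(condM); b <- length(repM)
  ssCond <- b * sum((condM - gm)^2)
  ssRep <- a * sum((repM - gm)^2)
  ssTot <- sum((value - gm)^2)
  ssErr <- ssTot - ssCond - ssRep
  Fv <- (ssCond / (a - 1)) / (ssErr / ((a - 1) * (b - 1)))
  c(F = Fv, p = pf(Fv, a - 1, (a - 1) * (b - 1), lower.tail = FALSE))
}

randomMask3d <- function(seed, d = c(20L, 20L, 20L), p = 0.4) {
  set.seed(seed)
  BinaryMask(array(runif(prod(d)) < p, d), rep(0.5, length(d)))
}
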
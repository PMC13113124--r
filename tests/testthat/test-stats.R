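test_that("percent-of-vehicle normalization anchors the vehicle at 100", {
  veh <- c(140, 160)
  expect_equal(normalizePercentOfVehicle(mean(veh), veh), 100)
  expect_equal(normalizePercentOfVehicle(50, veh, background = 50), 0)
  expect_equal(normalizePercentOfVehicle(125, c(140, 160), background = 50), 75)
  expect_error(normalizePercentOfVehicle(1, c(1, 2), background = 10),
               "positive")
})

test_that("densitometry normalization maps the control to one", {
  expect_equal(densitometryNormalize(30, 15, 30 / 15), 1)
  expect_equal(densitometryNormalize(60, 15, 30 / 15), 2)
  set.seed(8)
  target <- runif(6, 10, 100); ref <- runif(6, 5, 50)
  ctrl <- target[1] / ref[1]
  expect_equal(densitometryNormalize(target, ref, ctrl),
               (target / ref) / ctrl)
  expect_error(densitometryNormalize(5, 0, 1), "positive")
})

test_that("autophagic index is the Baf/untreated ratio", {
  expect_equal(autophagicIndex(2, 2), 1)
  expect_equal(autophagicIndex(3, 2), 1.5)
  expect_equal(autophagicIndex(c(3, 4), c(2, 8)), c(1.5, 0.5))
  expect_error(autophagicIndex(1, 0), "positive")
})

welchData <- data.frame(
  condition = rep(c("a", "b", "c"), each = 4),
  replicate = rep(1:4, 3),
  value = c(0.9, 1.8, 2.5, 3.3, 2.0, 4.1, 5.2, 7.9, 1.1, 1.3, 1.2, 1.6))

dunnData <- data.frame(
  condition = rep(c("a", "b", "c"), each = 5),
  replicate = rep(1:5, 3),
  value = c(1.2, 2.3, 3.1, 4.8, 2.2,
            2.1, 3.9, 4.5, 5.0, 6.2,
            7.1, 8.3, 6.9, 9.0, 7.7))

test_that("Welch ANOVA matches the textbook formula and the null case", {
  r <- welchAnova(welchData)
  o <- welchOracle(welchData$value, welchData$condition)
  expect_equal(r@statistic, unname(o["F"]), tolerance = 1e-8)
  expect_equal(r@pValue, unname(o["p"]), tolerance = 1e-8)
  # frozen independent reference for the same data
  expect_equal(r@statistic, 4.4874938360, tolerance = 1e-8)
  expect_equal(r@pValue, 0.0906379536, tolerance = 1e-8)

  ident <- data.frame(condition = rep(c("a", "b", "c"), each = 4),
                      value = rep(c(1, 2, 3, 4), 3))
  ri <- welchAnova(ident)
  expect_equal(ri@statistic, 0)
  expect_equal(ri@pValue, 1)
  expect_error(welchAnova(data.frame(condition = "a", value = 1)),
               "at least 2")
})

test_that("Kruskal-Wallis matches the tie-corrected formula", {
  r <- kruskalWallis(dunnData)
  expect_equal(r@statistic, kruskalOracle(dunnData$value, dunnData$condition),
               tolerance = 1e-10)
  expect_equal(r@statistic, 10.22, tolerance = 1e-8)  # frozen reference

  perm <- data.frame(condition = rep(c("a", "b", "c"), each = 4),
                     value = c(1, 2, 3, 4, 4, 3, 2, 1, 2, 1, 4, 3))
  expect_equal(kruskalWallis(perm)@statistic, 0)
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(17)
  d <- data.frame(condition = rep(c("ctl", "cbe", "ima"), each = 4),
                  replicate = rep(1:4, 3))
  d$value <- c(1, 1.2, 0.9, 1.1, 1.9, 2.2, 1.7, 2.4, 1.2, 1.5, 1.0, 1.4) +
    rep(rnorm(4, 0, 0.2), 3)
  r <- rmAnova(d)
  o <- rmAnovaOracle(d$value, d$condition, d$replicate)
  expect_equal(r@statistic, unname(o["F"]), tolerance = 1e-8)
  expect_equal(r@pValue, unname(o["p"]), tolerance = 1e-8)

  expect_error(rmAnova(d[-1, ]), "incomplete blocks")
  # technical replicates are averaged before testing
  d2 <- rbind(d, d)    # duplicated technical values change nothing
  expect_equal(rmAnova(d2)@statistic, r@statistic, tolerance = 1e-10)
})

test_that("Dunn post hoc reproduces the frozen rank-based reference", {
  ph <- postHoc(dunnData, "dunn")
  ph <- ph[order(ph$group1, ph$group2), ]
  expect_equal(ph$statistic,
               c(-0.9192388155, -3.1112698372, -2.1920310217),
               tolerance = 1e-8)
  expect_equal(ph$p_adj, c(1, 0.0055885389, 0.0851318002), tolerance = 1e-8)
})

test_that("classical Dunnett agrees with an established implementation", {
  skip_if_not_installed("multcomp")
  set.seed(42)
  d <- data.frame(condition = rep(c("ctl", "t1", "t2", "t3"), each = 6))
  d$value <- rnorm(24, mean = rep(c(0, 0.5, 1.5, 0.1), each = 6), sd = 1)
  ph <- postHoc(d, "dunnett", control = "ctl", varEqual = TRUE)
  fit <- stats::aov(value ~ condition, data = transform(d, condition = factor(condition)))
  gl <- summary(multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett")))
  ref <- as.numeric(gl$test$pvalues)
  ph <- ph[match(c("t1", "t2", "t3"), ph$group1), ]
  expect_equal(ph$p_adj, ref, tolerance = 5e-3, ignore_attr = TRUE)
})

test_that("Welch-SE Dunnett behaves sensibly and degenerates to p = 1", {
  set.seed(9)
  d <- data.frame(condition = rep(c("ctl", "t1", "t2"), each = 8))
  d$value <- rnorm(24, rep(c(0, 0, 3), each = 8), rep(c(1, 3, 1), each = 8))
  ph <- postHoc(d, "dunnett", control = "ctl")
  expect_true(ph$p_adj[ph$group1 == "t2"] < 0.01)
  expect_true(ph$p_adj[ph$group1 == "t1"] > 0.1)
  expect_error(postHoc(d, "dunnett", control = "nope"), "unknown control")

  ident <- data.frame(condition = rep(c("a", "b", "c"), each = 4),
                      value = rep(c(1, 2, 3, 4), 3))
  for (m in c("dunnett", "dunn", "tukey", "bonferroni")) {
    ph <- postHoc(ident, m, control = "a")
    expect_true(all(ph$p_adj == 1), info = m)
  }
})

test_that("Bonferroni multiplies raw p by the comparison count, capped", {
  set.seed(10)
  d <- data.frame(condition = rep(c("a", "b", "c"), each = 5),
                  value = rnorm(15, rep(c(0, 1, 0.2), each = 5)))
  ph <- postHoc(d, "bonferroni")
  for (j in seq_len(nrow(ph))) {
    raw <- t.test(d$value[d$condition == ph$group1[j]],
                  d$value[d$condition == ph$group2[j]])$p.value
    expect_equal(ph$p_adj[j], min(3 * raw, 1), tolerance = 1e-10)
  }
})

test_that("adjusted p-values are valid probabilities above the raw ones", {
  set.seed(33)
  for (i in 1:10) {
    d <- data.frame(condition = rep(c("a", "b", "c", "d"), each = 5),
                    value = rnorm(20))
    ph <- postHoc(d, "dunn", padjust = "holm")
    raw <- 2 * pnorm(-abs(ph$statistic))
    expect_true(all(ph$p_adj >= raw - 1e-12))
    expect_true(all(ph$p_adj >= 0 & ph$p_adj <= 1))
  }
})

test_that("the normality report flags clearly non-normal groups", {
  set.seed(2)
  d <- data.frame(condition = rep(c("norm", "exp"), each = 30),
                  value = c(rnorm(30), rexp(30)^3))
  rep_ <- normalityReport(d)
  expect_true(rep_$normal[rep_$condition == "norm"])
  expect_false(rep_$normal[rep_$condition == "exp"])
})
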
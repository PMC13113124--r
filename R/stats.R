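#' Average technical replicates within biological replicates
#'
#' Biological replicates are the statistical unit; technical values are
#' averaged within each (condition, replicate) pair before any test.
#'
#' @param data data.frame with columns \code{condition},
#'   \code{replicate}, \code{value} (long format)
#' @return data.frame with one row per condition x biological replicate
#' @export
aggregateBiological <- function(data) {
  stopifnot(all(c("condition", "value") %in% names(data)))
  if (!"replicate" %in% names(data)) return(data)
  out <- aggregate(value ~ condition + replicate, data = data, FUN = mean)
  out[order(out$condition, out$replicate), , drop = FALSE]
}

checkGroups <- function(data, minGroups = 2L) {
  if (!all(c("condition", "value") %in% names(data)))
    stop("data must have columns 'condition' and 'value'")
  if (any(!is.finite(data$value))) stop("values must be finite")
  g <- table(data$condition)
  if (length(g) < minGroups) stop("need at least ", minGroups, " conditions")
  if (any(g == 0)) stop("empty group")
  invisible(g)
}

#' Express values as percentage of the vehicle condition
#'
#' Background-subtracted values relative to the mean of
#' background-subtracted vehicle values, times 100; the normalization
#' used for luminescence-based ATP measurements. By construction the
#' vehicle mean maps to 100.
#'
#' @param values numeric measurements
#' @param vehicleValues numeric vehicle-condition measurements from the
#'   same experiment
#' @param background scalar background signal (default 0)
#' @return numeric percentages
#' @examples
#' normalizePercentOfVehicle(c(125, 150), c(140, 160), background = 50)
#' @export
normalizePercentOfVehicle <- function(values, vehicleValues, background = 0) {
  denom <- mean(vehicleValues - background)
  if (!is.finite(denom) || denom <= 0)
    stop("mean background-subtracted vehicle signal must be positive")
  100 * (values - background) / denom
}

#' Densitometry normalization to a loading control and a control sample
#'
#' Target band intensity divided by its loading-control (or, for
#' phosphorylated targets, total-protein) band, expressed relative to
#' the same ratio in the control sample, so the control maps to 1.
#'
#' @param target numeric target-band intensities
#' @param reference numeric loading-control intensities (> 0)
#' @param controlRatio scalar target/reference ratio of the control
#'   sample (> 0)
#' @return numeric relative levels
#' @export
densitometryNormalize <- function(target, reference, controlRatio) {
  if (any(reference <= 0)) stop("reference intensities must be positive")
  if (length(controlRatio) != 1L || controlRatio <= 0)
    stop("controlRatio must be a positive scalar")
  (target / reference) / controlRatio
}

#' Autophagic index
#'
#' Ratio of p62/SQSTM1 levels in lysosome-blocked (bafilomycin A1)
#' versus untreated conditions; a flux readout where larger values mean
#' more degradation-competent autophagy. Vectorized over replicates.
#'
#' @param p62Baf p62 level(s) with Baf A1
#' @param p62Untreated p62 level(s) without Baf A1 (> 0)
#' @return elementwise ratio
#' @export
autophagicIndex <- function(p62Baf, p62Untreated) {
  if (any(p62Untreated <= 0)) stop("untreated p62 levels must be positive")
  p62Baf / p62Untreated
}

testResult <- function(statistic, parameter, p, method, nGroups) {
  new("TestResult", statistic = unname(statistic),
      parameter = parameter, pValue = unname(p), method = method,
      posthoc = data.frame(), nGroups = as.integer(nGroups))
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' @param data long-format data.frame (condition, replicate, value);
#'   technical values are averaged within biological replicate first
#' @return a \linkS4class{TestResult}
#' @seealso \code{\link{postHoc}} for the Dunnett companion
#' @export
welchAnova <- function(data) {
  d <- aggregateBiological(data)
  checkGroups(d)
  ft <- oneway.test(value ~ factor(condition), data = d, var.equal = FALSE)
  p <- if (ft$statistic == 0) 1 else unname(ft$p.value)
  testResult(ft$statistic, ft$parameter, p,
             "Welch's one-way ANOVA (unequal variances)",
             length(unique(d$condition)))
}

#' Kruskal-Wallis rank-sum test
#'
#' @inheritParams welchAnova
#' @return a \linkS4class{TestResult}
#' @export
kruskalWallis <- function(data) {
  d <- aggregateBiological(data)
  checkGroups(d)
  kt <- kruskal.test(value ~ factor(condition), data = d)
  testResult(kt$statistic, kt$parameter, unname(kt$p.value),
             "Kruskal-Wallis rank-sum test", length(unique(d$condition)))
}

#' One-way repeated-measures ANOVA
#'
#' Requires complete blocks: after technical averaging every biological
#' replicate must contribute exactly one value to every condition.
#'
#' @inheritParams welchAnova
#' @return a \linkS4class{TestResult}
#' @export
rmAnova <- function(data) {
  if (!"replicate" %in% names(data))
    stop("repeated-measures ANOVA needs a 'replicate' column")
  d <- aggregateBiological(data)
  checkGroups(d)
  tab <- table(d$replicate, d$condition)
  if (any(tab != 1L))
    stop("incomplete blocks: every replicate needs one value per condition")
  d$condition <- factor(d$condition)
  d$replicate <- factor(d$replicate)
  fit <- aov(value ~ condition + Error(replicate), data = d)
  s <- summary(fit)[["Error: Within"]][[1]]
  row <- grep("^condition", rownames(s))
  Fv <- s[row, "F value"]
  p <- s[row, "Pr(>F)"]
  df <- c(df1 = s[row, "Df"], df2 = s[nrow(s), "Df"])
  testResult(Fv, df, min(p, 1), "One-way repeated-measures ANOVA",
             nlevels(d$condition))
}

#' Post hoc pairwise comparisons
#'
#' \describe{
#'   \item{dunnett}{All treatments against \code{control}. By default
#'     the standard errors are unpooled per-group (Welch-style) with
#'     Satterthwaite degrees of freedom, the companion to Welch's
#'     ANOVA; \code{varEqual = TRUE} gives the classical pooled-variance
#'     Dunnett procedure. Multiplicity is handled exactly through the
#'     multivariate t distribution of the comparison statistics.}
#'   \item{dunn}{Rank-based z statistics on the joint ranking with tie
#'     correction, the companion to Kruskal-Wallis; adjusted with
#'     \code{padjust} (default Bonferroni).}
#'   \item{tukey}{Tukey's honest significant difference on a one-way
#'     fit (studentized range distribution).}
#'   \item{bonferroni}{Pairwise t tests (paired when \code{paired =
#'     TRUE}) with raw p multiplied by the number of comparisons,
#'     capped at 1.}
#' }
#'
#' @param data long-format data.frame (condition, replicate, value)
#' @param method one of "dunnett", "dunn", "tukey", "bonferroni"
#' @param control control condition label (required for dunnett)
#' @param varEqual dunnett only: pool variances (default FALSE)
#' @param padjust dunn only: p.adjust method (default "bonferroni")
#' @param paired bonferroni only: paired t tests on complete blocks
#' @return data.frame with columns group1, group2, estimate, statistic,
#'   p_adj (one row per comparison)
#' @export
postHoc <- function(data, method = c("dunnett", "dunn", "tukey", "bonferroni"),
                    control = NULL, varEqual = FALSE,
                    padjust = "bonferroni", paired = FALSE) {
  method <- match.arg(method)
  d <- aggregateBiological(data)
  checkGroups(d)
  d$condition <- as.character(d$condition)
  groups <- split(d$value, d$condition)
  switch(method,
         dunnett = dunnettTest(groups, control, varEqual),
         dunn = dunnTest(groups, padjust),
         tukey = tukeyTest(d),
         bonferroni = bonferroniTest(d, paired))
}

dunnettTest <- function(groups, control, varEqual) {
  if (is.null(control) || !control %in% names(groups))
    stop("unknown control group")
  trt <- setdiff(names(groups), control)
  x0 <- groups[[control]]
  n0 <- length(x0); m0 <- mean(x0); v0 <- var(x0)
  k <- length(trt)
  est <- se <- tstat <- dfs <- numeric(k)
  if (varEqual) {
    allv <- unlist(groups)
    ns <- lengths(groups)
    sp2 <- sum(vapply(groups, function(g) (length(g) - 1) * var(g), 0)) /
      (length(allv) - length(groups))
    for (i in seq_len(k)) {
      xi <- groups[[trt[i]]]
      est[i] <- mean(xi) - m0
      se[i] <- sqrt(sp2 * (1 / length(xi) + 1 / n0))
      tstat[i] <- est[i] / se[i]
    }
    df <- length(allv) - length(groups)
    lam <- sqrt(lengths(groups)[trt] / (lengths(groups)[trt] + n0))
    R <- outer(lam, lam)
    diag(R) <- 1
  } else {
    covs <- v0 / n0
    for (i in seq_len(k)) {
      xi <- groups[[trt[i]]]
      ni <- length(xi); vi <- var(xi)
      est[i] <- mean(xi) - m0
      se[i] <- sqrt(vi / ni + v0 / n0)
      tstat[i] <- est[i] / se[i]
      dfs[i] <- (vi / ni + v0 / n0)^2 /
        ((vi / ni)^2 / (ni - 1) + (v0 / n0)^2 / (n0 - 1))
    }
    df <- min(dfs)           # conservative common df for the mvt step
    R <- outer(se, se, function(a, b) covs / (a * b))
    diag(R) <- 1
  }
  padj <- vapply(seq_len(k), function(i) {
    if (tstat[i] == 0) return(1)
    lowtri <- rep(-abs(tstat[i]), k)
    pr <- mvtnorm::pmvt(lower = lowtri, upper = -lowtri, corr = R,
                        df = as.integer(round(df)))
    min(max(1 - pr, 0), 1)
  }, 0)
  data.frame(group1 = trt, group2 = control, estimate = est,
             statistic = tstat, p_adj = padj, row.names = NULL)
}

dunnTest <- function(groups, padjust) {
  x <- unlist(groups)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- table(x)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- combn(names(groups), 2)
  z <- est <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    sd_ab <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[[a]] + 1 / ns[[b]]))
    est[j] <- rbar[[a]] - rbar[[b]]
    z[j] <- if (sd_ab == 0) 0 else est[j] / sd_ab
  }
  praw <- 2 * pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], estimate = est,
             statistic = z, p_adj = p.adjust(praw, method = padjust),
             row.names = NULL)
}

tukeyTest <- function(d) {
  fit <- aov(value ~ factor(condition), data = d)
  tk <- TukeyHSD(fit)[[1]]
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(group1 = vapply(nm, `[`, "", 1),
             group2 = vapply(nm, `[`, "", 2),
             estimate = tk[, "diff"],
             statistic = NA_real_,
             p_adj = pmin(tk[, "p adj"], 1), row.names = NULL)
}

bonferroniTest <- function(d, paired) {
  conds <- sort(unique(d$condition))
  pairs <- combn(conds, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    estimate = NA_real_, statistic = NA_real_,
                    p_adj = NA_real_)
  for (j in seq_len(m)) {
    a <- d[d$condition == pairs[1, j], ]
    b <- d[d$condition == pairs[2, j], ]
    if (paired) {
      a <- a[order(a$replicate), ]; b <- b[order(b$replicate), ]
      if (!identical(as.character(a$replicate), as.character(b$replicate)))
        stop("incomplete blocks for paired comparisons")
    }
    if (identical(a$value, b$value)) {
      out$estimate[j] <- 0; out$statistic[j] <- 0; out$p_adj[j] <- 1
      next
    }
    if (paired && var(a$value - b$value) == 0) {
      # constant nonzero difference: t is unbounded
      out$estimate[j] <- mean(a$value - b$value)
      out$statistic[j] <- sign(out$estimate[j]) * Inf
      out$p_adj[j] <- 0
      next
    }
    tt <- t.test(a$value, b$value, paired = paired)
    out$estimate[j] <- if (paired) unname(tt$estimate)
                       else unname(diff(rev(tt$estimate)))
    out$statistic[j] <- unname(tt$statistic)
    out$p_adj[j] <- min(tt$p.value * m, 1)
  }
  out
}

#' Shapiro-Wilk normality report per group
#'
#' Normality gatekeeper: reports per-condition Shapiro-Wilk p-values so
#' the analyst can choose the parametric or rank-based family; it never
#' switches tests silently.
#'
#' @inheritParams welchAnova
#' @param alpha flag level (default 0.05)
#' @return data.frame (condition, W, p, normal)
#' @export
normalityReport <- function(data, alpha = 0.05) {
  d <- aggregateBiological(data)
  checkGroups(d, minGroups = 1L)
  res <- lapply(split(d$value, d$condition), function(v) {
    if (length(v) < 3 || length(unique(v)) == 1)
      return(c(W = NA_real_, p = NA_real_))
    s <- shapiro.test(v)
    c(W = unname(s$statistic), p = s$p.value)
  })
  out <- do.call(rbind, res)
  data.frame(condition = rownames(out), W = out[, "W"], p = out[, "p"],
             normal = out[, "p"] >= alpha, row.names = NULL)
}
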
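# Validation statistics: Bland-Altman agreement against a reference, mean
# absolute error, success rate, ICC with F-based confidence intervals, and
# one-way ANOVA with effect sizes and post-hoc power.

#' Limits of agreement from a bias and SD
#'
#' @param bias mean difference.
#' @param sd standard deviation of the differences (>= 0).
#' @param z multiplier (1.96 for 95% limits).
#' @return c(lower, upper) = bias -/+ z * sd.
#' @examples
#' loaFromBiasSd(-0.8, 2.4)   # c(-5.504, 3.904)
#' @export
loaFromBiasSd <- function(bias, sd, z = 1.96) {
  stopifnot(sd >= 0)
  c(lower = bias - z * sd, upper = bias + z * sd)
}

#' Bland-Altman agreement of measurements against a reference
#'
#' Differences are \code{values - reference}; bias is their mean, sdDiff
#' their sample SD (n - 1 denominator), and the limits of agreement are
#' \code{bias +/- z * sdDiff}.  Values are stored at full precision;
#' rounding to one decimal is applied only when reporting (show method).
#'
#' @param values numeric measurements.
#' @param reference scalar reference (e.g. the phantom's 70 degrees) or a
#'   vector of paired reference measurements.
#' @param z limits-of-agreement multiplier (default 1.96).
#' @return an \linkS4class{AgreementStats}.
#' @examples
#' blandAltmanVsReference(c(68, 70, 72), 70)
#' @export
blandAltmanVsReference <- function(values, reference, z = 1.96) {
  stopifnot(z > 0)
  d <- values - reference
  if (length(d) < 2L)
    stop("blandAltmanVsReference: need >= 2 differences (SD undefined)")
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- loaFromBiasSd(bias, s, z)
  new("AgreementStats", bias = bias, sdDiff = s,
      loaLower = unname(loa[1]), loaUpper = unname(loa[2]),
      n = length(d), z = z)
}

#' Mean absolute error against a reference
#'
#' @param values numeric measurements.
#' @param reference scalar or paired vector.
#' @return mean of |value - reference|.
#' @export
meanAbsoluteError <- function(values, reference) {
  if (!length(values)) stop("meanAbsoluteError: empty input")
  mean(abs(values - reference))
}

#' Success rate as a fraction and a "k/n" count string
#'
#' @param outcomes logical vector of per-trial successes.
#' @return \code{list(rate = successes/n, label = "k/n")}.
#' @examples
#' successRate(rep(TRUE, 40))   # rate 1, label "40/40"
#' @export
successRate <- function(outcomes) {
  if (!length(outcomes)) stop("successRate: empty input")
  k <- sum(outcomes)
  n <- length(outcomes)
  list(rate = k / n, label = sprintf("%d/%d", k, n))
}

# two-way mean squares of a complete subjects x raters matrix
twoWayMeanSquares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rowM <- rowMeans(m); colM <- colMeans(m)
  ssr <- k * sum((rowM - grand)^2)
  ssc <- n * sum((colM - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  c(MSR = ssr / (n - 1), MSC = ssc / (k - 1),
    MSE = sse / ((n - 1) * (k - 1)))
}

#' Two-way random-effects ICC with absolute agreement
#'
#' Computes ICC(2,1) (single measurement) or ICC(2,k) (average of the k
#' raters) from the two-way ANOVA mean squares of a complete
#' subjects x raters matrix, with the F-based 95% confidence interval.
#' The model label is recorded in the result.
#'
#' @param m numeric matrix, subjects in rows, raters/occasions in columns,
#'   no missing cells.
#' @param type "single" for ICC(2,1) (default), "average" for ICC(2,k).
#' @param conf confidence level (default 0.95).
#' @return an \linkS4class{ICCResult}.
#' @examples
#' m <- cbind(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 4.2))
#' iccTwoWay(m)
#' @export
iccTwoWay <- function(m, type = c("single", "average"), conf = 0.95) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("iccTwoWay: need >= 2 subjects and >= 2 raters")
  if (anyNA(m)) stop("iccTwoWay: missing cells are not supported")
  if (stats::var(as.vector(m)) == 0)
    stop("iccTwoWay: zero total variance, ICC undefined")
  n <- nrow(m); k <- ncol(m)
  ms <- twoWayMeanSquares(m)
  msr <- ms[["MSR"]]; msc <- ms[["MSC"]]; mse <- ms[["MSE"]]
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  # Satterthwaite df for the F bounds of the single-measure ICC
  a <- k * icc1 / (n * (1 - icc1))
  b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fL <- stats::qf(1 - alpha / 2, n - 1, v)
  fU <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - fL * mse) /
    (fL * (k * msc + (k * n - k - n) * mse) + n * msr)
  up1 <- n * (fU * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fU * msr)
  # degenerate designs (e.g. zero subject variance) can break the
  # Satterthwaite approximation; fall back to the admissible range
  if (!is.finite(lo1)) lo1 <- -1
  if (!is.finite(up1)) up1 <- 1
  lo1 <- min(lo1, icc1)
  up1 <- max(up1, icc1)
  if (type == "single") {
    new("ICCResult", icc = icc1, ciLower = lo1, ciUpper = up1,
        model = "ICC(2,1) two-way random, absolute agreement, single measurement",
        nSubjects = n, nRaters = k, meanSquares = ms)
  } else {
    sb <- function(x) k * x / (1 + (k - 1) * x)
    new("ICCResult", icc = sb(icc1), ciLower = sb(lo1), ciUpper = sb(up1),
        model = sprintf(
          "ICC(2,%d) two-way random, absolute agreement, average of %d", k, k),
        nSubjects = n, nRaters = k, meanSquares = ms)
  }
}

#' Cohen's f from eta squared
#'
#' @param eta2 proportion of variance explained, in [0, 1).
#' @return sqrt(eta2 / (1 - eta2)).
#' @examples
#' cohensFFromEta2(0.291)   # 0.6406...
#' @export
cohensFFromEta2 <- function(eta2) {
  if (any(eta2 < 0) || any(eta2 >= 1))
    stop("cohensFFromEta2: eta2 must lie in [0, 1)")
  sqrt(eta2 / (1 - eta2))
}

#' One-way ANOVA with effect sizes and post-hoc power
#'
#' Computes F, p, eta squared (SS_between / SS_total), Cohen's f, and the
#' post-hoc power at the observed effect size from the noncentral-F
#' distribution with noncentrality \code{f^2 * N} at alpha = 0.05.
#'
#' @param groups list of numeric vectors, one per group, each with >= 2
#'   observations.
#' @param alpha significance level used for the power computation.
#' @return an \linkS4class{AnovaResult}.
#' @examples
#' onewayAnova(list(c(1, 2, 3), c(4, 5, 6)))   # F = 13.5
#' @export
onewayAnova <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("onewayAnova: need >= 2 groups")
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L)) stop("onewayAnova: every group needs >= 2 observations")
  x <- unlist(groups)
  g <- length(groups)
  N <- length(x)
  grand <- mean(x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  sst <- ssb + ssw
  df1 <- g - 1; df2 <- N - g
  fstat <- if (ssw == 0 && ssb == 0) 0 else (ssb / df1) / (ssw / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  eta2 <- if (sst == 0) 0 else ssb / sst
  f <- cohensFFromEta2(min(eta2, 1 - 1e-12))
  power <- 1 - stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2,
                         ncp = f^2 * N)
  new("AnovaResult", fStat = fstat, pValue = p, eta2 = eta2, cohensF = f,
      power = power, groupNs = ns, df = c(df1, df2),
      sumSquares = c(SSB = ssb, SSW = ssw, SST = sst))
}
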
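# Agreement and reliability statistics.

test_that("limits of agreement reproduce hand-computed values", {
  expect_equal(unname(loaFromBiasSd(-0.8, 2.4, 1.96)), c(-5.504, 3.904))
  expect_equal(unname(loaFromBiasSd(3, 0, 1.96)), c(3, 3))
  expect_error(loaFromBiasSd(0, -1), "sd")
})

test_that("Bland-Altman against a scalar reference", {
  ba <- blandAltmanVsReference(c(68, 70, 72), 70)
  expect_equal(ba@bias, 0)
  expect_equal(ba@sdDiff, 2)
  expect_equal(ba@loaLower, -3.92)
  expect_equal(ba@loaUpper, 3.92)
  expect_identical(ba@n, 3L)

  exact <- blandAltmanVsReference(rep(70, 5), 70)
  expect_equal(exact@bias, 0)
  expect_equal(exact@loaLower, 0)
  expect_equal(exact@loaUpper, 0)

  expect_error(blandAltmanVsReference(70, 70), "2")
})

test_that("MAE and success rate", {
  expect_equal(meanAbsoluteError(c(70, 70, 70), 70), 0)
  expect_equal(meanAbsoluteError(c(69, 71), 70), 1)
  expect_error(meanAbsoluteError(numeric(0), 70), "empty")
  expect_equal(successRate(rep(TRUE, 40)),
               list(rate = 1, label = "40/40"))
  expect_equal(successRate(c(TRUE, FALSE))$rate, 0.5)
  expect_identical(successRate(rep(FALSE, 5))$label, "0/5")
  expect_error(successRate(logical(0)), "empty")
})

test_that("ICC(2,1) handles the degenerate branches", {
  # all raters agree exactly, subjects differ: perfect reliability
  m <- cbind(1:6, 1:6, 1:6)
  r <- iccTwoWay(m)
  expect_equal(r@icc, 1)
  # no subject variance, raters add distinct constants: non-positive ICC
  m2 <- cbind(rep(5, 6), rep(7, 6), rep(9, 6))
  expect_lte(iccTwoWay(m2)@icc, 0)
  # zero total variance is undefined
  expect_error(iccTwoWay(matrix(3, 4, 3)), "variance")
})

test_that("ICC(2,1) matches the independent aov-based oracle", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:25, 1); k <- sample(2:5, 1)
    m <- outer(rnorm(n, 0, runif(1, 0.5, 3)), rep(1, k)) +
         outer(rep(1, n), rnorm(k, 0, runif(1, 0.1, 1))) +
         matrix(rnorm(n * k), n, k)
    r <- iccTwoWay(m)
    expect_equal(r@icc, iccOracleAov(m), tolerance = 1e-10)
    expect_lte(r@ciLower, r@icc)
    expect_gte(r@ciUpper, r@icc)
  }
})

test_that("ICC(2,1) recovers the generating variance ratio", {
  set.seed(3)
  n <- 30; k <- 4
  m <- outer(rnorm(n, 0, 3), rep(1, k)) +
       outer(rep(1, n), rnorm(k, 0, sqrt(0.5))) +
       matrix(rnorm(n * k, 0, 1), n, k)
  r <- iccTwoWay(m)
  expect_lt(abs(r@icc - 9 / (9 + 0.5 + 1)), 0.05)
  expect_match(r@model, "ICC\\(2,1\\)")
})

test_that("ICC(2,k) is the Spearman-Brown step-up of ICC(2,1)", {
  set.seed(12)
  m <- matrix(rnorm(40), 10, 4) + rnorm(10)
  s <- iccTwoWay(m, "single")
  a <- iccTwoWay(m, "average")
  k <- 4
  expect_equal(a@icc, k * s@icc / (1 + (k - 1) * s@icc), tolerance = 1e-12)
  expect_gte(a@icc, s@icc)
})

test_that("one-way ANOVA matches hand computation and stats::aov", {
  r <- onewayAnova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r@fStat, 13.5)
  expect_equal(r@df, c(1, 4))
  expect_equal(r@sumSquares[["SSB"]], 13.5)
  expect_equal(r@sumSquares[["SSW"]], 4)

  set.seed(21)
  groups <- list(rnorm(8, 0), rnorm(10, 1), rnorm(7, 0.5))
  r2 <- onewayAnova(groups)
  long <- data.frame(y = unlist(groups),
                     g = factor(rep(seq_along(groups), lengths(groups))))
  tab <- summary(stats::aov(y ~ g, data = long))[[1]]
  expect_equal(r2@fStat, tab["g", "F value"], tolerance = 1e-10)
  expect_equal(r2@pValue, tab["g", "Pr(>F)"], tolerance = 1e-10)
  # eta2 complement identity
  expect_equal(r2@eta2 + r2@sumSquares[["SSW"]] / r2@sumSquares[["SST"]], 1)
  expect_gte(r2@power, 0); expect_lte(r2@power, 1)

  ident <- onewayAnova(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(ident@fStat, 0)
  expect_equal(ident@eta2, 0)

  expect_error(onewayAnova(list(1, c(2, 3))), "observations")
})

test_that("Cohen's f from eta squared", {
  expect_equal(cohensFFromEta2(0), 0)
  expect_equal(cohensFFromEta2(0.5), 1)
  expect_equal(roundHalfAway(cohensFFromEta2(0.291), 2L), 0.64)
  expect_error(cohensFFromEta2(1), "eta2")
})

test_that("agreement metrics are invariant to a common shift", {
  set.seed(55)
  vals <- rnorm(20, 70, 2)
  for (shift in c(-10, 4.2)) {
    b0 <- blandAltmanVsReference(vals, 70)
    b1 <- blandAltmanVsReference(vals + shift, 70 + shift)
    expect_equal(b1@bias, b0@bias, tolerance = 1e-12)
    expect_equal(b1@loaUpper - b1@loaLower, b0@loaUpper - b0@loaLower,
                 tolerance = 1e-12)
    expect_equal(meanAbsoluteError(vals + shift, 70 + shift),
                 meanAbsoluteError(vals, 70), tolerance = 1e-12)
    m <- matrix(vals, 5, 4)
    expect_equal(iccTwoWay(m + shift)@icc, iccTwoWay(m)@icc,
                 tolerance = 1e-10)
    g <- list(vals[1:10], vals[11:20])
    expect_equal(onewayAnova(lapply(g, `+`, shift))@eta2,
                 onewayAnova(g)@eta2, tolerance = 1e-10)
  }
})

test_that("AgreementStats enforces its limits-of-agreement identity", {
  set.seed(77)
  for (i in 1:10) {
    ba <- blandAltmanVsReference(rnorm(10, 70, 3), 70)
    expect_equal(ba@loaLower, ba@bias - ba@z * ba@sdDiff)
    expect_equal(ba@loaUpper, ba@bias + ba@z * ba@sdDiff)
  }
})
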
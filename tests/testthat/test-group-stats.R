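test_that("pooled t test reproduces the hand-computed example", {
  res <- studentTTest(c(1, 2, 3), c(2, 3, 4))
  # pooled s^2 = 1, t = -1 / sqrt(2/3)
  expect_equal(res$statistic, -1 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$p_value, 0.2878641, tolerance = 1e-6)
  expect_identical(res$df, 4)
  expect_equal(res$group_summaries$x$median, 2)
})

test_that("t test degenerate conventions hold", {
  x <- c(2, 5, 7)
  same <- studentTTest(x, x)
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  zeroSame <- studentTTest(c(3, 3), c(3, 3))
  expect_identical(zeroSame$p_value, 1)
  expect_warning(zeroDiff <- studentTTest(c(3, 3), c(4, 4)), "zero variance")
  expect_identical(zeroDiff$p_value, 0)
})

test_that("t test holds its nominal size under the null", {
  set.seed(606)
  reject <- mean(replicate(1000, {
    studentTTest(rnorm(30), rnorm(30))$p_value < 0.05
  }))
  expect_gt(reject, 0.03)
  expect_lt(reject, 0.07)
})

test_that("two-group ANOVA equals the squared t statistic", {
  set.seed(707)
  for (i in 1:10) {
    x <- rnorm(8, sd = 2); y <- rnorm(11, mean = 0.5)
    tt <- studentTTest(x, y)
    an <- oneWayAnova(c(x, y), rep(c("a", "b"), c(8, 11)))
    expect_equal(an$statistic, tt$statistic^2, tolerance = 1e-10)
    expect_equal(an$p_value, tt$p_value, tolerance = 1e-10)
  }
})

test_that("ANOVA matches a brute-force sum-of-squares oracle", {
  set.seed(808)
  v <- rnorm(18)
  g <- rep(c("a", "b", "c"), each = 6)
  res <- oneWayAnova(v, g)
  grand <- mean(v)
  means <- tapply(v, g, mean)
  ssb <- sum(6 * (means - grand)^2)
  ssw <- sum((v - means[g])^2)
  expect_equal(res$statistic, (ssb / 2) / (ssw / 15), tolerance = 1e-12)
  # constant input convention and validation
  expect_identical(oneWayAnova(rep(5, 6), rep(c("a", "b"), 3))$statistic, 0)
  expect_error(oneWayAnova(1:4, c("a", "a", "a", "b")), "fewer than 2")
})

test_that("group statistics are invariant to common affine transforms", {
  set.seed(909)
  x <- rnorm(10); y <- rnorm(12, 1)
  t0 <- studentTTest(x, y)
  t1 <- studentTTest(3 * x + 2, 3 * y + 2)
  expect_equal(t1$statistic, t0$statistic, tolerance = 1e-10)
  a0 <- oneWayAnova(c(x, y), rep(1:2, c(10, 12)))
  a1 <- oneWayAnova(c(3 * x + 2, 3 * y + 2), rep(1:2, c(10, 12)))
  expect_equal(a1$statistic, a0$statistic, tolerance = 1e-10)
})

test_that("bonferroni adjustment caps, scales and stays monotone", {
  expect_equal(bonferroniAdjust(c(0.01, 0.2, 0.04)),
               c(0.03, 0.6, 0.12))
  expect_equal(bonferroniAdjust(c(0.5, 0.5, 0.5)), c(1, 1, 1))
  expect_identical(bonferroniAdjust(0.123), 0.123)  # m = 1: identity
  p <- sort(runif(20))
  adj <- bonferroniAdjust(p)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
  expect_identical(bonferroniAdjust(bonferroniAdjust(rep(0.9, 5))),
                   rep(1, 5))  # idempotent above the cap
})

test_that("exact rank-sum p-values match the enumeration example", {
  res <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_true(res$exact)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  same <- wilcoxonRankSum(c(5, 6, 7), c(5, 6, 7))
  expect_identical(same$p_value, 1)
})

test_that("exact rank-sum agrees with an independent enumeration oracle", {
  set.seed(111)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    # draws from a small integer support force ties / midranks
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    res <- wilcoxonRankSum(x, y)
    expect_true(res$exact)
    expect_equal(res$p_value, enumerateWilcoxonP(x, y), tolerance = 1e-12)
  }
  # tie-free exact case against the base R reference
  x <- c(1.1, 2.3, 3.7, 4.2); y <- c(0.5, 2.9, 5.1)
  expect_equal(wilcoxonRankSum(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})

test_that("large-sample rank-sum approximation holds its size", {
  set.seed(222)
  reject <- mean(replicate(1000, {
    wilcoxonRankSum(rnorm(30), rnorm(30))$p_value < 0.05
  }))
  expect_gt(reject, 0.03)
  expect_lt(reject, 0.07)
})

test_that("probe panel covers every probe and flags degenerate ones", {
  co <- miniCohort()
  # make P2 constant
  m <- SummarizedExperiment::assay(methData(co))
  m["P2", ] <- 0.5
  meth <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = m),
    rowData = SummarizedExperiment::rowData(methData(co)))
  co2 <- Cohort(exprData(co), meth, clinicalData(co))
  pp <- probeCorrelationPanel(co2, "TG")
  expect_identical(nrow(pp), 2L)
  expect_identical(pp$reason[pp$probe_id == "P2"], "degenerate")
  expect_true(is.na(pp$pearson_r[pp$probe_id == "P2"]))
  expect_false(is.na(pp$pearson_r[pp$probe_id == "P1"]))
  expect_identical(pp$promoter_flag, c(TRUE, FALSE))
})

test_that("probe panel recovers a planted negative methylation correlation", {
  cfg <- syntheticConfig(nSamples = c("ER+" = 300L, "ER-" = 300L),
                         methExprCorrelation = -0.4,
                         promoterProbeCount = 5L, seed = 333L)
  sim <- generateCohort(cfg)
  pp <- probeCorrelationPanel(sim$cohort, "ID4")
  prom <- pp[pp$promoter_flag, ]
  expect_true(all(prom$pearson_r < 0))
  expect_true(all(abs(prom$pearson_r - (-0.4)) <= 0.1))
  expect_equal(prom$pearson_r,
               unname(sim$truth$realized_promoter_correlation),
               tolerance = 1e-12)
})
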
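test_that("standardization gives mean zero and unit Euclidean norm", {
  expect_equal(standardizeVector(c(1, 2, 3)),
               c(-1 / sqrt(2), 0, 1 / sqrt(2)), tolerance = 1e-12)
  set.seed(101)
  for (i in 1:20) {
    v <- standardizeVector(rnorm(sample(3:50, 1), sd = runif(1, 0.1, 10)))
    expect_lt(abs(mean(v)), 1e-12)
    expect_lt(abs(sqrt(sum(v^2)) - 1), 1e-12)
  }
  expect_error(standardizeVector(c(5, 5, 5)), "degenerate")
})

test_that("jacobi-position score follows the closed form sqrt(1 - r)", {
  # uncorrelated fixture: residualize to make r exactly 0
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  y0 <- residuals(lm(y ~ x))
  expect_equal(svdAssocScore(x, y0)$score, 1.0, tolerance = 1e-10)
  # perfect anticorrelation
  expect_equal(svdAssocScore(x, -x)$score, sqrt(2), tolerance = 1e-12)
  # brute-force oracle on random pairs, plus the full-SVD cross-check
  set.seed(202)
  for (i in 1:25) {
    a <- rnorm(30); b <- rnorm(30) + runif(1, -1, 1) * a
    r <- bruteForcePearson(a, b)
    res <- svdAssocScore(a, b)
    expect_equal(res$score, sqrt(1 - r), tolerance = 1e-10)
    expect_equal(res$r, r, tolerance = 1e-10)
    d <- svd(cbind(standardizeVector(a), standardizeVector(b)))$d
    expect_equal(sort(d), sort(c(sqrt(1 + r), sqrt(1 - r))),
                 tolerance = 1e-10)
    expect_equal(svdAssocScore(a, b, mode = "abs_correlation")$score,
                 sqrt(1 + abs(r)), tolerance = 1e-10)
  }
})

test_that("association score is invariant to affine rescaling", {
  set.seed(303)
  a <- rnorm(40); b <- rnorm(40) - 0.5 * a
  base <- svdAssocScore(a, b)$score
  expect_equal(svdAssocScore(3 * a - 7, b)$score, base, tolerance = 1e-12)
  expect_equal(svdAssocScore(a, 0.01 * b + 100)$score, base,
               tolerance = 1e-12)
})

test_that("degenerate association inputs are rejected", {
  expect_error(svdAssocScore(1:5, rep(2, 5)), "degenerate")
  expect_error(svdAssocScore(1:5, 1:4), "length mismatch")
  expect_error(svdAssocScore(c(1, 2), c(2, 1)), "fewer than 3")
})

test_that("pearson correlation matches its definition and conventions", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearsonCorrelation(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCorrelation(x, -x)$r, -1)
  set.seed(404)
  a <- rnorm(10); b <- rnorm(10) + a
  res <- pearsonCorrelation(a, b)
  expect_equal(res$r, bruteForcePearson(a, b), tolerance = 1e-12)
  ct <- cor.test(a, b)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  # symmetry and p range on random non-degenerate inputs
  for (i in 1:10) {
    u <- rnorm(12); v <- rnorm(12)
    f <- pearsonCorrelation(u, v); g <- pearsonCorrelation(v, u)
    expect_identical(f$r, g$r)
    expect_identical(f$p, g$p)
    expect_gt(f$p, 0)
    expect_lte(f$p, 1)
  }
  # pairwise-complete filtering
  a[3] <- NA
  expect_equal(pearsonCorrelation(a, b)$n, 9L)
})

test_that("median selection takes strictly-above-threshold genes", {
  co <- miniCohort()
  res <- runScreen(co, "TG", c("G1", "G2", "G3", "G4"),
                   selectionQuantile = 0.5)
  # per stratum: 4 distinct scores, median rule keeps exactly the top 2
  for (s in unique(res$stratum)) {
    sub <- res[res$stratum == s, ]
    expect_identical(sum(sub$selected), 2L)
    top2 <- sub$gene[order(-sub$svd_score)][1:2]
    expect_setequal(sub$gene[sub$selected], top2)
  }
  expect_identical(res$stratum, rep(sort(unique(res$stratum)), each = 4))
})

test_that("tied scores select nothing under the strict rule", {
  co <- miniCohort()
  em <- SummarizedExperiment::assay(exprData(co))
  tied <- rbind(em, A1 = em["TG", ], A2 = em["TG", ], A3 = em["TG", ],
                A4 = em["TG", ])
  co2 <- Cohort(
    SummarizedExperiment::SummarizedExperiment(
      assays = list(log2expr = tied)),
    methData(co), clinicalData(co))
  res <- runScreen(co2, "TG", c("A1", "A2", "A3", "A4"))
  expect_false(any(res$selected))
})

test_that("screen validates genes and strata", {
  co <- miniCohort()
  expect_error(runScreen(co, "TG", c("G1", "NOPE")), "absent.*NOPE")
  expect_error(runScreen(co, "TG", "G1", stratumVariable = "not_there"),
               "not found")
})

test_that("a planted single-stratum signal is recovered by the screen", {
  cfg <- syntheticConfig(
    nSamples = c("ER+" = 500L, "ER-" = 500L),
    panelGenes = sprintf("gene%02d", 1:66),
    plantedCorrelations = list(
      "ER+" = stats::setNames(rep(-0.4, 6), sprintf("gene%02d", 1:6)),
      "ER-" = stats::setNames(numeric(0), character(0))),
    survivalHR = c("ER+" = 1, "ER-" = 1),
    promoterProbeCount = 1L, bodyProbeCount = 0L,
    seed = 515L)
  sim <- generateCohort(cfg)
  res <- runScreen(sim$cohort, "ID4", cfg@panelGenes,
                   selectionQuantile = 1 - 6 / 66,
                   mode = "abs_correlation")
  selPos <- res$gene[res$stratum == "ER+" & res$selected]
  selNeg <- res$gene[res$stratum == "ER-" & res$selected]
  expect_setequal(selPos, sprintf("gene%02d", 1:6))
  # in the null stratum the quantile rule still flags a few top-ranked
  # noise genes, but never the planted ones
  expect_false(any(sprintf("gene%02d", 1:6) %in% selNeg))
})

test_that("venn partition is exact set algebra over a shared panel", {
  mk <- function(stratum, selected, panel = c("E", "F", "G", "V", "W")) {
    data.frame(gene = panel, stratum = stratum,
               selected = panel %in% selected)
  }
  vp <- vennPartition(mk("A", c("F", "G", "E")), mk("B", c("E", "V")))
  expect_identical(vp$only_a, c("F", "G"))
  expect_identical(vp$only_b, "V")
  expect_identical(vp$shared, "E")
  # disjoint and identical selections
  expect_identical(vennPartition(mk("A", "F"), mk("B", "V"))$shared,
                   character(0))
  same <- vennPartition(mk("A", c("E", "F")), mk("B", c("E", "F")))
  expect_identical(same$only_a, character(0))
  expect_identical(same$only_b, character(0))
  expect_identical(same$shared, c("E", "F"))
  expect_error(vennPartition(mk("A", "E"), mk("B", "E", panel = c("X", "Y"))),
               "same panel")
})
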
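test_that("expression matrix round-trips with IDs in file order", {
  se <- readExpressionMatrix(exprFixturePath())
  m <- SummarizedExperiment::assay(se, "log2expr")
  expect_identical(dim(m), c(2L, 3L))
  expect_identical(rownames(m), c("G1", "G2"))
  expect_identical(colnames(m), c("S1", "S2", "S3"))
  expect_identical(m["G1", ], c(S1 = 1.5, S2 = 2.25, S3 = 3.125))
  expect_true(is.na(m["G2", "S2"]))
})

test_that("orientation flag changes layout, never content", {
  a <- SummarizedExperiment::assay(readExpressionMatrix(exprFixturePath()))
  b <- SummarizedExperiment::assay(readExpressionMatrix(
    exprFixturePathTransposed(), orientation = "samples_x_genes"))
  expect_identical(a, b)
})

test_that("malformed expression input is rejected with coordinates", {
  dup <- writeTsv(c("gene\tS1\tS2", "G1\t1\t2", "G1\t3\t4"))
  expect_error(readExpressionMatrix(dup), "duplicate.*G1")
  bad <- writeTsv(c("gene\tS1\tS2", "G1\t1\ttwo", "G2\t3\t4"))
  expect_error(readExpressionMatrix(bad), "non-numeric.*'two'.*G1.*S2")
})

test_that("beta values are validated into [0,1] with boundary values legal", {
  fx <- methFixturePaths()
  se <- readMethylationMatrix(fx$beta, fx$annotation)
  m <- SummarizedExperiment::assay(se, "beta")
  expect_identical(unname(m["P1", ]), c(0, 0.5, 1, 0.25))
  expect_identical(
    SummarizedExperiment::rowData(se)$promoter_flag, c(TRUE, FALSE, TRUE))
  bad <- methFixturePaths(betas = c("0\t0.5\t1.2\t0.25",
                                    "0.1\t0.2\t0.3\t0.4",
                                    "0.9\t0.8\t0.7\t0.6"))
  expect_error(readMethylationMatrix(bad$beta, bad$annotation),
               "outside \\[0,1\\].*P1.*S3")
})

test_that("probes without annotation default to non-promoter with a warning", {
  fx <- methFixturePaths()
  ann <- writeTsv(c("probe_id\tpromoter_flag", "P1\tTRUE"))
  expect_warning(se <- readMethylationMatrix(fx$beta, ann),
                 "missing annotation")
  expect_identical(
    SummarizedExperiment::rowData(se)$promoter_flag, c(TRUE, FALSE, FALSE))
})

test_that("clinical values normalize to the canonical vocabulary", {
  expect_warning(cl <- readClinicalTable(clinFixturePath()), "no mapping")
  expect_identical(as.character(cl["S1", "er_status"]), "ER+")
  expect_identical(as.character(cl["S2", "er_status"]), "ER-")
  expect_identical(as.character(cl["S4", "er_status"]), "unknown")
  expect_identical(cl$os_months[1], 34.2)
  expect_identical(cl$os_event[1:2], c(TRUE, FALSE))
})

test_that("clinical validation catches structural problems", {
  neg <- clinFixturePath(extraRow = "S5\tPositive\tLumA\t-3\t1")
  expect_error(suppressWarnings(readClinicalTable(neg)), "negative")
  noid <- writeTsv(c("patient\ter_status", "S1\tPositive"))
  expect_error(readClinicalTable(noid), "sample-ID column")
})

test_that("harmonization intersects, sorts and is idempotent", {
  mk <- function(samples) SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = matrix(seq_along(samples), nrow = 1,
                                    dimnames = list("G1", samples))))
  mkMeth <- function(samples) SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = matrix(0.5, nrow = 1, ncol = length(samples),
                                dimnames = list("P1", samples))),
    rowData = S4Vectors::DataFrame(promoter_flag = TRUE, region = NA,
                                   row.names = "P1"))
  mkClin <- function(samples) S4Vectors::DataFrame(
    er_status = factor(rep("ER+", length(samples)),
                       levels = c("ER+", "ER-", "unknown")),
    pam50 = factor(rep("LumA", length(samples))),
    os_months = rep(1, length(samples)),
    os_event = rep(TRUE, length(samples)), row.names = samples)
  expect_message(
    co <- harmonizeCohort(mk(c("C", "A", "B")), mkMeth(c("B", "C", "D")),
                          mkClin(c("B", "C"))),
    "harmonized to 2 samples")
  expect_identical(sampleIDs(co), c("B", "C"))
  # identical sample sets: nothing dropped
  expect_message(
    co2 <- harmonizeCohort(mk(c("A", "B")), mkMeth(c("A", "B")),
                           mkClin(c("A", "B"))),
    "dropped: expression 0, methylation 0, clinical 0")
  # idempotence
  expect_message(
    co3 <- harmonizeCohort(exprData(co2), methData(co2), clinicalData(co2)))
  expect_identical(
    SummarizedExperiment::assay(exprData(co3)),
    SummarizedExperiment::assay(exprData(co2)))
  expect_error(
    suppressMessages(harmonizeCohort(mk("A"), mkMeth("B"), mkClin("C"))),
    "no samples shared")
})

test_that("results tables round-trip at full precision in key order", {
  df <- data.frame(stratum = c("B", "A", "A"),
                   gene = c("g1", "g2", "g1"),
                   value = c(1 / 3, pi, exp(-10)))
  path <- tempfile(fileext = ".tsv")
  writeResultsTable(df, path, key = c("stratum", "gene"))
  back <- readResultsTable(path)
  expect_identical(back$stratum, c("A", "A", "B"))
  expect_identical(back$gene, c("g1", "g2", "g1"))
  expect_equal(back$value, c(exp(-10), pi, 1 / 3), tolerance = 1e-14)
  # empty input: header-only file
  writeResultsTable(df[0, ], path)
  expect_identical(readLines(path), "stratum\tgene\tvalue")
})

test_that("a generated cohort survives a full write/read/harmonize cycle", {
  sim <- generateCohort(fastSimConfig(seed = 42L))
  prefix <- tempfile()
  paths <- writeCohort(sim$cohort, prefix)
  suppressMessages(back <- harmonizeCohort(
    readExpressionMatrix(paths["expression"]),
    readMethylationMatrix(paths["methylation"], paths["annotation"]),
    readClinicalTable(paths["clinical"])))
  expect_identical(sampleIDs(back), sampleIDs(sim$cohort))
  expect_equal(
    SummarizedExperiment::assay(exprData(back)),
    SummarizedExperiment::assay(exprData(sim$cohort)), tolerance = 1e-12)
  expect_equal(
    SummarizedExperiment::assay(methData(back)),
    SummarizedExperiment::assay(methData(sim$cohort)), tolerance = 1e-12)
})
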
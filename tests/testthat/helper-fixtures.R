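# Small programmatic fixtures: TSV writers and a hand-built mini cohort.

writeTsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

exprFixturePath <- function() {
  writeTsv(c("gene\tS1\tS2\tS3",
             "G1\t1.5\t2.25\t3.125",
             "G2\t4\tNA\t6.5"))
}

exprFixturePathTransposed <- function() {
  writeTsv(c("sample\tG1\tG2",
             "S1\t1.5\t4",
             "S2\t2.25\tNA",
             "S3\t3.125\t6.5"))
}

methFixturePaths <- function(betas = c("0\t0.5\t1\t0.25",
                                       "0.1\t0.2\t0.3\t0.4",
                                       "0.9\t0.8\t0.7\t0.6")) {
  beta <- writeTsv(c("probe\tS1\tS2\tS3\tS4",
                     paste0("P", 1:3, "\t", betas)))
  ann <- writeTsv(c("probe_id\tpromoter_flag\tregion",
                    "P1\tTRUE\tpromoter",
                    "P2\tFALSE\tgene_body",
                    "P3\tTRUE\tpromoter"))
  list(beta = beta, annotation = ann)
}

clinFixturePath <- function(extraRow = NULL) {
  writeTsv(c("sample_id\ter_status\tpam50\tos_months\tos_event",
             "S1\tPositive\tLumA\t34.2\t1",
             "S2\tNegative\tBasal\t12\t0",
             "S3\tPositive\tLumB\t60\t0",
             "S4\tIndeterminate\tLumA\t5\t1",
             extraRow))
}

# Deterministic 5-gene x 8-sample cohort, two strata, no randomness.
miniCohort <- function() {
  genes <- c("TG", paste0("G", 1:4))
  samples <- paste0("S", 1:8)
  tg <- c(1, 2, 3, 4, 5, 6, 7, 8)
  em <- rbind(
    TG = tg,
    G1 = -tg,                      # r = -1
    G2 = c(2, 1, 4, 3, 6, 5, 8, 7),
    G3 = c(8, 1, 7, 2, 6, 3, 5, 4),
    G4 = c(1, 2, 3, 4, 5, 6, 8, 7))
  colnames(em) <- samples
  betas <- matrix(seq(0.1, 0.9, length.out = 16), nrow = 2,
                  dimnames = list(c("P1", "P2"), samples))
  expr <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = em))
  meth <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = betas),
    rowData = S4Vectors::DataFrame(promoter_flag = c(TRUE, FALSE),
                                   region = c("promoter", "gene_body"),
                                   row.names = c("P1", "P2")))
  clin <- S4Vectors::DataFrame(
    er_status = factor(rep(c("ER+", "ER-"), each = 4),
                       levels = c("ER+", "ER-", "unknown")),
    pam50 = factor(rep(c("LumA", "Basal"), each = 4),
                   levels = c("LumA", "LumB", "Basal", "Normal", "Her2",
                              "unknown")),
    os_months = c(10, 20, 30, 40, 15, 25, 35, 45),
    os_event = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    row.names = samples)
  Cohort(expr, meth, clin)
}

fastSimConfig <- function(...) {
  syntheticConfig(
    nSamples = c("ER+" = 60L, "ER-" = 60L),
    promoterProbeCount = 2L, bodyProbeCount = 1L,
    ...)
}
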
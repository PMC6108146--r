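#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DFrame
#' @import SummarizedExperiment
NULL

ER_LEVELS <- c("ER+", "ER-", "unknown")
PAM50_LEVELS <- c("LumA", "LumB", "Basal", "Normal", "Her2", "unknown")

#' Cohort: harmonized expression, methylation and clinical data
#'
#' Container for the three components of a TCGA-style breast cohort:
#' a gene-expression \linkS4class{SummarizedExperiment} (assay
#' \code{"log2expr"}, log2(norm_count+1) units), a methylation
#' \linkS4class{SummarizedExperiment} (assay \code{"beta"}, beta values in
#' [0,1], probe annotation with a \code{promoter_flag} in \code{rowData}),
#' and a clinical \code{DataFrame} (columns \code{er_status}, \code{pam50},
#' \code{os_months}, \code{os_event}). Validity requires all three to share
#' one identical, ordered sample axis; \code{\link{harmonizeCohort}} builds
#' such an object from unharmonized components.
#'
#' @slot expression SummarizedExperiment of log2 expression, genes x samples.
#' @slot methylation SummarizedExperiment of beta values, probes x samples.
#' @slot clinical DataFrame of per-sample clinical covariates.
#'
#' @aliases Cohort
#' @exportClass Cohort
setClass("Cohort",
  slots = c(
    expression  = "SummarizedExperiment",
    methylation = "SummarizedExperiment",
    clinical    = "DFrame"
  )
)

setValidity("Cohort", function(object) {
  ex <- colnames(object@expression)
  me <- colnames(object@methylation)
  cl <- rownames(object@clinical)
  if (length(ex) == 0L)
    return("cohort has no samples")
  if (!identical(ex, me) || !identical(ex, cl))
    return("expression, methylation and clinical components must share an identical ordered sample axis")
  if (anyDuplicated(ex))
    return("duplicate sample IDs")
  if (!"promoter_flag" %in% colnames(SummarizedExperiment::rowData(object@methylation)))
    return("methylation rowData must carry a promoter_flag column")
  need <- c("er_status", "pam50", "os_months", "os_event")
  miss <- setdiff(need, colnames(object@clinical))
  if (length(miss))
    return(paste0("clinical table lacks column(s): ", paste(miss, collapse = ", ")))
  TRUE
})

#' Construct a Cohort from already-harmonized components
#'
#' Thin constructor; see \code{\link{harmonizeCohort}} for the usual entry
#' point that intersects and reorders sample axes first.
#'
#' @param expression SummarizedExperiment, genes x samples.
#' @param methylation SummarizedExperiment, probes x samples.
#' @param clinical DataFrame keyed by sample ID (rownames).
#' @return A validated \linkS4class{Cohort}.
#' @export
Cohort <- function(expression, methylation, clinical) {
  new("Cohort", expression = expression, methylation = methylation,
      clinical = clinical)
}

setMethod("show", "Cohort", function(object) {
  cat("Cohort object\n")
  cat(sprintf("  expression : %d genes x %d samples\n",
              nrow(object@expression), ncol(object@expression)))
  cat(sprintf("  methylation: %d probes (%d promoter) x %d samples\n",
              nrow(object@methylation),
              sum(SummarizedExperiment::rowData(object@methylation)$promoter_flag),
              ncol(object@methylation)))
  er <- table(object@clinical$er_status)
  cat("  clinical   :", paste(sprintf("%s=%d", names(er), as.integer(er)),
                              collapse = " "), "\n")
})

#' SyntheticConfig: study conditions for the cohort generator
#'
#' Declares the planted statistical structure for
#' \code{\link{generateCohort}}: per-stratum sample sizes, the target gene
#' and panel, target-vs-gene correlations planted per stratum via a
#' Gaussian one-factor copula, an ER-stratum expression shift for the
#' target, the promoter methylation/expression correlation, per-stratum
#' hazard ratios for high-vs-low target expression, exponential baseline
#' hazard and censoring rates (per month), the marginal expression SD and
#' the seed. Defaults encode the structure of the studied TCGA-like
#' breast cohort: ER+ n=601 vs ER- n=179, ID4 shifted down by 1.5 log2
#' units in ER+, negative promoter-probe correlation (-0.4), reported ER+
#' correlations for FOXA1/GATA3/ESR1/CCND1/AKT1/IGF1R, ER- associations
#' for VEGFA/JUN/MKI67, shared associations for
#' CTNNB1/ERBB2/CTSD/KRT19/MMP2/XBP1, and a protective hazard ratio of
#' 0.5 for high target expression in ER+ only.
#'
#' @slot nSamples named integer, samples per stratum (names = stratum labels).
#' @slot targetGene character(1), target gene symbol.
#' @slot panelGenes character, candidate panel gene symbols.
#' @slot plantedCorrelations named list (per stratum) of named numerics:
#'   planted Pearson correlation of each associated gene with the target.
#' @slot targetShift named numeric per stratum, additive shift (log2 units)
#'   of the target-gene mean.
#' @slot promoterProbeCount integer(1), promoter probes simulated.
#' @slot bodyProbeCount integer(1), non-promoter (gene body) probes.
#' @slot methExprCorrelation numeric(1) in (-1, 0], planted correlation of
#'   promoter beta with target expression.
#' @slot survivalHR named numeric per stratum, hazard ratio high vs low
#'   target expression.
#' @slot baselineHazard numeric(1) > 0, events per month in the low arm.
#' @slot censoringRate numeric(1) > 0, censoring events per month.
#' @slot noiseSD numeric(1) > 0, marginal SD of log2 expression.
#' @slot seed integer(1), RNG seed for the generator.
#'
#' @aliases SyntheticConfig
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  slots = c(
    nSamples            = "integer",
    targetGene          = "character",
    panelGenes          = "character",
    plantedCorrelations = "list",
    targetShift         = "numeric",
    promoterProbeCount  = "integer",
    bodyProbeCount      = "integer",
    methExprCorrelation = "numeric",
    survivalHR          = "numeric",
    baselineHazard      = "numeric",
    censoringRate       = "numeric",
    noiseSD             = "numeric",
    seed                = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  strata <- names(object@nSamples)
  if (is.null(strata) || anyDuplicated(strata))
    return("nSamples must be a named vector with unique stratum labels")
  if (any(object@nSamples < 4L))
    return("at least 4 samples per stratum are required")
  if (length(object@targetGene) != 1L)
    return("targetGene must be a single identifier")
  if (object@targetGene %in% object@panelGenes)
    return("target gene must not be part of the panel")
  if (anyDuplicated(object@panelGenes))
    return("duplicate panel genes")
  if (!all(names(object@plantedCorrelations) %in% strata))
    return("plantedCorrelations names must be stratum labels")
  for (s in names(object@plantedCorrelations)) {
    r <- object@plantedCorrelations[[s]]
    if (length(r) && (is.null(names(r)) || !all(names(r) %in% object@panelGenes)))
      return("planted correlations must be named by panel genes")
    if (any(abs(r) >= 1))
      return("planted correlations must lie strictly inside (-1, 1)")
  }
  if (!all(strata %in% names(object@targetShift)))
    return("targetShift must name every stratum")
  if (object@methExprCorrelation > 0 || object@methExprCorrelation <= -1)
    return("methExprCorrelation must lie in (-1, 0]")
  if (!all(strata %in% names(object@survivalHR)))
    return("survivalHR must name every stratum")
  if (any(object@survivalHR <= 0) || object@baselineHazard <= 0 ||
      object@censoringRate <= 0 || object@noiseSD <= 0)
    return("hazards, rates and noiseSD must be strictly positive")
  if (object@promoterProbeCount < 1L)
    return("at least one promoter probe is required")
  TRUE
})

#' Build a SyntheticConfig
#'
#' All arguments have defaults encoding the studied cohort conditions; see
#' \linkS4class{SyntheticConfig} for their meaning.
#'
#' @param nSamples named integer vector of per-stratum sample counts.
#' @param targetGene target gene symbol.
#' @param panelGenes candidate panel; defaults to the packaged 66-gene
#'   breast-cancer panel (\code{\link{genePanel}}).
#' @param plantedCorrelations per-stratum named correlation vectors.
#' @param targetShift per-stratum additive mean shift for the target gene.
#' @param promoterProbeCount,bodyProbeCount numbers of simulated promoter /
#'   gene-body methylation probes.
#' @param methExprCorrelation planted promoter beta vs target correlation.
#' @param survivalHR per-stratum hazard ratio, high vs low target arm.
#' @param baselineHazard,censoringRate exponential rates per month.
#' @param noiseSD marginal SD of simulated log2 expression.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(nSamples = c("ER+" = 50L, "ER-" = 50L), seed = 7L)
#' cfg
#' @export
syntheticConfig <- function(
    nSamples = c("ER+" = 601L, "ER-" = 179L),
    targetGene = "ID4",
    panelGenes = genePanel()$gene,
    plantedCorrelations = list(
      "ER+" = c(FOXA1 = -0.326, GATA3 = -0.3515, ESR1 = -0.333,
                CCND1 = -0.19, AKT1 = -0.068, IGF1R = -0.065,
                CTNNB1 = -0.30, ERBB2 = -0.30, CTSD = -0.30,
                KRT19 = -0.30, MMP2 = -0.30, XBP1 = -0.30),
      "ER-" = c(VEGFA = -0.33, JUN = -0.33, MKI67 = -0.33,
                CTNNB1 = -0.30, ERBB2 = -0.30, CTSD = -0.30,
                KRT19 = -0.30, MMP2 = -0.30, XBP1 = -0.30)),
    targetShift = c("ER+" = -1.5, "ER-" = 0),
    promoterProbeCount = 5L,
    bodyProbeCount = 8L,
    methExprCorrelation = -0.4,
    survivalHR = c("ER+" = 0.5, "ER-" = 1.0),
    baselineHazard = 0.005,
    censoringRate = 0.01,
    noiseSD = 1.0,
    seed = 1L) {
  new("SyntheticConfig",
      nSamples = as.integer(nSamples) |> stats::setNames(names(nSamples)),
      targetGene = targetGene,
      panelGenes = panelGenes,
      plantedCorrelations = plantedCorrelations,
      targetShift = targetShift,
      promoterProbeCount = as.integer(promoterProbeCount),
      bodyProbeCount = as.integer(bodyProbeCount),
      methExprCorrelation = methExprCorrelation,
      survivalHR = survivalHR,
      baselineHazard = baselineHazard,
      censoringRate = censoringRate,
      noiseSD = noiseSD,
      seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig\n")
  cat(sprintf("  strata      : %s\n",
              paste(sprintf("%s (n=%d)", names(object@nSamples),
                            object@nSamples), collapse = ", ")))
  cat(sprintf("  target gene : %s (shift %s)\n", object@targetGene,
              paste(sprintf("%s=%g", names(object@targetShift),
                            object@targetShift), collapse = " ")))
  cat(sprintf("  panel       : %d genes, planted associations: %s\n",
              length(object@panelGenes),
              paste(sprintf("%s=%d", names(object@plantedCorrelations),
                            lengths(object@plantedCorrelations)),
                    collapse = " ")))
  cat(sprintf("  methylation : %d promoter + %d body probes, r = %g\n",
              object@promoterProbeCount, object@bodyProbeCount,
              object@methExprCorrelation))
  cat(sprintf("  survival    : HR %s; h0 = %g/mo, censoring %g/mo\n",
              paste(sprintf("%s=%g", names(object@survivalHR),
                            object@survivalHR), collapse = " "),
              object@baselineHazard, object@censoringRate))
  cat(sprintf("  seed        : %d\n", object@seed))
})
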
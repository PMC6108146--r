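# Latent one-factor Gaussian draw: y correlated r with factor z, unit
# variance margins. |r| < 1 guarantees positive definiteness.
.latentCorrelated <- function(z, r) {
  r * z + sqrt(1 - r^2) * stats::rnorm(length(z))
}

#' Generate a synthetic cohort with planted structure
#'
#' Draws a full \linkS4class{Cohort} realizing the statistical structure
#' declared by a \linkS4class{SyntheticConfig}:
#' \itemize{
#'   \item \strong{Expression}: per stratum, a one-factor Gaussian copula
#'     ties every associated panel gene to the target gene at its planted
#'     correlation (unassociated genes are independent); margins are
#'     Gaussian with SD \code{noiseSD} around a baseline mean, and the
#'     target mean is shifted by \code{targetShift} per stratum.
#'   \item \strong{Methylation}: promoter-probe betas are a logistic
#'     squash of a latent Gaussian tied to the cohort-wide standardized
#'     target expression at \code{methExprCorrelation}, so lower target
#'     expression comes with higher promoter methylation; gene-body
#'     probes are independent noise. All betas lie strictly in (0,1).
#'   \item \strong{Survival}: within each stratum, samples above the
#'     stratum median target expression form the "high" arm (strict
#'     median rule, identical to \code{\link{dichotomizeByMedian}});
#'     event times are exponential with rate
#'     \code{baselineHazard * HR^high}, censoring exponential with
#'     \code{censoringRate}; observed time is the minimum with the
#'     matching event flag.
#' }
#' Fully reproducible from \code{config@seed}.
#'
#' @param config A \linkS4class{SyntheticConfig}.
#' @return list with \code{cohort} (a \linkS4class{Cohort}) and
#'   \code{truth}, the planted-structure oracle: per-stratum associated
#'   gene sets and planted correlations, hazard ratios, the realized
#'   promoter-probe correlations, and the per-stratum high/low
#'   assignment used for the hazard draw.
#' @examples
#' sim <- generateCohort(syntheticConfig(
#'   nSamples = c("ER+" = 40L, "ER-" = 40L), seed = 11L))
#' sim$cohort
#' @export
generateCohort <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  strata <- names(config@nSamples)
  genes <- c(config@targetGene, config@panelGenes)
  baselineMean <- 8  # typical log2(norm_count+1) scale

  exprCols <- list(); clinRows <- list(); zAll <- list()
  for (s in strata) {
    n <- config@nSamples[[s]]
    z <- stats::rnorm(n)
    zAll[[s]] <- z
    planted <- config@plantedCorrelations[[s]]
    if (is.null(planted)) planted <- stats::setNames(numeric(0), character(0))
    em <- matrix(NA_real_, nrow = length(genes), ncol = n,
                 dimnames = list(genes, NULL))
    em[config@targetGene, ] <-
      baselineMean + config@targetShift[[s]] + config@noiseSD * z
    for (g in config@panelGenes) {
      r <- if (g %in% names(planted)) planted[[g]] else 0
      em[g, ] <- baselineMean + config@noiseSD * .latentCorrelated(z, r)
    }
    # survival: strict within-stratum median split on target expression
    tv <- em[config@targetGene, ]
    high <- tv > stats::median(tv)
    rate <- config@baselineHazard * config@survivalHR[[s]]^high
    tEvent <- stats::rexp(n, rate = rate)
    tCens <- stats::rexp(n, rate = config@censoringRate)
    exprCols[[s]] <- em
    clinRows[[s]] <- data.frame(
      er_status = s,
      pam50 = if (s == "ER+") sample(c("LumA", "LumB"), n, TRUE, c(0.7, 0.3))
              else sample(c("Basal", "Normal", "Her2"), n, TRUE,
                          c(0.6, 0.25, 0.15)),
      os_months = pmin(tEvent, tCens),
      os_event = tEvent <= tCens,
      high_arm = high,
      stringsAsFactors = FALSE)
  }
  exprMat <- do.call(cbind, exprCols)
  clin <- do.call(rbind, clinRows)
  nTotal <- ncol(exprMat)
  ids <- sprintf("S%05d", seq_len(nTotal))
  colnames(exprMat) <- ids

  # methylation tied to the pooled standardized target expression
  tAll <- exprMat[config@targetGene, ]
  tStd <- (tAll - mean(tAll)) / stats::sd(tAll)
  squashScale <- 0.8
  nProm <- config@promoterProbeCount
  nBody <- config@bodyProbeCount
  probeIds <- c(sprintf("cg_prom_%02d", seq_len(nProm)),
                if (nBody > 0L) sprintf("cg_body_%02d", seq_len(nBody)))
  betas <- matrix(NA_real_, nrow = length(probeIds), ncol = nTotal,
                  dimnames = list(probeIds, ids))
  promOffsets <- seq(-1, 1, length.out = nProm)
  for (i in seq_len(nProm)) {
    lat <- .latentCorrelated(tStd, config@methExprCorrelation)
    betas[i, ] <- stats::plogis(promOffsets[i] + squashScale * lat)
  }
  if (nBody > 0L) {
    bodyOffsets <- seq(-1.5, 0.5, length.out = nBody)
    for (j in seq_len(nBody)) {
      betas[nProm + j, ] <-
        stats::plogis(bodyOffsets[j] + squashScale * stats::rnorm(nTotal))
    }
  }
  promoterFlag <- c(rep(TRUE, nProm), rep(FALSE, nBody))
  meth <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = betas),
    rowData = S4Vectors::DataFrame(
      promoter_flag = promoterFlag,
      region = c(rep("promoter", nProm), rep("gene_body", nBody)),
      row.names = probeIds))
  expr <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = exprMat))
  clinical <- S4Vectors::DataFrame(
    er_status = factor(clin$er_status, levels = ER_LEVELS),
    pam50 = factor(clin$pam50, levels = PAM50_LEVELS),
    os_months = clin$os_months,
    os_event = clin$os_event,
    row.names = ids)

  realizedMeth <- vapply(seq_len(nProm), function(i)
    stats::cor(betas[i, ], tAll), numeric(1))
  truth <- list(
    strata = strata,
    planted_correlations = config@plantedCorrelations,
    associated_genes = lapply(config@plantedCorrelations,
                              function(r) sort(names(r))),
    hazard_ratios = config@survivalHR,
    high_arm = stats::setNames(clin$high_arm, ids),
    realized_promoter_correlation =
      stats::setNames(realizedMeth, probeIds[seq_len(nProm)]),
    seed = config@seed)
  list(cohort = Cohort(expr, meth, clinical), truth = truth)
}

#' Simulate a droplet digital PCR readout
#'
#' Each droplet contains template with probability \code{1 - exp(-lambda)}
#' (Poisson occupancy), so positives are binomial.
#'
#' @param lambdaPerDroplet mean template copies per droplet (>= 0).
#' @param nDroplets number of droplets (>= 1).
#' @param seed optional RNG seed.
#' @param dropletVolumeNl droplet volume carried along (default 0.85 nl).
#' @return list with \code{n_positive}, \code{n_total},
#'   \code{droplet_volume_nl}.
#' @export
generateDropletReadout <- function(lambdaPerDroplet, nDroplets, seed = NULL,
                                   dropletVolumeNl = 0.85) {
  if (lambdaPerDroplet < 0 || nDroplets < 1L)
    stop("need lambda >= 0 and at least one droplet")
  if (!is.null(seed)) set.seed(seed)
  p <- 1 - exp(-lambdaPerDroplet)
  list(n_positive = stats::rbinom(1L, nDroplets, p),
       n_total = as.integer(nDroplets),
       droplet_volume_nl = dropletVolumeNl)
}

#' Simulate an MS-MLPA probe reading
#'
#' The digested target signal is the true methylated fraction times the
#' undigested target signal; all four signals (target/reference x
#' digested/undigested) carry multiplicative lognormal noise with the
#' given coefficient of variation.
#'
#' @param trueMethylatedFraction fraction in [0,1].
#' @param referenceSignal reference-probe base signal (> 0).
#' @param noiseCv coefficient of variation of the lognormal noise (>= 0).
#' @param seed optional RNG seed.
#' @param targetSignal target-probe base signal (> 0, default 1000).
#' @return list with \code{target_digested}, \code{target_undigested},
#'   \code{reference_digested}, \code{reference_undigested}.
#' @export
generateMlpaReadout <- function(trueMethylatedFraction, referenceSignal = 1000,
                                noiseCv = 0, seed = NULL,
                                targetSignal = 1000) {
  if (trueMethylatedFraction < 0 || trueMethylatedFraction > 1)
    stop("methylated fraction must lie in [0,1]")
  if (noiseCv < 0) stop("noiseCv must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  noise <- function() {
    if (noiseCv == 0) return(1)
    sdlog <- sqrt(log(1 + noiseCv^2))
    stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean 1
  }
  list(target_digested = trueMethylatedFraction * targetSignal * noise(),
       target_undigested = targetSignal * noise(),
       reference_digested = referenceSignal * noise(),
       reference_undigested = referenceSignal * noise())
}
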
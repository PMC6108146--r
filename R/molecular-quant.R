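#' Poisson-corrected concentration from droplet counts
#'
#' Digital-PCR quantification: with \code{p} the fraction of positive
#' droplets, the mean template copies per droplet is
#' \code{lambda = -ln(1 - p)} (Poisson correction for multiply occupied
#' droplets), and the concentration is \code{lambda} divided by the
#' droplet volume in microliters. The 95\% CI is the binomial Wilson
#' interval on \code{p} propagated through \code{-ln(1 - .)}. A well with
#' every droplet positive is saturated: a lower-bound estimate from
#' \code{(n - 0.5)/n} is reported with \code{saturated = TRUE} and a
#' warning. Zero positives give an all-zero result.
#'
#' @param nPositive number of positive (template-containing) droplets.
#' @param nTotal total accepted droplets (>= 1).
#' @param dropletVolumeNl droplet volume in nanoliters (default 0.85, the
#'   QX200 system constant).
#' @return list of class \code{"QuantResult"}: \code{lambda_per_droplet},
#'   \code{copies_per_ul}, \code{ci95_low}, \code{ci95_high} (copies/ul),
#'   \code{saturated}, \code{n_total}, \code{n_positive}.
#' @examples
#' poissonConcentration(5000, 10000)$copies_per_ul   # ~815.5
#' @export
poissonConcentration <- function(nPositive, nTotal, dropletVolumeNl = 0.85) {
  if (nTotal < 1L || nPositive < 0L || nPositive > nTotal)
    stop("need 0 <= nPositive <= nTotal and nTotal >= 1")
  if (dropletVolumeNl <= 0)
    stop("droplet volume must be positive")
  volUl <- dropletVolumeNl * 1e-3
  mk <- function(lambda, lo, hi, saturated) {
    structure(list(lambda_per_droplet = lambda,
                   copies_per_ul = lambda / volUl,
                   ci95_low = lo / volUl, ci95_high = hi / volUl,
                   saturated = saturated,
                   n_total = nTotal, n_positive = nPositive),
              class = "QuantResult")
  }
  if (nPositive == 0L)
    return(mk(0, 0, 0, FALSE))
  saturated <- nPositive == nTotal
  if (saturated) {
    warning("all droplets positive: reporting saturation lower bound")
    phat <- (nTotal - 0.5) / nTotal
  } else {
    phat <- nPositive / nTotal
  }
  lambda <- -log(1 - phat)
  # Wilson interval on the positive fraction
  z <- stats::qnorm(0.975)
  n <- nTotal
  centre <- (phat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  pLo <- max(0, centre - half)
  pHi <- min(1 - .Machine$double.eps, centre + half)
  mk(lambda, -log(1 - pLo), -log(1 - pHi), saturated)
}

#' @export
print.QuantResult <- function(x, ...) {
  cat(sprintf(
    "ddPCR quantification: %d/%d positive droplets%s\n  lambda = %.6g copies/droplet\n  %.6g copies/ul (95%% CI %.6g - %.6g)\n",
    x$n_positive, x$n_total, if (x$saturated) " [SATURATED]" else "",
    x$lambda_per_droplet, x$copies_per_ul, x$ci95_low, x$ci95_high))
  invisible(x)
}

#' Combine technical ddPCR replicates
#'
#' Replicate wells are combined by the mean of their per-replicate
#' concentrations.
#'
#' @param results list of \code{QuantResult}s.
#' @return mean copies per microliter.
#' @export
combineReplicates <- function(results) {
  mean(vapply(results, function(r) r$copies_per_ul, numeric(1)))
}

#' Methylated/unmethylated concentration ratio
#'
#' Ratio of the methylation-specific to the unmethylation-specific assay
#' concentration (parallel reactions).
#'
#' @param methylated,unmethylated \code{QuantResult}s (or bare copies/ul
#'   numbers).
#' @return the ratio; an unmethylated concentration of zero is an error
#'   (the ratio is undefined, not infinite).
#' @export
methylationRatio <- function(methylated, unmethylated) {
  m <- if (inherits(methylated, "QuantResult")) methylated$copies_per_ul
       else methylated
  u <- if (inherits(unmethylated, "QuantResult")) unmethylated$copies_per_ul
       else unmethylated
  if (u <= 0)
    stop("undefined ratio: unmethylated concentration is zero")
  m / u
}

#' MS-MLPA methylation dosage ratio
#'
#' Reference-normalized digested/undigested signal ratio:
#' \code{(target_digested / ref_digested) / (target_undigested /
#' ref_undigested)}, clipped at 0 below. When several reference probes
#' are supplied their mean signal is used.
#'
#' @param targetDigested,targetUndigested target-probe peak signals in the
#'   digested and undigested reactions.
#' @param referenceDigested,referenceUndigested reference-probe signals
#'   (vectors allowed; means are taken).
#' @return the dosage ratio (nonnegative real).
#' @export
mlpaDosageRatio <- function(targetDigested, targetUndigested,
                            referenceDigested, referenceUndigested) {
  rd <- mean(referenceDigested)
  ru <- mean(referenceUndigested)
  if (targetUndigested <= 0 || ru <= 0 || rd <= 0)
    stop("invalid MLPA reading: undigested and reference signals must be positive")
  max(0, (targetDigested / rd) / (targetUndigested / ru))
}

#' MS-MLPA methylation call
#'
#' A CpG site is called methylated when its dosage ratio is strictly
#' above the cutoff (default 8\%).
#'
#' @param ratio dosage ratio from \code{\link{mlpaDosageRatio}} (>= 0).
#' @param cutoff call threshold, default 0.08.
#' @return logical: TRUE = methylated.
#' @export
mlpaCall <- function(ratio, cutoff = 0.08) {
  if (any(ratio < 0))
    stop("dosage ratio must be nonnegative")
  ratio > cutoff
}
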
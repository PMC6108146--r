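#' Median dichotomization into high/low expression groups
#'
#' Labels a sample \code{"high"} when its value is strictly greater than
#' the sample median; values equal to the median are \code{"low"}. With
#' every value equal no split exists and an error is raised.
#'
#' @param values named numeric vector (names = sample IDs), at least 2
#'   finite values.
#' @return list with \code{labels} (named character, \code{"high"}/
#'   \code{"low"}) and \code{median_used}.
#' @examples
#' dichotomizeByMedian(c(a = 1, b = 2, c = 3, d = 4))$labels
#' @export
dichotomizeByMedian <- function(values) {
  fin <- values[is.finite(values)]
  if (length(fin) < 2L)
    stop("need at least 2 finite values")
  med <- stats::median(fin)
  if (all(fin == med))
    stop("no split possible: all values equal the median")
  labels <- ifelse(fin > med, "high", "low")
  list(labels = stats::setNames(labels, names(fin)), median_used = med)
}

#' Kaplan-Meier product-limit survival estimate
#'
#' \code{S(t) = prod_{t_i <= t} (1 - d_i / n_i)} over the distinct event
#' times; censored individuals at an event time stay at risk for events
#' occurring at that time (events precede censoring on ties).
#'
#' @param osMonths nonnegative survival/censoring times (months).
#' @param osEvent logical, TRUE = death observed.
#' @return list of class \code{"KMCurve"}: \code{event_times},
#'   \code{at_risk}, \code{events}, \code{survival} (one entry per
#'   distinct event time), \code{n_total}.
#' @export
kmEstimate <- function(osMonths, osEvent) {
  if (length(osMonths) != length(osEvent))
    stop("times and event flags differ in length")
  keep <- !is.na(osMonths) & !is.na(osEvent)
  osMonths <- osMonths[keep]; osEvent <- as.logical(osEvent[keep])
  if (length(osMonths) < 1L)
    stop("no usable observations")
  if (any(osMonths < 0))
    stop("negative survival time")
  fit <- survival::survfit(
    survival::Surv(osMonths, osEvent) ~ 1, conf.type = "none")
  sm <- summary(fit, censored = FALSE)   # rows at event times only
  structure(list(event_times = sm$time,
                 at_risk = sm$n.risk,
                 events = sm$n.event,
                 survival = sm$surv,
                 n_total = length(osMonths)),
            class = "KMCurve")
}

#' @export
print.KMCurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve, n = %d, %d event time(s)\n",
              x$n_total, length(x$event_times)))
  print(data.frame(time = x$event_times, at_risk = x$at_risk,
                   events = x$events, survival = x$survival),
        row.names = FALSE)
  invisible(x)
}

#' Evaluate a KM curve at arbitrary times
#'
#' Right-continuous step-function evaluation of the product-limit
#' estimate.
#'
#' @param curve a \code{KMCurve}.
#' @param times numeric vector of times.
#' @return survival probabilities at \code{times}.
#' @export
kmSurvivalAt <- function(curve, times) {
  vapply(times, function(t) {
    i <- which(curve$event_times <= t)
    if (length(i) == 0L) 1 else curve$survival[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard log-rank: at each distinct event time a 2x2 table contributes
#' the hypergeometric expected events and variance for group A;
#' \code{chi^2 = (O - E)^2 / V} on 1 df.
#'
#' @param timesA,eventsA times and logical event flags for group A.
#' @param timesB,eventsB same for group B.
#' @return list of class \code{"LogRankResult"}: \code{chi_square},
#'   \code{p_value}, \code{observed}, \code{expected} (per group, A then
#'   B), \code{n} per group.
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  if (length(timesA) < 1L || length(timesB) < 1L)
    stop("both groups need at least one observation")
  if (sum(eventsA, eventsB) == 0)
    stop("undefined test: no events in either group")
  time <- c(timesA, timesB)
  event <- as.logical(c(eventsA, eventsB))
  group <- factor(rep(c("A", "B"), c(length(timesA), length(timesB))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi <- unname(sd$chisq)
  structure(list(chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 observed = unname(sd$obs),
                 expected = unname(sd$exp),
                 n = unname(sd$n)),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf(
    "Log-rank test: chi^2 = %.4g, p = %.4g\n  group A: %g observed / %.3g expected (n = %d)\n  group B: %g observed / %.3g expected (n = %d)\n",
    x$chi_square, x$p_value, x$observed[1], x$expected[1], x$n[1],
    x$observed[2], x$expected[2], x$n[2]))
  invisible(x)
}

#' Median-dichotomized survival analysis per stratum
#'
#' For each stratum of the clinical variable (\code{"unknown"} excluded):
#' dichotomize the target gene's expression at the *within-stratum*
#' median, fit a KM curve per arm, and compare arms with the log-rank
#' test. Strata whose arms end up with fewer than 2 samples, with no
#' events, or with constant expression are skipped with a recorded
#' reason.
#'
#' @param cohort A \linkS4class{Cohort} with survival columns
#'   \code{os_months}/\code{os_event} in its clinical table.
#' @param targetGene target gene symbol.
#' @param stratumVariable clinical column to stratify on
#'   (default \code{"er_status"}).
#' @return named list, one element per stratum: either a list with
#'   \code{labels} (DichotomyLabels), \code{median_used},
#'   \code{km_high}, \code{km_low} and \code{logrank}, or a list with a
#'   \code{skipped} reason.
#' @export
stratifiedSurvivalAnalysis <- function(cohort, targetGene,
                                       stratumVariable = "er_status") {
  em <- SummarizedExperiment::assay(exprData(cohort), "log2expr")
  if (!targetGene %in% rownames(em))
    stop(sprintf("target gene '%s' absent from expression matrix", targetGene))
  cl <- clinicalData(cohort)
  if (!stratumVariable %in% colnames(cl))
    stop(sprintf("clinical variable '%s' not found", stratumVariable))
  strat <- as.character(cl[[stratumVariable]])
  out <- list()
  for (s in sort(setdiff(unique(strat[!is.na(strat)]), "unknown"))) {
    idx <- which(!is.na(strat) & strat == s)
    usable <- idx[!is.na(cl$os_months[idx]) & !is.na(cl$os_event[idx])]
    if (length(usable) < 4L) {
      out[[s]] <- list(skipped = "fewer than 4 samples with survival data")
      next
    }
    vals <- stats::setNames(em[targetGene, usable], rownames(cl)[usable])
    di <- tryCatch(dichotomizeByMedian(vals), error = function(e) NULL)
    if (is.null(di)) {
      out[[s]] <- list(skipped = "constant target expression: no median split")
      next
    }
    hi <- names(di$labels)[di$labels == "high"]
    lo <- names(di$labels)[di$labels == "low"]
    if (length(hi) < 2L || length(lo) < 2L) {
      out[[s]] <- list(skipped = "a dichotomy arm has fewer than 2 samples")
      next
    }
    tHi <- cl[hi, "os_months"]; eHi <- cl[hi, "os_event"]
    tLo <- cl[lo, "os_months"]; eLo <- cl[lo, "os_event"]
    if (sum(eHi, eLo) == 0) {
      out[[s]] <- list(skipped = "no events observed")
      next
    }
    out[[s]] <- list(labels = di$labels,
                     median_used = di$median_used,
                     km_high = kmEstimate(tHi, eHi),
                     km_low = kmEstimate(tLo, eLo),
                     logrank = logrankTest(tHi, eHi, tLo, eLo))
  }
  out
}
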
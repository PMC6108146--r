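.fiveNum <- function(v) {
  v <- v[is.finite(v)]
  q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
       n = length(v))
}

#' Unpaired Student's t test (pooled variance)
#'
#' Classical equal-variance two-sample t test; Welch's correction is
#' available behind \code{welch = TRUE}. Degenerate inputs follow fixed
#' conventions: zero pooled variance with equal means gives t = 0, p = 1;
#' zero pooled variance with unequal means gives an infinite statistic and
#' p = 0 with a warning.
#'
#' @param x,y numeric vectors, each with at least 2 finite values.
#' @param welch use Welch's unequal-variance correction.
#' @return list with \code{statistic_name}, \code{statistic},
#'   \code{p_value}, \code{df} and per-group five-number
#'   \code{group_summaries}.
#' @examples
#' studentTTest(c(1, 2, 3), c(2, 3, 4))$statistic   # -1.2247
#' @export
studentTTest <- function(x, y, welch = FALSE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 finite values")
  summaries <- list(x = .fiveNum(x), y = .fiveNum(y))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic_name = "student_t", statistic = 0, p_value = 1,
                  df = length(x) + length(y) - 2,
                  group_summaries = summaries))
    }
    warning("zero variance with unequal means: p-value degenerates to 0")
    return(list(statistic_name = "student_t",
                statistic = sign(mean(x) - mean(y)) * Inf, p_value = 0,
                df = length(x) + length(y) - 2, group_summaries = summaries))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(statistic_name = "student_t",
       statistic = unname(ht$statistic),
       p_value = ht$p.value,
       df = unname(ht$parameter),
       group_summaries = summaries)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: F = MS_between / MS_within on
#' (k-1, N-k) degrees of freedom. If the values carry no variance at all
#' the statistic is 0 with p = 1.
#'
#' @param values numeric vector of observations.
#' @param groups grouping vector (coerced to factor); at least 2 groups
#'   with at least 2 members each, no empty group.
#' @return list with \code{statistic_name = "F"}, \code{statistic},
#'   \code{p_value}, degrees of freedom and per-group summaries.
#' @export
oneWayAnova <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  counts <- table(groups)
  if (length(counts) < 2L)
    stop("need at least 2 non-empty groups")
  if (any(counts < 2L))
    stop(sprintf("group(s) with fewer than 2 members: %s",
                 paste(names(counts)[counts < 2L], collapse = ", ")))
  summaries <- lapply(split(values, groups), .fiveNum)
  df1 <- length(counts) - 1L
  df2 <- length(values) - length(counts)
  if (stats::var(values) == 0) {
    return(list(statistic_name = "F", statistic = 0, p_value = 1,
                df = c(df1, df2), group_summaries = summaries))
  }
  ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(statistic_name = "F", statistic = unname(ht$statistic),
       p_value = ht$p.value, df = unname(ht$parameter),
       group_summaries = summaries)
}

#' Bonferroni correction
#'
#' \code{p_adj = min(1, m * p)} with \code{m} the number of comparisons.
#'
#' @param pValues numeric vector of p-values in [0,1].
#' @return adjusted p-values, same length and order.
#' @export
bonferroniAdjust <- function(pValues) {
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  stats::p.adjust(pValues, method = "bonferroni")
}

# Exact two-sided rank-sum p by enumerating all assignments of n1 of the
# pooled midranks to group x: P = 2 * min(P(W <= w), P(W >= w)), capped.
.wilcoxExactP <- function(ranks, n1, w) {
  combs <- utils::combn(length(ranks), n1)
  sums <- colSums(matrix(ranks[combs], nrow = n1))
  lo <- mean(sums <= w + 1e-9)
  hi <- mean(sums >= w - 1e-9)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Midranks are used for ties. When the combined sample size is at most
#' \code{exactBelow} the two-sided p-value is computed by full enumeration
#' of rank assignments (valid with ties); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric vectors, each nonempty.
#' @param exactBelow combined-size cutoff for exact enumeration
#'   (default 12).
#' @return list with \code{statistic_name = "wilcoxon_W"} (rank sum of
#'   \code{x}), \code{statistic}, \code{p_value}, \code{exact} flag and
#'   group summaries.
#' @export
wilcoxonRankSum <- function(x, y, exactBelow = 12L) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L)
    stop("each group needs at least one finite value")
  pooled <- c(x, y)
  ranks <- rank(pooled)          # midranks for ties
  w <- sum(ranks[seq_len(n1)])
  N <- n1 + n2
  if (N <= exactBelow) {
    p <- .wilcoxExactP(ranks, n1, w)
    exact <- TRUE
  } else {
    mu <- n1 * (N + 1) / 2
    tieTab <- table(pooled)
    tieAdj <- sum(tieTab^3 - tieTab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tieAdj)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  list(statistic_name = "wilcoxon_W", statistic = w, p_value = p,
       exact = exact, group_summaries = list(x = .fiveNum(x), y = .fiveNum(y)))
}

#' Per-probe methylation/expression correlation panel
#'
#' For every methylation probe, the Pearson correlation (with p-value)
#' between its beta values and the target gene's expression across the
#' cohort's shared samples, on pairwise-complete observations. Promoter
#' probes are flagged. Probes with fewer than 3 complete pairs or
#' constant values are reported with missing r and a reason. An optional
#' Benjamini-Hochberg column complements the raw p-values.
#'
#' @param cohort A \linkS4class{Cohort} (or pass \code{meth} and
#'   \code{expr} SummarizedExperiments directly).
#' @param targetGene target gene symbol.
#' @param bh add a \code{p_bh} Benjamini-Hochberg column (default TRUE).
#' @return data.frame with \code{probe_id}, \code{pearson_r},
#'   \code{p_value}, optional \code{p_bh}, \code{promoter_flag},
#'   \code{n_used}, \code{reason}; one row per probe.
#' @export
probeCorrelationPanel <- function(cohort, targetGene, bh = TRUE) {
  em <- SummarizedExperiment::assay(exprData(cohort), "log2expr")
  mm <- SummarizedExperiment::assay(methData(cohort), "beta")
  if (!targetGene %in% rownames(em))
    stop(sprintf("target gene '%s' absent from expression matrix", targetGene))
  if (ncol(mm) < 3L)
    stop("fewer than 3 shared samples")
  tv <- em[targetGene, ]
  flags <- SummarizedExperiment::rowData(methData(cohort))$promoter_flag
  rows <- lapply(seq_len(nrow(mm)), function(i) {
    res <- tryCatch({
      pe <- pearsonCorrelation(mm[i, ], tv)
      data.frame(probe_id = rownames(mm)[i], pearson_r = pe$r,
                 p_value = pe$p, promoter_flag = flags[i], n_used = pe$n,
                 reason = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      reason <- if (grepl("degenerate", conditionMessage(e)))
        "degenerate" else "insufficient_pairs"
      data.frame(probe_id = rownames(mm)[i], pearson_r = NA_real_,
                 p_value = NA_real_, promoter_flag = flags[i],
                 n_used = NA_integer_, reason = reason,
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  if (bh)
    out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}
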
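#' Center to mean zero and scale to unit Euclidean norm
#'
#' The normalization behind the pairwise singular-value score: after it,
#' the 2x2 cross-product matrix of a target/gene column pair has unit
#' diagonal and the Pearson correlation off-diagonal.
#'
#' @param values numeric vector, at least 2 finite values, nonconstant.
#' @return numeric vector with mean 0 and Euclidean norm 1.
#' @examples
#' standardizeVector(c(1, 2, 3))   # -1/sqrt(2), 0, 1/sqrt(2)
#' @export
standardizeVector <- function(values) {
  if (sum(is.finite(values)) < 2L)
    stop("need at least 2 finite values")
  centered <- values - mean(values)
  nrm <- sqrt(sum(centered^2))
  if (nrm == 0)
    stop("degenerate input: constant vector cannot be standardized")
  centered / nrm
}

.pairwiseComplete <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch between target and gene vectors")
  keep <- is.finite(x) & is.finite(y)
  list(x = x[keep], y = y[keep], n = sum(keep))
}

#' Pairwise singular-value association score
#'
#' Scores the association between a target gene and a candidate gene from
#' the singular values of the two-column matrix of their standardized
#' expression profiles, keeping the singular values *unsorted* so each one
#' stays attached to its gene.
#'
#' Mode \code{"jacobi_position"} (default) applies one one-sided Jacobi
#' rotation to the standardized pair \code{[target, gene]}. The rotation
#' angle satisfies \code{tan(2 theta) = 2c/(a-b)} with \code{a}, \code{b}
#' the column squared norms and \code{c} their inner product; standardized
#' columns have \code{a = b = 1}, so \code{theta = pi/4} (the positive
#' angle is taken). The score is the post-rotation Euclidean norm of the
#' column sitting in the gene's original position, which for standardized
#' columns is exactly \code{sqrt(1 - r)} with \code{r} the Pearson
#' correlation: strong negative correlations score highest. Mode
#' \code{"abs_correlation"} returns the sign-agnostic larger singular
#' value \code{sqrt(1 + |r|)}.
#'
#' @param target,gene numeric vectors of equal length; pairwise-complete
#'   filtering is applied, at least 3 complete pairs and nonconstant
#'   values are required.
#' @param mode \code{"jacobi_position"} or \code{"abs_correlation"}.
#' @return list with \code{score}, the implied Pearson \code{r}, and
#'   \code{n} complete pairs used.
#' @examples
#' x <- rnorm(30); y <- -x + rnorm(30)
#' svdAssocScore(x, y)$score   # > 1: negative association
#' @export
svdAssocScore <- function(target, gene,
                          mode = c("jacobi_position", "abs_correlation")) {
  mode <- match.arg(mode)
  pc <- .pairwiseComplete(target, gene)
  if (pc$n < 3L)
    stop("fewer than 3 pairwise-complete observations")
  t1 <- standardizeVector(pc$x)
  g1 <- standardizeVector(pc$y)
  r <- sum(t1 * g1)
  score <- if (mode == "jacobi_position") {
    theta <- pi / 4  # a = b = 1 after standardization
    rotatedGene <- -t1 * sin(theta) + g1 * cos(theta)
    sqrt(sum(rotatedGene^2))
  } else {
    sqrt(1 + abs(r))
  }
  list(score = score, r = r, n = pc$n)
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' Classical product-moment correlation on pairwise-complete pairs, with
#' the two-sided p-value of \code{t = r * sqrt((n-2)/(1-r^2))} on
#' \code{n-2} degrees of freedom.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs,
#'   both nonconstant.
#' @return list with \code{r}, \code{p} and \code{n}.
#' @export
pearsonCorrelation <- function(x, y) {
  pc <- .pairwiseComplete(x, y)
  if (pc$n < 3L)
    stop("fewer than 3 pairwise-complete observations")
  dx <- pc$x - mean(pc$x)
  dy <- pc$y - mean(pc$y)
  denom <- sqrt(sum(dx^2) * sum(dy^2))
  if (denom == 0)
    stop("degenerate input: constant vector")
  r <- sum(dx * dy) / denom
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((pc$n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = pc$n - 2)
  }
  list(r = r, p = p, n = pc$n)
}

#' Run the stratified association screen
#'
#' For every stratum of the clinical variable (levels \code{"unknown"} are
#' excluded; strata with fewer than 4 samples are skipped with a warning),
#' scores every panel gene against the target gene on that stratum's
#' samples, takes the \code{selectionQuantile} quantile of the stratum's
#' scores as threshold, and flags genes whose score is *strictly* above
#' it. Pearson r and p accompany every score.
#'
#' @param cohort A \linkS4class{Cohort}.
#' @param targetGene target gene symbol; must be in the expression matrix.
#' @param panel character vector of panel genes; all must be present.
#' @param stratumVariable clinical column to stratify on
#'   (default \code{"er_status"}).
#' @param selectionQuantile quantile of the per-stratum score distribution
#'   used as selection threshold (default 0.5, i.e. the median rule).
#' @param mode score mode, see \code{\link{svdAssocScore}}.
#' @return data.frame with one row per (stratum, gene), ordered by stratum
#'   then gene: \code{gene}, \code{stratum}, \code{svd_score},
#'   \code{pearson_r}, \code{pearson_p}, \code{n_used}, \code{selected}.
#' @export
runScreen <- function(cohort, targetGene, panel,
                      stratumVariable = "er_status",
                      selectionQuantile = 0.5,
                      mode = c("jacobi_position", "abs_correlation")) {
  mode <- match.arg(mode)
  em <- SummarizedExperiment::assay(exprData(cohort), "log2expr")
  absent <- setdiff(c(targetGene, panel), rownames(em))
  if (length(absent))
    stop(sprintf("gene(s) absent from expression matrix: %s",
                 paste(absent, collapse = ", ")))
  cl <- clinicalData(cohort)
  if (!stratumVariable %in% colnames(cl))
    stop(sprintf("clinical variable '%s' not found", stratumVariable))
  strat <- as.character(cl[[stratumVariable]])
  levelsKeep <- setdiff(unique(strat[!is.na(strat)]), "unknown")
  levelsKeep <- sort(levelsKeep)
  if (length(levelsKeep) < 2L)
    warning("fewer than 2 usable strata")
  out <- list()
  for (s in levelsKeep) {
    idx <- which(!is.na(strat) & strat == s)
    if (length(idx) < 4L) {
      warning(sprintf("stratum '%s' has fewer than 4 samples; skipped", s))
      next
    }
    tv <- em[targetGene, idx]
    rows <- lapply(panel, function(g) {
      res <- tryCatch({
        sc <- svdAssocScore(tv, em[g, idx], mode = mode)
        pe <- pearsonCorrelation(tv, em[g, idx])
        data.frame(gene = g, stratum = s, svd_score = sc$score,
                   pearson_r = pe$r, pearson_p = pe$p, n_used = sc$n,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        warning(sprintf("gene '%s' in stratum '%s': %s", g, s,
                        conditionMessage(e)))
        data.frame(gene = g, stratum = s, svd_score = NA_real_,
                   pearson_r = NA_real_, pearson_p = NA_real_,
                   n_used = NA_integer_, stringsAsFactors = FALSE)
      })
      res
    })
    df <- do.call(rbind, rows)
    threshold <- stats::quantile(df$svd_score, probs = selectionQuantile,
                                 na.rm = TRUE, names = FALSE)
    df$selected <- !is.na(df$svd_score) & df$svd_score > threshold
    attr(df, "threshold") <- threshold
    out[[s]] <- df
  }
  thresholds <- vapply(out, attr, numeric(1), "threshold")
  res <- do.call(rbind, out)
  if (is.null(res))
    stop("no stratum could be screened")
  res <- res[order(res$stratum, res$gene, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "thresholds") <- thresholds
  attr(res, "mode") <- mode
  attr(res, "selection_quantile") <- selectionQuantile
  res
}

#' Cross-stratum Venn partition of selected genes
#'
#' Splits the selected genes of two screen strata into the three disjoint
#' Venn regions.
#'
#' @param resultsA,resultsB rows of a \code{\link{runScreen}} result for
#'   two strata (or any data.frames with \code{gene} and \code{selected});
#'   both must cover the same panel.
#' @return list of class \code{"VennPartition"} with sorted character
#'   vectors \code{only_a}, \code{only_b}, \code{shared}, plus the two
#'   stratum labels.
#' @export
vennPartition <- function(resultsA, resultsB) {
  if (!setequal(resultsA$gene, resultsB$gene))
    stop("the two result sets do not cover the same panel")
  selA <- resultsA$gene[resultsA$selected %in% TRUE]
  selB <- resultsB$gene[resultsB$selected %in% TRUE]
  structure(list(
    only_a = sort(setdiff(selA, selB)),
    only_b = sort(setdiff(selB, selA)),
    shared = sort(intersect(selA, selB)),
    stratum_a = if (length(resultsA$stratum)) resultsA$stratum[1L] else NA,
    stratum_b = if (length(resultsB$stratum)) resultsB$stratum[1L] else NA
  ), class = "VennPartition")
}

#' @export
print.VennPartition <- function(x, ...) {
  cat(sprintf("Venn partition (%s | %s)\n", x$stratum_a, x$stratum_b))
  cat(sprintf("  only %s (%d): %s\n", x$stratum_a, length(x$only_a),
              paste(x$only_a, collapse = ", ")))
  cat(sprintf("  only %s (%d): %s\n", x$stratum_b, length(x$only_b),
              paste(x$only_b, collapse = ", ")))
  cat(sprintf("  shared (%d): %s\n", length(x$shared),
              paste(x$shared, collapse = ", ")))
  invisible(x)
}
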
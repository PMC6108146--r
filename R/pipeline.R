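#' Read an analysis configuration file
#'
#' Flat YAML key-value configuration for \code{\link{runAnalysis}}.
#' Either an \code{inputs:} block (paths \code{expression},
#' \code{methylation}, \code{annotation}, \code{clinical}) or a
#' \code{simulate:} block (arguments of \code{\link{syntheticConfig}})
#' must be present, never both. Remaining keys: \code{target_gene},
#' \code{panel_file} (one gene per line; omitted = packaged 66-gene
#' panel), \code{stratum_variable}, \code{screen_quantile},
#' \code{screen_mode}, \code{outdir}, \code{seed}.
#'
#' @param path YAML file path.
#' @return configuration list for \code{\link{runAnalysis}}.
#' @export
readAnalysisConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    for (nm in c("nSamples", "targetShift", "survivalHR"))
      if (!is.null(sim[[nm]])) sim[[nm]] <- unlist(sim[[nm]])
    if (!is.null(sim$plantedCorrelations))
      sim$plantedCorrelations <- lapply(sim$plantedCorrelations, unlist)
    cfg$simulate <- sim
  }
  cfg
}

.stageSafely <- function(manifest, name, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(list(ok = TRUE, value = fun()),
                  error = function(e) list(ok = FALSE,
                                           error = conditionMessage(e)))
  manifest$stages[[name]] <- list(
    status = if (res$ok) "ok" else "failed",
    error = if (res$ok) NULL else res$error,
    rows = if (res$ok && is.data.frame(res$value)) nrow(res$value) else NULL,
    seconds = round(proc.time()[["elapsed"]] - t0, 3))
  list(manifest = manifest, value = if (res$ok) res$value else NULL)
}

#' Run the full in-silico analysis chain
#'
#' Executes, in fixed order, (1) target-gene expression group comparisons
#' across the stratum variable and the PAM50 subtypes, (2)
#' median-dichotomized stratified survival analysis, (3) the per-probe
#' methylation/expression correlation panel, and (4) the stratified
#' association screen with its cross-stratum Venn partition. Each stage
#' writes one TSV into \code{outdir}; a JSON run manifest records the
#' config echo, seed, versions and per-stage status/row counts. A failing
#' stage is recorded in the manifest without aborting independent stages.
#'
#' @param config configuration list (see \code{\link{readAnalysisConfig}});
#'   exactly one of \code{config$inputs} and \code{config$simulate} must
#'   be present.
#' @return invisibly, a list with the \code{cohort}, per-stage results and
#'   the \code{manifest}.
#' @export
runAnalysis <- function(config) {
  hasInputs <- !is.null(config$inputs)
  hasSim <- !is.null(config$simulate)
  if (hasInputs == hasSim)
    stop("exactly one of 'inputs' and 'simulate' must be configured")
  outdir <- config$outdir
  if (is.null(outdir)) stop("'outdir' must be configured")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)

  targetGene <- if (is.null(config$target_gene)) "ID4" else config$target_gene
  stratumVariable <- if (is.null(config$stratum_variable)) "er_status"
                     else config$stratum_variable
  quantileQ <- if (is.null(config$screen_quantile)) 0.5
               else as.numeric(config$screen_quantile)
  mode <- if (is.null(config$screen_mode)) "jacobi_position"
          else config$screen_mode
  panel <- if (!is.null(config$panel_file))
    readLines(config$panel_file) else genePanel()$gene
  panel <- setdiff(trimws(panel[nzchar(trimws(panel))]), targetGene)

  truth <- NULL
  if (hasSim) {
    simArgs <- config$simulate
    scfg <- if (methods::is(simArgs, "SyntheticConfig")) simArgs
            else do.call(syntheticConfig, simArgs)
    sim <- generateCohort(scfg)
    cohort <- sim$cohort
    truth <- sim$truth
  } else {
    inp <- config$inputs
    for (nm in c("expression", "methylation", "annotation", "clinical"))
      if (is.null(inp[[nm]]) || !file.exists(inp[[nm]]))
        stop(sprintf("input '%s' missing or unreadable", nm))
    cohort <- harmonizeCohort(
      readExpressionMatrix(inp$expression),
      readMethylationMatrix(inp$methylation, inp$annotation),
      readClinicalTable(inp$clinical, inp$column_map))
  }

  manifest <- list(
    package = "epiScreen",
    version = as.character(utils::packageVersion("epiScreen")),
    r_version = as.character(getRversion()),
    seed = seed,
    target_gene = targetGene,
    stratum_variable = stratumVariable,
    screen_quantile = quantileQ,
    screen_mode = mode,
    n_samples = length(sampleIDs(cohort)),
    simulated = hasSim,
    stages = list())
  results <- list(cohort = cohort, truth = truth)

  em <- SummarizedExperiment::assay(exprData(cohort), "log2expr")
  cl <- clinicalData(cohort)

  # stage 1: expression group comparisons
  st <- .stageSafely(manifest, "expression_groups", function() {
    strat <- as.character(cl[[stratumVariable]])
    lev <- sort(setdiff(unique(strat[!is.na(strat)]), "unknown"))
    rows <- list()
    if (length(lev) >= 2L) {
      tt <- studentTTest(em[targetGene, strat == lev[1L]],
                         em[targetGene, strat == lev[2L]])
      rows[[1L]] <- data.frame(
        comparison = sprintf("%s_vs_%s", lev[1L], lev[2L]),
        statistic_name = tt$statistic_name, statistic = tt$statistic,
        p_value = tt$p_value)
    }
    pam <- as.character(cl$pam50)
    ok <- !is.na(pam) & pam != "unknown"
    counts <- table(pam[ok])
    if (sum(counts >= 2L) >= 2L) {
      keep <- ok & pam %in% names(counts)[counts >= 2L]
      an <- oneWayAnova(em[targetGene, keep], pam[keep])
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = "pam50_anova", statistic_name = an$statistic_name,
        statistic = an$statistic, p_value = an$p_value)
    }
    df <- do.call(rbind, rows)
    writeResultsTable(df, file.path(outdir, "expression_groups.tsv"),
                      key = "comparison")
    df
  })
  manifest <- st$manifest; results$expression_groups <- st$value

  # stage 2: survival
  st <- .stageSafely(manifest, "survival", function() {
    sv <- stratifiedSurvivalAnalysis(cohort, targetGene, stratumVariable)
    summ <- do.call(rbind, lapply(names(sv), function(s) {
      r <- sv[[s]]
      if (!is.null(r$skipped))
        return(data.frame(stratum = s, n = NA_integer_,
                          median_used = NA_real_, chi_square = NA_real_,
                          p_value = NA_real_, skipped = r$skipped))
      data.frame(stratum = s, n = length(r$labels),
                 median_used = r$median_used,
                 chi_square = r$logrank$chi_square,
                 p_value = r$logrank$p_value, skipped = NA_character_)
    }))
    writeResultsTable(summ, file.path(outdir, "survival_summary.tsv"),
                      key = "stratum")
    km <- do.call(rbind, lapply(names(sv), function(s) {
      r <- sv[[s]]
      if (!is.null(r$skipped)) return(NULL)
      do.call(rbind, lapply(c("high", "low"), function(arm) {
        cv <- r[[paste0("km_", arm)]]
        if (length(cv$event_times) == 0L) return(NULL)
        data.frame(stratum = s, arm = arm, time = cv$event_times,
                   at_risk = cv$at_risk, events = cv$events,
                   survival = cv$survival)
      }))
    }))
    if (!is.null(km))
      writeResultsTable(km, file.path(outdir, "survival_km_steps.tsv"),
                        key = c("stratum", "arm", "time"))
    attr(summ, "detail") <- sv
    summ
  })
  manifest <- st$manifest; results$survival <- st$value

  # stage 3: methylation correlation panel
  st <- .stageSafely(manifest, "probe_panel", function() {
    pp <- probeCorrelationPanel(cohort, targetGene)
    writeResultsTable(pp, file.path(outdir, "probe_correlations.tsv"),
                      key = "probe_id")
    pp
  })
  manifest <- st$manifest; results$probe_panel <- st$value

  # stage 4: association screen + Venn
  st <- .stageSafely(manifest, "screen", function() {
    sc <- runScreen(cohort, targetGene, panel,
                    stratumVariable = stratumVariable,
                    selectionQuantile = quantileQ, mode = mode)
    writeResultsTable(sc, file.path(outdir, "association_screen.tsv"),
                      key = c("stratum", "gene"))
    strata <- unique(sc$stratum)
    if (length(strata) >= 2L) {
      vp <- vennPartition(sc[sc$stratum == strata[1L], ],
                          sc[sc$stratum == strata[2L], ])
      venn <- data.frame(
        region = rep(c(paste0("only_", strata[1L]),
                       paste0("only_", strata[2L]), "shared"),
                     c(length(vp$only_a), length(vp$only_b),
                       length(vp$shared))),
        gene = c(vp$only_a, vp$only_b, vp$shared))
      writeResultsTable(venn, file.path(outdir, "venn_partition.tsv"),
                        key = c("region", "gene"))
      attr(sc, "venn") <- vp
    }
    sc
  })
  manifest <- st$manifest; results$screen <- st$value

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  results$manifest <- manifest
  invisible(results)
}
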
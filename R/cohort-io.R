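NA_STRINGS <- c("NA", "", "NaN")

# Parse a TSV with one header row and an identifier first column into a
# numeric matrix, reporting the exact cell on a parse failure.
.readTsvMatrix <- function(path, what = "matrix") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "",
                          na.strings = character(0))
  if (ncol(df) < 2L)
    stop(sprintf("%s file '%s' needs an identifier column plus at least one data column", what, path))
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate row identifier(s) in '%s': %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  cols <- colnames(df)[-1L]
  if (anyDuplicated(cols))
    stop(sprintf("duplicate column identifier(s) in '%s': %s", path,
                 paste(unique(cols[duplicated(cols)]), collapse = ", ")))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  missing <- matrix(raw %in% NA_STRINGS, nrow = nrow(raw))
  num <- suppressWarnings(as.numeric(raw))
  bad <- is.na(num) & !missing
  if (any(bad)) {
    idx <- which(bad)[1L]
    rr <- (idx - 1L) %% nrow(raw) + 1L
    cc <- (idx - 1L) %/% nrow(raw) + 1L
    stop(sprintf("non-numeric cell '%s' in '%s' at row '%s', column '%s'",
                 raw[idx], path, ids[rr], cols[cc]))
  }
  m <- matrix(num, nrow = nrow(raw), dimnames = list(ids, cols))
  m
}

#' Read a gene-expression matrix (Xena-dialect TSV)
#'
#' Reads a tab-separated matrix of log2(norm_count+1) expression values
#' with one header row and the identifiers in the first column. The Xena
#' dialect ships genes as rows; the transposed dialect is handled through
#' \code{orientation}. Cells \code{"NA"}, \code{""} and \code{"NaN"} are
#' read as missing; any other non-numeric cell raises an error naming its
#' row and column.
#'
#' @param path TSV file path.
#' @param orientation \code{"genes_x_samples"} (default) or
#'   \code{"samples_x_genes"}; output is always canonical genes x samples.
#' @return A \code{SummarizedExperiment} with assay \code{"log2expr"}.
#' @export
readExpressionMatrix <- function(path,
    orientation = c("genes_x_samples", "samples_x_genes")) {
  orientation <- match.arg(orientation)
  m <- .readTsvMatrix(path, "expression")
  if (orientation == "samples_x_genes") m <- t(m)
  SummarizedExperiment::SummarizedExperiment(assays = list(log2expr = m))
}

#' Read a methylation beta-value matrix with probe annotation
#'
#' Beta values are methylation fraction estimates and must lie in [0,1];
#' any out-of-range value raises an error with its probe/sample
#' coordinates. The annotation TSV is keyed by probe ID and must carry a
#' \code{promoter_flag} column (logical or 0/1); an optional \code{region}
#' column is kept as a genomic-position label. Probes absent from the
#' annotation get \code{promoter_flag = FALSE} with a warning.
#'
#' @param path probes x samples beta TSV.
#' @param annotationPath probe annotation TSV.
#' @return A \code{SummarizedExperiment} with assay \code{"beta"} and
#'   \code{rowData} columns \code{promoter_flag} and \code{region}.
#' @export
readMethylationMatrix <- function(path, annotationPath) {
  m <- .readTsvMatrix(path, "methylation")
  out <- which(!is.na(m) & (m < 0 | m > 1))
  if (length(out)) {
    idx <- out[1L]
    rr <- (idx - 1L) %% nrow(m) + 1L
    cc <- (idx - 1L) %/% nrow(m) + 1L
    stop(sprintf("beta value %g outside [0,1] at probe '%s', sample '%s'",
                 m[idx], rownames(m)[rr], colnames(m)[cc]))
  }
  ann <- utils::read.delim(annotationPath, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "")
  if (!all(c("probe_id", "promoter_flag") %in% colnames(ann)))
    stop("annotation file must have 'probe_id' and 'promoter_flag' columns")
  if (anyDuplicated(ann$probe_id))
    stop("duplicate probe IDs in annotation")
  hit <- match(rownames(m), ann$probe_id)
  if (anyNA(hit))
    warning(sprintf("%d probe(s) missing annotation; promoter_flag set to FALSE",
                    sum(is.na(hit))))
  flag <- ifelse(is.na(hit), FALSE, as.logical(ann$promoter_flag[hit]))
  region <- if ("region" %in% colnames(ann))
    ifelse(is.na(hit), NA_character_, as.character(ann$region[hit]))
  else rep(NA_character_, nrow(m))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = m),
    rowData = S4Vectors::DataFrame(promoter_flag = flag, region = region,
                                   row.names = rownames(m)))
}

.defaultErMap <- c("ER+" = "ER+", "ER-" = "ER-",
                   "Positive" = "ER+", "Negative" = "ER-",
                   "positive" = "ER+", "negative" = "ER-")
.defaultPam50Map <- stats::setNames(PAM50_LEVELS, PAM50_LEVELS)
.defaultEventMap <- c("1" = TRUE, "0" = FALSE, "TRUE" = TRUE, "FALSE" = FALSE,
                      "dead" = TRUE, "alive" = FALSE,
                      "DECEASED" = TRUE, "LIVING" = FALSE)

#' Read and normalize a clinical table
#'
#' Maps the raw clinical TSV onto the canonical vocabulary: ER status in
#' \{ER+, ER-, unknown\}, PAM50 in \{LumA, LumB, Basal, Normal, Her2,
#' unknown\}, overall-survival time in months (nonnegative) and a logical
#' event flag (TRUE = death observed). Raw values without a mapping become
#' \code{"unknown"} (or \code{NA} for time/event) and a single warning
#' reports how many values fell through.
#'
#' @param path clinical TSV with a header row.
#' @param columnMap named list with the source column names
#'   (\code{sample_id}, \code{er_status}, \code{pam50}, \code{os_months},
#'   \code{os_event}) and optional value maps \code{er_map},
#'   \code{pam50_map} (named character) and \code{event_map} (named
#'   logical).
#' @return A \code{DataFrame} keyed by sample ID with columns
#'   \code{er_status}, \code{pam50}, \code{os_months}, \code{os_event}.
#' @export
readClinicalTable <- function(path, columnMap = list()) {
  if (is.null(columnMap)) columnMap <- list()
  cm <- utils::modifyList(
    list(sample_id = "sample_id", er_status = "er_status", pam50 = "pam50",
         os_months = "os_months", os_event = "os_event",
         er_map = .defaultErMap, pam50_map = .defaultPam50Map,
         event_map = .defaultEventMap),
    columnMap)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "")
  if (!cm$sample_id %in% colnames(df))
    stop(sprintf("mandatory sample-ID column '%s' missing", cm$sample_id))
  ids <- df[[cm$sample_id]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sample ID(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  unmapped <- 0L

  mapCat <- function(col, map, levels) {
    if (!col %in% colnames(df)) return(rep("unknown", nrow(df)))
    raw <- df[[col]]
    out <- unname(map[raw])
    bad <- is.na(out) & !(raw %in% NA_STRINGS)
    unmapped <<- unmapped + sum(bad)
    out[is.na(out)] <- "unknown"
    factor(out, levels = levels)
  }
  er <- mapCat(cm$er_status, cm$er_map, ER_LEVELS)
  pam <- mapCat(cm$pam50, cm$pam50_map, PAM50_LEVELS)

  osm <- rep(NA_real_, nrow(df))
  if (cm$os_months %in% colnames(df)) {
    raw <- df[[cm$os_months]]
    osm <- suppressWarnings(as.numeric(raw))
    if (any(!is.na(osm) & osm < 0))
      stop("negative overall-survival time encountered")
  }
  ose <- rep(NA, nrow(df))
  if (cm$os_event %in% colnames(df)) {
    raw <- df[[cm$os_event]]
    ose <- unname(cm$event_map[raw])
    bad <- is.na(ose) & !(raw %in% NA_STRINGS)
    unmapped <- unmapped + sum(bad)
  }
  if (unmapped > 0L)
    warning(sprintf("%d clinical value(s) had no mapping and were set to unknown/NA",
                    unmapped))
  S4Vectors::DataFrame(er_status = er, pam50 = pam, os_months = osm,
                       os_event = ose, row.names = ids)
}

#' Harmonize expression, methylation and clinical components into a Cohort
#'
#' The shared sample axis is the lexicographically sorted intersection of
#' the three sample-ID sets; every component is subset and reordered onto
#' it. Per-component dropped-sample counts are reported via
#' \code{message}. The operation is idempotent.
#'
#' @param expr expression \code{SummarizedExperiment}
#'   (\code{\link{readExpressionMatrix}}).
#' @param meth methylation \code{SummarizedExperiment}
#'   (\code{\link{readMethylationMatrix}}).
#' @param clin clinical \code{DataFrame} (\code{\link{readClinicalTable}}).
#' @return A \linkS4class{Cohort}.
#' @export
harmonizeCohort <- function(expr, meth, clin) {
  shared <- sort(Reduce(intersect,
                        list(colnames(expr), colnames(meth), rownames(clin))))
  if (length(shared) == 0L)
    stop("no samples shared by expression, methylation and clinical components")
  message(sprintf(
    "harmonized to %d samples (dropped: expression %d, methylation %d, clinical %d)",
    length(shared), ncol(expr) - length(shared), ncol(meth) - length(shared),
    nrow(clin) - length(shared)))
  Cohort(expression = expr[, shared],
         methylation = meth[, shared],
         clinical = clin[shared, , drop = FALSE])
}

#' Write / read a results table as deterministic TSV
#'
#' Rows are stably sorted by the declared key columns and numbers written
#' at 15 significant digits so a write/read round trip reproduces values
#' to full double precision. Missing values are written as \code{NA}.
#'
#' @param records data.frame of results sharing one schema.
#' @param path output TSV path.
#' @param key character vector of column names to sort by (stable);
#'   default: no re-sorting.
#' @return \code{writeResultsTable} invisibly returns \code{path};
#'   \code{readResultsTable} returns a data.frame.
#' @export
writeResultsTable <- function(records, path, key = character()) {
  records <- as.data.frame(records)
  if (length(key)) {
    if (!all(key %in% colnames(records)))
      stop("sort key column(s) absent from records")
    ord <- do.call(order, c(unname(records[key]), list(method = "radix")))
    records <- records[ord, , drop = FALSE]
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  fmt <- lapply(records, function(col) {
    if (is.double(col)) {
      out <- vapply(col, function(v)
        if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE,
                                       trim = TRUE), "")
      out
    } else as.character(col)
  })
  out <- as.data.frame(fmt, check.names = FALSE, optional = TRUE)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    quote = "", na.strings = NA_STRINGS)
}

#' Write a Cohort's components to TSV files
#'
#' Emits the Xena-dialect expression and beta matrices, the probe
#' annotation and the clinical table under a common prefix, matching what
#' the readers expect.
#'
#' @param cohort A \linkS4class{Cohort}.
#' @param prefix path prefix; files \code{<prefix>_expression.tsv},
#'   \code{_methylation.tsv}, \code{_probe_annotation.tsv},
#'   \code{_clinical.tsv} are produced.
#' @return Invisibly, the named vector of written paths.
#' @export
writeCohort <- function(cohort, prefix) {
  paths <- c(expression = paste0(prefix, "_expression.tsv"),
             methylation = paste0(prefix, "_methylation.tsv"),
             annotation = paste0(prefix, "_probe_annotation.tsv"),
             clinical = paste0(prefix, "_clinical.tsv"))
  writeMatrixTsv <- function(m, path, idName) {
    df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                     check.names = FALSE)
    colnames(df)[1L] <- idName
    writeResultsTable(df, path)
  }
  writeMatrixTsv(SummarizedExperiment::assay(exprData(cohort), "log2expr"),
                 paths["expression"], "gene")
  writeMatrixTsv(SummarizedExperiment::assay(methData(cohort), "beta"),
                 paths["methylation"], "probe")
  rd <- SummarizedExperiment::rowData(methData(cohort))
  writeResultsTable(
    data.frame(probe_id = rownames(rd), promoter_flag = rd$promoter_flag,
               region = rd$region), paths["annotation"])
  cl <- clinicalData(cohort)
  writeResultsTable(
    data.frame(sample_id = rownames(cl),
               er_status = as.character(cl$er_status),
               pam50 = as.character(cl$pam50),
               os_months = cl$os_months,
               os_event = as.integer(cl$os_event)), paths["clinical"])
  invisible(paths)
}

#' The packaged 66-gene breast-cancer candidate panel
#'
#' Gene symbols, names and molecular/cellular function annotations for the
#' candidate panel screened against the target gene.
#'
#' @return data.frame with columns \code{gene}, \code{gene_name},
#'   \code{function}.
#' @examples
#' nrow(genePanel())
#' @export
genePanel <- function() {
  path <- system.file("extdata", "gene_panel.tsv", package = "epiScreen",
                      mustWork = TRUE)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    quote = "")
}
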
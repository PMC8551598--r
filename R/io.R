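## Plain-text readers and writers (TSV tables, dense delimited matrices,
## JSON reports). All outputs are deterministic: no timestamps.

#' Read / write tabular and matrix artefacts
#'
#' `writeTsv()`/`readTsv()` handle header-rowed TSV tables;
#' `writeMatrixTsv()`/`readMatrixTsv()` dense numeric matrices with row and
#' column names; `writeJsonReport()` writes a JSON report with unboxed
#' scalars.
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return the parsed object; writers return `path` invisibly.
#' @name io
NULL

#' @rdname io
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readTsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname io
#' @export
writeMatrixTsv <- function(x, path) {
  utils::write.table(as.matrix(x), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname io
#' @export
readMatrixTsv <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
}

#' @rdname io
#' @export
writeJsonReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an ICN map table
#'
#' Expects columns `region_id` and `icn_label` (optional `hemisphere`).
#'
#' @param path TSV path.
#' @return Named character vector, region id -> ICN label.
#' @export
readIcnMap <- function(path) {
  d <- readTsv(path)
  stats::setNames(d$icn_label, d$region_id)
}

#' Write an ICN map table
#'
#' @param icnMap Named character vector (region id -> ICN label).
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
writeIcnMap <- function(icnMap, path) {
  writeTsv(data.frame(region_id = names(icnMap), icn_label = unname(icnMap)),
           path)
}

#' Write a cohort to disk as plain-text artefacts
#'
#' Behaviour table and covariates as TSV, one regions x timepoints matrix file
#' per subject, FD traces, and the ICN map.
#'
#' @param cohort A [SyntheticCohort-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeTsv(cohort@behaviour, file.path(dir, "behaviour.tsv"))
  writeTsv(cohort@covariates, file.path(dir, "covariates.tsv"))
  writeIcnMap(cohort@icnMap, file.path(dir, "icn_map.tsv"))
  writeMatrixTsv(cohort@fdTrace, file.path(dir, "fd_trace.tsv"))
  tsDir <- file.path(dir, "timeseries")
  dir.create(tsDir, showWarnings = FALSE)
  for (id in names(cohort@timeseries))
    writeMatrixTsv(cohort@timeseries[[id]], file.path(tsDir, paste0(id, ".tsv")))
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir Directory containing the cohort artefacts.
#' @return A [SyntheticCohort-class].
#' @export
readCohort <- function(dir) {
  behaviour <- readTsv(file.path(dir, "behaviour.tsv"))
  covariates <- readTsv(file.path(dir, "covariates.tsv"))
  icn <- readIcnMap(file.path(dir, "icn_map.tsv"))
  fd <- readMatrixTsv(file.path(dir, "fd_trace.tsv"))
  ids <- behaviour$subject_id
  ts <- lapply(ids, function(id)
    readMatrixTsv(file.path(dir, "timeseries", paste0(id, ".tsv"))))
  names(ts) <- ids
  methods::new("SyntheticCohort", behaviour = behaviour,
               trueLabels = stats::setNames(behaviour$group, ids),
               timeseries = ts, covariates = covariates,
               fdTrace = fd[ids, , drop = FALSE], icnMap = icn)
}
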
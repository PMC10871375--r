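## End-to-end orchestration with run manifests: generate -> etl (nlp + deid
## + flatten) -> study (phenotype + cube + suppress) -> merge -> analyze.
## Logs are structured one-event-per-line and never contain identifiers or
## note text.

logEvent <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

writeManifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

writeTables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "encounters", "conditions", "observations", "symptoms")) {
    write.csv(slot(tables, nm), file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Read study tables written by [runETL()]
#' @param dir ETL output directory.
#' @return a [StudyTableSet-class].
#' @export
readTables <- function(dir) {
  rd <- function(nm, cls) {
    df <- read.csv(file.path(dir, paste0(nm, ".csv")), stringsAsFactors = FALSE,
                   colClasses = cls)
    df
  }
  new("StudyTableSet",
      patients = rd("patients", c(id = "character")),
      encounters = rd("encounters", c(id = "character", patient = "character")),
      conditions = rd("conditions", c(encounter = "character",
                                      patient = "character", code = "character")),
      observations = rd("observations", c(encounter = "character",
                                          patient = "character",
                                          code = "character")),
      symptoms = rd("symptoms", c(encounter = "character",
                                  patient = "character", code = "character")))
}

#' Run the site ETL stage
#'
#' Reads a site's bulk NDJSON export, runs symptom NLP over the notes
#' (notes are consumed inside this stage and never written out),
#' de-identifies the structured and NLP-derived resources with the keyed
#' codebook, flattens to study tables, writes the tables as CSV and emits a
#' run manifest.
#'
#' @param siteDir directory with the site's NDJSON export.
#' @param outDir output directory for tables and manifest.
#' @param rules a [DeidRules-class]; default the shipped template.
#' @param secret codebook secret string.
#' @param dict a [SymptomDictionary-class].
#' @param cues negation cue configuration.
#' @return a [StudyTableSet-class], invisibly; side effects: CSV tables,
#'   `deid/` NDJSON and `manifest.yaml` under `outDir`.
#' @export
runETL <- function(siteDir, outDir, rules = defaultDeidRules(),
                   secret = Sys.getenv("COHORTCUBE_SECRET"),
                   dict = defaultSymptomDictionary(), cues = negationCues()) {
  if (!nzchar(secret)) {
    stop("no codebook secret supplied (argument 'secret' or COHORTCUBE_SECRET)")
  }
  manifest <- list(command = "etl", site = basename(siteDir),
                   input = siteDir, output = outDir,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  fail <- function(stage, e) {
    manifest$failedStage <- stage
    manifest$error <- conditionMessage(e)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeManifest(manifest, file.path(outDir, "manifest.yaml"))
    stop(e)
  }
  export <- tryCatch(readBulkExport(siteDir), error = function(e) fail("read", e))
  logEvent("etl", "site=", export@site, " patients=",
           length(export@records$Patient))
  symRecords <- tryCatch(
    extractSymptomRecords(export, dict, cues, exportDir = siteDir),
    error = function(e) fail("nlp", e)
  )
  logEvent("nlp", "symptom_records=", length(symRecords))
  cb <- codebook(secret)
  deid <- tryCatch({
    withSym <- export
    withSym@records$Observation <- c(withSym@records$Observation, symRecords)
    applyDeidExport(withSym, rules, cb)
  }, error = function(e) fail("deid", e))
  tables <- tryCatch(flattenResources(deid), error = function(e) fail("flatten", e))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeBulkExport(deid, file.path(outDir, "deid"))
  writeTables(tables, outDir)
  manifest$rows <- list(
    patients = nrow(tables@patients), encounters = nrow(tables@encounters),
    conditions = nrow(tables@conditions),
    observations = nrow(tables@observations), symptoms = nrow(tables@symptoms)
  )
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  writeManifest(manifest, file.path(outDir, "manifest.yaml"))
  logEvent("etl", "done rows=", paste(unlist(manifest$rows), collapse = "/"))
  invisible(tables)
}

#' Run a study at one site: phenotype, variables, cube, suppression
#'
#' @param tables a [StudyTableSet-class] or an ETL output directory.
#' @param spec a [StudySpec-class].
#' @param site site label recorded in the matrix metadata.
#' @param threshold small-cell suppression threshold.
#' @param out optional CSV path; when given the suppressed matrix and its
#'   metadata YAML are written there.
#' @return the suppressed [AggregateMatrix-class].
#' @export
runStudy <- function(tables, spec, site = "site", threshold = 10L, out = NULL) {
  if (is.character(tables)) tables <- readTables(tables)
  cohort <- evaluateCase(tables, spec)
  cohort <- deriveVariables(cohort, tables, spec)
  vars <- vapply(spec@variables, function(v) v@name, character(1))
  m <- cubeCounts(cohort, vars, metadata = list(
    sites = site, period = spec@period, countUnit = spec@countUnit,
    variableDescriptions = setNames(
      vapply(spec@variables, function(v) v@kind, character(1)), vars
    )
  ))
  m <- suppressCells(m, threshold)
  logEvent("study", "site=", site, " cohort=", nrow(cohort),
           " cells=", nrow(aggCounts(m)))
  if (!is.null(out)) writeAggregateMatrix(m, out)
  m
}

#' Merge site matrices (coordinating-site step)
#'
#' @param matrices list of [AggregateMatrix-class], or character paths to
#'   matrix CSVs written by [writeAggregateMatrix()].
#' @param out optional CSV path for the merged network matrix.
#' @return the merged [AggregateMatrix-class].
#' @export
runMerge <- function(matrices, out = NULL) {
  if (is.character(matrices)) matrices <- lapply(matrices, readAggregateMatrix)
  m <- mergeMatrices(matrices)
  logEvent("merge", "sites=", paste(aggMetadata(m)$sites, collapse = ","),
           " cells=", nrow(aggCounts(m)))
  if (!is.null(out)) writeAggregateMatrix(m, out)
  m
}

#' Compute a measure from an aggregate matrix
#'
#' @param matrix an [AggregateMatrix-class] or a matrix CSV path.
#' @param measure one of "prevalence", "or", "rr", "cprob", "chi2",
#'   "trend".
#' @param ... measure arguments: `variable`/`level` for prevalence;
#'   `exposure`/`outcome` (each c(variable, level)) for or/rr/cprob/chi2;
#'   `nlpVariable`/`icdVariable`/`monthVariable` for trend.
#' @return the measure's value (list or data.frame).
#' @export
runAnalyze <- function(matrix, measure = c("prevalence", "or", "rr", "cprob",
                                           "chi2", "trend"), ...) {
  if (is.character(matrix)) matrix <- readAggregateMatrix(matrix)
  measure <- match.arg(measure)
  args <- list(...)
  ct <- function() crossTab(matrix, args$exposure, args$outcome)
  switch(measure,
    prevalence = prevalence(matrix, args$variable, args$level %||% "TRUE"),
    or = oddsRatio(ct()),
    rr = relativeRisk(ct()),
    cprob = conditionalProbability(ct(), args$direction %||% "outcome_given_exposure"),
    chi2 = chiSquare(ct(), correct = isTRUE(args$correct)),
    trend = trendSeries(matrix, args$nlpVariable, args$icdVariable,
                        args$monthVariable %||% "month")
  )
}
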
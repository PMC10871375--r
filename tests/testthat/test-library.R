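deidSmallExport <- function() {
  pop <- smallPopulation()
  ex <- pop$exports[[1]]
  cb <- codebook(testSecret)
  withSym <- ex
  withSym@records$Observation <- c(
    withSym@records$Observation,
    extractSymptomRecords(ex, defaultSymptomDictionary())
  )
  applyDeidExport(withSym, defaultDeidRules(), cb)
}

test_that("flatten conserves row counts and keeps references resolvable", {
  de <- deidSmallExport()
  tabs <- flattenResources(de)
  expect_identical(nrow(tabs@patients), length(de@records$Patient))
  expect_identical(nrow(tabs@encounters), length(de@records$Encounter))
  nSym <- sum(vapply(de@records$Observation, function(r) {
    any(vapply(r$meta$tag, function(t) identical(t$code, "nlp"), logical(1)))
  }, logical(1)))
  expect_identical(nrow(tabs@symptoms), nSym)
  expect_identical(nrow(tabs@observations), length(de@records$Observation) - nSym)

  # join patient<->encounter preserved through flattening
  expect_true(all(tabs@encounters$patient %in% tabs@patients$id))
  expect_true(all(tabs@observations$encounter %in% tabs@encounters$id))
  expect_true(all(tabs@symptoms$encounter %in% tabs@encounters$id))
})

test_that("observations without a numeric value are excluded with a message", {
  ex <- new("BulkExport", records = list(
    Patient = list(mkPatient("p1")),
    Encounter = list(mkEncounter("e1", "p1")),
    Condition = list(),
    Observation = list(
      mkObservation("o1", "p1", "e1", "8480-6", 120),
      local({
        o <- mkObservation("o2", "p1", "e1", "8462-4", 80)
        o$valueQuantity <- NULL
        o
      })
    ),
    DocumentReference = list(), MedicationRequest = list()
  ), site = "s", exportTime = "")
  expect_message(tabs <- flattenResources(ex), "o2.*excluded")
  expect_identical(nrow(tabs@observations), 1L)
})

test_that("dangling encounter references are kept as NA with a warning", {
  ex <- new("BulkExport", records = list(
    Patient = list(mkPatient("p1")),
    Encounter = list(mkEncounter("e1", "p1"), mkEncounter("e2", "ghost")),
    Condition = list(), Observation = list(),
    DocumentReference = list(), MedicationRequest = list()
  ), site = "s", exportTime = "")
  expect_warning(tabs <- flattenResources(ex), "unknown patients")
  expect_identical(nrow(tabs@encounters), 2L)
  expect_true(is.na(tabs@encounters$patient[tabs@encounters$id == "e2"]))
})

test_that("hypertension phenotype recovers the 140/90 critical values", {
  spec <- hypertensionStudySpec()
  isCase <- function(sys, dia) {
    cohort <- evaluateCase(bpTables(sys, dia), spec)
    cohort$case[cohort$unit == "e1"]
  }
  expect_true(isCase(142, 85))   # systolic arm
  expect_false(isCase(139, 89))  # strict boundary below both
  expect_true(isCase(120, 95))   # diastolic arm
  expect_true(isCase(140, 60))   # inclusive comparator, systolic
  expect_true(isCase(110, 90))   # inclusive comparator, diastolic
  expect_false(isCase(100, 70))
})

test_that("case evaluation respects the study period and exclusions", {
  spec <- hypertensionStudySpec()
  outside <- bpTables(180, 110, month = "2020-06")
  cohort <- evaluateCase(outside, spec)
  expect_identical(nrow(cohort), 0L) # encounter outside the period: no unit

  # exclusion removes an otherwise-included unit
  specEx <- spec
  specEx@caseDefinition <- caseDefinition(
    inclusion = specEx@caseDefinition@inclusion,
    exclusion = thresholdCriterion("8462-4", ">=", 100)
  )
  t1 <- bpTables(150, 105)
  expect_false(evaluateCase(t1, specEx)$case[1])
  expect_true(evaluateCase(bpTables(150, 95), specEx)$case[1])
})

test_that("adding codes to an inclusion value set never removes cases", {
  pop <- smallPopulation()
  etl <- etlSmallPopulation()
  tabs <- etl$tables[[1]]
  base <- diseasePrevalenceStudySpec()
  wide <- base
  wide@valueSets$disease <- valueSet("disease", c("U07.1", "R05"))
  cBase <- evaluateCase(tabs, base)
  cWide <- evaluateCase(tabs, wide)
  expect_true(all(cBase$unit[cBase$case] %in% cWide$unit[cWide$case]))
})

test_that("variable derivation: bins, months, booleans", {
  tabs <- bpTables(150, 95, month = "2021-03", birthYear = 2014L)
  spec <- hypertensionStudySpec()
  cohort <- deriveVariables(evaluateCase(tabs, spec), tabs, spec)
  expect_identical(cohort$age_group, "5-11")   # age 7 under edges 0,5,12,18,65,90
  expect_identical(cohort$month, "2021-03")
  expect_identical(cohort$hypertensive, "TRUE")

  # boolean symptom variable from the NLP table: true iff >=1 affirmed
  # in-period mention
  tabs2 <- bpTables(120, 70)
  tabs2@symptoms <- data.frame(encounter = "e1", patient = "p1", code = "R50.9",
                               month = "2021-03", source = "nlp",
                               stringsAsFactors = FALSE)
  spec2 <- symptomTrendStudySpec(symptoms = c(fever = "R50.9"))
  spec2@caseDefinition <- caseDefinition(anyOf(
    thresholdCriterion("8480-6", ">", 0) # everyone
  ))
  cohort2 <- deriveVariables(evaluateCase(tabs2, spec2), tabs2, spec2)
  expect_identical(cohort2$fever_nlp, "TRUE")
  expect_identical(cohort2$fever_icd, "FALSE")
})

test_that("events outside the study period never influence case status or variables", {
  etl <- etlSmallPopulation()
  tabs <- etl$tables[[1]]
  spec <- diseasePrevalenceStudySpec()
  before <- deriveVariables(evaluateCase(tabs, spec), tabs, spec)

  # perturb: append out-of-period condition and symptom rows for everyone
  tabs2 <- tabs
  tabs2@encounters <- rbind(tabs2@encounters, data.frame(
    id = "zzz-out", patient = tabs@patients$id[1], month = "2019-01",
    class = "EMER", stringsAsFactors = FALSE
  ))
  tabs2@conditions <- rbind(tabs2@conditions, data.frame(
    encounter = "zzz-out", patient = tabs@patients$id[1],
    system = "x", code = "U07.1", stringsAsFactors = FALSE
  ))
  tabs2@symptoms <- rbind(tabs2@symptoms, data.frame(
    encounter = "zzz-out", patient = tabs@patients$id[1], code = "R50.9",
    month = "2019-01", source = "nlp", stringsAsFactors = FALSE
  ))
  after <- deriveVariables(evaluateCase(tabs2, spec), tabs2, spec)
  expect_identical(before, after)
})

test_that("study specs round-trip through YAML and unresolved value sets error", {
  spec <- hypertensionStudySpec()
  expect_s4_class(spec, "StudySpec")
  expect_identical(spec@countUnit, "encounters")

  broken <- diseasePrevalenceStudySpec()
  broken@valueSets$disease <- NULL
  expect_error(evaluateCase(bpTables(120, 70), broken), "not loaded")
})
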
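# Programmatic fixtures and independent oracles shared across test files.

testSecret <- "unit-test-secret-0123456789"

mkPatient <- function(id, given = "Grace", family = "Whitfield",
                      gender = "female", birthDate = "1980-06-15") {
  list(resourceType = "Patient", id = id,
       name = list(list(family = family, given = list(given))),
       gender = gender, birthDate = birthDate,
       address = list(list(line = list("12 Maple Avenue"), city = "Springfield")),
       telecom = list(list(system = "phone", value = "555-0101-001")))
}

mkEncounter <- function(id, patient, date = "2021-03-15") {
  list(resourceType = "Encounter", id = id, status = "finished",
       class = list(code = "EMER"),
       subject = list(reference = paste0("Patient/", patient)),
       period = list(start = paste0(date, "T09:00:00")))
}

mkCondition <- function(id, patient, encounter, code, date = "2021-03-15") {
  list(resourceType = "Condition", id = id,
       code = list(coding = list(list(
         system = "http://hl7.org/fhir/sid/icd-10-cm", code = code
       ))),
       subject = list(reference = paste0("Patient/", patient)),
       encounter = list(reference = paste0("Encounter/", encounter)),
       recordedDate = date)
}

mkObservation <- function(id, patient, encounter, code, value,
                          date = "2021-03-15", unit = "mm[Hg]") {
  list(resourceType = "Observation", id = id, status = "final",
       code = list(coding = list(list(system = "http://loinc.org", code = code))),
       subject = list(reference = paste0("Patient/", patient)),
       encounter = list(reference = paste0("Encounter/", encounter)),
       effectiveDateTime = date,
       valueQuantity = list(value = value, unit = unit))
}

mkDocRef <- function(id, patient, encounter, text, date = "2021-03-15",
                     contentType = "text/plain") {
  list(resourceType = "DocumentReference", id = id, status = "current",
       subject = list(reference = paste0("Patient/", patient)),
       date = paste0(date, "T09:30:00"),
       context = list(encounter = list(list(
         reference = paste0("Encounter/", encounter)
       ))),
       content = list(list(attachment = list(
         contentType = contentType,
         data = jsonlite::base64_enc(charToRaw(text))
       ))))
}

# StudyTableSet with one patient/encounter carrying one blood-pressure pair
bpTables <- function(sys, dia, month = "2021-03", birthYear = 1980L) {
  new("StudyTableSet",
    patients = data.frame(id = "p1", sex = "female", birthYear = birthYear,
                          stringsAsFactors = FALSE),
    encounters = data.frame(id = "e1", patient = "p1", month = month,
                            class = "EMER", stringsAsFactors = FALSE),
    conditions = data.frame(encounter = character(), patient = character(),
                            system = character(), code = character()),
    observations = data.frame(
      encounter = c("e1", "e1"), patient = c("p1", "p1"),
      code = c("8480-6", "8462-4"), value = c(sys, dia),
      unit = "mm[Hg]", stringsAsFactors = FALSE
    ),
    symptoms = data.frame(encounter = character(), patient = character(),
                          code = character(), month = character(),
                          source = character()))
}

# random discrete cohort for cube property tests
randomCohort <- function(n, nvars, maxLevels = 3) {
  cols <- lapply(seq_len(nvars), function(j) {
    k <- sample(2:maxLevels, 1)
    sample(paste0("L", seq_len(k)), n, replace = TRUE,
           prob = rexp(k))
  })
  df <- as.data.frame(setNames(cols, paste0("v", seq_len(nvars))),
                      stringsAsFactors = FALSE)
  df
}

allSubsets <- function(variables) {
  subs <- list(character(0))
  for (k in seq_along(variables)) {
    subs <- c(subs, utils::combn(variables, k, simplify = FALSE))
  }
  subs
}

# independent oracle: enumerate all 2^n subsets and count by explicit
# row-filtering per assignment (no grouping machinery shared with the
# implementation)
bruteCubeFilter <- function(cohort, variables) {
  out <- character()
  cnt <- integer()
  for (sub in allSubsets(variables)) {
    if (length(sub) == 0) {
      out <- c(out, "()")
      cnt <- c(cnt, nrow(cohort))
      next
    }
    combos <- unique(cohort[, sub, drop = FALSE])
    for (i in seq_len(nrow(combos))) {
      keep <- rep(TRUE, nrow(cohort))
      for (v in sub) {
        keep <- keep & as.character(cohort[[v]]) == as.character(combos[i, v])
      }
      out <- c(out, paste(paste0(sub, "=", unlist(combos[i, , drop = TRUE])),
                          collapse = ";"))
      cnt <- c(cnt, sum(keep))
    }
  }
  setNames(cnt, out)
}

# faster independent route via base-R string tabulation, used for the bulk
# random-cohort equivalence runs
bruteCubeTable <- function(cohort, variables) {
  out <- character()
  cnt <- integer()
  for (sub in allSubsets(variables)) {
    if (length(sub) == 0) {
      out <- c(out, "()")
      cnt <- c(cnt, nrow(cohort))
      next
    }
    key <- do.call(paste, c(lapply(cohort[sub], as.character), sep = "\r"))
    tab <- table(key)
    lv <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- c(out, vapply(lv, function(levels) {
      paste(paste0(sub, "=", levels), collapse = ";")
    }, character(1)))
    cnt <- c(cnt, as.integer(tab))
  }
  setNames(cnt, out)
}

# canonical map form of an AggregateMatrix for set-wise comparison
countsToMap <- function(m) {
  counts <- aggCounts(m)
  vars <- aggVariables(m)
  if (nrow(counts) == 0) return(setNames(integer(0), character(0)))
  keys <- vapply(seq_len(nrow(counts)), function(i) {
    fixed <- vars[!is.na(unlist(counts[i, vars]))]
    if (length(fixed) == 0) return("()")
    paste(paste0(fixed, "=", unlist(counts[i, fixed])), collapse = ";")
  }, character(1))
  setNames(as.integer(counts$cnt), keys)
}

expectSameMap <- function(got, want) {
  expect_setequal(names(got), names(want))
  expect_identical(unname(got[sort(names(got))]),
                   unname(want[sort(names(want))]))
}

# small cached synthetic population shared by integration-flavoured tests
.popCache <- new.env(parent = emptyenv())
smallPopulation <- function() {
  if (is.null(.popCache$pop)) {
    cfg <- syntheticConfig(nPatients = 120L, nSites = 2L, seed = 7L)
    .popCache$pop <- generatePopulation(cfg)
  }
  .popCache$pop
}

etlSmallPopulation <- function() {
  if (is.null(.popCache$etl)) {
    pop <- smallPopulation()
    dir <- file.path(tempdir(), "cc-small-pop")
    unlink(dir, recursive = TRUE)
    writeSiteExports(pop$exports, dir)
    tabs <- lapply(names(pop$exports), function(s) {
      suppressMessages(runETL(file.path(dir, s), file.path(dir, paste0("etl-", s)),
                              secret = testSecret))
    })
    names(tabs) <- names(pop$exports)
    .popCache$etl <- list(dir = dir, tables = tabs)
  }
  .popCache$etl
}
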
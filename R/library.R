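## Study-table flattening and computable-phenotype evaluation: case
## definition + study variables + study period, evaluated over simplified
## tabular views of the de-identified resources.

#' Construct a value set
#'
#' @param id value-set identifier.
#' @param codes character vector of codes.
#' @param system code-system label.
#' @return a [ValueSet-class].
#' @export
valueSet <- function(id, codes, system = "ICD-10-CM") {
  new("ValueSet", id = id, system = system, codes = unique(as.character(codes)))
}

#' Read a value set from a two-column CSV (system, code)
#'
#' Mirrors VSAC-style exports: a header row then one (system, code) pair
#' per line. The file's first system label is used for the set.
#'
#' @param path CSV path.
#' @param id value-set identifier; defaults to the file name.
#' @return a [ValueSet-class].
#' @export
readValueSetCSV <- function(path, id = tools::file_path_sans_ext(basename(path))) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("system", "code") %in% names(df))) {
    stop("value-set CSV needs columns 'system' and 'code'")
  }
  valueSet(id, df$code, system = df$system[1])
}

#' Phenotype criterion primitives and combinators
#'
#' `codeCriterion()` tests membership of a unit's codes (condition, symptom
#' or medication table) in a value set; `thresholdCriterion()` compares a
#' numeric observation against a threshold; `anyOf()` / `allOf()` combine
#' criteria (at the encounter level: an encounter satisfies `allOf` iff it
#' satisfies every branch).
#'
#' @param table one of "condition", "symptom", "medication".
#' @param valueset value-set id (resolved against the study spec).
#' @return a criterion list usable in [caseDefinition()].
#' @export
codeCriterion <- function(table, valueset) {
  list(type = "code", table = table, valueset = valueset)
}

#' @rdname codeCriterion
#' @param code observation code (e.g. LOINC) the threshold applies to.
#' @param cmp comparator: one of ">=", ">", "<=", "<", "==".
#' @param value numeric threshold.
#' @export
thresholdCriterion <- function(code, cmp, value) {
  list(type = "threshold", code = code, cmp = cmp, value = value)
}

#' @rdname codeCriterion
#' @param ... sub-criteria.
#' @export
anyOf <- function(...) list(type = "any", criteria = list(...))

#' @rdname codeCriterion
#' @export
allOf <- function(...) list(type = "all", criteria = list(...))

#' Construct a case definition
#'
#' @param inclusion criterion tree (required).
#' @param exclusion criterion tree, or NULL for none. Exclusion is
#'   evaluated after inclusion: a unit is a case iff inclusion holds and
#'   exclusion does not.
#' @return a [CaseDefinition-class].
#' @export
caseDefinition <- function(inclusion, exclusion = NULL) {
  new("CaseDefinition", inclusion = inclusion,
      exclusion = if (is.null(exclusion)) list() else exclusion)
}

#' Construct a study variable
#'
#' @param name variable name.
#' @param kind one of "boolean", "categorical", "binned", "month".
#' @param rule derivation rule list; see [StudyVariable-class].
#' @return a [StudyVariable-class].
#' @export
studyVariable <- function(name, kind, rule) {
  new("StudyVariable", name = name, kind = kind, rule = rule)
}

#' Construct a study specification
#'
#' @param name study label.
#' @param caseDefinition a [CaseDefinition-class].
#' @param variables list of [StudyVariable-class] (order defines the
#'   aggregate-matrix variable order).
#' @param valueSets named list of [ValueSet-class] referenced by criteria.
#' @param period c(start, end) months "YYYY-MM", inclusive.
#' @param countUnit "patients" or "encounters".
#' @param includeComparison retain in-period non-cases as a comparison
#'   cohort.
#' @return a [StudySpec-class].
#' @export
studySpec <- function(name, caseDefinition, variables, valueSets = list(),
                      period, countUnit = "patients",
                      includeComparison = FALSE) {
  if (length(valueSets) > 0 && is.null(names(valueSets))) {
    names(valueSets) <- vapply(valueSets, function(v) v@id, character(1))
  }
  new("StudySpec", name = name, caseDefinition = caseDefinition,
      variables = variables, valueSets = valueSets,
      period = period, countUnit = countUnit,
      includeComparison = includeComparison)
}

parseCriterion <- function(x) {
  if (!is.null(x$any)) return(list(type = "any", criteria = lapply(x$any, parseCriterion)))
  if (!is.null(x$all)) return(list(type = "all", criteria = lapply(x$all, parseCriterion)))
  ty <- x$type
  if (identical(ty, "code_in_valueset") || identical(ty, "code")) {
    return(codeCriterion(x$table, x$valueset))
  }
  if (identical(ty, "medication_in_valueset")) {
    return(codeCriterion("medication", x$valueset))
  }
  if (identical(ty, "numeric_threshold") || identical(ty, "threshold")) {
    return(thresholdCriterion(x$code, x$cmp, x$value))
  }
  stop("unknown criterion in study spec YAML: ", ty %||% "<untyped>")
}

#' Read a study specification from YAML
#'
#' Schema: `name`, `study_period: [start, end]`, `count_unit`,
#' `include_comparison`, `value_sets: {id: {system, codes}}`,
#' `case_definition: {inclusion: ..., exclusion: ...}` (criteria as
#' `{type: code_in_valueset|numeric_threshold|medication_in_valueset, ...}`
#' nested under `any:` / `all:`), and `variables:` with `{name, kind,
#' source, ...}`.
#'
#' @param path YAML path.
#' @return a [StudySpec-class].
#' @export
readStudySpec <- function(path) {
  raw <- yaml::read_yaml(path)
  vsets <- lapply(names(raw$value_sets %||% list()), function(id) {
    v <- raw$value_sets[[id]]
    valueSet(id, unlist(v$codes), system = v$system %||% "ICD-10-CM")
  })
  names(vsets) <- names(raw$value_sets %||% list())
  incl <- parseCriterion(raw$case_definition$inclusion)
  excl <- if (!is.null(raw$case_definition$exclusion)) {
    parseCriterion(raw$case_definition$exclusion)
  }
  vars <- lapply(raw$variables %||% list(), function(v) {
    rule <- v
    rule$name <- NULL
    rule$kind <- NULL
    if (!is.null(rule$criterion)) rule$criterion <- parseCriterion(rule$criterion)
    if (!is.null(rule$edges)) rule$edges <- unlist(rule$edges)
    studyVariable(v$name, v$kind, rule)
  })
  studySpec(
    name = raw$name %||% tools::file_path_sans_ext(basename(path)),
    caseDefinition = caseDefinition(incl, excl),
    variables = vars, valueSets = vsets,
    period = unlist(raw$study_period),
    countUnit = raw$count_unit %||% "patients",
    includeComparison = isTRUE(raw$include_comparison)
  )
}

#' The shipped hypertension study specification
#'
#' Vital-sign computable phenotype: an encounter is hypertensive when
#' systolic pressure >= 140 mm Hg or diastolic pressure >= 90 mm Hg (both
#' comparators inclusive, OR-combined). A medication-in-value-set exclusion
#' hook is present but ships with no codes excluded.
#'
#' @param countUnit "patients" or "encounters".
#' @return a [StudySpec-class].
#' @export
hypertensionStudySpec <- function(countUnit = "encounters") {
  readStudySpec(system.file("extdata", "hypertension-study.yaml",
                            package = "CohortCube")) -> sp
  sp@countUnit <- countUnit
  validObject(sp)
  sp
}

#' Flatten de-identified resources into study tables
#'
#' Builds the tabular study views from a de-identified export: patients,
#' encounters, conditions, observations and NLP-derived symptoms
#' (observations carrying the source tag "nlp"). Rows failing minimal-field
#' validation (e.g. an observation without a numeric value) are excluded
#' with a message; dangling references are kept as NA with a warning.
#'
#' @param export a de-identified [BulkExport-class] (raw ids must not be
#'   present; pass output of [applyDeidExport()]).
#' @return a [StudyTableSet-class].
#' @export
flattenResources <- function(export) {
  stopifnot(is(export, "BulkExport"))
  recs <- export@records
  stripRef <- function(x) {
    if (is.null(x) || is.null(x$reference)) NA_character_
    else sub("^[A-Za-z]+/", "", x$reference)
  }

  patients <- rbindlist(lapply(recs$Patient, function(r) {
    list(
      id = r$id, sex = r$gender %||% NA_character_,
      birthYear = as.integer(substr(r$birthDate %||% "", 1, 4))
    )
  }))
  if (nrow(patients) == 0) {
    patients <- data.table(id = character(), sex = character(),
                           birthYear = integer())
  }

  encounters <- rbindlist(lapply(recs$Encounter, function(r) {
    list(
      id = r$id, patient = stripRef(r$subject),
      month = substr(r$period$start %||% "", 1, 7),
      class = r$class$code %||% NA_character_
    )
  }))
  if (nrow(encounters) == 0) {
    encounters <- data.table(id = character(), patient = character(),
                             month = character(), class = character())
  }

  isNlp <- function(r) {
    tags <- r$meta$tag
    any(vapply(tags %||% list(), function(t) identical(t$code, "nlp"), logical(1)))
  }

  condRows <- list()
  for (r in recs$Condition) {
    coding <- r$code$coding[[1]]
    if (is.null(coding$code)) {
      message("flatten: Condition ", r$id, " lacks a code; excluded")
      next
    }
    condRows[[length(condRows) + 1]] <- list(
      encounter = stripRef(r$encounter), patient = stripRef(r$subject),
      system = coding$system %||% NA_character_, code = coding$code
    )
  }
  conditions <- rbindlist(condRows)
  if (nrow(conditions) == 0) {
    conditions <- data.table(encounter = character(), patient = character(),
                             system = character(), code = character())
  }

  obsRows <- list()
  symRows <- list()
  for (r in recs$Observation) {
    coding <- r$code$coding[[1]]
    if (isNlp(r)) {
      symRows[[length(symRows) + 1]] <- list(
        encounter = stripRef(r$encounter), patient = stripRef(r$subject),
        code = coding$code, month = substr(r$effectiveDateTime %||% "", 1, 7),
        source = "nlp"
      )
      next
    }
    v <- r$valueQuantity$value
    if (is.null(v) || !is.numeric(v)) {
      message("flatten: Observation ", r$id, " lacks a numeric value; excluded")
      next
    }
    obsRows[[length(obsRows) + 1]] <- list(
      encounter = stripRef(r$encounter), patient = stripRef(r$subject),
      code = coding$code, value = as.numeric(v),
      unit = r$valueQuantity$unit %||% NA_character_
    )
  }
  observations <- rbindlist(obsRows)
  if (nrow(observations) == 0) {
    observations <- data.table(encounter = character(), patient = character(),
                               code = character(), value = numeric(),
                               unit = character())
  }
  symptoms <- rbindlist(symRows)
  if (nrow(symptoms) == 0) {
    symptoms <- data.table(encounter = character(), patient = character(),
                           code = character(), month = character(),
                           source = character())
  }

  dangling <- setdiff(encounters$patient, c(patients$id, NA_character_))
  if (length(dangling) > 0) {
    warning(length(dangling), " encounter(s) reference unknown patients; kept with NA")
    encounters[encounters$patient %in% dangling, "patient"] <- NA_character_
  }

  new("StudyTableSet",
      patients = as.data.frame(patients), encounters = as.data.frame(encounters),
      conditions = as.data.frame(conditions),
      observations = as.data.frame(observations),
      symptoms = as.data.frame(symptoms))
}

## evaluate a criterion tree -> character vector of qualifying encounter ids
## (restricted to in-period encounters)
evalCriterion <- function(cr, tables, spec, periodEnc) {
  if (cr$type == "any") {
    ids <- lapply(cr$criteria, evalCriterion, tables = tables, spec = spec,
                  periodEnc = periodEnc)
    return(unique(unlist(ids)))
  }
  if (cr$type == "all") {
    ids <- lapply(cr$criteria, evalCriterion, tables = tables, spec = spec,
                  periodEnc = periodEnc)
    return(Reduce(intersect, ids))
  }
  if (cr$type == "code") {
    vs <- spec@valueSets[[cr$valueset]]
    if (is.null(vs)) {
      stop("value set '", cr$valueset, "' referenced but not loaded")
    }
    tab <- switch(cr$table,
      condition = tables@conditions,
      symptom = tables@symptoms,
      medication = stop("medication table not available in this table set")
    )
    hit <- tab$encounter[tab$code %in% vs@codes]
    return(intersect(unique(hit), periodEnc))
  }
  if (cr$type == "threshold") {
    ob <- tables@observations
    cmpFun <- match.fun(cr$cmp)
    hit <- ob$encounter[ob$code == cr$code & cmpFun(ob$value, cr$value)]
    return(intersect(unique(hit), periodEnc))
  }
  stop("unknown criterion type: ", cr$type)
}

#' Evaluate the case definition over study tables
#'
#' A unit (patient or encounter, per the spec's `countUnit`) is a case iff
#' the inclusion criterion holds and the exclusion criterion does not,
#' using only events at encounters inside the study period. For
#' `countUnit = "patients"` a patient is a case if any in-period encounter
#' qualifies. Non-case units are retained only when the spec requests a
#' comparison cohort; otherwise they are dropped.
#'
#' @param tables a [StudyTableSet-class].
#' @param spec a [StudySpec-class].
#' @return data.frame cohort: `unit` (id), `case` (logical).
#' @export
evaluateCase <- function(tables, spec) {
  stopifnot(is(tables, "StudyTableSet"), is(spec, "StudySpec"))
  validObject(spec)
  enc <- tables@encounters
  inPeriod <- !is.na(enc$month) & enc$month >= spec@period[1] &
    enc$month <= spec@period[2]
  periodEnc <- enc$id[inPeriod]
  inclEnc <- evalCriterion(spec@caseDefinition@inclusion, tables, spec, periodEnc)
  exclEnc <- if (length(spec@caseDefinition@exclusion) > 0) {
    evalCriterion(spec@caseDefinition@exclusion, tables, spec, periodEnc)
  } else {
    character()
  }
  if (spec@countUnit == "encounters") {
    unit <- periodEnc
    case <- unit %in% inclEnc & !(unit %in% exclEnc)
  } else {
    unit <- unique(enc$patient[inPeriod])
    unit <- unit[!is.na(unit)]
    inclPat <- unique(enc$patient[match(inclEnc, enc$id)])
    exclPat <- unique(enc$patient[match(exclEnc, enc$id)])
    case <- unit %in% inclPat & !(unit %in% exclPat)
  }
  cohort <- data.frame(unit = unit, case = case, stringsAsFactors = FALSE)
  if (!spec@includeComparison) cohort <- cohort[cohort$case, , drop = FALSE]
  rownames(cohort) <- NULL
  cohort
}

binLabel <- function(x, edges) {
  lab <- paste0(edges[-length(edges)], "-", edges[-1] - 1)
  i <- findInterval(x, edges, rightmost.closed = FALSE)
  out <- ifelse(i >= 1 & i < length(edges), lab[pmax(i, 1)], "unknown")
  out[is.na(x)] <- "unknown"
  out
}

#' Derive study variables onto the cohort
#'
#' Adds one column per study variable: booleans as "TRUE"/"FALSE",
#' binned integers as labelled intervals ("5-11"), months as "YYYY-MM".
#' For patient-level cohorts, the reference encounter is the first
#' in-period encounter (month order); criterion-derived booleans are true
#' iff any in-period encounter qualifies.
#'
#' @param cohort output of [evaluateCase()].
#' @param tables a [StudyTableSet-class].
#' @param spec a [StudySpec-class].
#' @return labelled cohort data.frame: unit, case, one column per variable
#'   (all character).
#' @export
deriveVariables <- function(cohort, tables, spec) {
  enc <- tables@encounters
  pat <- tables@patients
  inPeriod <- !is.na(enc$month) & enc$month >= spec@period[1] &
    enc$month <= spec@period[2]
  periodEnc <- enc$id[inPeriod]
  encRows <- enc[inPeriod, , drop = FALSE]

  if (spec@countUnit == "encounters") {
    refEnc <- encRows[match(cohort$unit, encRows$id), , drop = FALSE]
    unitPatient <- refEnc$patient
  } else {
    # reference encounter = first in-period encounter by month
    ord <- encRows[order(encRows$month, encRows$id), , drop = FALSE]
    refEnc <- ord[match(cohort$unit, ord$patient), , drop = FALSE]
    unitPatient <- cohort$unit
  }
  refMonth <- refEnc$month
  birthYear <- pat$birthYear[match(unitPatient, pat$id)]

  unitHasEnc <- function(encIds) {
    if (spec@countUnit == "encounters") {
      cohort$unit %in% encIds
    } else {
      hitPat <- unique(encRows$patient[encRows$id %in% encIds])
      cohort$unit %in% hitPat
    }
  }

  out <- cohort
  for (v in spec@variables) {
    src <- v@rule$source
    col <- switch(src,
      case = as.character(out$case),
      criterion = {
        ids <- evalCriterion(v@rule$criterion, tables, spec, periodEnc)
        as.character(unitHasEnc(ids))
      },
      sex = {
        s <- pat$sex[match(unitPatient, pat$id)]
        ifelse(is.na(s), "unknown", s)
      },
      age = {
        age <- as.integer(substr(refMonth, 1, 4)) - birthYear
        binLabel(age, v@rule$edges)
      },
      month = ifelse(is.na(refMonth), "unknown", refMonth),
      stop("unknown variable source '", src, "' for variable ", v@name)
    )
    if (anyNA(col)) col[is.na(col)] <- "unknown"
    if (any(!nzchar(col))) col[!nzchar(col)] <- "unknown"
    out[[v@name]] <- col
  }
  out
}
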
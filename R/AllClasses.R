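#' @import methods
#' @importFrom data.table as.data.table data.table rbindlist setorderv setnames :=
#' @importFrom stats rbinom rnorm rpois runif qnorm pchisq setNames
#' @importFrom utils read.csv write.csv
NULL

## Resource records are kept as parsed JSON (nested named lists), the lingua
## franca of FHIR tooling; the S4 layer starts at the container level.

#' Bulk-FHIR export for one site
#'
#' Holds the parsed NDJSON resources of a single site's bulk export, grouped
#' by resource type, together with the site label. Resources themselves are
#' nested named lists mirroring the FHIR JSON.
#'
#' @slot records named list; one element per resource type, each a list of
#'   parsed resources.
#' @slot site character(1) site label.
#' @slot exportTime character(1) ISO timestamp of export assembly.
#' @export
setClass("BulkExport",
  representation(records = "list", site = "character", exportTime = "character"),
  prototype(records = list(), site = "site", exportTime = "")
)

setValidity("BulkExport", function(object) {
  bad <- setdiff(names(object@records), fhirResourceTypes())
  if (length(bad) > 0) {
    return(paste("unknown resource types:", paste(bad, collapse = ", ")))
  }
  for (ty in names(object@records)) {
    for (r in object@records[[ty]]) {
      if (!identical(r$resourceType, ty)) {
        return(sprintf("record under '%s' declares resourceType '%s'", ty, r$resourceType))
      }
    }
  }
  TRUE
})

#' Keyed pseudonymization codebook
#'
#' Deterministic keyed mapping from identifiers to pseudonyms (HMAC-SHA256
#' rendered in a lowercase alphabet). No identifier-to-pseudonym table is
#' stored; the cache environment exists only to detect hash collisions.
#'
#' @slot secret character(1) high-entropy key; never serialized by [show()].
#' @slot algorithm character(1) label of the keyed construction.
#' @slot cache environment mapping issued pseudonyms back to their inputs,
#'   used solely for collision detection.
#' @export
setClass("Codebook",
  representation(secret = "character", algorithm = "character", cache = "environment")
)

setValidity("Codebook", function(object) {
  if (length(object@secret) != 1 || !nzchar(object@secret)) {
    return("codebook secret must be a non-empty string")
  }
  if (nchar(object@secret) < 16) {
    return("codebook secret must have at least 16 characters")
  }
  TRUE
})

#' De-identification rule set
#'
#' Allow-list field rules per resource type. Every field not named by a rule
#' is dropped (fail-safe default); named fields carry one action of
#' `keep`, `drop`, `generalize_date_to_month`, or `pseudonymize`.
#'
#' @slot rules named list; per resource type, a named character vector
#'   mapping a dot-separated field path to its action.
#' @export
setClass("DeidRules", representation(rules = "list"))

setValidity("DeidRules", function(object) {
  ok <- c("keep", "drop", "generalize_date_to_month", "pseudonymize")
  for (ty in names(object@rules)) {
    acts <- object@rules[[ty]]
    if (is.null(names(acts)) || any(!nzchar(names(acts)))) {
      return(sprintf("rules for %s must be a named vector of field paths", ty))
    }
    if (!all(acts %in% ok)) {
      return(sprintf("unknown action(s) for %s: %s", ty,
                     paste(setdiff(acts, ok), collapse = ", ")))
    }
  }
  TRUE
})

#' Symptom dictionary for note-text matching
#'
#' Concept entries with their textual surface forms. Matching is
#' case-insensitive at word boundaries; surface forms are stored lowercase
#' and must be unique across concepts.
#'
#' @slot entries data.frame with columns `code` (concept code), `label`
#'   (preferred label) and `form` (one surface form per row, lowercase).
#' @slot system character(1) code-system label for the concept codes.
#' @export
setClass("SymptomDictionary",
  representation(entries = "data.frame", system = "character"),
  prototype(system = "ICD-10-CM")
)

setValidity("SymptomDictionary", function(object) {
  e <- object@entries
  if (!all(c("code", "label", "form") %in% names(e))) {
    return("entries needs columns code, label, form")
  }
  if (nrow(e) == 0) return("dictionary has no entries")
  if (any(!nzchar(e$form))) return("empty surface form")
  if (any(e$form != tolower(e$form))) return("surface forms must be lowercase")
  if (anyDuplicated(e$form)) {
    return(paste("surface forms duplicated across concepts:",
                 paste(unique(e$form[duplicated(e$form)]), collapse = ", ")))
  }
  TRUE
})

#' Terminology value set
#'
#' A named collection of codes (VSAC style) used by case definitions and
#' study variables.
#'
#' @slot id character(1) value-set identifier.
#' @slot system character(1) code-system label (e.g. "ICD-10-CM").
#' @slot codes character vector of unique codes.
#' @export
setClass("ValueSet",
  representation(id = "character", system = "character", codes = "character")
)

setValidity("ValueSet", function(object) {
  if (length(object@codes) == 0) return("value set has no codes")
  if (anyDuplicated(object@codes)) return("value set codes must be unique")
  TRUE
})

#' Computable case definition
#'
#' Inclusion and exclusion criteria, each a boolean combination tree over
#' primitives: `codeCriterion()` (code-in-value-set over the condition,
#' symptom or medication table), `thresholdCriterion()` (numeric comparison
#' over the observation table), combined with `anyOf()` / `allOf()`.
#' Exclusion is evaluated after inclusion.
#'
#' @slot inclusion list; a criterion tree (required).
#' @slot exclusion list; a criterion tree or empty list (no exclusion).
#' @export
setClass("CaseDefinition", representation(inclusion = "list", exclusion = "list"))

setValidity("CaseDefinition", function(object) {
  if (length(object@inclusion) == 0) return("at least one inclusion criterion required")
  chk <- function(cr) {
    if (is.null(cr$type)) return("criterion missing type")
    if (cr$type %in% c("any", "all")) {
      if (length(cr$criteria) == 0) return(sprintf("%sOf() with no criteria", cr$type))
      for (sub in cr$criteria) {
        m <- chk(sub)
        if (!isTRUE(m)) return(m)
      }
      return(TRUE)
    }
    if (cr$type == "code") {
      if (!cr$table %in% c("condition", "symptom", "medication")) {
        return(sprintf("code criterion over unknown table '%s'", cr$table))
      }
      if (is.null(cr$valueset)) return("code criterion missing valueset id")
      return(TRUE)
    }
    if (cr$type == "threshold") {
      if (!cr$cmp %in% c(">=", ">", "<=", "<", "==")) {
        return(sprintf("unknown comparator '%s'", cr$cmp))
      }
      return(TRUE)
    }
    sprintf("unknown criterion type '%s'", cr$type)
  }
  chk(object@inclusion)
})

#' Study variable
#'
#' A discrete element of the aggregate matrix: boolean, categorical, binned
#' integer or month, derived per cohort unit from the study tables.
#'
#' @slot name character(1) variable name (unique within a spec).
#' @slot kind character(1) one of "boolean", "categorical", "binned", "month".
#' @slot rule list; derivation rule. Supported sources: `case` (the case
#'   flag), `criterion` (a criterion tree evaluated per unit), `sex`
#'   (patient sex), `age` (age at encounter, with `edges` for binning),
#'   `month` (encounter month).
#' @export
setClass("StudyVariable",
  representation(name = "character", kind = "character", rule = "list")
)

setValidity("StudyVariable", function(object) {
  if (!object@kind %in% c("boolean", "categorical", "binned", "month")) {
    return(sprintf("unknown kind '%s'", object@kind))
  }
  if (is.null(object@rule$source)) return("rule missing source")
  if (identical(object@rule$source, "age")) {
    e <- object@rule$edges
    if (is.null(e) || length(e) < 2 || any(diff(e) <= 0)) {
      return("age rule needs strictly increasing bin edges")
    }
  }
  TRUE
})

#' Study specification
#'
#' Case definition, ordered study variables (the set the power-set matrix is
#' computed over), study period and counting unit.
#'
#' @slot name character(1) study label.
#' @slot caseDefinition a [CaseDefinition-class] object.
#' @slot variables list of [StudyVariable-class] objects, order significant.
#' @slot valueSets named list of [ValueSet-class] objects referenced by the
#'   criteria and variables.
#' @slot period character(2) study period as c(start, end), "YYYY-MM",
#'   inclusive.
#' @slot countUnit character(1) "patients" or "encounters".
#' @slot includeComparison logical(1); retain non-case units as a comparison
#'   cohort (all in-period non-cases) instead of dropping them.
#' @export
setClass("StudySpec",
  representation(
    name = "character", caseDefinition = "CaseDefinition",
    variables = "list", valueSets = "list", period = "character",
    countUnit = "character", includeComparison = "logical"
  )
)

setValidity("StudySpec", function(object) {
  if (length(object@period) != 2 || any(!grepl("^\\d{4}-\\d{2}$", object@period))) {
    return("period must be c(start, end) in YYYY-MM form")
  }
  if (object@period[1] > object@period[2]) return("period start after end")
  if (!object@countUnit %in% c("patients", "encounters")) {
    return("countUnit must be 'patients' or 'encounters'")
  }
  nm <- vapply(object@variables, function(v) v@name, character(1))
  if (anyDuplicated(nm)) return("variable names must be unique")
  TRUE
})

#' Tabular study tables
#'
#' Flattened, de-identified representations of the FHIR resources consumed
#' by phenotype evaluation: patients, encounters, conditions, observations
#' and NLP-derived symptoms.
#'
#' @slot patients data.frame: id, sex, birthYear.
#' @slot encounters data.frame: id, patient, month, class.
#' @slot conditions data.frame: encounter, patient, system, code.
#' @slot observations data.frame: encounter, patient, code, value, unit.
#' @slot symptoms data.frame: encounter, patient, code, month, source.
#' @export
setClass("StudyTableSet",
  representation(
    patients = "data.frame", encounters = "data.frame",
    conditions = "data.frame", observations = "data.frame",
    symptoms = "data.frame"
  )
)

setValidity("StudyTableSet", function(object) {
  need <- list(
    patients = c("id", "sex", "birthYear"),
    encounters = c("id", "patient", "month", "class"),
    conditions = c("encounter", "patient", "system", "code"),
    observations = c("encounter", "patient", "code", "value", "unit"),
    symptoms = c("encounter", "patient", "code", "month", "source")
  )
  for (nm in names(need)) {
    if (!all(need[[nm]] %in% names(slot(object, nm)))) {
      return(sprintf("table '%s' lacks columns %s", nm,
                     paste(setdiff(need[[nm]], names(slot(object, nm))), collapse = ", ")))
    }
  }
  TRUE
})

#' Aggregate count matrix over the power set of study variables
#'
#' Sparse counts for every observed level combination of every subset of the
#' study variables, including the null-set row (no variable fixed) whose
#' count is the total cohort size. An empty cell in a variable column means
#' "variable not in this subset" and is stored as `NA`, distinct from any
#' explicit level.
#'
#' @slot variables character vector of variable names, order significant.
#' @slot counts data.frame with one character column per variable (NA =
#'   variable not in the row's subset) plus integer column `cnt`.
#' @slot metadata list: `sites` (character), `period` (character(2)),
#'   `threshold` (suppression threshold applied, NA if unsuppressed),
#'   `compiled` (timestamp), `variableDescriptions` (named character),
#'   `countUnit`.
#' @export
setClass("AggregateMatrix",
  representation(variables = "character", counts = "data.frame", metadata = "list")
)

setValidity("AggregateMatrix", function(object) {
  cn <- names(object@counts)
  if (!identical(cn, c(object@variables, "cnt"))) {
    return("counts columns must be the variables followed by 'cnt'")
  }
  if (nrow(object@counts) > 0) {
    if (any(object@counts$cnt < 0)) return("negative count")
    nv <- length(object@variables)
    if (nv > 0) {
      nullRows <- rowSums(!is.na(object@counts[, object@variables, drop = FALSE])) == 0
    } else {
      nullRows <- rep(TRUE, nrow(object@counts))
    }
    if (sum(nullRows) > 1) return("more than one null-set row")
    thr <- object@metadata$threshold
    if (!is.null(thr) && !is.na(thr) && any(object@counts$cnt < thr)) {
      return("counts below recorded suppression threshold")
    }
    if (sum(nullRows) == 1 && any(object@counts$cnt > object@counts$cnt[nullRows])) {
      return("a cell exceeds the null-set (total) count")
    }
  }
  TRUE
})

#' 2x2 contingency table extracted from an aggregate matrix
#'
#' Exposure-by-outcome cell counts with `a` the joint (exposed, outcome)
#' cell, `b` exposed without outcome, `c` outcome without exposure, `d`
#' neither.
#'
#' @slot a,b,c,d numeric(1) non-negative cell counts.
#' @slot exposure character(2) c(variable, level).
#' @slot outcome character(2) c(variable, level).
#' @export
setClass("CrossTab",
  representation(
    a = "numeric", b = "numeric", c = "numeric", d = "numeric",
    exposure = "character", outcome = "character"
  )
)

setValidity("CrossTab", function(object) {
  if (any(c(object@a, object@b, object@c, object@d) < 0)) {
    return("negative cell count")
  }
  TRUE
})

#' Synthetic population configuration
#'
#' Ground-truth parameters of the multi-site synthetic bulk-FHIR generator.
#' All probabilities in [0, 1]; a fixed seed yields byte-identical exports.
#'
#' @slot nPatients integer(1) total patients across sites.
#' @slot nSites integer(1) number of sites.
#' @slot studyWindow character(2) c(start, end), "YYYY-MM", inclusive;
#'   encounter months are drawn uniformly over this window.
#' @slot diseasePrevalence numeric(1) probability of the index disease.
#' @slot symptomProfile data.frame: code, label, pDisease (symptom
#'   probability given disease), pHealthy (given no disease).
#' @slot icdCodingSensitivity numeric(1) probability a truly present symptom
#'   receives an ICD-10 Condition code at an encounter.
#' @slot noteMentionSensitivity numeric(1) probability a truly present
#'   symptom is affirmed in the encounter note.
#' @slot negatedMentionRate numeric(1) probability an absent symptom is
#'   mentioned with a negation cue.
#' @slot diseaseCodingSensitivity numeric(1) probability a diseased patient
#'   receives the disease ICD-10 code at each encounter.
#' @slot hypertensionPrevalence numeric(1) probability of the hypertensive
#'   vital-sign stratum.
#' @slot vitalsModel list with elements `hypertensive` and `normal`, each
#'   list(sysMean, sysSd, diaMean, diaSd) in mm Hg.
#' @slot meanExtraEncounters numeric(1) Poisson mean of encounters beyond
#'   the guaranteed first.
#' @slot seed integer(1) RNG seed.
#' @export
setClass("SyntheticConfig",
  representation(
    nPatients = "integer", nSites = "integer", studyWindow = "character",
    diseasePrevalence = "numeric", symptomProfile = "data.frame",
    icdCodingSensitivity = "numeric", noteMentionSensitivity = "numeric",
    negatedMentionRate = "numeric", diseaseCodingSensitivity = "numeric",
    hypertensionPrevalence = "numeric", vitalsModel = "list",
    meanExtraEncounters = "numeric", seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  probs <- c(
    object@diseasePrevalence, object@icdCodingSensitivity,
    object@noteMentionSensitivity, object@negatedMentionRate,
    object@diseaseCodingSensitivity, object@hypertensionPrevalence,
    object@symptomProfile$pDisease, object@symptomProfile$pHealthy
  )
  if (any(probs < 0 | probs > 1)) return("all probabilities must lie in [0, 1]")
  if (object@nPatients < 1) return("nPatients must be positive")
  if (object@nSites < 1) return("nSites must be positive")
  if (object@nSites > object@nPatients) return("more sites than patients")
  if (length(object@studyWindow) != 2 ||
      any(!grepl("^\\d{4}-\\d{2}$", object@studyWindow))) {
    return("studyWindow must be c(start, end) in YYYY-MM form")
  }
  if (!all(c("code", "label", "pDisease", "pHealthy") %in% names(object@symptomProfile))) {
    return("symptomProfile needs columns code, label, pDisease, pHealthy")
  }
  TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "BulkExport", function(object) {
  cat(sprintf("BulkExport site '%s'\n", object@site))
  for (ty in names(object@records)) {
    cat(sprintf("  %-20s %d\n", ty, length(object@records[[ty]])))
  }
})

setMethod("show", "Codebook", function(object) {
  issued <- if (!is.null(object@cache$rev)) length(ls(object@cache$rev)) else 0L
  cat(sprintf("Codebook <%s> (secret withheld), %d pseudonyms issued\n",
              object@algorithm, issued))
})

setMethod("show", "SymptomDictionary", function(object) {
  cat(sprintf("SymptomDictionary [%s]: %d concepts, %d surface forms\n",
              object@system, length(unique(object@entries$code)),
              nrow(object@entries)))
})

setMethod("show", "StudySpec", function(object) {
  cat(sprintf("StudySpec '%s': %s, period %s..%s, %d variable(s)%s\n",
              object@name, object@countUnit, object@period[1], object@period[2],
              length(object@variables),
              if (object@includeComparison) " (+comparison cohort)" else ""))
})

setMethod("show", "StudyTableSet", function(object) {
  cat("StudyTableSet\n")
  for (nm in c("patients", "encounters", "conditions", "observations", "symptoms")) {
    cat(sprintf("  %-13s %d rows\n", nm, nrow(slot(object, nm))))
  }
})

setMethod("show", "AggregateMatrix", function(object) {
  thr <- object@metadata$threshold
  cat(sprintf(
    "AggregateMatrix: %d variable(s) [%s], %d cells, %s\n",
    length(object@variables), paste(object@variables, collapse = ", "),
    nrow(object@counts),
    if (is.null(thr) || is.na(thr)) "unsuppressed"
    else sprintf("suppressed at %d", thr)
  ))
  if (length(object@metadata$sites) > 0) {
    cat(sprintf("  sites: %s\n", paste(object@metadata$sites, collapse = ", ")))
  }
})

setMethod("show", "CrossTab", function(object) {
  cat(sprintf("CrossTab %s=%s x %s=%s\n", object@exposure[1], object@exposure[2],
              object@outcome[1], object@outcome[2]))
  print(matrix(c(object@a, object@b, object@c, object@d), 2, 2, byrow = TRUE,
               dimnames = list(
                 exposure = c("yes", "no"),
                 outcome = c("yes", "no")
               )))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d patients / %d sites, window %s..%s, prevalence %.2f, seed %d\n",
    object@nPatients, object@nSites, object@studyWindow[1], object@studyWindow[2],
    object@diseasePrevalence, object@seed
  ))
})
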
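## Shipped study specifications beyond the hypertension YAML: programmatic
## builders for the respiratory-disease surveillance studies the synthetic
## network is generated for.

#' Disease-surveillance study specifications
#'
#' `diseasePrevalenceStudySpec()` selects every in-period patient, keeps
#' the non-cases as a comparison cohort and labels rows with the disease
#' case flag (ICD-coded index disease) plus one NLP-derived symptom flag —
#' the spec used for prevalence and crosstab measures over the merged
#' network matrix. `symptomTrendStudySpec()` selects disease-positive
#' encounters and labels each with encounter month plus NLP- and ICD-derived
#' flags for the chosen symptoms — the spec behind the NLP-vs-ICD monthly
#' trend comparison.
#'
#' @param period study period c(start, end), "YYYY-MM".
#' @param symptom named character(1): flag name -> symptom concept code.
#' @param diseaseCode ICD-10 code of the index disease.
#' @return a [StudySpec-class].
#' @export
diseasePrevalenceStudySpec <- function(period = c("2021-01", "2021-12"),
                                       symptom = c(fever = "R50.9"),
                                       diseaseCode = "U07.1") {
  symName <- names(symptom)
  vsets <- list(disease = valueSet("disease", diseaseCode))
  vsets[[symName]] <- valueSet(symName, unname(symptom))
  studySpec(
    name = "disease-prevalence",
    caseDefinition = caseDefinition(codeCriterion("condition", "disease")),
    variables = list(
      studyVariable("disease", "boolean", list(source = "case")),
      studyVariable(paste0(symName, "_nlp"), "boolean", list(
        source = "criterion",
        criterion = codeCriterion("symptom", symName)
      ))
    ),
    valueSets = vsets,
    period = period, countUnit = "patients", includeComparison = TRUE
  )
}

#' @rdname diseasePrevalenceStudySpec
#' @param symptoms named character vector: flag base name -> concept code;
#'   each yields `<name>_nlp` and `<name>_icd` boolean variables.
#' @export
symptomTrendStudySpec <- function(period = c("2021-01", "2021-12"),
                                  symptoms = c(fever = "R50.9", cough = "R05"),
                                  diseaseCode = "U07.1") {
  vsets <- list(disease = valueSet("disease", diseaseCode))
  vars <- list(studyVariable("month", "month", list(source = "month")))
  for (nm in names(symptoms)) {
    vsets[[nm]] <- valueSet(nm, unname(symptoms[[nm]]))
    vars[[length(vars) + 1]] <- studyVariable(
      paste0(nm, "_nlp"), "boolean",
      list(source = "criterion", criterion = codeCriterion("symptom", nm))
    )
    vars[[length(vars) + 1]] <- studyVariable(
      paste0(nm, "_icd"), "boolean",
      list(source = "criterion", criterion = codeCriterion("condition", nm))
    )
  }
  studySpec(
    name = "symptom-trend",
    caseDefinition = caseDefinition(codeCriterion("condition", "disease")),
    variables = vars, valueSets = vsets,
    period = period, countUnit = "encounters", includeComparison = FALSE
  )
}
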
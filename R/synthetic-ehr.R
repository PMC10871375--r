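## Seeded multi-site synthetic bulk-FHIR generator. Emulates the inputs the
## pipeline would pull from real EHRs — patients, encounters, ICD-coded
## conditions, blood-pressure observations, clinical notes with affirmed and
## negated symptom mentions — with known ground truth so every downstream
## stage has an oracle. Deliberately not a care-pathway simulator.

#' Default symptom prevalence profile
#'
#' Per-symptom probabilities conditional on disease status for the five
#' shipped symptom concepts.
#'
#' @return data.frame: code, label, pDisease, pHealthy.
#' @export
defaultSymptomProfile <- function() {
  data.frame(
    code = c("R50.9", "R68.83", "R05", "R06.0", "R51"),
    label = c("fever", "chills", "cough", "dyspnea", "headache"),
    pDisease = c(0.60, 0.40, 0.70, 0.30, 0.35),
    pHealthy = c(0.05, 0.03, 0.10, 0.04, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Create a synthetic population configuration
#'
#' Defaults encode the study conditions the package is exercised under: a
#' five-site network, disease prevalence 0.3, note-mention sensitivity 0.9
#' exceeding ICD coding sensitivity 0.5 (so text-derived detection
#' outperforms coded detection by construction), a 12-month study window,
#' and blood-pressure strata centred above/below the 140/90 mm Hg critical
#' values.
#'
#' @param nPatients total patients across all sites.
#' @param nSites number of sites.
#' @param studyWindow c(start, end) months "YYYY-MM".
#' @param diseasePrevalence probability of the index disease.
#' @param symptomProfile data.frame as [defaultSymptomProfile()].
#' @param icdCodingSensitivity P(ICD code | symptom present) per encounter.
#' @param noteMentionSensitivity P(affirmed note mention | symptom present)
#'   per encounter.
#' @param negatedMentionRate P(negated mention | symptom absent) per
#'   encounter.
#' @param diseaseCodingSensitivity P(disease ICD code | diseased) per
#'   encounter.
#' @param hypertensionPrevalence probability of the hypertensive stratum.
#' @param vitalsModel per-stratum mm Hg means/sds, see
#'   [SyntheticConfig-class].
#' @param meanExtraEncounters Poisson mean of encounters beyond the first.
#' @param seed RNG seed.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nPatients = 1000L,
                            nSites = 5L,
                            studyWindow = c("2021-01", "2021-12"),
                            diseasePrevalence = 0.3,
                            symptomProfile = defaultSymptomProfile(),
                            icdCodingSensitivity = 0.5,
                            noteMentionSensitivity = 0.9,
                            negatedMentionRate = 0.2,
                            diseaseCodingSensitivity = 1.0,
                            hypertensionPrevalence = 0.25,
                            vitalsModel = list(
                              hypertensive = list(sysMean = 150, sysSd = 10,
                                                  diaMean = 95, diaSd = 8),
                              normal = list(sysMean = 118, sysSd = 8,
                                            diaMean = 75, diaSd = 6)
                            ),
                            meanExtraEncounters = 0.3,
                            seed = 20210101L) {
  new("SyntheticConfig",
      nPatients = as.integer(nPatients), nSites = as.integer(nSites),
      studyWindow = studyWindow, diseasePrevalence = diseasePrevalence,
      symptomProfile = symptomProfile,
      icdCodingSensitivity = icdCodingSensitivity,
      noteMentionSensitivity = noteMentionSensitivity,
      negatedMentionRate = negatedMentionRate,
      diseaseCodingSensitivity = diseaseCodingSensitivity,
      hypertensionPrevalence = hypertensionPrevalence,
      vitalsModel = vitalsModel,
      meanExtraEncounters = meanExtraEncounters,
      seed = as.integer(seed))
}

#' Read a synthetic configuration from YAML
#' @param path YAML file whose keys mirror the [syntheticConfig()] arguments
#'   (snake_case accepted).
#' @return a [SyntheticConfig-class].
#' @export
readSyntheticConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  pick <- function(...) {
    for (k in c(...)) if (!is.null(raw[[k]])) return(raw[[k]])
    NULL
  }
  args <- list()
  grab <- function(arg, ...) {
    v <- pick(...)
    if (!is.null(v)) args[[arg]] <<- v
  }
  grab("nPatients", "nPatients", "n_patients")
  grab("nSites", "nSites", "n_sites")
  grab("studyWindow", "studyWindow", "study_window")
  grab("diseasePrevalence", "diseasePrevalence", "disease_prevalence")
  grab("icdCodingSensitivity", "icdCodingSensitivity", "icd_coding_sensitivity")
  grab("noteMentionSensitivity", "noteMentionSensitivity", "note_mention_sensitivity")
  grab("negatedMentionRate", "negatedMentionRate", "negated_mention_rate")
  grab("diseaseCodingSensitivity", "diseaseCodingSensitivity", "disease_coding_sensitivity")
  grab("hypertensionPrevalence", "hypertensionPrevalence", "hypertension_prevalence")
  grab("meanExtraEncounters", "meanExtraEncounters", "mean_extra_encounters")
  grab("seed", "seed")
  if (!is.null(raw$studyWindow) || !is.null(raw$study_window)) {
    args$studyWindow <- unlist(args$studyWindow)
  }
  sp <- pick("symptomProfile", "symptom_profile")
  if (!is.null(sp)) {
    args$symptomProfile <- do.call(rbind, lapply(sp, function(x) {
      data.frame(code = x$code, label = x$label,
                 pDisease = x$pDisease %||% x$p_disease,
                 pHealthy = x$pHealthy %||% x$p_healthy,
                 stringsAsFactors = FALSE)
    }))
  }
  vm <- pick("vitalsModel", "vitals_model")
  if (!is.null(vm)) args$vitalsModel <- vm
  do.call(syntheticConfig, args)
}

monthSeq <- function(start, end) {
  format(seq(as.Date(paste0(start, "-01")), as.Date(paste0(end, "-01")),
             by = "month"), "%Y-%m")
}

firstNamePool <- c("Grace", "Henry", "Isabel", "Jasper", "Karen", "Leo",
                   "Miriam", "Noah", "Olive", "Peter", "Quinn", "Rosa",
                   "Samuel", "Teresa", "Ursula", "Victor", "Wanda", "Xavier",
                   "Yvonne", "Zachary")
lastNamePool <- c("Whitfield", "Okafor", "Marchetti", "Lindqvist", "Barros",
                  "Castellano", "Duvall", "Eriksen", "Fontaine", "Grimaldi",
                  "Herrera", "Ivanova", "Jankowski", "Kowalczyk", "Laurent",
                  "Moreau", "Nakamura", "Oliveira", "Petrov", "Quintana")
streetPool <- c("Maple Avenue", "Oakwood Drive", "Birchwood Lane",
                "Chestnut Boulevard", "Willow Court", "Juniper Road",
                "Sycamore Terrace", "Magnolia Street")
cityPool <- c("Springfield", "Riverton", "Lakewood", "Fairview",
              "Greenville", "Brookside")

affirmTemplates <- c("Patient reports %s.", "Presents with %s.",
                     "%s noted on exam.", "Complains of %s today.")
negateTemplates <- c("Patient denies %s.", "No %s.", "Negative for %s.",
                     "Patient presents without %s.")

capFirst <- function(x) paste0(toupper(substr(x, 1, 1)), substring(x, 2))

#' Generate a seeded multi-site synthetic population
#'
#' Draws patients, encounters, ICD-coded conditions, blood-pressure
#' observations and clinical notes from the configured ground-truth model
#' and returns one [BulkExport-class] per site plus the ground truth. The
#' same configuration (including seed) yields byte-identical NDJSON when
#' written.
#'
#' @param config a [SyntheticConfig-class].
#' @param dict symptom dictionary supplying the surface forms used in note
#'   templates; defaults to the shipped dictionary and must cover the codes
#'   in the config's symptom profile.
#' @return list with elements `exports` (list of [BulkExport-class], one per
#'   site) and `groundTruth` (list of data.frames `patients`, `encounters`).
#' @export
generatePopulation <- function(config, dict = defaultSymptomDictionary()) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  sp <- config@symptomProfile
  if (!all(sp$code %in% dict@entries$code)) {
    stop("symptom profile codes missing from dictionary: ",
         paste(setdiff(sp$code, dict@entries$code), collapse = ", "))
  }
  formsByCode <- split(dict@entries$form, dict@entries$code)

  set.seed(config@seed)
  nPat <- config@nPatients
  nSym <- nrow(sp)
  months <- monthSeq(config@studyWindow[1], config@studyWindow[2])
  sites <- sprintf("site%02d", seq_len(config@nSites))
  windowYear <- as.integer(substr(config@studyWindow[1], 1, 4))

  ## ---- patient-level draws (vectorized) -------------------------------
  patId <- sprintf("pt%06d", seq_len(nPat))
  patSite <- sites[((seq_len(nPat) - 1L) %% config@nSites) + 1L]
  given <- sample(firstNamePool, nPat, replace = TRUE)
  family <- sample(lastNamePool, nPat, replace = TRUE)
  gender <- sample(c("female", "male"), nPat, replace = TRUE)
  age <- sample(0:89, nPat, replace = TRUE)
  birthYear <- windowYear - age
  birthDate <- sprintf("%04d-%02d-%02d", birthYear,
                       sample(1:12, nPat, replace = TRUE),
                       sample(1:28, nPat, replace = TRUE))
  street <- sprintf("%d %s", sample(1:999, nPat, replace = TRUE),
                    sample(streetPool, nPat, replace = TRUE))
  city <- sample(cityPool, nPat, replace = TRUE)
  phone <- sprintf("555-%04d-%03d", sample(0:9999, nPat, replace = TRUE),
                   sample(0:999, nPat, replace = TRUE))
  disease <- rbinom(nPat, 1, config@diseasePrevalence) == 1
  hypertensive <- rbinom(nPat, 1, config@hypertensionPrevalence) == 1
  trueSym <- matrix(FALSE, nPat, nSym, dimnames = list(NULL, sp$code))
  for (j in seq_len(nSym)) {
    p <- ifelse(disease, sp$pDisease[j], sp$pHealthy[j])
    trueSym[, j] <- rbinom(nPat, 1, p) == 1
  }
  nEnc <- 1L + rpois(nPat, config@meanExtraEncounters)

  ## ---- encounter-level draws ------------------------------------------
  encPat <- rep(seq_len(nPat), nEnc)
  nE <- length(encPat)
  encId <- sprintf("enc%06d", seq_len(nE))
  encMonth <- sample(months, nE, replace = TRUE)
  encDay <- sample(1:28, nE, replace = TRUE)
  encDate <- sprintf("%s-%02d", encMonth, encDay)
  encTrue <- trueSym[encPat, , drop = FALSE]
  affirm <- matrix(rbinom(nE * nSym, 1, config@noteMentionSensitivity) == 1,
                   nE, nSym) & encTrue
  negMention <- matrix(rbinom(nE * nSym, 1, config@negatedMentionRate) == 1,
                       nE, nSym) & !encTrue
  icdCoded <- matrix(rbinom(nE * nSym, 1, config@icdCodingSensitivity) == 1,
                     nE, nSym) & encTrue
  diseaseCoded <- disease[encPat] &
    (rbinom(nE, 1, config@diseaseCodingSensitivity) == 1)
  formPick <- matrix(runif(nE * nSym), nE, nSym)
  tmplPickA <- matrix(sample.int(length(affirmTemplates), nE * nSym, replace = TRUE),
                      nE, nSym)
  tmplPickN <- matrix(sample.int(length(negateTemplates), nE * nSym, replace = TRUE),
                      nE, nSym)
  vm <- config@vitalsModel
  ht <- hypertensive[encPat]
  sys <- round(rnorm(nE, ifelse(ht, vm$hypertensive$sysMean, vm$normal$sysMean),
                     ifelse(ht, vm$hypertensive$sysSd, vm$normal$sysSd)))
  dia <- round(rnorm(nE, ifelse(ht, vm$hypertensive$diaMean, vm$normal$diaMean),
                     ifelse(ht, vm$hypertensive$diaSd, vm$normal$diaSd)))
  sys <- as.integer(pmin(pmax(sys, 60), 260))
  dia <- as.integer(pmin(pmax(dia, 30), 160))
  medGets <- hypertensive & (rbinom(nPat, 1, 0.5) == 1)

  ## ---- assemble resources ---------------------------------------------
  patients <- lapply(seq_len(nPat), function(i) {
    list(
      resourceType = "Patient", id = patId[i],
      name = list(list(family = family[i], given = list(given[i]))),
      gender = gender[i], birthDate = birthDate[i],
      address = list(list(line = list(street[i]), city = city[i])),
      telecom = list(list(system = "phone", value = phone[i]))
    )
  })

  encounters <- lapply(seq_len(nE), function(e) {
    list(
      resourceType = "Encounter", id = encId[e], status = "finished",
      class = list(system = "http://terminology.hl7.org/CodeSystem/v3-ActCode",
                   code = "EMER"),
      subject = list(reference = paste0("Patient/", patId[encPat[e]])),
      period = list(start = paste0(encDate[e], "T09:00:00"))
    )
  })

  condCount <- 0L
  conditions <- vector("list", sum(icdCoded) + sum(diseaseCoded))
  condOne <- function(e, code) {
    list(
      resourceType = "Condition", id = sprintf("cnd%06d", condCount),
      code = list(coding = list(list(
        system = "http://hl7.org/fhir/sid/icd-10-cm", code = code
      ))),
      subject = list(reference = paste0("Patient/", patId[encPat[e]])),
      encounter = list(reference = paste0("Encounter/", encId[e])),
      recordedDate = encDate[e]
    )
  }
  for (e in seq_len(nE)) {
    if (diseaseCoded[e]) {
      condCount <- condCount + 1L
      conditions[[condCount]] <- condOne(e, "U07.1")
    }
    for (j in which(icdCoded[e, ])) {
      condCount <- condCount + 1L
      conditions[[condCount]] <- condOne(e, sp$code[j])
    }
  }
  conditions <- conditions[seq_len(condCount)]

  obsOne <- function(e, k, loinc, value) {
    list(
      resourceType = "Observation", id = sprintf("obs%06d-%d", e, k),
      status = "final",
      category = list(list(coding = list(list(code = "vital-signs")))),
      code = list(coding = list(list(system = "http://loinc.org", code = loinc))),
      subject = list(reference = paste0("Patient/", patId[encPat[e]])),
      encounter = list(reference = paste0("Encounter/", encId[e])),
      effectiveDateTime = encDate[e],
      valueQuantity = list(value = value, unit = "mm[Hg]")
    )
  }
  observations <- vector("list", 2L * nE)
  for (e in seq_len(nE)) {
    observations[[2L * e - 1L]] <- obsOne(e, 1L, "8480-6", sys[e])
    observations[[2L * e]] <- obsOne(e, 2L, "8462-4", dia[e])
  }

  docrefs <- lapply(seq_len(nE), function(e) {
    sent <- c("Emergency department visit note.")
    for (j in seq_len(nSym)) {
      forms <- formsByCode[[sp$code[j]]]
      form <- forms[ceiling(formPick[e, j] * length(forms))]
      if (affirm[e, j]) {
        sent <- c(sent, capFirst(sprintf(affirmTemplates[tmplPickA[e, j]], form)))
      } else if (negMention[e, j]) {
        sent <- c(sent, capFirst(sprintf(negateTemplates[tmplPickN[e, j]], form)))
      }
    }
    txt <- paste(sent, collapse = " ")
    list(
      resourceType = "DocumentReference", id = sprintf("doc%06d", e),
      status = "current",
      subject = list(reference = paste0("Patient/", patId[encPat[e]])),
      date = paste0(encDate[e], "T09:30:00"),
      context = list(encounter = list(list(
        reference = paste0("Encounter/", encId[e])
      ))),
      content = list(list(attachment = list(
        contentType = "text/plain",
        data = jsonlite::base64_enc(charToRaw(txt))
      )))
    )
  })

  firstEnc <- match(seq_len(nPat), encPat)
  medrx <- lapply(which(medGets), function(i) {
    e <- firstEnc[i]
    list(
      resourceType = "MedicationRequest", id = sprintf("med%06d", i),
      status = "active", intent = "order",
      medicationCodeableConcept = list(
        coding = list(list(
          system = "http://www.nlm.nih.gov/research/umls/rxnorm",
          code = "197361"
        )),
        text = "amlodipine 5 mg tablet"
      ),
      subject = list(reference = paste0("Patient/", patId[i])),
      encounter = list(reference = paste0("Encounter/", encId[e])),
      authoredOn = encDate[e]
    )
  })

  ## ---- split by site ---------------------------------------------------
  exports <- lapply(sites, function(s) {
    pidx <- which(patSite == s)
    eidx <- which(patSite[encPat] == s)
    recs <- list(
      Patient = patients[pidx],
      Encounter = encounters[eidx],
      Condition = conditions[
        vapply(conditions, function(r) {
          sub("Patient/", "", r$subject$reference) %in% patId[pidx]
        }, logical(1))
      ],
      Observation = observations[rep(eidx, each = 2L) * 2L -
                                   rep(c(1L, 0L), times = length(eidx))],
      DocumentReference = docrefs[eidx],
      MedicationRequest = medrx[
        vapply(medrx, function(r) {
          sub("Patient/", "", r$subject$reference) %in% patId[pidx]
        }, logical(1))
      ]
    )
    new("BulkExport", records = recs, site = s,
        exportTime = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  })
  names(exports) <- sites

  gtPat <- data.frame(
    id = patId, site = patSite, disease = disease,
    hypertension = hypertensive, birthYear = birthYear,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(nSym)) gtPat[[paste0("sym_", sp$code[j])]] <- trueSym[, j]
  gtEnc <- data.frame(id = encId, patient = patId[encPat], month = encMonth,
                      stringsAsFactors = FALSE)

  list(exports = exports, groundTruth = list(patients = gtPat, encounters = gtEnc))
}

#' Write per-site NDJSON exports
#'
#' One subdirectory per site containing the six NDJSON files. Refuses to
#' write into an existing non-empty directory unless `overwrite = TRUE`.
#'
#' @param exports list of [BulkExport-class] from [generatePopulation()].
#' @param outDir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `outDir`, invisibly.
#' @export
writeSiteExports <- function(exports, outDir, overwrite = FALSE) {
  if (dir.exists(outDir) && length(list.files(outDir, all.files = TRUE,
                                              no.. = TRUE)) > 0 && !overwrite) {
    stop("output directory ", outDir,
         " exists and is not empty (use overwrite = TRUE)")
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (ex in exports) writeBulkExport(ex, file.path(outDir, ex@site))
  invisible(outDir)
}

#' Write ground truth as CSV (oracle only; never fed to the pipeline)
#'
#' @param groundTruth ground-truth list from [generatePopulation()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeGroundTruth <- function(groundTruth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(groundTruth$patients,
            file.path(dir, "ground-truth-patients.csv"), row.names = FALSE)
  write.csv(groundTruth$encounters,
            file.path(dir, "ground-truth-encounters.csv"), row.names = FALSE)
  invisible(dir)
}
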
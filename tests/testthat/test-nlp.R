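# brute-force scan oracle: slide over every position and compare every
# surface form by hand, then check word boundaries with character classes
oracleScan <- function(text, dict) {
  lower <- tolower(text)
  n <- nchar(text)
  isWord <- function(ch) grepl("[A-Za-z0-9_]", ch)
  hits <- data.frame(code = character(), start = integer(), end = integer())
  for (i in seq_len(nrow(dict@entries))) {
    form <- dict@entries$form[i]
    k <- nchar(form)
    for (s in seq_len(n - k + 1)) {
      if (substr(lower, s, s + k - 1) != form) next
      before <- if (s > 1) substr(text, s - 1, s - 1) else ""
      after <- if (s + k <= n) substr(text, s + k, s + k) else ""
      if ((before == "" || !isWord(before)) && (after == "" || !isWord(after))) {
        hits <- rbind(hits, data.frame(code = dict@entries$code[i],
                                       start = s - 1L, end = s - 1L + k))
      }
    }
  }
  hits[order(hits$start), , drop = FALSE]
}

test_that("mention extraction matches a brute-force scan at word boundaries", {
  dict <- defaultSymptomDictionary()
  texts <- c(
    "Cough and fever noted.",
    "Coughing all night, fevers since Tuesday.",
    "shortness of breath with headaches; no rigors.",
    "FEVER! cough? breathless... cephalalgia",
    "unrelated text with no terms at all"
  )
  for (tx in texts) {
    got <- extractMentions(tx, dict)
    want <- oracleScan(tx, dict)
    # the implementation resolves overlaps; the oracle has none in these
    # fixtures, so spans must agree exactly
    expect_identical(got$start, want$start, label = tx)
    expect_identical(got$end, want$end, label = tx)
    expect_identical(got$code, want$code, label = tx)
    # span invariant: matched text equals a registered form case-insensitively
    if (nrow(got) > 0) {
      expect_identical(tolower(got$text), got$form)
      expect_true(all(got$end <= nchar(tx)))
    }
  }
})

test_that("printed offsets of the canonical example are stable", {
  got <- extractMentions("Cough and fever noted.", defaultSymptomDictionary())
  expect_identical(got$code, c("R05", "R50.9"))
  expect_identical(got$start, c(0L, 10L))
  expect_identical(got$end, c(5L, 15L))
})

test_that("word-boundary rule blocks sub-token matches", {
  dict <- symptomDictionary(data.frame(
    code = "R05", label = "cough", form = "cough", stringsAsFactors = FALSE
  ))
  expect_identical(nrow(extractMentions("coughing fits", dict)), 0L)
  expect_identical(nrow(extractMentions("a cough.", dict)), 1L)
})

test_that("longest match wins on overlapping surface forms", {
  dict <- symptomDictionary(data.frame(
    code = c("X1", "X2"), label = c("breath", "sob"),
    form = c("breath", "shortness of breath"), stringsAsFactors = FALSE
  ))
  got <- extractMentions("shortness of breath today", dict)
  expect_identical(got$code, "X2")
  expect_identical(got$form, "shortness of breath")
})

test_that("negation rules follow cue, window and scope-termination logic", {
  dict <- defaultSymptomDictionary()
  cases <- list(
    list(text = "Patient denies fever and chills.",
         want = c(fever = "negated", chills = "negated")),
    list(text = "Patient has a cough.", want = c(cough = "affirmed")),
    list(text = "No cough but positive for fever.",
         want = c(cough = "negated", fever = "affirmed")),
    list(text = "Negative for rigors; cough persists.",
         want = c(chills = "negated", cough = "affirmed")),
    list(text = "Fever was ruled out.", want = c(fever = "negated")),
    # cue beyond the 5-token window does not reach the mention
    list(text = "No acute distress or other complaints besides a persistent cough.",
         want = c(cough = "affirmed")),
    # sentence boundary cuts scope
    list(text = "Patient denies chills. Fever noted on exam.",
         want = c(chills = "negated", fever = "affirmed"))
  )
  for (cs in cases) {
    got <- extractSymptoms(cs$text, dict)
    expect_identical(setNames(got$polarity, got$label), cs$want, label = cs$text)
  }
})

test_that("identical text yields identical mentions, offsets and polarities", {
  dict <- defaultSymptomDictionary()
  tx <- "No cough but positive for fever. Denies shivering."
  expect_identical(extractSymptoms(tx, dict), extractSymptoms(tx, dict))
})

test_that("structured records carry only affirmed mentions and no note text", {
  doc <- mkDocRef("d1", "p1", "e1",
                  "Patient reports fever. Denies cough. Headache noted.")
  men <- extractSymptoms(resolveNoteText(doc), defaultSymptomDictionary())
  recs <- mentionsToRecords(men, doc)
  expect_identical(length(recs), 2L)
  codes <- vapply(recs, function(r) r$code$coding[[1]]$code, "")
  expect_setequal(codes, c("R50.9", "R51"))
  for (r in recs) {
    expect_identical(r$encounter$reference, "Encounter/e1")
    expect_identical(r$effectiveDateTime, "2021-03")
    expect_identical(r$meta$tag[[1]]$code, "nlp")
    js <- as.character(jsonlite::toJSON(r, auto_unbox = TRUE))
    expect_false(grepl("Patient reports", js, fixed = TRUE))
    expect_false(grepl("Denies cough", js, fixed = TRUE))
  }
  expect_identical(mentionsToRecords(men[0, ], doc), list())
})

test_that("generator notes are recovered with full recall and correct polarity", {
  pop <- smallPopulation()
  gt <- pop$groundTruth$patients
  dict <- defaultSymptomDictionary()
  ex <- pop$exports[[2]]
  recs <- extractSymptomRecords(ex, dict)
  # every affirmed record corresponds to a truly present symptom
  for (r in recs) {
    pat <- sub("Patient/", "", r$subject$reference)
    expect_true(gt[gt$id == pat, paste0("sym_", r$code$coding[[1]]$code)])
  }
})
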
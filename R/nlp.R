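## Deterministic symptom extraction: dictionary matching of surface forms
## at word boundaries plus NegEx-style scoped negation cues. Stands where a
## learned clinical-NLP stack would sit in production; every rule is
## configurable so the stage can be swapped without touching its contract.

#' Build a symptom dictionary
#'
#' @param entries data.frame with columns `code`, `label`, `form` (one
#'   lowercase surface form per row; forms unique across concepts).
#' @param system code-system label for the concept codes.
#' @return a [SymptomDictionary-class].
#' @export
symptomDictionary <- function(entries, system = "ICD-10-CM") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  new("SymptomDictionary", entries = entries, system = system)
}

#' The shipped symptom value set
#'
#' Five respiratory-illness symptoms (fever, chills, cough, dyspnea,
#' headache), each with an ICD-10-CM code and 2-3 surface forms, shared
#' between the note-text extractor and the coded-data value sets.
#'
#' @return a [SymptomDictionary-class].
#' @export
defaultSymptomDictionary <- function() {
  readSymptomDictionary(system.file("extdata", "symptoms.yaml", package = "CohortCube"))
}

#' Read a symptom dictionary from YAML
#'
#' @param path YAML file: list of entries with `code`, `label`, `forms`.
#' @return a [SymptomDictionary-class].
#' @export
readSymptomDictionary <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(raw$concepts, function(e) {
    data.frame(code = e$code, label = e$label,
               form = tolower(unlist(e$forms)), stringsAsFactors = FALSE)
  })
  symptomDictionary(do.call(rbind, rows), system = raw$system %||% "ICD-10-CM")
}

#' Negation cue configuration
#'
#' NegEx-style trigger rules: pre-cues negate a mention within `window`
#' tokens before it, post-cues within `window` tokens after; scope is
#' terminated by conjunction terminators and sentence boundaries.
#'
#' @param pre character vector of pre-mention cues (may be multi-word).
#' @param post character vector of post-mention cues.
#' @param terminators scope-terminating conjunctions.
#' @param window scope window in tokens (default 5).
#' @return list with class-free cue configuration.
#' @export
negationCues <- function(pre = c("no", "not", "denies", "denied", "without",
                                 "negative for", "absence of", "free of"),
                         post = c("unlikely", "was ruled out", "is ruled out",
                                  "ruled out"),
                         terminators = c("but", "however", "although", "yet",
                                         "except", "aside"),
                         window = 5L) {
  list(pre = tolower(pre), post = tolower(post),
       terminators = tolower(terminators), window = as.integer(window))
}

#' Read negation cues from YAML
#' @param path YAML file with keys pre, post, terminators, window.
#' @return cue configuration list as from [negationCues()].
#' @export
readNegationCues <- function(path) {
  raw <- yaml::read_yaml(path)
  negationCues(pre = unlist(raw$pre), post = unlist(raw$post),
               terminators = unlist(raw$terminators),
               window = raw$window %||% 5L)
}

#' Extract dictionary mentions from note text
#'
#' Finds all case-insensitive matches of the dictionary's surface forms at
#' word boundaries, resolves overlaps longest-match-first, and returns them
#' ordered by span start. Spans are 0-based half-open offsets over the
#' note text. Polarity is left unset (NA); see [detectNegation()].
#'
#' @param text note text (non-empty string).
#' @param dict a [SymptomDictionary-class].
#' @return data.frame: code, label, form, start, end, text, polarity.
#' @examples
#' extractMentions("Cough and fever noted.", defaultSymptomDictionary())
#' @export
extractMentions <- function(text, dict) {
  stopifnot(is(dict, "SymptomDictionary"))
  if (length(text) != 1 || is.na(text) || !nzchar(text)) {
    stop("text must be a single non-empty string")
  }
  e <- dict@entries
  hits <- list()
  for (i in seq_len(nrow(e))) {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", e$form[i]), "\\b")
    m <- gregexpr(pat, text, ignore.case = TRUE, perl = TRUE)[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    hits[[length(hits) + 1]] <- data.frame(
      code = e$code[i], label = e$label[i], form = e$form[i],
      start = as.integer(m) - 1L, end = as.integer(m) - 1L + len,
      stringsAsFactors = FALSE
    )
  }
  if (length(hits) == 0) {
    return(data.frame(code = character(), label = character(), form = character(),
                      start = integer(), end = integer(), text = character(),
                      polarity = character(), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, hits)
  # longest-match-wins, then earliest; greedy non-overlapping selection
  h <- h[order(-(h$end - h$start), h$start, h$code), , drop = FALSE]
  taken <- logical(nchar(text))
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    span <- (h$start[i] + 1L):h$end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$start), , drop = FALSE]
  h$text <- substring(text, h$start + 1L, h$end)
  h$polarity <- NA_character_
  rownames(h) <- NULL
  h
}

## tokenize with offsets; sentence ids advance at . ! ? ;
tokenizeWithOffsets <- function(text) {
  m <- gregexpr("[A-Za-z0-9']+", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      sentence = integer()))
  }
  len <- attr(m, "match.length")
  tok <- data.frame(
    token = tolower(substring(text, m, m + len - 1L)),
    start = as.integer(m) - 1L, end = as.integer(m) - 1L + len,
    stringsAsFactors = FALSE
  )
  # sentence index = number of boundary chars before the token
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bnd <- cumsum(chars %in% c(".", "!", "?", ";"))
  tok$sentence <- bnd[tok$start + 1L]
  tok
}

## n-gram cue lookup over a token window walking away from the mention
matchCueInWindow <- function(tokens, idx, cues, window, terminators, forward) {
  steps <- 0L
  i <- idx
  repeat {
    i <- if (forward) i + 1L else i - 1L
    steps <- steps + 1L
    if (i < 1 || i > nrow(tokens) || steps > window) return(FALSE)
    if (tokens$sentence[i] != tokens$sentence[idx]) return(FALSE)
    if (tokens$token[i] %in% terminators) return(FALSE)
    for (cue in cues) {
      cueTok <- strsplit(cue, " ", fixed = TRUE)[[1]]
      k <- length(cueTok)
      first <- if (forward) i else i - k + 1L
      if (first < 1 || first + k - 1L > nrow(tokens)) next
      if (identical(tokens$token[first:(first + k - 1L)], cueTok)) return(TRUE)
    }
  }
}

#' Rule-based negation detection for one mention
#'
#' A mention is negated iff a pre-cue occurs within the scope window before
#' its span, or a post-cue within the window after it, with scope cut by
#' conjunction terminators ("but", "however", ...) and sentence boundaries.
#' Otherwise it is affirmed (uncertainty is treated as affirmed).
#'
#' @param text the note text the mention was extracted from.
#' @param start,end 0-based half-open span of the mention.
#' @param cues cue configuration from [negationCues()].
#' @param tokens pre-tokenized text (internal reuse); computed if NULL.
#' @return character(1) "negated" or "affirmed".
#' @export
detectNegation <- function(text, start, end, cues = negationCues(), tokens = NULL) {
  if (is.null(tokens)) tokens <- tokenizeWithOffsets(text)
  if (start < 0 || end > nchar(text) || start >= end) {
    stop("mention span out of bounds")
  }
  firstTok <- which(tokens$start >= start & tokens$start < end)[1]
  lastTok <- rev(which(tokens$end > start & tokens$end <= end))[1]
  if (is.na(firstTok)) return("affirmed")
  if (matchCueInWindow(tokens, firstTok, cues$pre, cues$window,
                       cues$terminators, forward = FALSE)) {
    return("negated")
  }
  if (matchCueInWindow(tokens, lastTok, cues$post, cues$window,
                       cues$terminators, forward = TRUE)) {
    return("negated")
  }
  "affirmed"
}

#' Extract symptom mentions with polarity from a note
#'
#' Convenience wrapper: [extractMentions()] then [detectNegation()] per
#' mention (tokenizing the note once).
#'
#' @param text note text.
#' @param dict a [SymptomDictionary-class].
#' @param cues cue configuration from [negationCues()].
#' @return mention data.frame with `polarity` filled in.
#' @examples
#' extractSymptoms("No cough but positive for fever.", defaultSymptomDictionary())
#' @export
extractSymptoms <- function(text, dict = defaultSymptomDictionary(),
                            cues = negationCues()) {
  m <- extractMentions(text, dict)
  if (nrow(m) == 0) return(m)
  tokens <- tokenizeWithOffsets(text)
  m$polarity <- vapply(seq_len(nrow(m)), function(i) {
    detectNegation(text, m$start[i], m$end[i], cues, tokens = tokens)
  }, character(1))
  m
}

#' Convert affirmed mentions to structured symptom resources
#'
#' Emits one Observation-shaped resource per affirmed mention, carrying the
#' concept code, the source document's subject and encounter references and
#' the document month. No note text, span text or offsets are copied into
#' the output.
#'
#' @param mentions mention data.frame with polarity (see
#'   [extractSymptoms()]).
#' @param doc the source DocumentReference resource.
#' @param system code-system label for the emitted codes.
#' @return list of Observation resources tagged with source "nlp".
#' @export
mentionsToRecords <- function(mentions, doc, system = "ICD-10-CM") {
  if (!identical(doc$resourceType, "DocumentReference")) {
    stop("doc must be a DocumentReference")
  }
  aff <- mentions[!is.na(mentions$polarity) & mentions$polarity == "affirmed", ,
                  drop = FALSE]
  if (nrow(aff) == 0) return(list())
  month <- substr(doc$date %||% "", 1, 7)
  lapply(seq_len(nrow(aff)), function(i) {
    list(
      resourceType = "Observation",
      id = sprintf("%s-sym-%d", doc$id, i),
      meta = list(tag = list(list(system = "urn:cohortcube:source", code = "nlp"))),
      status = "final",
      code = list(coding = list(list(system = system, code = aff$code[i])),
                  text = aff$label[i]),
      subject = doc$subject,
      encounter = list(reference = doc$context$encounter[[1]]$reference),
      effectiveDateTime = month
    )
  })
}

#' Run symptom NLP over every note of an export
#'
#' Resolves each DocumentReference's note text, extracts polarity-resolved
#' mentions and returns the affirmed ones as structured resources. Notes are
#' consumed here and never leave this stage.
#'
#' @param export a [BulkExport-class].
#' @param dict a [SymptomDictionary-class].
#' @param cues cue configuration.
#' @param exportDir directory for resolving attachment urls.
#' @return list of symptom Observation resources (source "nlp").
#' @export
extractSymptomRecords <- function(export, dict = defaultSymptomDictionary(),
                                  cues = negationCues(), exportDir = ".") {
  docs <- export@records$DocumentReference
  out <- lapply(docs, function(doc) {
    txt <- resolveNoteText(doc, exportDir)
    mentionsToRecords(extractSymptoms(txt, dict, cues), doc, system = dict@system)
  })
  unlist(out, recursive = FALSE, use.names = FALSE) %||% list()
}
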
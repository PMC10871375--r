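## De-identification: allow-list field rules plus a keyed codebook that
## pseudonymizes identifiers deterministically so joins survive without a
## stored PHI mapping.

#' Create a pseudonymization codebook
#'
#' The codebook is a keyed one-way construction: pseudonyms are
#' HMAC-SHA256(secret, identifier) rendered as 24 lowercase letters. The
#' same (secret, identifier) pair always yields the same pseudonym; no
#' identifier-to-pseudonym table is kept (the internal cache only detects
#' collisions, which are astronomically unlikely at 26^24 output space).
#'
#' @param secret high-entropy key string (>= 16 characters). Supply via
#'   environment variable or CLI flag; never written into any export.
#' @return a [Codebook-class].
#' @examples
#' cb <- codebook("correct-horse-battery-staple")
#' pseudonymize("Patient/123", cb)
#' @export
codebook <- function(secret) {
  cache <- new.env(parent = emptyenv())
  cb <- new("Codebook", secret = secret, algorithm = "hmac-sha256/a-z24",
            cache = cache)
  validObject(cb)
  cache$fwd <- new.env(parent = emptyenv())  # identifier -> pseudonym memo
  cache$rev <- new.env(parent = emptyenv())  # pseudonym -> identifier (collision check)
  cache$rawKey <- charToRaw(secret)
  cb
}

#' Pseudonymize one identifier
#'
#' Deterministic under a fixed codebook secret; fixed 24-character output in
#' a lowercase a-z alphabet (so no digit-bearing source identifier can ever
#' resurface as a substring).
#'
#' @param identifier non-empty identifier string.
#' @param cb a [Codebook-class].
#' @return character(1) pseudonym.
#' @export
pseudonymize <- function(identifier, cb) {
  stopifnot(is(cb, "Codebook"))
  if (length(identifier) != 1 || is.na(identifier) || !nzchar(identifier)) {
    stop("identifier must be a single non-empty string")
  }
  memo <- get0(identifier, envir = cb@cache$fwd, inherits = FALSE)
  if (!is.null(memo)) return(memo)
  mac <- digest::hmac(cb@cache$rawKey, charToRaw(identifier),
                      algo = "sha256", raw = TRUE)
  p <- paste(letters[(as.integer(mac[1:24]) %% 26L) + 1L], collapse = "")
  prev <- get0(p, envir = cb@cache$rev, inherits = FALSE)
  if (is.null(prev)) {
    assign(p, identifier, envir = cb@cache$rev)
  } else if (!identical(prev, identifier)) {
    stop("codebook collision detected between two distinct identifiers")
  }
  assign(identifier, p, envir = cb@cache$fwd)
  p
}

## pseudonymize the id part of a "Type/id" reference, keeping the type
## prefix so joins and polymorphic references stay interpretable
pseudonymizeReference <- function(ref, cb) {
  if (grepl("^[A-Za-z]+/", ref)) {
    ty <- sub("/.*$", "", ref)
    paste0(ty, "/", pseudonymize(ref, cb))
  } else {
    pseudonymize(ref, cb)
  }
}

#' Default de-identification rule template
#'
#' Allow-list rules (default action: drop) reviewed for the six pipeline
#' resource types: identifiers and references pseudonymized, dates
#' generalized to month, clinical codes and values kept. DocumentReference
#' note content is dropped — note text never crosses the site boundary.
#'
#' @return a [DeidRules-class].
#' @export
defaultDeidRules <- function() {
  readDeidRules(system.file("extdata", "deid-default.yaml", package = "CohortCube"))
}

#' Read de-identification rules from YAML
#'
#' The YAML maps resource type -> {field path: action}, actions one of
#' keep, drop, generalize_date_to_month, pseudonymize. Field paths are
#' dot-separated for nested fields (e.g. `period.start`).
#'
#' @param path YAML file path.
#' @return a [DeidRules-class].
#' @export
readDeidRules <- function(path) {
  raw <- yaml::read_yaml(path)
  rules <- lapply(raw, function(x) unlist(x))
  new("DeidRules", rules = rules)
}

getPath <- function(x, parts) {
  for (p in parts) {
    if (!is.list(x) || is.null(x[[p]])) return(NULL)
    x <- x[[p]]
  }
  x
}

setPath <- function(x, parts, value) {
  if (length(parts) == 1) {
    x[[parts]] <- value
    return(x)
  }
  sub <- x[[parts[1]]]
  if (is.null(sub)) sub <- list()
  x[[parts[1]]] <- setPath(sub, parts[-1], value)
  x
}

## recursive pseudonymization of reference-bearing values: a bare string,
## a {reference: ...} object, or a list of either
pseudonymizeValue <- function(v, cb) {
  if (is.character(v) && length(v) == 1) return(pseudonymizeReference(v, cb))
  if (is.list(v)) {
    if (!is.null(v$reference)) {
      v$reference <- pseudonymizeReference(v$reference, cb)
      return(v)
    }
    return(lapply(v, pseudonymizeValue, cb = cb))
  }
  v
}

#' De-identify one FHIR resource
#'
#' Applies allow-list rules: the output contains only fields named by a
#' keep/generalize/pseudonymize rule (plus `resourceType`); everything
#' else, including any field the rules never anticipated, is dropped.
#' Reference fields are pseudonymized consistently with resource ids so
#' joins survive.
#'
#' @param record parsed FHIR resource (named list).
#' @param rules a [DeidRules-class] covering the record's resource type.
#' @param cb a [Codebook-class].
#' @return de-identified resource (named list).
#' @export
applyDeid <- function(record, rules, cb) {
  stopifnot(is(rules, "DeidRules"), is(cb, "Codebook"))
  ty <- record$resourceType
  acts <- rules@rules[[ty]]
  if (is.null(acts)) {
    stop("no de-identification rules for resource type '", ty, "'")
  }
  out <- list(resourceType = ty)
  for (fieldPath in names(acts)) {
    action <- acts[[fieldPath]]
    if (action == "drop") next
    parts <- strsplit(fieldPath, ".", fixed = TRUE)[[1]]
    val <- getPath(record, parts)
    if (is.null(val)) next
    val <- switch(action,
      keep = val,
      generalize_date_to_month = substr(val, 1, 7),
      pseudonymize = if (identical(fieldPath, "id")) {
        # key the record's own id by its type so it matches "Type/id" refs
        pseudonymize(paste0(ty, "/", val), cb)
      } else {
        pseudonymizeValue(val, cb)
      }
    )
    out <- setPath(out, parts, val)
  }
  out
}

#' De-identify a whole bulk export
#'
#' Applies [applyDeid()] to every record of every resource type present in
#' the rules. Resource types without a rule entry are removed wholesale
#' (with a message), consistent with allow-list semantics.
#'
#' @param export a [BulkExport-class].
#' @param rules a [DeidRules-class].
#' @param cb a [Codebook-class].
#' @return a de-identified [BulkExport-class].
#' @export
applyDeidExport <- function(export, rules, cb) {
  stopifnot(is(export, "BulkExport"))
  records <- list()
  for (ty in names(export@records)) {
    if (length(export@records[[ty]]) == 0) {
      records[[ty]] <- list()
      next
    }
    if (is.null(rules@rules[[ty]])) {
      message("deid: no rules for ", ty, "; dropping ",
              length(export@records[[ty]]), " record(s)")
      records[[ty]] <- list()
      next
    }
    records[[ty]] <- lapply(export@records[[ty]], applyDeid, rules = rules, cb = cb)
  }
  new("BulkExport", records = records, site = export@site,
      exportTime = export@exportTime)
}
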
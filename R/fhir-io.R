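## Bulk-FHIR NDJSON reading/writing. Dialect: UTF-8, one JSON object per
## line, blank lines ignored with a warning (matches Bulk Data Access
## output conventions).

#' Resource types consumed by the pipeline
#'
#' @return character vector of the six supported FHIR resource types.
#' @export
fhirResourceTypes <- function() {
  c("Patient", "Encounter", "Condition", "Observation",
    "DocumentReference", "MedicationRequest")
}

#' Read one bulk-FHIR NDJSON file
#'
#' Parses a newline-delimited JSON file into a list of resources (nested
#' named lists), preserving file order. Every line must be a well-formed
#' JSON object whose `resourceType` matches `resourceType`; mismatches are
#' an error, never silently skipped.
#'
#' @param path path to an `.ndjson` file.
#' @param resourceType expected resource type, one of [fhirResourceTypes()].
#' @return list of parsed resources in file order.
#' @examples
#' f <- tempfile(fileext = ".ndjson")
#' writeLines('{"resourceType":"Patient","id":"p1"}', f)
#' readNDJSON(f, "Patient")
#' @export
readNDJSON <- function(path, resourceType) {
  resourceType <- match.arg(resourceType, fhirResourceTypes())
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    warning(sprintf("%s: ignoring %d blank line(s)", basename(path), sum(blank)))
  }
  keep <- which(!blank)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    rec <- tryCatch(
      jsonlite::fromJSON(lines[ln], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("%s: parse error at line %d: %s",
                     basename(path), ln, conditionMessage(e)), call. = FALSE)
      }
    )
    if (!identical(rec$resourceType, resourceType)) {
      stop(sprintf(
        "%s: line %d declares resourceType '%s', expected '%s'",
        basename(path), ln, rec$resourceType %||% "<missing>", resourceType
      ), call. = FALSE)
    }
    if (is.null(rec$id) || !nzchar(rec$id)) {
      stop(sprintf("%s: line %d has no id", basename(path), ln), call. = FALSE)
    }
    out[[i]] <- rec
  }
  out
}

#' Write resources as bulk-FHIR NDJSON
#'
#' Serializes a list of resources (all of one type) to newline-delimited
#' JSON. `readNDJSON()` of the written file reproduces the input
#' field-for-field.
#'
#' @param records list of parsed resources sharing one `resourceType`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNDJSON <- function(records, path) {
  if (length(records) > 0) {
    types <- unique(vapply(records, function(r) r$resourceType %||% "", character(1)))
    if (length(types) != 1) {
      stop("records of mixed resource types: ", paste(types, collapse = ", "))
    }
  }
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null", digits = NA))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines) > 0) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a site's full bulk export directory
#'
#' Reads the six per-type NDJSON files of one site into a
#' [BulkExport-class]. `Patient.ndjson` is mandatory; an absent file for
#' another type yields zero records of that type.
#'
#' @param dir directory containing `Patient.ndjson` etc.
#' @param site site label; defaults to the directory name.
#' @return a [BulkExport-class] object.
#' @export
readBulkExport <- function(dir, site = basename(normalizePath(dir))) {
  if (!dir.exists(dir)) stop("no such export directory: ", dir)
  pf <- file.path(dir, "Patient.ndjson")
  if (!file.exists(pf)) {
    stop("export directory lacks Patient.ndjson: ", dir)
  }
  records <- list()
  for (ty in fhirResourceTypes()) {
    f <- file.path(dir, paste0(ty, ".ndjson"))
    records[[ty]] <- if (file.exists(f)) readNDJSON(f, ty) else list()
  }
  new("BulkExport", records = records, site = site,
      exportTime = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

#' Write a BulkExport to an NDJSON directory
#'
#' @param export a [BulkExport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBulkExport <- function(export, dir) {
  stopifnot(is(export, "BulkExport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ty in fhirResourceTypes()) {
    writeNDJSON(export@records[[ty]] %||% list(), file.path(dir, paste0(ty, ".ndjson")))
  }
  invisible(dir)
}

#' Resolve the plain text of a clinical note
#'
#' Extracts note text from a DocumentReference: inline base64 `data` is
#' decoded (tried first), otherwise a relative `url` attachment is read from
#' the export directory. HTML content is tag-stripped to text with
#' whitespace collapsed; `text/plain` passes through. Other content types
#' (e.g. PDF) raise an unsupported-format error.
#'
#' @param doc a DocumentReference resource (parsed list).
#' @param exportDir directory for resolving relative attachment urls.
#' @return character(1) plain note text.
#' @export
resolveNoteText <- function(doc, exportDir = ".") {
  if (!identical(doc$resourceType, "DocumentReference")) {
    stop("not a DocumentReference: ", doc$resourceType %||% "<missing>")
  }
  att <- doc$content[[1]]$attachment
  if (is.null(att)) stop("DocumentReference ", doc$id, " has no attachment")
  ctype <- tolower(att$contentType %||% "text/plain")
  ctype <- sub(";.*$", "", trimws(ctype))
  if (!ctype %in% c("text/plain", "text/html")) {
    stop(sprintf("unsupported note format '%s' for document %s", ctype, doc$id))
  }
  if (!is.null(att$data)) {
    raw <- jsonlite::base64_dec(att$data)
    txt <- rawToChar(raw)
    Encoding(txt) <- "UTF-8"
  } else if (!is.null(att$url)) {
    f <- file.path(exportDir, att$url)
    if (!file.exists(f)) {
      stop(sprintf("attachment file '%s' for document %s not found", att$url, doc$id))
    }
    txt <- paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  } else {
    stop("DocumentReference ", doc$id, " attachment has neither data nor url")
  }
  if (ctype == "text/html") txt <- stripHTML(txt)
  txt
}

## tag-strip + whitespace collapse; standard named entities come free with
## the XML parser
stripHTML <- function(x) {
  txt <- xml2::xml_text(xml2::read_html(paste0("<body>", x, "</body>")))
  trimws(gsub("[[:space:]]+", " ", txt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
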
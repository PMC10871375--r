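## The aggregate matrix: counts over the power set of study-variable
## combinations, sparse (unobserved combinations omitted), with the
## null-set row carrying the total cohort size; small-cell suppression and
## push-model merging across sites.

emptyCounts <- function(variables) {
  df <- as.data.frame(setNames(
    rep(list(character(0)), length(variables)), variables
  ), stringsAsFactors = FALSE)
  df$cnt <- integer(0)
  df
}

canonicalOrder <- function(counts, variables) {
  if (nrow(counts) == 0) return(counts)
  size <- if (length(variables) > 0) {
    rowSums(!is.na(counts[, variables, drop = FALSE]))
  } else {
    rep(0L, nrow(counts))
  }
  # subset shape key: which variables are fixed, in declared order
  shape <- apply(!is.na(counts[, variables, drop = FALSE]), 1, function(z) {
    paste(variables[z], collapse = "|")
  })
  ord <- do.call(order, c(list(size, shape),
                          lapply(variables, function(v) counts[[v]])))
  out <- counts[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute the power-set aggregate count matrix
#'
#' For every subset of the study variables and every observed level
#' combination over that subset, counts the cohort rows matching it. The
#' empty subset yields the null-set row whose count is the total cohort
#' size. Unobserved level combinations are omitted, so the matrix is sparse
#' relative to the full power set; the number of distinct subset shapes is
#' 2^n for n variables.
#'
#' @param cohort labelled cohort data.frame (e.g. from
#'   [deriveVariables()]); one row per counting unit.
#' @param variables ordered character vector of variable column names.
#' @param metadata optional list merged into the matrix metadata (`sites`,
#'   `period`, `countUnit`, `variableDescriptions`).
#' @param nMax hard cap on the number of variables (2^n growth guard).
#' @return an unsuppressed [AggregateMatrix-class].
#' @examples
#' cohort <- data.frame(disease = c("1", "1", "0", "1"),
#'                      cough = c("1", "0", "0", "1"))
#' cubeCounts(cohort, c("disease", "cough"))
#' @export
cubeCounts <- function(cohort, variables, metadata = list(), nMax = 10L) {
  if (length(variables) > nMax) {
    stop("refusing to cube ", length(variables), " variables (nMax = ", nMax,
         "): the power set has 2^n subset shapes")
  }
  missingCols <- setdiff(variables, names(cohort))
  if (length(missingCols) > 0) {
    stop("cohort lacks variable column(s): ", paste(missingCols, collapse = ", "))
  }
  for (v in variables) {
    col <- cohort[[v]]
    if (is.double(col) && any(col != floor(col), na.rm = TRUE)) {
      stop("variable '", v, "' is continuous; bin it into discrete levels first")
    }
  }
  n <- length(variables)
  if (nrow(cohort) == 0) {
    counts <- emptyCounts(variables)
    counts[1, "cnt"] <- 0L
    counts <- as.data.frame(counts)
  } else {
    dt <- as.data.table(lapply(
      setNames(as.list(cohort[, variables, drop = FALSE]), variables),
      as.character
    ))
    if (n == 0) dt <- data.table(.dummy = rep(1L, nrow(cohort)))
    pieces <- list(data.table(cnt = nrow(cohort)))
    if (n > 0) {
      for (k in seq_len(n)) {
        for (sub in utils::combn(variables, k, simplify = FALSE)) {
          pieces[[length(pieces) + 1]] <- dt[, list(cnt = .N), by = sub]
        }
      }
    }
    counts <- as.data.frame(rbindlist(pieces, fill = TRUE))
    counts <- counts[, c(variables, "cnt"), drop = FALSE]
  }
  counts$cnt <- as.integer(counts$cnt)
  counts <- canonicalOrder(counts, variables)
  meta <- list(
    sites = metadata$sites %||% character(),
    period = metadata$period %||% character(),
    countUnit = metadata$countUnit %||% "units",
    variableDescriptions = metadata$variableDescriptions %||%
      setNames(rep("", n), variables),
    threshold = NA_integer_,
    compiled = metadata$compiled %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  new("AggregateMatrix", variables = variables, counts = counts, metadata = meta)
}

#' Apply small-cell suppression
#'
#' Removes every cell (row) whose count is below the threshold — rows are
#' dropped entirely, never masked. The threshold applies uniformly,
#' including to the null-set row: if the whole cohort is smaller than the
#' threshold the result is an empty matrix and a refusal is logged.
#'
#' @param matrix an [AggregateMatrix-class].
#' @param threshold positive integer; cells with fewer units are removed
#'   (default 10).
#' @return the suppressed [AggregateMatrix-class] with the threshold
#'   recorded in its metadata.
#' @export
suppressCells <- function(matrix, threshold = 10L) {
  stopifnot(is(matrix, "AggregateMatrix"))
  threshold <- as.integer(threshold)
  if (threshold < 1) stop("threshold must be >= 1")
  counts <- matrix@counts
  total <- nullSetCount(matrix)
  if (!is.na(total) && total < threshold) {
    message("suppression refusal: cohort size ", total,
            " is below threshold ", threshold, "; emitting an empty matrix")
    counts <- emptyCounts(matrix@variables)
  } else {
    counts <- counts[counts$cnt >= threshold, , drop = FALSE]
    rownames(counts) <- NULL
  }
  meta <- matrix@metadata
  meta$threshold <- threshold
  new("AggregateMatrix", variables = matrix@variables, counts = counts,
      metadata = meta)
}

#' Merge site matrices into a network matrix
#'
#' Cellwise sum over the union of assignments (push-model federation: each
#' input was computed and suppressed locally; a cell suppressed at a site
#' contributes nothing to the network sum). Inputs must share the variable
#' list, study period and suppression threshold; the merged result is
#' re-suppressed at that threshold, guarding cells reconstructed from few
#' sites.
#'
#' @param matrices list of [AggregateMatrix-class].
#' @return the merged [AggregateMatrix-class]; metadata sites are the union
#'   of the inputs' sites.
#' @export
mergeMatrices <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  for (m in matrices) stopifnot(is(m, "AggregateMatrix"))
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!identical(m@variables, ref@variables)) {
      stop("merge error: variable lists differ ('",
           paste(ref@variables, collapse = ","), "' vs '",
           paste(m@variables, collapse = ","), "')")
    }
    if (!identical(m@metadata$period, ref@metadata$period)) {
      stop("merge error: study periods differ (",
           paste(ref@metadata$period, collapse = ".."), " vs ",
           paste(m@metadata$period, collapse = ".."), ")")
    }
    if (!identical(is.na(m@metadata$threshold), is.na(ref@metadata$threshold)) ||
        (!is.na(ref@metadata$threshold) &&
         m@metadata$threshold != ref@metadata$threshold)) {
      stop("merge error: suppression thresholds differ")
    }
  }
  if (length(matrices) == 1) return(ref)
  vars <- ref@variables
  all <- rbindlist(lapply(matrices, function(m) as.data.table(m@counts)))
  summed <- if (length(vars) > 0) {
    all[, list(cnt = sum(cnt)), by = vars]
  } else {
    all[, list(cnt = sum(cnt))]
  }
  counts <- canonicalOrder(as.data.frame(summed), vars)
  counts$cnt <- as.integer(counts$cnt)
  meta <- ref@metadata
  meta$sites <- sort(unique(unlist(lapply(matrices, function(m) m@metadata$sites))))
  meta$compiled <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  merged <- new("AggregateMatrix", variables = vars, counts = counts,
                metadata = meta)
  thr <- ref@metadata$threshold
  if (!is.na(thr)) merged <- suppressCells(merged, thr)
  merged
}

## ---- accessors --------------------------------------------------------

#' Accessors for AggregateMatrix
#'
#' `aggVariables()` returns the ordered variable names, `aggCounts()` the
#' sparse count table (one character column per variable, NA meaning the
#' variable is not in the row's subset, plus `cnt`), `aggMetadata()` the
#' provenance metadata, `suppressionThreshold()` the applied threshold (NA
#' if unsuppressed), and `nullSetCount()` the total cohort size (NA if the
#' null-set row was suppressed).
#'
#' @param x an [AggregateMatrix-class].
#' @return see individual descriptions.
#' @export
aggVariables <- function(x) x@variables

#' @rdname aggVariables
#' @export
aggCounts <- function(x) x@counts

#' @rdname aggVariables
#' @export
aggMetadata <- function(x) x@metadata

#' @rdname aggVariables
#' @export
suppressionThreshold <- function(x) x@metadata$threshold

#' @rdname aggVariables
#' @export
nullSetCount <- function(x) {
  getCell(x, setNames(character(0), character(0)), absentAsZero = FALSE,
          quietNA = TRUE)
}

## look up one cell by (partial) assignment; assignment is a named
## character vector variable -> level. Returns NA when the cell is absent.
getCell <- function(x, assignment, absentAsZero = FALSE, quietNA = FALSE) {
  counts <- x@counts
  if (nrow(counts) == 0) return(if (absentAsZero) 0L else NA_integer_)
  sel <- rep(TRUE, nrow(counts))
  for (v in x@variables) {
    sel <- sel & if (v %in% names(assignment)) {
      !is.na(counts[[v]]) & counts[[v]] == assignment[[v]]
    } else {
      is.na(counts[[v]])
    }
  }
  if (!any(sel)) return(if (absentAsZero) 0L else NA_integer_)
  counts$cnt[which(sel)[1]]
}

## ---- serialization -----------------------------------------------------

#' Write an aggregate matrix as CSV plus metadata YAML
#'
#' The CSV has one column per variable (empty cell = variable not in the
#' row's subset, distinct from any explicit level) plus `cnt`. Metadata
#' (sites, period, suppression threshold, compile time, variable
#' descriptions) goes to a companion YAML file.
#'
#' @param matrix an [AggregateMatrix-class].
#' @param csvPath output CSV path.
#' @param metaPath output YAML path; defaults to the CSV path with a
#'   `.meta.yaml` extension.
#' @return `csvPath`, invisibly.
#' @export
writeAggregateMatrix <- function(matrix, csvPath,
                                 metaPath = sub("\\.csv$", ".meta.yaml", csvPath)) {
  stopifnot(is(matrix, "AggregateMatrix"))
  out <- matrix@counts
  for (v in matrix@variables) {
    if (any(!is.na(out[[v]]) & !nzchar(out[[v]]))) {
      stop("variable '", v, "' has an empty-string level, which the CSV form",
           " cannot distinguish from 'not in subset'")
    }
    out[[v]][is.na(out[[v]])] <- ""
  }
  write.csv(out, csvPath, row.names = FALSE, quote = TRUE)
  meta <- matrix@metadata
  meta$variables <- as.list(matrix@variables)
  meta$threshold <- if (is.na(meta$threshold)) NULL else meta$threshold
  meta$variableDescriptions <- as.list(meta$variableDescriptions)
  yaml::write_yaml(meta, metaPath)
  invisible(csvPath)
}

#' Read an aggregate matrix written by [writeAggregateMatrix()]
#'
#' @param csvPath CSV path.
#' @param metaPath companion YAML path.
#' @return an [AggregateMatrix-class].
#' @export
readAggregateMatrix <- function(csvPath,
                                metaPath = sub("\\.csv$", ".meta.yaml", csvPath)) {
  raw <- read.csv(csvPath, stringsAsFactors = FALSE, colClasses = "character")
  meta <- if (file.exists(metaPath)) yaml::read_yaml(metaPath) else list()
  vars <- unlist(meta$variables) %||% setdiff(names(raw), "cnt")
  counts <- raw[, c(vars, "cnt"), drop = FALSE]
  for (v in vars) counts[[v]][!nzchar(counts[[v]])] <- NA_character_
  counts$cnt <- as.integer(counts$cnt)
  metadata <- list(
    sites = unlist(meta$sites) %||% character(),
    period = unlist(meta$period) %||% character(),
    countUnit = meta$countUnit %||% "units",
    variableDescriptions = unlist(meta$variableDescriptions) %||%
      setNames(rep("", length(vars)), vars),
    threshold = if (is.null(meta$threshold)) NA_integer_ else as.integer(meta$threshold),
    compiled = meta$compiled %||% ""
  )
  new("AggregateMatrix", variables = vars, counts = counts, metadata = metadata)
}
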
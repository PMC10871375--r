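## Analytics over aggregate counts alone: 2x2 extraction by marginal
## subtraction, then the classical count-based epidemiological measures.
## Policy for missing cells: in a never-suppressed matrix an absent cell is
## an exact zero (the sparse form omits zeros); in a suppressed matrix it
## is destroyed information and raises an incomputable error — never
## imputed.

cellOrStop <- function(matrix, assignment, what) {
  suppressed <- !is.na(matrix@metadata$threshold)
  v <- getCell(matrix, assignment, absentAsZero = !suppressed)
  if (is.na(v)) {
    stop("incomputable: required cell for ", what,
         " is absent from the suppressed matrix (suppressed cells are never imputed)")
  }
  v
}

#' Extract a 2x2 contingency table from an aggregate matrix
#'
#' `a` is the joint (exposure, outcome) cell; `b` and `c` follow by
#' subtraction from the exposure and outcome marginals, `d` by subtraction
#' from the null-set total. If any needed cell was removed by suppression
#' the extraction fails with an incomputable error.
#'
#' @param matrix an [AggregateMatrix-class].
#' @param exposure c(variable, level).
#' @param outcome c(variable, level).
#' @return a [CrossTab-class].
#' @examples
#' cohort <- data.frame(E = rep(c("1","1","0","0"), c(20, 20, 10, 50)),
#'                      O = rep(c("1","0","1","0"), c(20, 20, 10, 50)))
#' m <- cubeCounts(cohort, c("E", "O"))
#' crossTab(m, c("E", "1"), c("O", "1"))
#' @export
crossTab <- function(matrix, exposure, outcome) {
  stopifnot(is(matrix, "AggregateMatrix"),
            length(exposure) == 2, length(outcome) == 2)
  for (v in c(exposure[1], outcome[1])) {
    if (!v %in% matrix@variables) {
      stop("variable '", v, "' not in the aggregate matrix")
    }
  }
  total <- cellOrStop(matrix, setNames(character(0), character(0)), "total")
  margE <- cellOrStop(matrix, setNames(exposure[2], exposure[1]), "exposure marginal")
  margO <- cellOrStop(matrix, setNames(outcome[2], outcome[1]), "outcome marginal")
  joint <- cellOrStop(matrix, setNames(c(exposure[2], outcome[2]),
                                       c(exposure[1], outcome[1])), "joint cell")
  a <- as.numeric(joint)
  b <- as.numeric(margE - joint)
  c <- as.numeric(margO - joint)
  d <- as.numeric(total) - a - b - c
  if (any(c(a, b, c, d) < 0)) {
    stop("incomputable: marginal subtraction produced a negative cell ",
         "(suppression has removed needed information)")
  }
  new("CrossTab", a = a, b = b, c = c, d = d,
      exposure = as.character(exposure), outcome = as.character(outcome))
}

#' Build a 2x2 table directly from cell counts
#' @param a,b,c,d non-negative cell counts.
#' @param exposure,outcome axis labels c(variable, level).
#' @return a [CrossTab-class].
#' @export
crossTabFromCells <- function(a, b, c, d,
                              exposure = c("exposure", "yes"),
                              outcome = c("outcome", "yes")) {
  new("CrossTab", a = a, b = b, c = c, d = d,
      exposure = exposure, outcome = outcome)
}

ctCells <- function(t) c(a = t@a, b = t@b, c = t@c, d = t@d)

#' Odds ratio with 95% interval from a 2x2 table
#'
#' (a d)/(b c) with a log-scale Wald interval. A zero cell triggers the
#' Haldane-Anscombe correction (0.5 added to every cell), reported with
#' `corrected = TRUE` rather than silently.
#'
#' @param t a [CrossTab-class].
#' @param conf confidence level (default 0.95).
#' @return list: estimate, lower, upper, conf, corrected.
#' @export
oddsRatio <- function(t, conf = 0.95) {
  x <- ctCells(t)
  corrected <- any(x == 0)
  if (corrected) x <- x + 0.5
  est <- (x["a"] * x["d"]) / (x["b"] * x["c"])
  se <- sqrt(sum(1 / x))
  z <- qnorm(1 - (1 - conf) / 2)
  list(estimate = unname(est),
       lower = unname(exp(log(est) - z * se)),
       upper = unname(exp(log(est) + z * se)),
       conf = conf, corrected = corrected)
}

#' Relative risk with 95% interval from a 2x2 table
#'
#' [a/(a+b)] / [c/(c+d)] with a log-scale Wald interval; zero-cell inputs
#' get the 0.5 correction, flagged.
#'
#' @param t a [CrossTab-class].
#' @param conf confidence level.
#' @return list: estimate, lower, upper, conf, corrected.
#' @export
relativeRisk <- function(t, conf = 0.95) {
  x <- ctCells(t)
  if (x["a"] + x["b"] == 0 || x["c"] + x["d"] == 0) {
    stop("incomputable: a row of the 2x2 table is empty")
  }
  corrected <- any(x == 0)
  if (corrected) x <- x + 0.5
  p1 <- x["a"] / (x["a"] + x["b"])
  p0 <- x["c"] / (x["c"] + x["d"])
  est <- p1 / p0
  se <- sqrt(1 / x["a"] - 1 / (x["a"] + x["b"]) + 1 / x["c"] - 1 / (x["c"] + x["d"]))
  z <- qnorm(1 - (1 - conf) / 2)
  list(estimate = unname(est),
       lower = unname(exp(log(est) - z * se)),
       upper = unname(exp(log(est) + z * se)),
       conf = conf, corrected = corrected)
}

#' Conditional probability from a 2x2 table
#'
#' @param t a [CrossTab-class].
#' @param direction "outcome_given_exposure" (a/(a+b)) or
#'   "exposure_given_outcome" (a/(a+c)).
#' @return numeric(1) probability.
#' @export
conditionalProbability <- function(t, direction = c("outcome_given_exposure",
                                                    "exposure_given_outcome")) {
  direction <- match.arg(direction)
  x <- ctCells(t)
  denom <- if (direction == "outcome_given_exposure") {
    x["a"] + x["b"]
  } else {
    x["a"] + x["c"]
  }
  if (denom == 0) stop("incomputable: zero denominator for ", direction)
  unname(x["a"] / denom)
}

#' Prevalence of a variable level from the aggregate matrix
#'
#' Level marginal count divided by the null-set (total cohort) count.
#'
#' @param matrix an [AggregateMatrix-class].
#' @param variable variable name.
#' @param level level label.
#' @return numeric(1) probability.
#' @export
prevalence <- function(matrix, variable, level) {
  total <- cellOrStop(matrix, setNames(character(0), character(0)), "total")
  if (total == 0) stop("incomputable: empty cohort")
  cnt <- cellOrStop(matrix, setNames(level, variable), "level marginal")
  cnt / total
}

#' Chi-square test of independence on a 2x2 table
#'
#' Closed form N(ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)] with 1 degree of
#' freedom; optional Yates continuity correction (off by default).
#'
#' @param t a [CrossTab-class].
#' @param correct apply the Yates continuity correction.
#' @return list: statistic, df, p.value, corrected.
#' @export
chiSquare <- function(t, correct = FALSE) {
  x <- ctCells(t)
  N <- sum(x)
  margs <- c(x["a"] + x["b"], x["c"] + x["d"], x["a"] + x["c"], x["b"] + x["d"])
  if (any(margs == 0)) stop("incomputable: zero marginal in 2x2 table")
  dev <- abs(x["a"] * x["d"] - x["b"] * x["c"])
  if (correct) dev <- max(0, dev - N / 2)
  stat <- N * dev^2 / prod(margs)
  list(statistic = unname(stat), df = 1L,
       p.value = unname(pchisq(stat, df = 1, lower.tail = FALSE)),
       corrected = correct)
}

#' Monthly trend series for two symptom-detection methods
#'
#' For each month, the percentage of cohort units flagged by the
#' text-derived (NLP) variable and by the ICD-coded variable:
#' 100 * count(month, flag = TRUE) / count(month). Months whose denominator
#' or either numerator cell was removed by suppression are omitted from the
#' series and listed in the `omitted` component.
#'
#' @param matrix an [AggregateMatrix-class].
#' @param nlpVariable name of the boolean NLP-derived symptom variable.
#' @param icdVariable name of the boolean ICD-derived symptom variable.
#' @param monthVariable name of the month variable.
#' @param level level labelling a positive flag (default "TRUE").
#' @return list: `series` data.frame (month, denominator, pctNLP, pctICD),
#'   `omitted` character vector of months dropped for suppression.
#' @export
trendSeries <- function(matrix, nlpVariable, icdVariable,
                        monthVariable = "month", level = "TRUE") {
  for (v in c(nlpVariable, icdVariable, monthVariable)) {
    if (!v %in% matrix@variables) {
      stop("variable '", v, "' not in the aggregate matrix")
    }
  }
  counts <- matrix@counts
  monthRows <- !is.na(counts[[monthVariable]])
  months <- sort(unique(counts[[monthVariable]][monthRows]))
  # a fully suppressed month leaves no row at all; enumerate the study
  # period (from metadata) so such months can still be listed as omitted
  period <- matrix@metadata$period
  if (length(period) == 2 && all(grepl("^\\d{4}-\\d{2}$", period))) {
    months <- sort(union(months, monthSeq(period[1], period[2])))
  }
  suppressed <- !is.na(matrix@metadata$threshold)
  rows <- list()
  omitted <- character()
  for (m in months) {
    denom <- getCell(matrix, setNames(m, monthVariable),
                     absentAsZero = !suppressed)
    nlp <- getCell(matrix, setNames(c(m, level), c(monthVariable, nlpVariable)),
                   absentAsZero = !suppressed)
    icd <- getCell(matrix, setNames(c(m, level), c(monthVariable, icdVariable)),
                   absentAsZero = !suppressed)
    if (is.na(denom) || is.na(nlp) || is.na(icd) || denom == 0) {
      omitted <- c(omitted, m)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      month = m, denominator = denom,
      pctNLP = 100 * nlp / denom, pctICD = 100 * icd / denom,
      stringsAsFactors = FALSE
    )
  }
  series <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(month = character(), denominator = integer(),
               pctNLP = numeric(), pctICD = numeric())
  }
  list(series = series, omitted = omitted)
}
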
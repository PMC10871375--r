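worked2x2 <- function() {
  # {():100, E=1:40, O=1:30, (E=1,O=1):20} -> a=20 b=20 c=10 d=50
  cohort <- data.frame(
    E = c(rep("1", 40), rep("0", 60)),
    O = c(rep("1", 20), rep("0", 20), rep("1", 10), rep("0", 50)),
    stringsAsFactors = FALSE
  )
  cubeCounts(cohort, c("E", "O"))
}

test_that("crosstab extraction by marginal subtraction matches the oracle", {
  ct <- crossTab(worked2x2(), c("E", "1"), c("O", "1"))
  expect_identical(c(ct@a, ct@b, ct@c, ct@d), c(20, 20, 10, 50))
})

test_that("crosstab on a suppressed matrix with a missing cell is incomputable", {
  cohort <- data.frame(
    E = c(rep("1", 5), rep("0", 95)),
    O = c(rep("1", 3), rep("0", 2), rep("1", 27), rep("0", 68)),
    stringsAsFactors = FALSE
  )
  s <- suppressCells(cubeCounts(cohort, c("E", "O")), 10)
  expect_error(crossTab(s, c("E", "1"), c("O", "1")), "incomputable")
  # same extraction on the unsuppressed matrix works (absent cells are
  # exact zeros in the sparse representation)
  expect_identical(crossTab(cubeCounts(cohort, c("E", "O")),
                            c("E", "1"), c("O", "1"))@a, 3)
})

test_that("degenerate identity: joint = both marginals = total", {
  cohort <- data.frame(E = rep("1", 30), O = rep("1", 30),
                       stringsAsFactors = FALSE)
  ct <- crossTab(cubeCounts(cohort, c("E", "O")), c("E", "1"), c("O", "1"))
  expect_identical(c(ct@a, ct@b, ct@c, ct@d), c(30, 0, 0, 0))
})

test_that("odds ratio: closed form, symmetry, zero-cell correction", {
  or <- oddsRatio(crossTabFromCells(20, 10, 5, 15))
  expect_equal(or$estimate, 6.0)
  expect_false(or$corrected)
  expect_true(or$lower < 6 && or$upper > 6)

  expect_equal(oddsRatio(crossTabFromCells(7, 7, 7, 7))$estimate, 1.0)

  z <- oddsRatio(crossTabFromCells(10, 0, 5, 15))
  expect_true(z$corrected)
  expect_equal(z$estimate, (10.5 * 15.5) / (0.5 * 5.5))
})

test_that("relative risk and conditional probability follow their closed forms", {
  t <- crossTabFromCells(10, 20, 30, 40)
  expect_equal(relativeRisk(t)$estimate, (10 / 30) / (30 / 70))
  expect_equal(conditionalProbability(t, "outcome_given_exposure"), 10 / 30)
  expect_equal(conditionalProbability(t, "exposure_given_outcome"), 10 / 40)

  # identical row proportions give RR 1
  expect_equal(relativeRisk(crossTabFromCells(10, 30, 20, 60))$estimate, 1.0)
  expect_error(conditionalProbability(crossTabFromCells(0, 0, 5, 5)),
               "zero denominator")
})

test_that("OR and RR are invariant under scaling all four cells", {
  t1 <- crossTabFromCells(12, 18, 24, 46)
  t5 <- crossTabFromCells(60, 90, 120, 230)
  expect_equal(oddsRatio(t1)$estimate, oddsRatio(t5)$estimate)
  expect_equal(relativeRisk(t1)$estimate, relativeRisk(t5)$estimate)
})

test_that("chi-square matches the closed form and the classical test", {
  t <- crossTabFromCells(10, 20, 30, 40)
  got <- chiSquare(t)
  expect_equal(got$statistic, 100 * (10 * 40 - 20 * 30)^2 /
                 (30 * 70 * 40 * 60))
  expect_equal(got$statistic, 0.79365, tolerance = 1e-4)

  # independent oracle: stats::chisq.test without continuity correction
  ref <- suppressWarnings(chisq.test(matrix(c(10, 20, 30, 40), 2, byrow = TRUE),
                                     correct = FALSE))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p.value, unname(ref$p.value))

  refY <- chisq.test(matrix(c(10, 20, 30, 40), 2, byrow = TRUE), correct = TRUE)
  gotY <- chiSquare(t, correct = TRUE)
  expect_equal(gotY$statistic, unname(refY$statistic))
})

test_that("prevalence is the level marginal over the null-set count", {
  m <- worked2x2()
  expect_equal(prevalence(m, "E", "1"), 0.4)
  degenerate <- cubeCounts(data.frame(E = rep("1", 12)), "E")
  expect_equal(prevalence(degenerate, "E", "1"), 1.0)
})

test_that("aggregate-derived measures equal line-level measures when nothing is suppressed", {
  set.seed(12)
  cohort <- data.frame(
    E = sample(c("TRUE", "FALSE"), 500, replace = TRUE, prob = c(.4, .6)),
    O = sample(c("TRUE", "FALSE"), 500, replace = TRUE, prob = c(.3, .7)),
    stringsAsFactors = FALSE
  )
  m <- cubeCounts(cohort, c("E", "O"))
  ct <- crossTab(m, c("E", "TRUE"), c("O", "TRUE"))
  a <- sum(cohort$E == "TRUE" & cohort$O == "TRUE")
  b <- sum(cohort$E == "TRUE" & cohort$O == "FALSE")
  c_ <- sum(cohort$E == "FALSE" & cohort$O == "TRUE")
  d <- sum(cohort$E == "FALSE" & cohort$O == "FALSE")
  expect_identical(c(ct@a, ct@b, ct@c, ct@d), as.numeric(c(a, b, c_, d)))
  expect_equal(oddsRatio(ct)$estimate, (a * d) / (b * c_))
  expect_equal(prevalence(m, "E", "TRUE"), mean(cohort$E == "TRUE"))
})

test_that("trend series pairs NLP and ICD percentages per month", {
  cohort <- data.frame(
    month = rep(c("2021-01", "2021-02"), each = 50),
    f_nlp = rep(c("TRUE", "FALSE"), times = c(30, 70)),
    f_icd = rep(c("TRUE", "FALSE", "TRUE", "FALSE"), c(15, 35, 10, 40)),
    stringsAsFactors = FALSE
  )
  m <- cubeCounts(cohort, c("month", "f_nlp", "f_icd"))
  tr <- trendSeries(m, "f_nlp", "f_icd")
  expect_identical(tr$series$month, c("2021-01", "2021-02"))
  expect_equal(tr$series$pctNLP, c(60, 0))
  expect_equal(tr$series$pctICD, c(30, 20))
  expect_identical(tr$omitted, character(0))

  # single-month matrix gives a single pair
  one <- cubeCounts(cohort[cohort$month == "2021-01", ],
                    c("month", "f_nlp", "f_icd"))
  expect_identical(nrow(trendSeries(one, "f_nlp", "f_icd")$series), 1L)
})

test_that("months with suppressed denominators are omitted and listed", {
  cohort <- data.frame(
    month = rep(c("2021-01", "2021-02"), times = c(60, 8)),
    f_nlp = rep(c("TRUE", "FALSE", "TRUE"), c(40, 20, 8)),
    f_icd = rep(c("TRUE", "FALSE", "FALSE"), c(15, 45, 8)),
    stringsAsFactors = FALSE
  )
  s <- suppressCells(cubeCounts(cohort, c("month", "f_nlp", "f_icd"),
                                metadata = list(period = c("2021-01", "2021-02"))),
                     10)
  tr <- trendSeries(s, "f_nlp", "f_icd")
  expect_identical(tr$series$month, "2021-01")
  expect_identical(tr$omitted, "2021-02")
})
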
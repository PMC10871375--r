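test_that("cube matches explicit subset enumeration on the worked example", {
  cohort <- data.frame(disease = c("1", "1", "0", "1"),
                       cough = c("1", "0", "0", "1"),
                       stringsAsFactors = FALSE)
  m <- cubeCounts(cohort, c("disease", "cough"))
  want <- setNames(
    c(4L, 3L, 1L, 2L, 2L, 2L, 1L, 1L),
    c("()", "disease=1", "disease=0", "cough=1", "cough=0",
      "disease=1;cough=1", "disease=1;cough=0", "disease=0;cough=0")
  )
  expectSameMap(countsToMap(m), want)
  expectSameMap(countsToMap(m), bruteCubeFilter(cohort, c("disease", "cough")))
  expect_identical(nullSetCount(m), 4L)
})

test_that("empty cohort cubes to a single null-set row of zero", {
  m <- cubeCounts(data.frame(x = character(0), stringsAsFactors = FALSE), "x")
  expect_identical(nrow(aggCounts(m)), 1L)
  expect_identical(nullSetCount(m), 0L)
})

test_that("cube equals the row-filtering oracle on random cohorts", {
  set.seed(41)
  for (rep in 1:25) {
    nv <- sample(1:4, 1)
    cohort <- randomCohort(sample(5:60, 1), nv)
    vars <- names(cohort)
    m <- cubeCounts(cohort, vars)
    expectSameMap(countsToMap(m), bruteCubeFilter(cohort, vars))
  }
})

test_that("marginal consistency and monotone anti-chain hold pre-suppression", {
  set.seed(42)
  cohort <- randomCohort(400, 3)
  m <- cubeCounts(cohort, names(cohort))
  map <- countsToMap(m)
  total <- map[["()"]]
  expect_true(all(map <= total))

  # summing a variable's levels inside a fixed context reproduces the context
  levs <- unique(cohort$v1)
  ctx <- map[["v2=L1"]]
  parts <- vapply(levs, function(l) {
    key <- paste0("v1=", l, ";v2=L1")
    if (key %in% names(map)) map[[key]] else 0L
  }, integer(1))
  expect_identical(sum(parts), ctx)
})

test_that("continuous variables are rejected with advice to bin", {
  cohort <- data.frame(bp = c(120.5, 139.9))
  expect_error(cubeCounts(cohort, "bp"), "bin")
})

test_that("suppression removes only sub-threshold rows and records the threshold", {
  # counts {():15, d=1:12, (d=1,c=1):9}: the 9 goes, the rest stay
  cohort <- data.frame(
    d = c(rep("1", 12), rep("0", 3)),
    c = c(rep("1", 9), rep("0", 6)),
    stringsAsFactors = FALSE
  )
  m <- cubeCounts(cohort, c("d", "c"))
  s <- suppressCells(m, 10)
  map <- countsToMap(s)
  expect_identical(map[["()"]], 15L)
  expect_identical(map[["d=1"]], 12L)
  expect_false("d=1;c=1" %in% names(map))
  expect_true(all(map >= 10))
  expect_identical(suppressionThreshold(s), 10L)

  # threshold 1 is the identity (no zero-count rows exist in the sparse form)
  s1 <- suppressCells(m, 1)
  expectSameMap(countsToMap(s1), countsToMap(m))
})

test_that("a cohort below threshold suppresses to an empty matrix with a refusal", {
  cohort <- data.frame(x = rep("a", 7), stringsAsFactors = FALSE)
  m <- cubeCounts(cohort, "x")
  expect_message(s <- suppressCells(m, 10), "refusal")
  expect_identical(nrow(aggCounts(s)), 0L)
})

test_that("merge sums cellwise, re-suppresses, and unions site metadata", {
  mk <- function(d0, d1, site) {
    cohort <- data.frame(d = c(rep("1", d1), rep("0", d0)),
                         stringsAsFactors = FALSE)
    suppressCells(cubeCounts(cohort, "d", metadata = list(
      sites = site, period = c("2021-01", "2021-12")
    )), 10)
  }
  a <- mk(3, 12, "siteA")  # {():15, d=1:12}; d=0:3 suppressed locally
  b <- mk(9, 11, "siteB")  # {():20, d=1:11}; d=0:9 suppressed locally
  m <- mergeMatrices(list(a, b))
  map <- countsToMap(m)
  expect_identical(map[["()"]], 35L)
  expect_identical(map[["d=1"]], 23L)
  # locally suppressed cells contributed nothing: 3+9=12 would pass the
  # threshold but never reaches the merge
  expect_false("d=0" %in% names(map))
  expect_setequal(aggMetadata(m)$sites, c("siteA", "siteB"))

  expect_identical(countsToMap(mergeMatrices(list(a))), countsToMap(a))
})

test_that("merge is commutative and associative on random site fixtures", {
  set.seed(99)
  for (rep in 1:10) {
    cohorts <- lapply(1:3, function(i) randomCohort(sample(50:150, 1), 2))
    ms <- lapply(seq_along(cohorts), function(i) {
      suppressCells(cubeCounts(cohorts[[i]], c("v1", "v2"), metadata = list(
        sites = paste0("s", i), period = c("2021-01", "2021-12")
      )), 5)
    })
    ab_c <- mergeMatrices(list(mergeMatrices(ms[1:2]), ms[[3]]))
    a_bc <- mergeMatrices(list(ms[[1]], mergeMatrices(ms[2:3])))
    onePass <- mergeMatrices(ms)
    cba <- mergeMatrices(rev(ms))
    expectSameMap(countsToMap(ab_c), countsToMap(onePass))
    expectSameMap(countsToMap(a_bc), countsToMap(onePass))
    expectSameMap(countsToMap(cba), countsToMap(onePass))
  }
})

test_that("merge rejects mismatched variables, periods and thresholds", {
  c1 <- data.frame(a = c("x", "y"), b = c("1", "0"), stringsAsFactors = FALSE)
  mA <- cubeCounts(c1, c("a", "b"), metadata = list(period = c("2021-01", "2021-12")))
  mB <- cubeCounts(c1, c("a"), metadata = list(period = c("2021-01", "2021-12")))
  expect_error(mergeMatrices(list(mA, mB)), "variable lists differ")

  mC <- cubeCounts(c1, c("a", "b"), metadata = list(period = c("2020-01", "2020-12")))
  expect_error(mergeMatrices(list(mA, mC)), "periods differ")

  expect_error(
    mergeMatrices(list(suppressCells(mA, 1), mA)),
    "thresholds differ"
  )
})

test_that("matrix CSV + metadata YAML round-trips, empty cell meaning preserved", {
  set.seed(7)
  cohort <- randomCohort(120, 2)
  m <- suppressCells(cubeCounts(cohort, c("v1", "v2"), metadata = list(
    sites = "siteX", period = c("2021-01", "2021-12"), countUnit = "patients"
  )), 5)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeAggregateMatrix(m, csv)
  back <- readAggregateMatrix(csv)
  expect_identical(aggVariables(back), aggVariables(m))
  expectSameMap(countsToMap(back), countsToMap(m))
  expect_identical(suppressionThreshold(back), 5L)
  expect_identical(aggMetadata(back)$sites, "siteX")
  expect_identical(aggMetadata(back)$period, c("2021-01", "2021-12"))
})

test_that("variable cap guards the power-set explosion", {
  cohort <- as.data.frame(setNames(as.list(as.character(1:12)), paste0("v", 1:12)))
  expect_error(cubeCounts(cohort, paste0("v", 1:12)), "2\\^n")
})
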
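test_that("t-test report handles identity, separation and the Welch formula", {
  r0 <- tTestReport(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_false(r0$reject)

  r1 <- tTestReport(c(1, 2, 3), c(11, 12, 13))
  expect_gt(abs(r1$statistic), 10)
  expect_lt(r1$p, 0.01)
  expect_true(r1$reject)

  # independent direct-formula evaluation of the Welch statistic
  set.seed(5)
  x <- rnorm(12, 1, 2); y <- rnorm(17, 0, 0.5)
  r <- tTestReport(x, y, variant = "welch")
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  tW <- (mean(x) - mean(y)) / sqrt(vx + vy)
  dfW <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  pW <- 2 * pt(-abs(tW), dfW)
  expect_equal(r$statistic, tW, tolerance = 1e-10)
  expect_equal(r$df, dfW, tolerance = 1e-10)
  expect_equal(r$p, pW, tolerance = 1e-10)

  # zero variance in both groups with equal means
  rz <- tTestReport(c(2, 2, 2), c(2, 2, 2))
  expect_equal(rz$statistic, 0)
  expect_equal(rz$p, 1)
})

test_that("chi-square matches the closed contingency formula", {
  # worked example evaluated by hand from n(ad-bc)^2 / row/col products
  r <- chiSquareReport(14, 16, 4, 26, yates = FALSE)
  expect_equal(round(r$statistic, 3), 7.937)
  expect_identical(r$df, 1L)

  # proportional rows give exactly zero
  expect_equal(chiSquareReport(10, 20, 5, 10)$statistic, 0)

  # random tables vs the direct formula
  set.seed(8)
  for (i in 1:25) {
    cells <- rmultinom(1, 60, c(0.3, 0.25, 0.25, 0.2))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    if ((a + b) * (c + d) * (a + c) * (b + d) == 0) next
    n <- a + b + c + d
    direct <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(chiSquareReport(a, b, c, d)$statistic, direct,
                 tolerance = 1e-10)
  }
  expect_error(chiSquareReport(0, 0, 3, 4), "margin")
})

test_that("Fisher exact equals full hypergeometric enumeration", {
  expect_equal(fisherReport(2, 0, 0, 2)$p, 1 / 3, tolerance = 1e-12)

  fisherEnum <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    kk <- max(0, k - n):min(k, m)
    pr <- dhyper(kk, m, n, k)
    sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  set.seed(13)
  for (i in 1:30) {
    tot <- sample(8:40, 1)
    cells <- rmultinom(1, tot, runif(4, 0.1, 1))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    if ((a + b) * (c + d) * (a + c) * (b + d) == 0) next
    expect_equal(fisherReport(a, b, c, d)$p, fisherEnum(a, b, c, d),
                 tolerance = 1e-9)
  }
})

test_that("rate comparison falls back to Fisher for sparse expectations", {
  sparse <- compareRates(2, 28, 0, 30)
  expect_match(sparse$chosen, "fisher")
  dense <- compareRates(14, 16, 4, 26)
  expect_identical(dense$chosen, "chi-square")
})

test_that("rank-sum test enumerates small samples and approximates large ones", {
  r <- rankSumReport(c(1, 2), c(10, 20))
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)   # 2 of 6 rank assignments

  # same values in both groups: no evidence of a shift
  expect_equal(rankSumReport(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # exact and normal-approximate p agree at n = 10
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10, 0.3)
    pe <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    pa <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("positivity rates print as round-half-up integer percent", {
  r <- positivityRates(c(14, 4), c(30, 30))
  expect_identical(r$rate_percent, c(47, 13))
  expect_identical(positivityRates(0, 30)$rate_percent, 0)
  expect_identical(positivityRates(15, 30)$rate_percent, 50)
  expect_identical(positivityRates(1, 8)$rate_percent, 13)  # 12.5 rounds up
  expect_error(positivityRates(1, 0), "empty")
})

test_that("cohort report assembles every result block deterministically", {
  coh <- makeCohort(cohortSpec(n_per_group = 30, seed = 3))$table
  rep1 <- cohortReport(coh)
  expect_s3_class(rep1, "cohortReport")
  for (blk in c("Lacunar infarctions", "Microbleed positivity",
                "Microbleed counts", "Vertebral artery dominance",
                "Basilar curvature abnormality"))
    expect_match(rep1$markdown, blk)
  expect_identical(rep1$markdown, cohortReport(coh)$markdown)

  # identical groups: nothing is significant
  half <- coh[coh$group == "case", ]
  both <- rbind(half, transform(half, group = "control",
                                subject_id = paste0("X", subject_id)))
  repNull <- cohortReport(both)
  expect_false(repNull$lacunes$reject)
  expect_false(repNull$positivity$test$reject)
  expect_false(repNull$dominance$test$reject)

  expect_error(cohortReport(coh[, -3]), "lacune_count")

  dir <- withr::local_tempdir()
  paths <- writeCohortReport(rep1, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[2])
  expect_true(all(c("lacunes", "positivity", "dominance") %in% names(js)))
})

test_that("the study-sized lacune contrast is detected in most replicates", {
  # Welch test power under the reported group means/SDs at n = 30
  set.seed(17)
  rejects <- 0L
  reps <- 200
  for (i in seq_len(reps)) {
    x <- rnorm(30, 2.400, 3.358)
    y <- rnorm(30, 0.672, 1.252)
    rejects <- rejects + tTestReport(x, y)$reject
  }
  expect_gt(rejects / reps, 0.5)
})
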
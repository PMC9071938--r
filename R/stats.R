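#' Two-group t-test report
#'
#' Independent-samples t-test (Welch by default; Student by flag) with
#' group summaries reported as mean +/- SD. Degenerate input (zero variance
#' in both groups with equal means) yields t = 0, p = 1.
#'
#' @param x,y numeric vectors (n >= 2 each)
#' @param variant "welch" or "student"
#' @param alpha significance level
#' @return list: test, statistic, df, p, reject, summaries
#' @export
tTestReport <- function(x, y, variant = c("welch", "student"), alpha = 0.05) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    res <- list(statistic = 0, parameter = length(x) + length(y) - 2,
                p.value = 1)
  } else {
    res <- stats::t.test(x, y, var.equal = variant == "student")
  }
  p <- unname(res$p.value)
  list(test = paste0(variant, " t-test"),
       statistic = unname(res$statistic), df = unname(res$parameter),
       p = p, reject = p < alpha,
       summaries = data.frame(
         group = c("x", "y"), n = c(length(x), length(y)),
         mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y))))
}

.checkTable <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    stop("contingency table has a zero margin")
  invisible(cells)
}

#' Chi-square test on a 2x2 contingency table
#'
#' Rows are groups, columns positive/negative. Optional Yates continuity
#' correction.
#'
#' @param a,b,c,d table cells (row 1: a positives, b negatives; row 2: c, d)
#' @param yates apply the continuity correction?
#' @param alpha significance level
#' @return list: test, statistic, df, p, reject, expected
#' @export
chiSquareReport <- function(a, b, c, d, yates = FALSE, alpha = 0.05) {
  .checkTable(a, b, c, d)
  tab <- matrix(c(a, c, b, d), 2, 2)
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  p <- unname(res$p.value)
  list(test = if (yates) "chi-square (Yates)" else "chi-square",
       statistic = unname(res$statistic), df = unname(res$parameter),
       p = p, reject = p < alpha, expected = res$expected)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by hypergeometric enumeration (tables as or less probable
#' than the observed one).
#'
#' @inheritParams chiSquareReport
#' @return list: test, statistic (odds ratio estimate), p, reject
#' @export
fisherReport <- function(a, b, c, d, alpha = 0.05) {
  .checkTable(a, b, c, d)
  tab <- matrix(c(a, c, b, d), 2, 2)
  res <- stats::fisher.test(tab)
  p <- unname(res$p.value)
  list(test = "fisher exact", statistic = unname(res$estimate), df = NA,
       p = p, reject = p < alpha)
}

#' Group-rate comparison with automatic test choice
#'
#' Uses the chi-square test, falling back to Fisher's exact test when any
#' expected cell is below 5.
#'
#' @inheritParams chiSquareReport
#' @return the chosen test's report, with an extra \code{chosen} element
#' @export
compareRates <- function(a, b, c, d, yates = FALSE, alpha = 0.05) {
  .checkTable(a, b, c, d)
  tab <- matrix(c(a, c, b, d), 2, 2)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd < 5)) {
    rep <- fisherReport(a, b, c, d, alpha)
    rep$chosen <- "fisher (expected cell < 5)"
  } else {
    rep <- chiSquareReport(a, b, c, d, yates, alpha)
    rep$chosen <- "chi-square"
  }
  rep
}

#' Wilcoxon rank-sum report
#'
#' Two-sided rank-sum test with midrank ties; exact enumeration for
#' small untied samples (n <= 10 per group), normal approximation with
#' continuity correction otherwise.
#'
#' @param x,y numeric vectors
#' @param alpha significance level
#' @return list: test, statistic (W), p, reject
#' @export
rankSumReport <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  exact <- length(x) <= 10 && length(y) <= 10
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                             correct = TRUE))
  p <- unname(res$p.value)
  list(test = "wilcoxon rank-sum", statistic = unname(res$statistic),
       df = NA, p = p, reject = p < alpha)
}

#' Per-group positivity rates
#'
#' Rates as integer percent with round-half-up (so 14/30 prints as 47 and
#' 4/30 as 13).
#'
#' @param positives vector of per-group positive counts
#' @param sizes vector of group sizes (> 0)
#' @return data.frame: positives, n, rate_percent
#' @export
positivityRates <- function(positives, sizes) {
  if (any(sizes <= 0)) stop("empty group")
  if (any(positives > sizes)) stop("positives exceed group size")
  data.frame(positives = positives, n = sizes,
             rate_percent = roundHalfUp(100 * positives / sizes))
}

#' Full cohort report
#'
#' Reproduces the result layout of the study design on any cohort table:
#' lacunar-infarct counts (t-test), microbleed positivity (chi-square /
#' Fisher with rates), microbleed counts (t-test and rank-sum), vertebral
#' dominance rates, and basilar-curvature abnormality rates. No
#' multiple-testing correction is applied (noted in the footer).
#'
#' @param cohort data.frame with columns group, lacune_count, cmb_count,
#'   cmb_positive, dominant_side (and optionally curvature_type)
#' @param alpha significance level
#' @return list of class "cohortReport": per-block results plus a
#'   \code{markdown} rendering
#' @export
cohortReport <- function(cohort, alpha = 0.05) {
  need <- c("group", "lacune_count", "cmb_count", "cmb_positive",
            "dominant_side")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  cs <- cohort[cohort$group == "case", ]
  ct <- cohort[cohort$group == "control", ]
  if (!nrow(cs) || !nrow(ct)) stop("both groups must be present")

  # a rate test degenerates when one outcome column is empty in both
  # groups (legitimate in small cohorts); report it as not applicable
  safeRates <- function(a, b, c, d) {
    if ((a + c) == 0 || (b + d) == 0)
      list(test = "rate comparison (not applicable: zero margin)",
           statistic = NA_real_, df = NA, p = NA_real_, reject = FALSE,
           chosen = "none")
    else compareRates(a, b, c, d, alpha = alpha)
  }
  lac <- tTestReport(cs$lacune_count, ct$lacune_count, alpha = alpha)
  posCells <- c(sum(cs$cmb_positive), sum(!cs$cmb_positive),
                sum(ct$cmb_positive), sum(!ct$cmb_positive))
  positivity <- list(
    rates = positivityRates(c(posCells[1], posCells[3]),
                            c(nrow(cs), nrow(ct))),
    test = safeRates(posCells[1], posCells[2], posCells[3], posCells[4]))
  cmbN <- list(t = tTestReport(cs$cmb_count, ct$cmb_count, alpha = alpha),
               ranksum = rankSumReport(cs$cmb_count, ct$cmb_count, alpha))
  domCells <- c(sum(cs$dominant_side != "none"),
                sum(cs$dominant_side == "none"),
                sum(ct$dominant_side != "none"),
                sum(ct$dominant_side == "none"))
  dominance <- list(
    rates = positivityRates(c(domCells[1], domCells[3]),
                            c(nrow(cs), nrow(ct))),
    test = safeRates(domCells[1], domCells[2], domCells[3], domCells[4]))
  curvature <- NULL
  if ("curvature_type" %in% names(cohort)) {
    cc <- c(sum(cs$curvature_type != "normal"),
            sum(cs$curvature_type == "normal"),
            sum(ct$curvature_type != "normal"),
            sum(ct$curvature_type == "normal"))
    curvature <- list(
      rates = positivityRates(c(cc[1], cc[3]), c(nrow(cs), nrow(ct))),
      test = safeRates(cc[1], cc[2], cc[3], cc[4]))
  }
  fmt <- function(r) {
    if (is.na(r$p)) return(r$test)
    sprintf("%s: statistic = %.3f, p = %.4f (%s at alpha = %g)",
            r$test, r$statistic, r$p,
            if (r$reject) "reject" else "not significant", alpha)
  }
  ms <- function(v) sprintf("%.3f +/- %.3f", mean(v), stats::sd(v))
  md <- c(
    "# Cohort report", "",
    sprintf("## Lacunar infarctions (n = %d vs %d)", nrow(cs), nrow(ct)),
    sprintf("- case %s, control %s", ms(cs$lacune_count), ms(ct$lacune_count)),
    paste0("- ", fmt(lac)), "",
    "## Microbleed positivity",
    sprintf("- case %d/%d (%d%%), control %d/%d (%d%%)",
            posCells[1], nrow(cs), positivity$rates$rate_percent[1],
            posCells[3], nrow(ct), positivity$rates$rate_percent[2]),
    paste0("- ", fmt(positivity$test)), "",
    "## Microbleed counts",
    sprintf("- case %s, control %s", ms(cs$cmb_count), ms(ct$cmb_count)),
    paste0("- ", fmt(cmbN$t)),
    paste0("- ", fmt(cmbN$ranksum)), "",
    "## Vertebral artery dominance",
    sprintf("- case %d/%d (%d%%), control %d/%d (%d%%)",
            domCells[1], nrow(cs), dominance$rates$rate_percent[1],
            domCells[3], nrow(ct), dominance$rates$rate_percent[2]),
    paste0("- ", fmt(dominance$test)))
  if (!is.null(curvature)) {
    md <- c(md, "",
            "## Basilar curvature abnormality",
            sprintf("- case %d%%, control %d%%",
                    curvature$rates$rate_percent[1],
                    curvature$rates$rate_percent[2]),
            paste0("- ", fmt(curvature$test)))
  }
  md <- c(md, "", "_No multiple-testing correction applied._")
  structure(list(lacunes = lac, positivity = positivity, cmb_counts = cmbN,
                 dominance = dominance, curvature = curvature,
                 alpha = alpha, markdown = paste(md, collapse = "\n")),
            class = "cohortReport")
}

#' @export
print.cohortReport <- function(x, ...) {
  cat(x$markdown, "\n")
  invisible(x)
}

#' Write a cohort report to disk (Markdown + JSON)
#' @param report a \code{cohortReport}
#' @param dir output directory
#' @return invisibly, the two file paths
#' @export
writeCohortReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mdPath <- file.path(dir, "report.md")
  writeLines(report$markdown, mdPath)
  jsPath <- file.path(dir, "report.json")
  clean <- report[setdiff(names(report), "markdown")]
  jsonlite::write_json(clean, jsPath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(mdPath, jsPath))
}
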
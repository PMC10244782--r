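test_that("display rounding and p-value formatting follow the half-up rule", {
  expect_equal(roundHalfUp(21.445, 2), 21.45)
  expect_equal(roundHalfUp(2.384, 2), 2.38)
  expect_equal(roundHalfUp(-0.125, 2), -0.13)
  expect_identical(formatP(c(0.0004, 0.0005, 0.00124, 0.0207)),
                   c("<0.001", "0.001", "0.001", "0.021"))
})

test_that("chi-squared test matches the direct computation and flags zero margins", {
  ## case-control ppCNV burden contingency: carriers 162/1762 vs 11/303
  m <- matrix(c(162, 1600, 11, 292), nrow = 2, byrow = TRUE)
  ct <- chi2Test(m)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(ct$statistic, sum((m - e)^2 / e), tolerance = 1e-12)
  expect_equal(ct$p_value, stats::pchisq(ct$statistic, 1, lower.tail = FALSE))
  expect_equal(roundHalfUp(ct$p_value, 3), 0.001)
  ## uncorrected by default, Yates on request
  expect_lt(ct$p_value, chi2Test(m, correct = TRUE)$p_value)
  ## property: agrees with chisq.test on random tables
  set.seed(7)
  for (i in 1:50) {
    t2 <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(chi2Test(t2)$p_value,
                 suppressWarnings(stats::chisq.test(t2, correct = FALSE))$p.value)
  }
  expect_error(chi2Test(matrix(c(0, 0, 3, 5), 2)), "fisherExact")
  expect_error(chi2Test(matrix(c(1.5, 2, 3, 5), 2)), "non-negative integers")
})

test_that("Fisher's exact test reproduces stats::fisher.test", {
  set.seed(11)
  for (i in 1:60) {
    m <- matrix(rpois(4, 6), 2)
    if (sum(m) == 0) next
    expect_equal(fisherExact(m), stats::fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
  m <- matrix(c(9, 5, 153, 1595), 2, byrow = TRUE)
  expect_equal(fisherExact(m), stats::fisher.test(m)$p.value, tolerance = 1e-9)
  expect_error(fisherExact(matrix(0, 2, 2)), "empty table")
})

test_that("Welch t from summary statistics matches t.test on raw data", {
  set.seed(3)
  a <- rnorm(40, 10, 2); b <- rnorm(70, 11, 4)
  wt <- welchT(a, b)
  tt <- stats::t.test(a, b)
  expect_equal(wt$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(wt$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(wt$p_value, tt$p.value, tolerance = 1e-12)
  ## summary form gives the identical result
  ws <- welchT(c(mean(a), sd(a), 40), c(mean(b), sd(b), 70))
  expect_equal(ws$p_value, wt$p_value, tolerance = 1e-12)
  ## published-style summaries: weight comparison of the modeled cohort
  expect_equal(roundHalfUp(
    welchT(c(10.35, 5.78, 162), c(11.50, 7.75, 1600))$p_value, 4), 0.0207,
    tolerance = 1e-9)
  ## degenerate variance
  expect_equal(welchT(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  expect_equal(welchT(c(2, 2, 2), c(1, 1, 1))$p_value, 0)
  expect_error(welchT(1, c(1, 2)), "n >= 2")
})

test_that("detection rates and count expansion agree with the cohort counts", {
  cnt <- chdCohortCounts()
  flags <- cohortFlagsFromCounts(cnt)
  expect_identical(nrow(flags), 1762L)
  r <- detectionRates(flags)
  rr <- stats::setNames(r$percent, r$metric)
  expect_equal(unname(rr["any_cnv"]), 21.45)
  expect_equal(unname(rr["multiple_cnv"]), 2.38)
  expect_equal(unname(rr["ppcnv"]), 9.19)
  expect_equal(unname(rr["aneuploidy"]), 2.04)
  expect_equal(unname(rr["del22q11_or_dup"]), 2.38)
  expect_equal(unname(rr["other_syndrome"]), 4.77)
  ## nesting invariants
  expect_true(all(flags$ppcnv[flags$aneuploidy]))
  expect_true(all(flags$any_cnv[flags$ppcnv]))
  expect_identical(sum(flags$aneuploidy) + sum(flags$del22q11_or_dup) +
                     sum(flags$other_syndrome), sum(flags$ppcnv))
  expect_error(detectionRates(flags[0, ]), "empty cohort")
})

test_that("subgroup analysis builds one-vs-rest tables", {
  flags <- data.frame(sample_id = sprintf("s%02d", 1:40),
                      ppcnv = rep(c(TRUE, FALSE), c(10, 30)))
  clin <- data.frame(sample_id = flags$sample_id,
                     subgroup = rep(c("A", "B"), each = 20))
  ## A: 10/20 carriers, B: 0/20
  flags$ppcnv <- c(rep(TRUE, 10), rep(FALSE, 10), rep(FALSE, 20))
  sa <- subgroupAnalysis(flags, clin)
  rownames(sa) <- sa$subgroup
  expect_identical(sa["A", "n_present"], 10L)
  expect_equal(sa["A", "percent_present"], 50)
  m <- matrix(c(10, 10, 0, 20), 2, byrow = TRUE)
  expect_equal(sa["A", "p_value"], chi2Test(m)$p_value)
  expect_identical(unique(sa$method), "chi2")
  ## expected-count rule switches small comparisons to Fisher
  sa2 <- subgroupAnalysis(flags, clin, fisher_rule = "expected_lt5")
  expect_identical(unique(sa2$method), "chi2")  # expected counts all >= 5
  flags3 <- data.frame(sample_id = sprintf("s%02d", 1:40),
                       ppcnv = c(TRUE, rep(FALSE, 39)))
  sa3 <- subgroupAnalysis(flags3, clin, fisher_rule = "expected_lt5")
  expect_identical(unique(sa3$method), "fisher")
  expect_error(subgroupAnalysis(flags, clin[1:30, ]), "lacks some samples")
})

test_that("report assembly joins flags to clinical covariates", {
  pan <- smallPanel()
  n_car <- 40; n_non <- 160
  ids <- sprintf("S%04d", seq_len(n_car + n_non))
  tr <- diploidTruth(ids)
  rid <- S4Vectors::mcols(regions(pan))$region_id[1]
  for (s in ids[seq_len(n_car)]) tr <- withCnv(tr, pan, s, rid, 1)
  clin <- simulateClinical(tr, seed = 2)
  flags <- data.frame(sample_id = ids, any_cnv = FALSE, multiple_cnv = FALSE,
                      ppcnv = ids %in% ids[seq_len(n_car)],
                      aneuploidy = FALSE, del22q11_or_dup = FALSE,
                      other_syndrome = FALSE)
  rep <- buildReport(flags, clin)
  expect_identical(rep$n_total, 200L)
  expect_identical(unname(rep$group_sizes["carrier"]), 40L)
  expect_true(all(c("male_sex", "complex_surgery", "weight_kg", "cpbt_min") %in%
                    rep$tests$comparison))
  expect_identical(
    rep$tests$method[rep$tests$comparison == "weight_kg"], "welch_t")
  expect_true(all(rep$tests$p_value >= 0 & rep$tests$p_value <= 1))
  expect_identical(sort(unique(rep$subgroups$subgroup)),
                   sort(unique(clin$subgroup)))
  d <- withr::local_tempdir()
  writeReport(rep, d)
  expect_true(all(file.exists(file.path(
    d, c("report.json", "rates.tsv", "tests.tsv", "subgroups.tsv")))))
  j <- jsonlite::read_json(file.path(d, "report.json"))
  expect_identical(j$n_total, 200L)
  expect_error(buildReport(flags[1:10, ], clin), "different samples")
})
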
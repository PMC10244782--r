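#' Half-up rounding
#'
#' Rounds halves away from zero (the display convention used for the
#' percentages and p-values this package reports), unlike base `round()`'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Format a p-value for reporting
#'
#' Three decimals, half-up, with `"<0.001"` below 0.0005.
#'
#' @param p numeric p-values.
#' @return Character vector.
#' @export
formatP <- function(p) {
  ifelse(p < 0.0005, "<0.001", sprintf("%.3f", roundHalfUp(p, 3)))
}

#' Cohort detection rates
#'
#' Rates of each abnormality flag over the cohort, as numerator,
#' denominator and percent (half-up, 2 decimals).
#'
#' @param flags per-sample flag table from [flagPpcnv()].
#' @return `data.frame` with one row per metric.
#' @export
detectionRates <- function(flags) {
  if (!nrow(flags)) stop("empty cohort")
  metrics <- setdiff(colnames(flags), "sample_id")
  den <- nrow(flags)
  num <- vapply(metrics, function(m) sum(flags[[m]]), numeric(1))
  data.frame(metric = metrics, numerator = as.integer(num), denominator = den,
             percent = roundHalfUp(100 * num / den, 2), row.names = NULL,
             stringsAsFactors = FALSE)
}

.as2x2 <- function(t) {
  m <- matrix(as.numeric(t), nrow = 2, byrow = FALSE)
  if (is.matrix(t) && all(dim(t) == c(2, 2))) m <- matrix(as.numeric(t), 2)
  if (any(m < 0) || any(m != floor(m))) stop("counts must be non-negative integers")
  m
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected by default: the screening-cohort comparisons this package
#' reproduces were computed without continuity correction. Yates correction
#' available by flag.
#'
#' @param t 2x2 matrix of counts (rows = group, columns = outcome).
#' @param correct apply Yates continuity correction.
#' @return list with `statistic`, `p_value`, `df` (always 1).
#' @export
chi2Test <- function(t, correct = FALSE) {
  m <- .as2x2(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("a margin of the 2x2 table is zero; use fisherExact()")
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value), df = 1)
}

#' Fisher's exact test on a 2x2 table (two-sided)
#'
#' Two-sided p-value by summing, over all tables with the observed margins,
#' the hypergeometric probabilities not exceeding that of the observed
#' table (with the customary relative tolerance for ties).
#'
#' @param t 2x2 matrix of counts.
#' @return Two-sided p-value.
#' @export
fisherExact <- function(t) {
  m <- .as2x2(t)
  if (sum(m) == 0) stop("empty table")
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  lo <- max(0, c1 - r2)
  p <- .fisherPvec(r1, r2, c1)
  unname(p[m[1, 1] - lo + 1])
}

## two-sided p for every admissible top-left cell a of the margin set
## (r1, r2 row sums; c1 first column sum)
.fisherPvec <- function(r1, r2, c1) {
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  k <- lo:hi
  pr <- stats::dhyper(k, r1, r2, c1)
  keep <- outer(pr, pr * (1 + 1e-7), "<=")
  pmin(1, colSums(pr * keep))
}

#' Welch two-sample t-test from summaries or raw vectors
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, two-sided. Arguments are either raw numeric vectors or
#' summaries `c(mean, sd, n)`; the published group comparisons of the
#' modeled cohort are reproducible from their printed summary statistics
#' only under this unequal-variance form.
#'
#' @param a,b numeric vector of observations, or `c(mean, sd, n)`.
#' @param summary set `TRUE` to force interpreting length-3 inputs as
#'   `c(mean, sd, n)` (the default when both inputs have length 3 and
#'   integer third element).
#' @return list with `t`, `df`, `p_value`.
#' @export
welchT <- function(a, b, summary = NULL) {
  as_sum <- function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x))
  looks_sum <- function(x) length(x) == 3 && x[3] >= 2 && x[3] == floor(x[3])
  if (is.null(summary)) summary <- looks_sum(a) && looks_sum(b)
  sa <- if (summary) c(a[[1]], a[[2]], a[[3]]) else unname(as_sum(a))
  sb <- if (summary) c(b[[1]], b[[2]], b[[3]]) else unname(as_sum(b))
  if (sa[3] < 2 || sb[3] < 2) stop("each group needs n >= 2")
  if (sa[2] < 0 || sb[2] < 0) stop("negative SD")
  va <- sa[2]^2 / sa[3]; vb <- sb[2]^2 / sb[3]
  if (va + vb == 0) {
    return(list(t = if (sa[1] == sb[1]) 0 else Inf * sign(sa[1] - sb[1]),
                df = sa[3] + sb[3] - 2,
                p_value = if (sa[1] == sb[1]) 1 else 0))
  }
  tt <- (sa[1] - sb[1]) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (sa[3] - 1) + vb^2 / (sb[3] - 1))
  list(t = tt, df = df, p_value = 2 * stats::pt(-abs(tt), df))
}

#' Subgroup one-vs-rest ppCNV association
#'
#' For each CHD subgroup, a 2x2 of (subgroup vs rest) x (ppCNV present vs
#' absent), tested with the uncorrected chi-squared by default; setting
#' `fisher_rule = "expected_lt5"` switches a comparison to Fisher's exact
#' test when any expected cell count falls below 5.
#'
#' @param flags per-sample flag table (needs `sample_id`, `ppcnv`).
#' @param clinical clinical sheet with `sample_id` and `subgroup`.
#' @param fisher_rule `"never"` (default) or `"expected_lt5"`.
#' @return `data.frame` with per-subgroup counts, carrier percent, test
#'   method and p-value.
#' @export
subgroupAnalysis <- function(flags, clinical,
                             fisher_rule = c("never", "expected_lt5")) {
  fisher_rule <- match.arg(fisher_rule)
  if (!all(flags$sample_id %in% clinical$sample_id))
    stop("clinical sheet lacks some samples")
  sub <- clinical$subgroup[match(flags$sample_id, clinical$sample_id)]
  if (any(is.na(sub))) stop("missing subgroup for some samples")
  groups <- unique(sub)
  if (length(groups) < 2) stop("subgroup analysis needs at least 2 subgroups")
  pp <- flags$ppcnv
  out <- lapply(groups, function(g) {
    a <- sum(pp & sub == g); b <- sum(!pp & sub == g)
    c_ <- sum(pp & sub != g); d <- sum(!pp & sub != g)
    m <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
    exp_min <- min(outer(rowSums(m), colSums(m)) / sum(m))
    use_fisher <- fisher_rule == "expected_lt5" && exp_min < 5
    p <- if (use_fisher) fisherExact(m) else chi2Test(m)$p_value
    data.frame(subgroup = g, n = a + b, n_present = a, n_absent = b,
               percent_present = roundHalfUp(100 * a / (a + b), 2),
               method = if (use_fisher) "fisher" else "chi2", p_value = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assemble the cohort report
#'
#' Joins per-sample abnormality flags to the clinical sheet and computes
#' the full results set: detection rates; carrier vs non-carrier
#' comparisons (sex and complex surgery by chi-squared, the continuous
#' covariates by Welch's t, complications and outcome by chi-squared or
#' Fisher when a margin is degenerate); and the subgroup table.
#'
#' @param flags per-sample flag table from [flagPpcnv()].
#' @param clinical clinical sheet.
#' @param fisher_rule passed to [subgroupAnalysis()].
#' @return list with `n_total`, `rates`, `group_sizes`, `tests`
#'   (`data.frame` of comparison/statistic/p/method) and `subgroups`.
#' @export
buildReport <- function(flags, clinical, fisher_rule = "never") {
  if (!setequal(flags$sample_id, clinical$sample_id))
    stop("flag table and clinical sheet cover different samples")
  cl <- clinical[match(flags$sample_id, clinical$sample_id), ]
  carrier <- flags$ppcnv
  rates <- detectionRates(flags)
  tests <- list()
  add <- function(name, statistic, p, method)
    tests[[length(tests) + 1]] <<- data.frame(
      comparison = name, statistic = statistic, p_value = p,
      p_display = formatP(p), method = method, stringsAsFactors = FALSE)
  test2x2 <- function(name, yes) {
    m <- matrix(c(sum(yes & carrier), sum(!yes & carrier),
                  sum(yes & !carrier), sum(!yes & !carrier)),
                nrow = 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0))
      add(name, NA, fisherExact(m), "fisher")
    else {
      ct <- chi2Test(m)
      add(name, ct$statistic, ct$p_value, "chi2")
    }
  }
  test2x2("male_sex", cl$sex == "XY")
  test2x2("complex_surgery", cl$complex_surgery)
  for (f in intersect(c("age_months", "weight_kg", "cpbt_min", "acct_min",
                        "mvt_min"), colnames(cl))) {
    wt <- welchT(cl[[f]][carrier], cl[[f]][!carrier])
    add(f, wt$t, wt$p_value, "welch_t")
  }
  comp_cols <- setdiff(colnames(cl),
                       c("sample_id", "sex", "subgroup", "complex_surgery",
                         "age_months", "weight_kg", "cpbt_min", "acct_min",
                         "mvt_min", "outcome"))
  for (f in comp_cols) if (is.logical(cl[[f]])) test2x2(f, cl[[f]])
  if ("outcome" %in% colnames(cl))
    test2x2("died_1mo", cl$outcome == "died_1mo")
  list(n_total = nrow(flags), rates = rates,
       group_sizes = c(carrier = sum(carrier), noncarrier = sum(!carrier)),
       tests = do.call(rbind, tests),
       subgroups = if ("subgroup" %in% colnames(cl))
         subgroupAnalysis(flags, cl, fisher_rule) else NULL)
}

#' Write a cohort report
#'
#' Emits `report.json` plus human-readable `rates.tsv`, `tests.tsv` and
#' `subgroups.tsv` under `outdir`.
#'
#' @param report output of [buildReport()].
#' @param outdir output directory.
#' @return The directory, invisibly.
#' @export
writeReport <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wt <- function(x, f) if (!is.null(x))
    utils::write.table(x, file.path(outdir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(report$rates, "rates.tsv")
  wt(report$tests, "tests.tsv")
  wt(report$subgroups, "subgroups.tsv")
  invisible(outdir)
}

#' Abnormality counts of the modeled screening cohort
#'
#' The published carrier counts of the 1,762-patient congenital heart
#' disease screening cohort this package models: 378 samples with at least
#' one CNV, 42 with multiple CNVs, 162 ppCNV carriers (36 whole-chromosome
#' aneuploidies, 42 22q11 deletions/duplications, 84 other recurrent
#' microdeletion/microduplication syndromes), and 11 ppCNV carriers among
#' 303 population controls.
#'
#' @return Named list of counts.
#' @export
chdCohortCounts <- function() {
  list(n_total = 1762, any_cnv = 378, multiple_cnv = 42, ppcnv = 162,
       aneuploidy = 36, del22q11_or_dup = 42, other_syndrome = 84,
       n_controls = 303, control_ppcnv = 11)
}

#' Expand cohort counts to a per-sample flag table
#'
#' Builds a per-sample boolean flag table whose column sums equal the given
#' cohort counts, with nesting consistent with the flag semantics (ppCNV
#' carriers partitioned into aneuploidy, 22q11 and other-syndrome;
#' multiple-CNV samples drawn from the carriers).
#'
#' @param counts named list as from [chdCohortCounts()].
#' @return Flag `data.frame` in the layout of [flagPpcnv()] output.
#' @export
cohortFlagsFromCounts <- function(counts = chdCohortCounts()) {
  n <- counts$n_total
  idx <- function(k, from = 1) seq_len(n) >= from & seq_len(n) < from + k
  f <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                  any_cnv = idx(counts$any_cnv),
                  multiple_cnv = idx(counts$multiple_cnv),
                  ppcnv = idx(counts$ppcnv),
                  aneuploidy = idx(counts$aneuploidy),
                  del22q11_or_dup = idx(counts$del22q11_or_dup,
                                        from = counts$aneuploidy + 1),
                  other_syndrome = idx(counts$other_syndrome,
                                       from = counts$aneuploidy +
                                         counts$del22q11_or_dup + 1),
                  stringsAsFactors = FALSE)
  stopifnot(sum(f$ppcnv) == counts$aneuploidy + counts$del22q11_or_dup +
              counts$other_syndrome)
  f
}
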
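mkCall <- function(id, chrom, start, end, svtype = "DEL") {
  data.frame(sample_id = id, chrom = as.character(chrom), start = start,
             end = end, svtype = svtype,
             copy_number = if (svtype == "DEL") 1L else 3L,
             n_support_probes = 4L, region_id = NA_character_,
             mean_ratio = if (svtype == "DEL") 1 else 3,
             stringsAsFactors = FALSE)
}

## call spanning exactly the panel region an event targets
eventCall <- function(id, ev_row, panel) {
  reg <- regions(panel)
  k <- match(ev_row$region_id, S4Vectors::mcols(reg)$region_id)
  mkCall(id, as.character(GenomicRanges::seqnames(reg))[k],
         GenomicRanges::start(reg)[k], GenomicRanges::end(reg)[k],
         ev_row$svtype)
}

## interval on `chrom` with no overlap against any knowledge-base track
freeCall <- function(id, kb, chrom = "13", svtype = "DEL") {
  tracks <- list(kb@syndromes, kb@populationCnvs, kb@benignListed, kb@genes)
  for (s in seq(20e6, 100e6, by = 2e6)) {
    hit <- any(vapply(tracks, function(tr) {
      tr <- tr[as.character(GenomicRanges::seqnames(tr)) == chrom]
      any(GenomicRanges::start(tr) <= s + 1e6 & GenomicRanges::end(tr) >= s)
    }, logical(1)))
    if (!hit) return(mkCall(id, chrom, s, s + 1e6, svtype))
  }
  stop("no free interval found")
}

test_that("reciprocalOverlap is symmetric, bounded and exact", {
  expect_identical(reciprocalOverlap("1", 100, 199, "1", 100, 199), 1)
  expect_identical(reciprocalOverlap("1", 100, 199, "1", 300, 399), 0)
  expect_identical(reciprocalOverlap("1", 100, 199, "2", 100, 199), 0)
  ## nested interval: overlap / longer length
  expect_equal(reciprocalOverlap("5", 1000, 1999, "5", 1200, 1399), 200 / 1000)
  set.seed(42)
  a1 <- sample.int(1e6, 200); a2 <- a1 + sample.int(1e4, 200)
  b1 <- sample.int(1e6, 200); b2 <- b1 + sample.int(1e4, 200)
  ch <- sample(c("1", "2"), 200, replace = TRUE)
  ro_ab <- reciprocalOverlap(ch, a1, a2, ch, b1, b2)
  ro_ba <- reciprocalOverlap(ch, b1, b2, ch, a1, a2)
  expect_equal(ro_ab, ro_ba)
  expect_true(all(ro_ab >= 0 & ro_ab <= 1))
  expect_error(reciprocalOverlap("1", 10, 9, "1", 1, 5), "zero-length")
})

test_that("classification cascade assigns every tier by its rule", {
  pan <- smallPanel()
  kb <- makeDefaultKnowledgeBase(pan)
  ev <- defaultEventFrequencies(pan)
  pick <- function(cat, k = 1) ev[ev$kind == "cnv" &
                                    ev$expected_category == cat, ][k, ]
  cat22 <- .syndromeCatalog()
  co <- cat22[cat22$syndrome_name == "22q11 deletion syndrome", ]

  calls <- rbind(
    ## aneuploidy -> P1 regardless of location
    transform(mkCall("an", "21", 1, 48129895, "DEL"),
              svtype = "ANEUPLOIDY_GAIN", copy_number = 3L),
    ## full syndrome match -> P1
    mkCall("p1", co$chrom, co$start, co$end, "DEL"),
    ## partial syndrome overlap (half the region) -> LP1
    mkCall("lp_part", co$chrom, co$start,
           floor((co$start + co$end) / 2), "DEL"),
    ## suspected-dosage gene -> LP1
    eventCall("lp_gene", pick("likely_pathogenic"), pan),
    ## common population CNV (>1%) -> B1
    eventCall("b_common", pick("benign", 4), pan),
    ## rare population CNV with no gene -> B1
    eventCall("b_rare", pick("benign", 3), pan),
    ## benign-listed interval -> B1
    eventCall("b_listed", pick("benign", 1), pan),
    ## gene overlap + >=3 observations at <1% -> LB1
    eventCall("lb", pick("likely_benign"), pan),
    ## nothing in the knowledge base -> VUS
    freeCall("vus", kb))
  cls <- classifyCalls(calls, kb)
  got <- stats::setNames(cls$category, cls$sample_id)
  expect_identical(unname(got[c("an", "p1", "lp_part", "lp_gene")]),
                   c("pathogenic", "pathogenic", "likely_pathogenic",
                     "likely_pathogenic"))
  expect_identical(unname(got[c("b_common", "b_rare", "b_listed")]),
                   rep("benign", 3))
  expect_identical(unname(got[c("lb", "vus")]), c("likely_benign", "vus"))
  expect_identical(cls$matched_syndrome[cls$sample_id == "p1"],
                   "22q11 deletion syndrome")
  expect_identical(cls$is_ppcnv, cls$category %in%
                     c("pathogenic", "likely_pathogenic"))

  ## effect compatibility: a duplication of a deletion-only syndrome locus
  ## must not match that syndrome
  mds <- cat22[cat22$syndrome_name == "Miller-Dieker syndrome", ]
  expect_identical(mds$effect, "DEL")
  dup <- classifyCalls(mkCall("d", mds$chrom, mds$start, mds$end, "DUP"), kb)
  expect_false(dup$category %in% c("pathogenic") &&
                 identical(dup$matched_syndrome, "Miller-Dieker syndrome"))
  expect_true(is.na(dup$matched_syndrome) ||
                dup$matched_syndrome != "Miller-Dieker syndrome")

  ## population matches are type-specific: a DEL does not match a DUP record
  b4 <- pick("benign", 4)
  swapped <- eventCall("sw", b4, pan)
  swapped$svtype <- if (b4$svtype == "DEL") "DUP" else "DEL"
  expect_false(classifyCalls(swapped, kb)$category == "benign")
})

test_that("knowledge base round-trips through its on-disk form", {
  pan <- smallPanel()
  kb <- makeDefaultKnowledgeBase(pan)
  d <- withr::local_tempdir()
  writeKnowledgeBase(kb, d)
  kb2 <- loadKnowledgeBase(d)
  expect_identical(length(kb2@syndromes), length(kb@syndromes))
  expect_identical(length(kb2@populationCnvs), length(kb@populationCnvs))
  expect_identical(length(kb2@benignListed), length(kb@benignListed))
  expect_identical(length(kb2@genes), length(kb@genes))
  ev <- defaultEventFrequencies(pan)
  probe <- rbind(
    eventCall("a", ev[ev$expected_category == "likely_benign", ][1, ], pan),
    eventCall("b", ev[ev$expected_category == "benign", ][2, ], pan))
  expect_identical(classifyCalls(probe, kb2)$category,
                   classifyCalls(probe, kb)$category)
})

test_that("per-sample flags aggregate calls correctly", {
  pan <- smallPanel()
  kb <- makeDefaultKnowledgeBase(pan)
  ev <- defaultEventFrequencies(pan)
  cat_tab <- .syndromeCatalog()
  co22 <- cat_tab[cat_tab$syndrome_name == "22q11 deletion syndrome", ]
  wbs <- cat_tab[cat_tab$syndrome_name == "Williams-Beuren syndrome", ]
  calls <- rbind(
    transform(mkCall("s1", "21", 1, 48129895, "DEL"),
              svtype = "ANEUPLOIDY_GAIN", copy_number = 3L),
    mkCall("s2", co22$chrom, co22$start, co22$end, "DEL"),
    mkCall("s3", wbs$chrom, wbs$start, wbs$end, "DEL"),
    eventCall("s4", ev[ev$expected_category == "benign", ][4, ], pan),
    freeCall("s5", kb, chrom = "13"),
    freeCall("s5", kb, chrom = "18", svtype = "DUP"))
  f <- flagPpcnv(classifyCalls(calls, kb), sprintf("s%d", 1:6))
  rownames(f) <- f$sample_id
  expect_identical(f[c("s1", "s2", "s3", "s4", "s5"), "any_cnv"], rep(TRUE, 5))
  expect_identical(f["s6", "any_cnv"], FALSE)
  expect_identical(f$multiple_cnv, f$sample_id == "s5")
  expect_identical(f$ppcnv, f$sample_id %in% c("s1", "s2", "s3"))
  expect_identical(f$aneuploidy, f$sample_id == "s1")
  expect_identical(f$del22q11_or_dup, f$sample_id == "s2")
  expect_identical(f$other_syndrome, f$sample_id == "s3")
  ## empty calls give all-FALSE flags
  f0 <- flagPpcnv(classifyCalls(calls[0, ], kb), c("x", "y"))
  expect_false(any(unlist(f0[-1])))
})

test_that("control burden counts carriers by reciprocal overlap", {
  cases <- data.frame(chrom = c("22", "7"), start = c(18894835, 72744455),
                      end = c(21595240, 74142513))
  controls <- list(
    data.frame(chrom = "22", start = 18894835, end = 21595240),  # exact
    data.frame(chrom = "22", start = 18894835, end = 20000000),  # partial
    data.frame(chrom = character(), start = numeric(), end = numeric()),
    NULL)
  cb <- controlBurden(cases, controls)
  expect_identical(cb$n_carrier_controls, 1L)
  expect_equal(cb$carrier_fraction, 0.25)
  ## lowering the threshold admits the partial carrier
  cb2 <- controlBurden(cases, controls, ro_threshold = 0.4)
  expect_identical(cb2$n_carrier_controls, 2L)
  expect_error(controlBurden(cases, list()), "empty control set")
  expect_error(controlBurden(cases, controls, ro_threshold = 0), "ro_threshold")
})
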
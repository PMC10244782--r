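test_that("probe states threshold ratios with sex-aware expectations", {
  pan <- smallPanel()
  chr <- as.character(GenomicRanges::seqnames(probes(pan)))
  r <- diploidRatios(pan, c("f", "m"), sex = c("XX", "XY"))
  ix <- which(chr == "1")[1:6]
  r[ix[1], "f"] <- 1.5   # boundary is inclusive
  r[ix[2], "f"] <- 1.51
  r[ix[3], "f"] <- 2.5
  r[ix[4], "f"] <- 2.49
  r[ix[5], "f"] <- NA
  xix <- which(chr == "X")[1:2]
  r[xix[1], "m"] <- 0.7  # loss threshold on male X is 1.5/2 = 0.75
  r[xix[2], "m"] <- 0.8
  yix <- which(chr == "Y")[1]
  r[yix, "f"] <- 0.6     # Y material in an XX sample
  rm <- mkRatioMatrix(pan, r, sex = c("XX", "XY"))
  st <- callProbeStates(rm, pan)
  expect_identical(unname(st[ix[1:5], "f"]),
                   c("LOSS", "NEUTRAL", "GAIN", "NEUTRAL", "NOCALL"))
  expect_identical(unname(st[xix, "m"]), c("LOSS", "NEUTRAL"))
  expect_identical(unname(st[yix, "f"]), "GAIN")
  ## expected-0 probes with no signal are neutral, not losses
  yothers <- setdiff(which(chr == "Y"), yix)
  expect_true(all(st[yothers, "f"] == "NEUTRAL"))
  expect_error(callProbeStates(rm, pan, del_max = 2.1), "del_max < 2 < dup_min")
})

test_that("region calls require enough concordant probes", {
  pan <- smallPanel()
  mc <- S4Vectors::mcols(probes(pan))
  rid <- S4Vectors::mcols(regions(pan))$region_id[
    S4Vectors::mcols(regions(pan))$kind == "core_cnv"][1]
  i <- which(mc$region_id == rid)  # 4 probes
  r <- diploidRatios(pan, c("full", "partial", "dup"))
  r[i, "full"] <- 1
  r[i[1:3], "partial"] <- 1       # 3 of 4 concordant: below both rules
  r[i, "dup"] <- 3
  rm <- mkRatioMatrix(pan, r)
  st <- callProbeStates(rm, pan)
  calls <- callRegions(st, rm, pan)
  expect_identical(sort(calls$sample_id), c("dup", "full"))
  del <- calls[calls$sample_id == "full", ]
  expect_identical(del$svtype, "DEL")
  expect_identical(del$copy_number, 1L)
  expect_identical(del$n_support_probes, 4L)
  expect_identical(del$region_id, rid)
  dup <- calls[calls$sample_id == "dup", ]
  expect_identical(dup$svtype, "DUP")
  expect_identical(dup$copy_number, 3L)
  ## relaxing both the count and the fraction rule admits the 3/4 sample
  calls2 <- callRegions(st, rm, pan, min_probes = 3, region_fraction = 0.7)
  expect_true("partial" %in% calls2$sample_id)
  ## excluded chromosome suppresses the call
  ch <- del$chrom
  calls3 <- callRegions(st, rm, pan, exclude = list(full = ch))
  expect_false("full" %in% calls3$sample_id)
})

test_that("backbone segmentation merges runs and respects min_run", {
  pan <- smallPanel()
  p <- probes(pan)
  kind <- S4Vectors::mcols(p)$kind
  chr <- as.character(GenomicRanges::seqnames(p))
  bb2 <- which(kind %in% c("backbone", "telomeric") & chr == "2")
  r <- diploidRatios(pan, c("run", "short"))
  r[bb2[2:6], "run"] <- 3        # 5 consecutive gained backbone probes
  r[bb2[2:4], "short"] <- 3      # only 3: below min_run
  rm <- mkRatioMatrix(pan, r)
  st <- callProbeStates(rm, pan)
  seg <- mergeBackboneSegments(st, rm, pan)
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$sample_id, "run")
  expect_identical(seg$svtype, "DUP")
  expect_identical(seg$n_support_probes, 5L)
  expect_identical(seg$start, GenomicRanges::start(p)[bb2[2]])
  expect_identical(seg$end, GenomicRanges::end(p)[bb2[6]])
  seg2 <- mergeBackboneSegments(st, rm, pan, min_run = 3)
  expect_true("short" %in% seg2$sample_id)
})

test_that("aneuploidy calls and karyotype designations", {
  pan <- smallPanel()
  chr <- as.character(GenomicRanges::seqnames(probes(pan)))
  r <- diploidRatios(pan, c("t21", "xo", "xxy", "xyy", "nrm"),
                     sex = c("XX", "XX", "XY", "XY", "XY"))
  r[chr == "21", "t21"] <- 3
  r[chr == "X", "xo"] <- 1
  r[chr == "X", "xxy"] <- 2   # XXY: two X plus reference-scale Y
  r[chr == "Y", "xxy"] <- 2
  r[chr == "Y", "xyy"] <- 4   # two Y vs one-copy reference
  sx <- c("XX", "indeterminate", "indeterminate", "XY", "XY")
  rm <- mkRatioMatrix(pan, r, sex = sx)
  st <- callProbeStates(rm, pan)
  an <- callAneuploidies(st, rm, pan)
  k <- stats::setNames(an$karyotypes$designation, an$karyotypes$sample_id)
  expect_identical(unname(k[c("t21", "xo", "xxy", "xyy", "nrm")]),
                   c("47,XX,+21", "45,X", "47,XXY", "47,XYY", "46,XY"))
  tc <- an$calls[an$calls$sample_id == "t21", ]
  expect_identical(tc$chrom, "21")
  expect_identical(tc$svtype, "ANEUPLOIDY_GAIN")
  expect_identical(tc$copy_number, 3L)
  expect_identical(tc$end, unname(chromLengths(pan)["21"]))
  expect_error(callAneuploidies(st, rm, pan, chrom_fraction = 0.5),
               "chrom_fraction")
})

test_that("callCnvs output is non-overlapping, sorted and excludes references", {
  pan <- smallPanel()
  tr <- diploidTruth(c("S1", "S2"), sex = c("XX", "XY"))
  rid <- S4Vectors::mcols(regions(pan))$region_id[
    S4Vectors::mcols(regions(pan))$kind == "core_cnv"][2]
  tr <- withCnv(tr, pan, "S1", rid, 1)
  tr <- withAneuploidy(tr, "S2", "21", 3)
  sim <- simulateSignals(tr, pan, model = flatModel(pan), n_references = 4)
  rm <- quantifyRatios(sim$peaks, pan, reference_ids = sprintf("REF%02d", 1:4))
  res <- callCnvs(rm, pan)
  expect_false(any(grepl("^REF", res$calls$sample_id)))
  expect_identical(nrow(res$karyotypes), 2L)
  ## the deletion is recovered once, as a region call only
  s1 <- res$calls[res$calls$sample_id == "S1", ]
  expect_identical(s1$region_id, rid)
  expect_identical(s1$svtype, "DEL")
  ## the trisomy is a whole-chromosome call; no region/backbone calls on 21
  s2 <- res$calls[res$calls$sample_id == "S2", ]
  expect_identical(s2$svtype, "ANEUPLOIDY_GAIN")
  ## per-sample calls never overlap
  g <- callsAsGRanges(res$calls)
  for (sid in unique(res$calls$sample_id)) {
    gs <- g[S4Vectors::mcols(g)$sample_id == sid]
    expect_identical(sum(GenomicRanges::countOverlaps(gs, gs) > 1), 0L)
  }
  ## sorted by sample then genome position
  expect_false(is.unsorted(match(res$calls$sample_id,
                                 unique(res$calls$sample_id))))
  ## round-trip
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCalls(res$calls, f)
  back <- readCalls(f)
  expect_identical(back$sample_id, res$calls$sample_id)
  expect_equal(back$mean_ratio, res$calls$mean_ratio, tolerance = 1e-8)
})
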
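test_that("genotype simulation is deterministic and respects frequencies", {
  pan <- smallPanel()
  ev <- defaultEventFrequencies(pan)
  t1 <- simulateGenotypes(100, ev, pan, seed = 7)
  t2 <- simulateGenotypes(100, ev, pan, seed = 7)
  expect_identical(t1, t2)

  ev0 <- ev
  ev0$frequency <- 0
  t0 <- simulateGenotypes(50, ev0, pan, seed = 1)
  expect_identical(nrow(t0$cnvs), 0L)
  expect_identical(nrow(t0$aneuploidies), 0L)
  expect_identical(t0$samples$sex, t0$samples$sex_chromosomes)

  ev1 <- ev[grepl("^22q11_deletion", ev$event_id), ]
  ev1$frequency <- 1
  ta <- simulateGenotypes(25, ev1, pan, seed = 2)
  expect_identical(nrow(ta$cnvs), 25L)
  expect_true(all(ta$cnvs$chrom == "22" & ta$cnvs$svtype == "DEL"))

  bad <- ev[1:2, ]
  bad$kind <- "cnv"; bad$region_id <- "nonsense"
  expect_error(simulateGenotypes(5, bad, pan), "unknown region id")
  bad2 <- ev; bad2$frequency[1] <- 1.5
  expect_error(simulateGenotypes(5, bad2, pan), "\\[0,1\\]")
})

test_that("spike-in counts follow their binomial expectation", {
  pan <- smallPanel()
  ev <- defaultEventFrequencies(pan)
  tri <- ev[ev$event_id == "trisomy_21", ]
  expect_equal(tri$frequency, 25 / 1762, tolerance = 1e-12)
  n <- 1000
  tr <- simulateGenotypes(n, tri, pan, seed = 7)
  obs <- sum(tr$aneuploidies$chrom == "21")
  p <- tri$frequency
  expect_lt(abs(obs - n * p), 3 * sqrt(n * p * (1 - p)))
})

test_that("signal model is exact at zero noise", {
  pan <- smallPanel()
  chr <- as.character(GenomicRanges::seqnames(probes(pan)))
  auto <- chr %in% as.character(1:22)

  tr <- diploidTruth(c("A", "B"), sex = c("XX", "XY"))
  sim <- simulateSignals(tr, pan, model = flatModel(pan), n_references = 0)
  expect_true(all(sim$peaks[auto, "A"] == 1.0))
  expect_true(all(sim$peaks[auto, "B"] == 1.0))
  ## male X at half the female dose, equal scales
  expect_true(all(sim$peaks[chr == "X", "B"] ==
                    sim$peaks[chr == "X", "A"] / 2))
  expect_true(all(sim$peaks[chr == "Y", "A"] == 0))

  ## heterozygous deletion halves the covered probes
  rid <- S4Vectors::mcols(regions(pan))$region_id[
    S4Vectors::mcols(regions(pan))$kind == "core_cnv" &
      as.character(GenomicRanges::seqnames(regions(pan))) == "22"][1]
  trd <- withCnv(diploidTruth("D"), pan, "D", rid, 1)
  simd <- simulateSignals(trd, pan, model = flatModel(pan), n_references = 0)
  v <- trd$cnvs[1, ]
  pos <- GenomicRanges::start(probes(pan))
  covered <- chr == v$chrom & pos >= v$start & pos <= v$end
  expect_true(all(simd$peaks[covered, "D"] == 0.5))
  expect_true(all(simd$peaks[auto & !covered, "D"] == 1.0))
})

test_that("clinical covariates reproduce their stratum parameters", {
  pan <- smallPanel()
  n_car <- 162; n_non <- 1600
  ids <- sprintf("S%04d", seq_len(n_car + n_non))
  tr <- diploidTruth(ids)
  rid <- S4Vectors::mcols(regions(pan))$region_id[1]
  for (s in ids[seq_len(n_car)]) tr <- withCnv(tr, pan, s, rid, 1)
  cl <- simulateClinical(tr, seed = 11)
  carrier <- cl$sample_id %in% ids[seq_len(n_car)]
  prm <- defaultClinicalParams()
  m <- prm$carrier$normal$cpbt_min
  expect_lt(abs(mean(cl$cpbt_min[carrier]) - m[1]), 3 * m[2] / sqrt(n_car))
  m <- prm$noncarrier$normal$cpbt_min
  expect_lt(abs(mean(cl$cpbt_min[!carrier]) - m[1]), 3 * m[2] / sqrt(n_non))
  expect_true(all(cl$cpbt_min >= 0) && all(cl$mvt_min >= 0))
  expect_identical(cl, simulateClinical(tr, seed = 11))

  prm0 <- prm
  prm0$carrier$complications[] <- 0
  prm0$noncarrier$complications[] <- 0
  cl0 <- simulateClinical(tr, params = prm0, seed = 1)
  expect_false(any(cl0$hypoxemia) || any(cl0$infection) || any(cl0$hf))

  bad <- prm
  bad$carrier$normal$age_months[2] <- -1
  expect_error(simulateClinical(tr, params = bad), "negative SD")
})

test_that("cohort files round-trip on disk", {
  pan <- smallPanel()
  ev <- defaultEventFrequencies(pan)
  tr <- simulateGenotypes(10, ev, pan, seed = 4)
  sim <- simulateSignals(tr, pan, model = list(noise_cv = 0.05, seed = 4),
                         n_references = 3)
  cl <- simulateClinical(sim$truth, seed = 4,
                         exclude_ids = sim$samples$sample_id[
                           sim$samples$is_reference])
  d <- withr::local_tempdir()
  writeCohort(sim, cl, d)
  expect_identical(length(list.files(file.path(d, "peaks"))), 13L)
  back <- readCohortPeaks(d)
  expect_equal(back$peaks, sim$peaks, tolerance = 1e-8)
  expect_identical(back$samples$sample_id, sim$samples$sample_id)

  simdup <- sim
  simdup$samples$sample_id[2] <- simdup$samples$sample_id[1]
  expect_error(writeCohort(simdup, cl, d), "duplicate sample_id")

  ## empty cohort writes headers-only sheets
  tre <- diploidTruth(character(0))
  sime <- simulateSignals(tre, pan, model = flatModel(pan), n_references = 0)
  d2 <- withr::local_tempdir()
  writeCohort(sime, NULL, d2)
  expect_identical(nrow(read.delim(file.path(d2, "samples.tsv"))), 0L)
})
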
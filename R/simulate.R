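## map catalog syndrome names to the panel region ids carrying their locus
.catalogRegionIds <- function(panel) {
  cat_tab <- .syndromeCatalog()
  reg <- panel@regions
  key_reg <- sprintf("%s:%.0f-%.0f", as.character(seqnames(reg)),
                     start(reg), end(reg))
  key_cat <- sprintf("%s:%.0f-%.0f", cat_tab$chrom, cat_tab$start,
                     cat_tab$end)
  stats::setNames(mcols(reg)$region_id[match(key_cat, key_reg)],
                  cat_tab$syndrome_name)
}

#' Default cohort event frequencies
#'
#' Event table giving, for every modeled chromosomal abnormality, its
#' per-sample probability in the screened congenital-heart-disease cohort
#' (observed carrier counts over the 1,762-patient cohort). Aneuploidies
#' cover trisomy 21, 47,XXX, 47,XXY and monosomy X; recurrent-syndrome
#' deletions/duplications map onto the named core regions of `panel`;
#' non-syndromic pathogenic, likely pathogenic, benign, likely benign and
#' uncertain events are spread over unnamed core regions so every
#' classification tier occurs at its cohort rate.
#'
#' @param panel a [ProbePanel-class] whose region ids the events reference.
#' @param denominator cohort size the counts are scaled by.
#' @return `data.frame` with columns `event_id`, `kind` (`aneuploidy` or
#'   `cnv`), `chrom`, `region_id`, `svtype`, `copy_number`,
#'   `sex_chromosomes`, `expected_category`, `frequency`.
#' @export
defaultEventFrequencies <- function(panel, denominator = 1762) {
  rid <- .catalogRegionIds(panel)
  an <- data.frame(
    event_id = c("trisomy_21", "XXX", "XXY", "monosomy_X"),
    kind = "aneuploidy", chrom = c("21", "X", "X", "X"), region_id = NA,
    svtype = c("ANEUPLOIDY_GAIN", "ANEUPLOIDY_GAIN", "ANEUPLOIDY_GAIN",
               "ANEUPLOIDY_LOSS"),
    copy_number = c(3, 3, 2, 1),
    sex_chromosomes = c(NA, "XXX", "XXY", "X"),
    expected_category = "pathogenic",
    count = c(25, 4, 2, 4), stringsAsFactors = FALSE)
  syn_counts <- c(`22q11 deletion syndrome` = 36,
                  `Williams-Beuren syndrome` = 21,
                  `22q11 duplication syndrome` = 6,
                  `16p13.11 microdeletion or duplication syndrome` = 4,
                  `15q11.2 microdeletion syndrome` = 4,
                  `1q21.1 TAR syndrome` = 4,
                  `1q21.1 microduplication` = 4,
                  `Charcot-Marie-Tooth syndrome type 1A` = 2,
                  `22q11.2 distal deletion syndrome` = 1,
                  `3q29 microdeletion syndrome` = 1,
                  `2p21 microdeletion syndrome` = 1,
                  `Miller-Dieker syndrome` = 1,
                  `15q13.3 microdeletion syndrome` = 1,
                  `15q24 microdeletion syndrome` = 1,
                  `16p12.1 microdeletion syndrome` = 1,
                  `Renal cysts and diabetes syndrome` = 1,
                  `Leri-Weill dyschondrosteosis` = 1,
                  `Cri du Chat syndrome` = 1,
                  `8p23.1 microdeletion syndrome` = 1,
                  `7q11.23 duplication syndrome` = 1,
                  `Hereditary neuropathy with pressure palsies` = 1)
  cat_tab <- .syndromeCatalog()
  eff <- stats::setNames(cat_tab$effect, cat_tab$syndrome_name)
  is_dup <- eff[names(syn_counts)] == "DUP"
  syn <- data.frame(
    event_id = gsub("[^A-Za-z0-9]+", "_", tolower(names(syn_counts))),
    kind = "cnv",
    chrom = cat_tab$chrom[match(names(syn_counts), cat_tab$syndrome_name)],
    region_id = unname(rid[names(syn_counts)]),
    svtype = ifelse(is_dup, "DUP", "DEL"),
    copy_number = ifelse(is_dup, 3, 1),
    sex_chromosomes = NA, expected_category = "pathogenic",
    count = unname(syn_counts), stringsAsFactors = FALSE)

  ## non-syndromic events on unnamed core regions: 7 other pathogenic,
  ## 26 likely pathogenic, 103 benign, 68 likely benign, 33 uncertain
  reg <- panel@regions
  unnamed <- mcols(reg)$region_id[mcols(reg)$kind == "core_cnv" &
                                  is.na(mcols(reg)$syndrome_name)]
  classes <- c(pathogenic = 7, likely_pathogenic = 26, benign = 103,
               likely_benign = 68, vus = 33)
  n_need <- c(4, 8, 10, 6, 8)  # regions allotted per class
  if (length(unnamed) < sum(n_need))
    stop("panel has ", length(unnamed), " unnamed core regions; ",
         sum(n_need), " are needed for the non-syndromic event classes")
  reg_split <- split(unnamed[seq_len(sum(n_need))],
                     rep(names(classes), n_need))
  other <- do.call(rbind, lapply(names(classes), function(cls) {
    rids <- reg_split[[cls]]
    cnt <- .apportion(classes[[cls]], rep(1, length(rids)))
    sv <- rep_len(c("DEL", "DUP"), length(rids))
    data.frame(event_id = paste0(cls, "_", rids), kind = "cnv",
               chrom = as.character(seqnames(reg))[match(rids, mcols(reg)$region_id)],
               region_id = rids, svtype = sv,
               copy_number = ifelse(sv == "DUP", 3, 1),
               sex_chromosomes = NA, expected_category = cls,
               count = cnt, stringsAsFactors = FALSE)
  }))
  ev <- rbind(an, syn, other)
  ev$frequency <- ev$count / denominator
  ev$count <- NULL
  ev
}

#' Simulate cohort genotypes
#'
#' Draws, independently per sample and event, the chromosomal abnormalities
#' of an event table (see [defaultEventFrequencies()]). Sample sex is XY
#' with probability `p_male` unless a sex-chromosome aneuploidy event
#' overrides the complement. Deterministic for a fixed seed.
#'
#' @param n_samples number of case samples.
#' @param events event table with columns as in [defaultEventFrequencies()].
#' @param panel a [ProbePanel-class]; CNV events must reference its regions.
#' @param seed integer seed.
#' @param p_male probability of XY sex.
#' @param sample_ids optional ids (default `S0001..`).
#' @return list with `samples` (`sample_id`, `sex`, `sex_chromosomes`),
#'   `aneuploidies` (`sample_id`, `chrom`, `copy_count`), and `cnvs`
#'   (`sample_id`, `chrom`, `start`, `end`, `copy_number`, `svtype`,
#'   `region_id`, `expected_category`).
#' @export
simulateGenotypes <- function(n_samples, events, panel, seed = 1,
                              p_male = 0.51, sample_ids = NULL) {
  if (any(events$frequency < 0 | events$frequency > 1))
    stop("event frequencies must lie in [0,1]")
  cnv_ev <- events[events$kind == "cnv", ]
  known <- mcols(panel@regions)$region_id
  bad <- setdiff(cnv_ev$region_id, known)
  if (length(bad))
    stop("unknown region id in event table: ", paste(bad, collapse = ", "))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n_samples))
  rs <- .rngState(seed)
  on.exit(.rngRestore(rs))
  sex <- ifelse(stats::runif(n_samples) < p_male, "XY", "XX")
  hit <- matrix(stats::runif(n_samples * nrow(events)) <
                  rep(events$frequency, each = n_samples),
                nrow = n_samples)
  sex_chr <- sex
  an <- list(); cn <- list()
  reg <- panel@regions
  reg_idx <- match(cnv_ev$region_id, mcols(reg)$region_id)
  for (j in seq_len(nrow(events))) {
    who <- which(hit[, j])
    if (!length(who)) next
    e <- events[j, ]
    if (e$kind == "aneuploidy") {
      if (!is.na(e$sex_chromosomes)) {
        sex_chr[who] <- e$sex_chromosomes
      } else {
        an[[length(an) + 1]] <- data.frame(sample_id = sample_ids[who],
                                           chrom = e$chrom,
                                           copy_count = e$copy_number)
      }
    } else {
      k <- match(e$region_id, mcols(reg)$region_id)
      ## copy numbers are expressed against a two-copy baseline; on X the
      ## event shifts the sample's own dose (a deletion in an XY male is
      ## hemizygous, copy 0)
      cpy <- rep(e$copy_number, length(who))
      if (e$chrom == "X") {
        nx <- vapply(strsplit(sex_chr[who], ""),
                     function(s) sum(s == "X"), integer(1))
        cpy <- pmax(nx + e$copy_number - 2, 0)
      }
      cn[[length(cn) + 1]] <- data.frame(
        sample_id = sample_ids[who], chrom = e$chrom,
        start = start(reg)[k], end = end(reg)[k],
        copy_number = cpy, svtype = e$svtype,
        region_id = e$region_id, expected_category = e$expected_category)
    }
  }
  empty_an <- data.frame(sample_id = character(), chrom = character(),
                         copy_count = integer())
  empty_cn <- data.frame(sample_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         copy_number = integer(), svtype = character(),
                         region_id = character(),
                         expected_category = character())
  list(samples = data.frame(sample_id = sample_ids, sex = sex,
                            sex_chromosomes = sex_chr,
                            stringsAsFactors = FALSE),
       aneuploidies = if (length(an)) do.call(rbind, an) else empty_an,
       cnvs = if (length(cn)) do.call(rbind, cn) else empty_cn)
}

## per-sample copy number at every panel probe implied by a truth set
.truthCopyNumbers <- function(truth, panel) {
  p <- panel@probes
  chr <- as.character(seqnames(p))
  pos <- start(p)
  n <- nrow(truth$samples)
  cn <- matrix(2, nrow = length(p), ncol = n,
               dimnames = list(mcols(p)$probe_id, truth$samples$sample_id))
  nx <- vapply(strsplit(truth$samples$sex_chromosomes, ""),
               function(s) sum(s == "X"), integer(1))
  ny <- vapply(strsplit(truth$samples$sex_chromosomes, ""),
               function(s) sum(s == "Y"), integer(1))
  cn[chr == "X", ] <- rep(nx, each = sum(chr == "X"))
  cn[chr == "Y", ] <- rep(ny, each = sum(chr == "Y"))
  if (nrow(truth$aneuploidies)) {
    for (i in seq_len(nrow(truth$aneuploidies))) {
      a <- truth$aneuploidies[i, ]
      cn[chr == a$chrom, a$sample_id] <- a$copy_count
    }
  }
  if (nrow(truth$cnvs)) {
    for (i in seq_len(nrow(truth$cnvs))) {
      v <- truth$cnvs[i, ]
      cn[chr == v$chrom & pos >= v$start & pos <= v$end, v$sample_id] <-
        v$copy_number
    }
  }
  cn
}

#' Simulate raw probe peak intensities
#'
#' Multiplicative signal model: the expected peak height of probe *p* in
#' sample *s* is `efficiency[p] * scale[s] * copies(p, s) / 2`, with
#' independent multiplicative lognormal noise of coefficient of variation
#' `noise_cv` (noise expectation 1). Sex-chromosome probes use the sample's
#' true X/Y copy counts. Reference samples are appended as event-free
#' diploid XX/XY samples.
#'
#' @param truth genotype truth from [simulateGenotypes()].
#' @param panel a [ProbePanel-class].
#' @param model list with `probe_efficiency` (per-probe positive scales, or
#'   `NULL` to draw lognormal around 1), `sample_scale` (per-sample positive
#'   scales, or `NULL` to draw), `noise_cv` (>= 0) and `seed`.
#' @param n_references number of diploid reference samples to append
#'   (alternating XX/XY, ids `REF01..`).
#' @return list with `peaks` (probes x samples matrix), `samples` (sample
#'   sheet incl. references with `is_reference`), and `truth` (input truth
#'   extended with the reference samples).
#' @export
simulateSignals <- function(truth, panel, model = list(), n_references = 20) {
  model <- utils::modifyList(list(probe_efficiency = NULL, sample_scale = NULL,
                                  noise_cv = 0.05, seed = 1), model)
  if (model$noise_cv < 0) stop("noise_cv must be >= 0")
  if (n_references > 0) {
    ref_ids <- sprintf("REF%02d", seq_len(n_references))
    ref_sex <- rep_len(c("XX", "XY"), n_references)
    truth$samples <- rbind(truth$samples,
                           data.frame(sample_id = ref_ids, sex = ref_sex,
                                      sex_chromosomes = ref_sex,
                                      stringsAsFactors = FALSE))
  } else ref_ids <- character()
  np <- length(panel@probes)
  ns <- nrow(truth$samples)
  rs <- .rngState(model$seed)
  on.exit(.rngRestore(rs))
  eff <- model$probe_efficiency
  if (is.null(eff)) eff <- stats::rlnorm(np, meanlog = 0, sdlog = 0.4)
  if (any(eff <= 0)) stop("probe efficiencies must be positive")
  scl <- model$sample_scale
  if (is.null(scl)) scl <- stats::rlnorm(ns, meanlog = log(1000), sdlog = 0.3)
  scl <- rep_len(scl, ns)
  if (any(scl <= 0)) stop("sample scales must be positive")
  cn <- .truthCopyNumbers(truth, panel)
  mu <- (eff %o% scl) * cn / 2
  if (model$noise_cv > 0) {
    sdlog <- sqrt(log(1 + model$noise_cv^2))
    noise <- matrix(stats::rlnorm(np * ns, meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog), nrow = np)
    mu <- mu * noise
  }
  dimnames(mu) <- list(mcols(panel@probes)$probe_id, truth$samples$sample_id)
  samples <- truth$samples
  samples$is_reference <- samples$sample_id %in% ref_ids
  list(peaks = mu, samples = samples, truth = truth)
}

#' Default clinical covariate parameters
#'
#' Group means/SDs and proportions for the carrier (potentially pathogenic
#' CNV present, n = 162) and non-carrier (n = 1,600) strata of the modeled
#' cohort: age (months), weight (kg), cardiopulmonary bypass time (CPBT),
#' aortic cross-clamp time (ACCT) and mechanical ventilation time (MVT) in
#' minutes; male fraction; complex-surgery and complication rates;
#' one-month mortality; and the 12-level CHD subgroup composition.
#'
#' @return Nested list with `carrier` and `noncarrier` components.
#' @export
defaultClinicalParams <- function() {
  subgroups <- c("Heterotaxy", "Ebstein anomaly", "Patent ductus arteriosus",
                 "Atrioventricular septal defect",
                 "Atrioventricular valve malformation",
                 "Pulmonary vein malformation", "Other CHD", "Complex CHD",
                 "Left ventricular outflow tract obstruction",
                 "Right ventricular outflow tract obstruction",
                 "Conotruncal defects", "Septal defects")
  present <- c(0, 1, 3, 9, 5, 7, 0, 3, 27, 17, 32, 58)
  absent <- c(2, 7, 32, 30, 36, 42, 49, 50, 102, 111, 215, 923)
  mk <- function(age, weight, cpbt, acct, mvt, male, complex, rates, died, n,
                 sub_counts) {
    list(n = n,
         normal = list(age_months = age, weight_kg = weight, cpbt_min = cpbt,
                       acct_min = acct, mvt_min = mvt),
         male = male, complex_surgery = complex,
         complications = rates, died_1mo = died,
         subgroup_probs = stats::setNames(sub_counts / sum(sub_counts),
                                          subgroups))
  }
  comp_carrier <- c(delayed_sternal_closure = 5, hemostasis = 1,
                    ecmo_lvad = 1, diaphragmatic_paralysis = 2,
                    hypoxemia = 9, neurological = 0, hf = 5, mof = 2,
                    rf = 6, infection = 6) / 162
  comp_non <- c(delayed_sternal_closure = 42, hemostasis = 8, ecmo_lvad = 11,
                diaphragmatic_paralysis = 13, hypoxemia = 60,
                neurological = 2, hf = 32, mof = 21, rf = 32,
                infection = 29) / 1600
  list(carrier = mk(c(24.35, 30.38), c(10.35, 5.78), c(77.62, 53.58),
                    c(42.30, 29.57), c(80.56, 192.32), 81 / 162, 101 / 162,
                    comp_carrier, 2 / 162, 162, present),
       noncarrier = mk(c(25.02, 30.83), c(11.50, 7.75), c(62.61, 42.50),
                       c(33.19, 26.11), c(53.95, 149.07), 817 / 1600,
                       602 / 1600, comp_non, 9 / 1600, 1600, absent))
}

#' Simulate clinical covariates
#'
#' Draws per-sample clinical records conditionally on carrier stratum
#' (whether the sample's genotype truth contains any pathogenic or likely
#' pathogenic event). Continuous covariates are normal truncated at zero;
#' binary covariates Bernoulli; CHD subgroup multinomial; covariates are
#' conditionally independent given the stratum.
#'
#' @param truth genotype truth from [simulateGenotypes()] (reference
#'   samples, if present in `truth$samples`, are skipped via
#'   `exclude_ids`).
#' @param params parameter list as from [defaultClinicalParams()].
#' @param seed integer seed.
#' @param exclude_ids sample ids to omit (e.g. references).
#' @return `data.frame` of clinical records, one row per sample.
#' @export
simulateClinical <- function(truth, params = defaultClinicalParams(),
                             seed = 1, exclude_ids = character()) {
  for (st in c("carrier", "noncarrier"))
    if (any(vapply(params[[st]]$normal, function(x) x[2] < 0, logical(1))))
      stop("negative SD in clinical parameters")
  samples <- truth$samples[!(truth$samples$sample_id %in% exclude_ids), ]
  pp_ids <- unique(c(
    truth$cnvs$sample_id[truth$cnvs$expected_category %in%
                           c("pathogenic", "likely_pathogenic")],
    truth$aneuploidies$sample_id,
    samples$sample_id[samples$sex_chromosomes != samples$sex]))
  carrier <- samples$sample_id %in% pp_ids
  n <- nrow(samples)
  rs <- .rngState(seed)
  on.exit(.rngRestore(rs))
  draw_norm <- function(field) {
    out <- numeric(n)
    for (st in c(TRUE, FALSE)) {
      p <- params[[if (st) "carrier" else "noncarrier"]]$normal[[field]]
      k <- sum(carrier == st)
      out[carrier == st] <- pmax(stats::rnorm(k, p[1], p[2]), 0)
    }
    out
  }
  draw_bern <- function(getp) {
    pr <- ifelse(carrier, getp(params$carrier), getp(params$noncarrier))
    stats::runif(n) < pr
  }
  rec <- data.frame(sample_id = samples$sample_id, sex = samples$sex,
                    stringsAsFactors = FALSE)
  for (f in c("age_months", "weight_kg", "cpbt_min", "acct_min", "mvt_min"))
    rec[[f]] <- draw_norm(f)
  rec$complex_surgery <- draw_bern(function(p) p$complex_surgery)
  sub_lv <- names(params$carrier$subgroup_probs)
  rec$subgroup <- NA_character_
  for (st in c(TRUE, FALSE)) {
    p <- params[[if (st) "carrier" else "noncarrier"]]$subgroup_probs
    k <- sum(carrier == st)
    rec$subgroup[carrier == st] <- sample(sub_lv, k, replace = TRUE, prob = p)
  }
  for (cmp in names(params$carrier$complications))
    rec[[cmp]] <- draw_bern(function(p) p$complications[[cmp]])
  rec$outcome <- ifelse(draw_bern(function(p) p$died_1mo), "died_1mo", "cured")
  rec
}

#' Write and read a simulated cohort
#'
#' `writeCohort()` emits `samples.tsv`, `truth_aneuploidies.tsv`,
#' `truth_cnvs.tsv`, `clinical.tsv` and one peak table per sample under
#' `peaks/<sample_id>.tsv` (columns `probe_id`, `peak`). `readCohortPeaks()`
#' reloads the peak matrix.
#'
#' @param sim output of [simulateSignals()].
#' @param clinical clinical sheet from [simulateClinical()] (optional).
#' @param outdir output directory, created if needed.
#' @param dir a cohort directory written by `writeCohort()`.
#' @return `writeCohort()` the directory, invisibly; `readCohortPeaks()` a
#'   probes x samples matrix plus the sample sheet.
#' @export
writeCohort <- function(sim, clinical = NULL, outdir) {
  if (anyDuplicated(sim$samples$sample_id))
    stop("duplicate sample_id in cohort")
  if (!setequal(colnames(sim$peaks), sim$samples$sample_id))
    stop("sample ids of peaks and sample sheet disagree")
  if (!is.null(clinical) &&
      !all(clinical$sample_id %in% sim$samples$sample_id))
    stop("clinical sheet contains unknown sample ids")
  dir.create(file.path(outdir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(sim$samples, "samples.tsv")
  wt(sim$truth$aneuploidies, "truth_aneuploidies.tsv")
  wt(sim$truth$cnvs, "truth_cnvs.tsv")
  if (!is.null(clinical)) wt(clinical, "clinical.tsv")
  for (s in sim$samples$sample_id) {
    utils::write.table(
      data.frame(probe_id = rownames(sim$peaks), peak = sim$peaks[, s]),
      file.path(outdir, "peaks", paste0(s, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}

#' @rdname writeCohort
#' @export
readCohortPeaks <- function(dir) {
  samples <- utils::read.delim(file.path(dir, "samples.tsv"),
                               stringsAsFactors = FALSE)
  mats <- lapply(samples$sample_id, function(s) {
    t <- utils::read.delim(file.path(dir, "peaks", paste0(s, ".tsv")),
                           stringsAsFactors = FALSE)
    stats::setNames(t$peak, t$probe_id)
  })
  peaks <- do.call(cbind, mats)
  colnames(peaks) <- samples$sample_id
  list(peaks = peaks, samples = samples)
}
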
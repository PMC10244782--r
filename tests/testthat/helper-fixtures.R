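## compact genome-wide panel: the 18 catalog syndrome loci plus 36 unnamed
## core regions (enough for defaultEventFrequencies), 4 probes each, and
## sparse backbone/telomeric coverage
smallPanel <- function(seed = 1) {
  makeDefaultPanel(n_core_regions = 54, probes_per_region = 4,
                   backbone_spacing = 50e6, seed = seed)
}

## truth object with explicit samples and no events
diploidTruth <- function(sample_ids, sex = "XX") {
  sex <- rep_len(sex, length(sample_ids))
  list(samples = data.frame(sample_id = sample_ids, sex = sex,
                            sex_chromosomes = sex, stringsAsFactors = FALSE),
       aneuploidies = data.frame(sample_id = character(), chrom = character(),
                                 copy_count = integer()),
       cnvs = data.frame(sample_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         copy_number = integer(), svtype = character(),
                         region_id = character(),
                         expected_category = character()))
}

## add a CNV covering a panel region to a truth object
withCnv <- function(truth, panel, sample_id, region_id, copy_number,
                    category = "pathogenic") {
  reg <- regions(panel)
  k <- match(region_id, S4Vectors::mcols(reg)$region_id)
  truth$cnvs <- rbind(truth$cnvs, data.frame(
    sample_id = sample_id, chrom = as.character(GenomicRanges::seqnames(reg))[k],
    start = GenomicRanges::start(reg)[k], end = GenomicRanges::end(reg)[k],
    copy_number = copy_number,
    svtype = if (copy_number < 2) "DEL" else "DUP",
    region_id = region_id, expected_category = category,
    stringsAsFactors = FALSE))
  truth
}

withAneuploidy <- function(truth, sample_id, chrom, copy_count) {
  truth$aneuploidies <- rbind(truth$aneuploidies, data.frame(
    sample_id = sample_id, chrom = chrom, copy_count = copy_count,
    stringsAsFactors = FALSE))
  truth
}

## noiseless signal model with unit efficiencies/scales (ratios exact)
flatModel <- function(panel, seed = 1) {
  list(probe_efficiency = rep(1, length(probes(panel))),
       sample_scale = 1, noise_cv = 0, seed = seed)
}

## build a RatioMatrix directly from a ratio matrix (probes x samples)
mkRatioMatrix <- function(panel, ratios, sex = NULL, refs = character()) {
  ids <- colnames(ratios)
  if (is.null(sex)) sex <- rep("XX", length(ids))
  cd <- S4Vectors::DataFrame(sample_id = ids, is_reference = ids %in% refs,
                             qc_fail = FALSE, sex = sex)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ratio = ratios), rowRanges = probes(panel), colData = cd)
  methods::new("RatioMatrix", se)
}

## diploid ratio matrix (2.0 autosomes, sex-appropriate X/Y doses)
diploidRatios <- function(panel, sample_ids, sex = "XX") {
  sex <- rep_len(sex, length(sample_ids))
  chr <- as.character(GenomicRanges::seqnames(probes(panel)))
  r <- matrix(2, nrow = length(probes(panel)), ncol = length(sample_ids),
              dimnames = list(S4Vectors::mcols(probes(panel))$probe_id,
                              sample_ids))
  for (j in seq_along(sample_ids)) {
    if (sex[j] == "XY") {
      r[chr == "X", j] <- 1
      r[chr == "Y", j] <- 2
    } else {
      r[chr == "Y", j] <- 0
    }
  }
  r
}

## hand-written 8-probe single-region panel file on chr21
tinyPanelFile <- function(path) {
  lines <- c(
    "probe_id\tchrom\tstart\tend\tregion_id\tkind\tchannel\tamplicon_length",
    paste0("T", 1:8, "\t21\t", seq(10000000, 10700000, by = 100000), "\t",
           seq(10000000, 10700000, by = 100000) + 120,
           "\tr21\tcore_cnv\t", rep(1:4, 2), "\t", rep(c(100, 102), each = 4)))
  writeLines(lines, path)
  path
}
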
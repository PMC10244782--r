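#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<- seqnames<-
NULL

## canonical chromosome order used throughout (no "chr" prefix)
CHROMS <- c(as.character(1:22), "X", "Y")
AUTOSOMES <- as.character(1:22)

#' GRCh37 chromosome lengths
#'
#' Named vector of chromosome lengths (bp) for the 24 human chromosomes on
#' the GRCh37/hg19 assembly, the assembly on which the bundled syndrome
#' coordinates are expressed.
#'
#' @return Named numeric vector, names `"1".."22","X","Y"`.
#' @export
hg19ChromLengths <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566)
}

#' ProbePanel: a targeted ligation-probe panel
#'
#' Holds the ordered set of genomic probes (as a [GenomicRanges::GRanges]
#' with metadata columns `probe_id`, `region_id`, `kind`, `channel`,
#' `amplicon_length`) together with the target regions they interrogate
#' (`GRanges` with `region_id`, `kind`, `syndrome_name`) and the chromosome
#' lengths of the reference assembly. Probe `kind` is one of `core_cnv`,
#' `telomeric`, `backbone`, `snv_locus`.
#'
#' Coordinates are stored 1-based inclusive (the `GRanges` convention);
#' panel TSV and BED exports are 0-based half-open.
#'
#' @slot probes `GRanges` of probes, sorted by chromosome then start.
#' @slot regions `GRanges` of target regions.
#' @slot chromLengths named numeric vector of chromosome lengths.
#' @export
setClass("ProbePanel",
  slots = c(probes = "GRanges", regions = "GRanges", chromLengths = "numeric"))

setValidity("ProbePanel", function(object) {
  msgs <- character()
  p <- object@probes
  need <- c("probe_id", "region_id", "kind", "channel", "amplicon_length")
  miss <- setdiff(need, colnames(mcols(p)))
  if (length(miss))
    return(paste("probes lack metadata columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(mcols(p)$probe_id))
    msgs <- c(msgs, "duplicate probe_id values")
  if (!all(as.character(seqnames(p)) %in% CHROMS))
    msgs <- c(msgs, "probe chromosomes outside 1..22, X, Y")
  key <- paste(mcols(p)$channel, mcols(p)$amplicon_length)
  if (anyDuplicated(key))
    msgs <- c(msgs, "duplicate amplicon_length within a channel")
  rneed <- c("region_id", "kind")
  if (!all(rneed %in% colnames(mcols(object@regions))))
    msgs <- c(msgs, "regions lack region_id/kind metadata")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @describeIn ProbePanel-class number of probes in the panel
#' @param x,object a `ProbePanel`
#' @export
setMethod("length", "ProbePanel", function(x) length(x@probes))

#' Accessors for ProbePanel
#'
#' `probes()` and `regions()` return the probe and target-region `GRanges`;
#' `chromLengths()` the assembly chromosome lengths.
#'
#' @param x a `ProbePanel`.
#' @return `GRanges` or named numeric vector.
#' @export
probes <- function(x) x@probes

#' @rdname probes
#' @export
regions <- function(x) x@regions

#' @rdname probes
#' @export
chromLengths <- function(x) x@chromLengths

setMethod("show", "ProbePanel", function(object) {
  k <- table(mcols(object@probes)$kind)
  cat("ProbePanel with", length(object@probes), "probes on",
      length(unique(as.character(seqnames(object@probes)))), "chromosomes\n")
  cat("  probes by kind:",
      paste(names(k), as.integer(k), sep = "=", collapse = ", "), "\n")
  cat("  target regions:", length(object@regions),
      sprintf("(%d core CNV loci)",
              sum(mcols(object@regions)$kind == "core_cnv")), "\n")
})

#' RatioMatrix: normalized probe ratios
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with probes as rows
#' (rowRanges taken from the panel) and samples as columns. The single assay
#' `"ratio"` holds final normalized probe ratios on the diploid 2.0 scale:
#' a copy-neutral autosomal locus reads about 2.0, a heterozygous deletion
#' about 1.0, a three-copy duplication about 3.0. Column data records
#' `is_reference`, `qc_fail` and inferred `sex`.
#'
#' @export
setClass("RatioMatrix", contains = "RangedSummarizedExperiment")

setValidity("RatioMatrix", function(object) {
  if (!"ratio" %in% SummarizedExperiment::assayNames(object))
    return("assay 'ratio' missing")
  r <- SummarizedExperiment::assay(object, "ratio")
  if (any(r < 0, na.rm = TRUE)) return("negative ratios")
  need <- c("is_reference", "qc_fail")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    return(paste("colData lacks:", paste(miss, collapse = ", ")))
  TRUE
})

#' Accessors for RatioMatrix
#'
#' `ratioMatrix()` returns the probes x samples ratio matrix,
#' `referenceIds()` the sample ids used as normalization references,
#' `sampleSex()` the per-sample inferred sex (`XX`, `XY` or
#' `indeterminate`), `qcFailed()` the ids of samples flagged at QC.
#'
#' @param x a `RatioMatrix`.
#' @export
ratioMatrix <- function(x) SummarizedExperiment::assay(x, "ratio")

#' @rdname ratioMatrix
#' @export
referenceIds <- function(x)
  colnames(x)[SummarizedExperiment::colData(x)$is_reference]

#' @rdname ratioMatrix
#' @export
sampleSex <- function(x) {
  s <- SummarizedExperiment::colData(x)$sex
  stats::setNames(as.character(s), colnames(x))
}

#' @rdname ratioMatrix
#' @export
qcFailed <- function(x) colnames(x)[SummarizedExperiment::colData(x)$qc_fail]

#' KnowledgeBase: CNV interpretation evidence
#'
#' Container for the three evidence tracks used by the five-tier
#' classification cascade: recurrent microdeletion/microduplication
#' syndrome regions (`GRanges` with `syndrome_name` and `effect` in
#' `DEL`/`DUP`/`both`), population CNV records with observed frequency and
#' observation counts (`type`, `frequency`, `n_observations`), intervals
#' curated as benign, and gene intervals with dosage-sensitivity evidence
#' (`gene_name`, `dosage_evidence` in `confirmed`/`suspected`/`partial`/
#' `none`).
#'
#' @slot syndromes,populationCnvs,benignListed,genes `GRanges` tracks.
#' @export
setClass("KnowledgeBase",
  slots = c(syndromes = "GRanges", populationCnvs = "GRanges",
            benignListed = "GRanges", genes = "GRanges"))

setValidity("KnowledgeBase", function(object) {
  msgs <- character()
  if (!all(c("syndrome_name", "effect") %in% colnames(mcols(object@syndromes))))
    msgs <- c(msgs, "syndromes lack syndrome_name/effect")
  pc <- mcols(object@populationCnvs)
  if (!all(c("type", "frequency", "n_observations") %in% colnames(pc)))
    msgs <- c(msgs, "populationCnvs lack type/frequency/n_observations")
  else if (length(object@populationCnvs) &&
           (any(pc$frequency < 0) || any(pc$frequency > 1)))
    msgs <- c(msgs, "population frequencies outside [0,1]")
  if (!"gene_name" %in% colnames(mcols(object@genes)))
    msgs <- c(msgs, "genes lack gene_name")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "KnowledgeBase", function(object) {
  cat("KnowledgeBase:", length(object@syndromes), "syndrome regions,",
      length(object@populationCnvs), "population CNV records,",
      length(object@benignListed), "benign-listed intervals,",
      length(object@genes), "genes\n")
})
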
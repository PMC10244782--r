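#' Reciprocal overlap of two genomic intervals
#'
#' Overlap length divided by the length of the longer interval; 0 for
#' intervals on different chromosomes, 1 for identical intervals.
#' Symmetric in its arguments and vectorized over interval pairs.
#' Coordinates are 1-based inclusive.
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b interval coordinates.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
reciprocalOverlap <- function(chrom_a, start_a, end_a,
                              chrom_b, start_b, end_b) {
  len_a <- end_a - start_a + 1
  len_b <- end_b - start_b + 1
  if (any(len_a <= 0) || any(len_b <= 0))
    stop("zero-length interval in reciprocal overlap")
  ov <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b) + 1)
  ifelse(as.character(chrom_a) == as.character(chrom_b),
         ov / pmax(len_a, len_b), 0)
}

## reciprocal overlap of one call against every interval of a GRanges track
.roAgainst <- function(call, track) {
  if (!length(track)) return(numeric(0))
  reciprocalOverlap(call$chrom, call$start, call$end,
                    as.character(seqnames(track)), start(track), end(track))
}

#' Build the bundled synthetic knowledge base
#'
#' A synthetic stand-in for curated CNV interpretation resources: the
#' recurrent-syndrome catalog at GRCh37 coordinates, plus invented
#' population-frequency CNV records, benign-listed intervals and gene
#' intervals with dosage-evidence labels. It is generated in code and is
#' not a DGV/ISCA/DECIPHER/ClinGen download; frequencies, observation
#' counts and most gene intervals are fabrications chosen so that every
#' branch of the classification cascade is exercised. When a `panel` is
#' given, its unnamed core regions that carry benign/likely-benign/
#' uncertain simulated events (see [defaultEventFrequencies()]) receive
#' matching population and gene records so that simulated cohorts classify
#' to their intended tiers.
#'
#' @param panel optional [ProbePanel-class] to align population records to.
#' @return A [KnowledgeBase-class].
#' @export
makeDefaultKnowledgeBase <- function(panel = NULL) {
  cat_tab <- .syndromeCatalog()
  syn <- .mkGRanges(cat_tab$chrom, cat_tab$start, cat_tab$end,
                    syndrome_name = cat_tab$syndrome_name,
                    effect = cat_tab$effect)
  genes <- data.frame(
    chrom = c("22", "7", "8", "1", "17", "15", "16", "5", "2", "3"),
    start = c(19744226, 73442119, 11534468, 145507597, 14139000, 22833395,
              15481747, 2000000, 44500000, 195800000),
    end = c(19771116, 73484237, 11617509, 145513536, 15439000, 23086362,
            16292235, 2100000, 44600000, 195900000),
    gene_name = c("TBX1", "ELN", "GATA4", "RBM8A", "PMP22", "NIPA1",
                  "NDE1", "TERT_REGION", "ABCG5", "DLG1"),
    dosage_evidence = c("confirmed", "confirmed", "confirmed", "confirmed",
                        "confirmed", "suspected", "suspected", "suspected",
                        "partial", "suspected"),
    stringsAsFactors = FALSE)
  pop <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    type = character(), frequency = numeric(),
                    n_observations = integer(), stringsAsFactors = FALSE)
  benign <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), stringsAsFactors = FALSE)
  if (!is.null(panel)) {
    ev <- defaultEventFrequencies(panel)
    reg <- panel@regions
    at <- function(rids) {
      k <- match(rids, mcols(reg)$region_id)
      data.frame(chrom = as.character(seqnames(reg))[k], start = start(reg)[k],
                 end = end(reg)[k], stringsAsFactors = FALSE)
    }
    bt <- ev[ev$kind == "cnv" & ev$expected_category == "benign", ]
    if (nrow(bt)) {
      iv <- at(bt$region_id)
      half <- seq_len(nrow(bt)) %% 2 == 0
      ## half common in the population (>1%), half rare and gene-free
      pop <- rbind(pop, data.frame(iv, type = bt$svtype,
                                   frequency = ifelse(half, 0.02, 0.004),
                                   n_observations = ifelse(half, 60L, 2L)))
      benign <- rbind(benign, iv[seq_len(min(2, nrow(iv))), ])
    }
    lbt <- ev[ev$kind == "cnv" & ev$expected_category == "likely_benign", ]
    if (nrow(lbt)) {
      iv <- at(lbt$region_id)
      pop <- rbind(pop, data.frame(iv, type = lbt$svtype, frequency = 0.006,
                                   n_observations = 15L))
      genes <- rbind(genes,
                     data.frame(chrom = iv$chrom,
                                start = iv$start + 1000, end = iv$end - 1000,
                                gene_name = paste0("GENE_", lbt$region_id),
                                dosage_evidence = "none"))
    }
    lpt <- ev[ev$kind == "cnv" & ev$expected_category == "likely_pathogenic", ]
    if (nrow(lpt)) {
      iv <- at(lpt$region_id)
      genes <- rbind(genes,
                     data.frame(chrom = iv$chrom,
                                start = iv$start + 1000, end = iv$end - 1000,
                                gene_name = paste0("DOSAGE_", lpt$region_id),
                                dosage_evidence = "suspected"))
    }
    pt <- ev[ev$kind == "cnv" & ev$expected_category == "pathogenic" &
               !(ev$region_id %in% .catalogRegionIds(panel)), ]
    if (nrow(pt)) {
      iv <- at(pt$region_id)
      syn <- c(syn, .mkGRanges(iv$chrom, iv$start, iv$end,
                               syndrome_name = paste0("locus_", pt$region_id),
                               effect = "both"))
    }
  }
  methods::new(
    "KnowledgeBase",
    syndromes = syn,
    populationCnvs = .mkGRanges(pop$chrom, pop$start, pop$end,
                                type = pop$type, frequency = pop$frequency,
                                n_observations = pop$n_observations),
    benignListed = .mkGRanges(benign$chrom, benign$start, benign$end),
    genes = .mkGRanges(genes$chrom, genes$start, genes$end,
                       gene_name = genes$gene_name,
                       dosage_evidence = genes$dosage_evidence))
}

#' Read and write a knowledge base
#'
#' Three TSVs under a directory: `syndromes.tsv` (`chrom start end
#' syndrome_name effect`), `population_cnvs.tsv` (`chrom start end type
#' frequency n_observations benign_listed`) and `genes.tsv` (`chrom start
#' end gene_name dosage_evidence`).
#'
#' @param kb a [KnowledgeBase-class]; `dir` a directory.
#' @param dir directory path.
#' @return `writeKnowledgeBase()` the directory invisibly;
#'   `loadKnowledgeBase()` a `KnowledgeBase`.
#' @export
writeKnowledgeBase <- function(kb, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gr2df <- function(gr) cbind(
    data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
               end = end(gr)), as.data.frame(mcols(gr)))
  pc <- gr2df(kb@populationCnvs)
  bl <- gr2df(kb@benignListed)
  pc$benign_listed <- FALSE
  if (nrow(bl)) {
    bl$type <- NA; bl$frequency <- NA; bl$n_observations <- NA
    bl$benign_listed <- TRUE
    pc <- rbind(pc, bl[colnames(pc)])
  }
  utils::write.table(gr2df(kb@syndromes), file.path(dir, "syndromes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pc, file.path(dir, "population_cnvs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gr2df(kb@genes), file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeKnowledgeBase
#' @export
loadKnowledgeBase <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f),
                                      stringsAsFactors = FALSE)
  syn <- rd("syndromes.tsv")
  pc <- rd("population_cnvs.tsv")
  g <- rd("genes.tsv")
  is_bl <- !is.na(pc$benign_listed) & pc$benign_listed
  bl <- pc[is_bl, ]
  pc <- pc[!is_bl & !is.na(pc$frequency), ]
  methods::new(
    "KnowledgeBase",
    syndromes = .mkGRanges(syn$chrom, syn$start, syn$end,
                           syndrome_name = syn$syndrome_name,
                           effect = syn$effect),
    populationCnvs = .mkGRanges(pc$chrom, pc$start, pc$end, type = pc$type,
                                frequency = pc$frequency,
                                n_observations = as.integer(pc$n_observations)),
    benignListed = .mkGRanges(bl$chrom, bl$start, bl$end),
    genes = .mkGRanges(g$chrom, g$start, g$end, gene_name = g$gene_name,
                       dosage_evidence = g$dosage_evidence))
}

#' Classify CNV calls into the five-tier scheme
#'
#' Applies the rule cascade, first match wins:
#' \describe{
#'   \item{P1 (pathogenic)}{whole-chromosome aneuploidy, or reciprocal
#'     overlap of at least `match_ro` with a syndrome region of compatible
#'     effect (a deletion matches `DEL` or `both` syndromes only).}
#'   \item{LP1 (likely pathogenic)}{positive but sub-`match_ro` overlap
#'     with a compatible syndrome region, or overlap of a gene with
#'     `suspected` or `partial` dosage evidence.}
#'   \item{B1 (benign)}{matched population frequency above `benign_freq`;
#'     or listed benign; or a matched population record below `benign_freq`
#'     with no overlapping gene.}
#'   \item{LB1 (likely benign)}{overlaps at least one gene and matched in
#'     the population at least `min_obs` times at frequency below
#'     `benign_freq`.}
#'   \item{VUS}{anything else.}
#' }
#' Population and benign-listed records match a call at reciprocal overlap
#' `match_ro` and (for population records) equal CNV type. `is_ppcnv` marks
#' the pathogenic and likely pathogenic tiers.
#'
#' @param calls calls `data.frame` from [callCnvs()].
#' @param kb a [KnowledgeBase-class].
#' @param match_ro reciprocal-overlap threshold for "matched in location
#'   and size" (default 0.90).
#' @param min_obs minimum population observations for likely benign
#'   (default 3).
#' @param benign_freq population frequency above which a CNV is benign
#'   (default 0.01).
#' @return The calls with `category`, `is_ppcnv`, `matched_syndrome` and
#'   `rule_fired` columns appended.
#' @export
classifyCalls <- function(calls, kb, match_ro = 0.90, min_obs = 3,
                          benign_freq = 0.01) {
  n <- nrow(calls)
  category <- character(n); rule <- character(n)
  syndrome <- rep(NA_character_, n)
  syn_eff <- mcols(kb@syndromes)$effect
  for (i in seq_len(n)) {
    cl <- calls[i, ]
    if (grepl("^ANEUPLOIDY", cl$svtype)) {
      category[i] <- "pathogenic"; rule[i] <- "P1"
      next
    }
    compat <- syn_eff == "both" | syn_eff == cl$svtype
    ro_syn <- .roAgainst(cl, kb@syndromes)
    ro_syn[!compat] <- 0
    if (any(ro_syn >= match_ro)) {
      category[i] <- "pathogenic"; rule[i] <- "P1"
      syndrome[i] <- mcols(kb@syndromes)$syndrome_name[which.max(ro_syn)]
      next
    }
    gene_ov <- .roAgainst(cl, kb@genes) > 0
    dosage <- mcols(kb@genes)$dosage_evidence
    if (any(ro_syn > 0) ||
        any(gene_ov & dosage %in% c("suspected", "partial"))) {
      category[i] <- "likely_pathogenic"; rule[i] <- "LP1"
      if (any(ro_syn > 0))
        syndrome[i] <- mcols(kb@syndromes)$syndrome_name[which.max(ro_syn)]
      next
    }
    ro_pop <- .roAgainst(cl, kb@populationCnvs)
    ro_pop[mcols(kb@populationCnvs)$type != cl$svtype] <- 0
    matched <- ro_pop >= match_ro
    freq <- if (any(matched))
      max(mcols(kb@populationCnvs)$frequency[matched]) else NA
    nobs <- if (any(matched))
      max(mcols(kb@populationCnvs)$n_observations[matched]) else 0L
    listed <- any(.roAgainst(cl, kb@benignListed) >= match_ro)
    has_gene <- any(gene_ov)
    if ((!is.na(freq) && freq > benign_freq) || listed ||
        (!is.na(freq) && freq < benign_freq && !has_gene)) {
      category[i] <- "benign"; rule[i] <- "B1"
      next
    }
    if (has_gene && !is.na(freq) && freq < benign_freq && nobs >= min_obs) {
      category[i] <- "likely_benign"; rule[i] <- "LB1"
      next
    }
    category[i] <- "vus"; rule[i] <- "VUS"
  }
  calls$category <- category
  calls$is_ppcnv <- category %in% c("pathogenic", "likely_pathogenic")
  calls$matched_syndrome <- syndrome
  calls$rule_fired <- rule
  calls
}

#' Per-sample abnormality flags
#'
#' Collapses classified calls to one row per sample: `any_cnv` (any
#' retained call, uncertain included), `multiple_cnv` (two or more),
#' `ppcnv` (any pathogenic or likely pathogenic), `aneuploidy`,
#' `del22q11_or_dup` (a ppCNV matching the 22q11 deletion or duplication
#' syndrome) and `other_syndrome` (ppCNV that is neither an aneuploidy nor
#' 22q11).
#'
#' @param classified classified calls from [classifyCalls()].
#' @param sample_ids full cohort sample ids (samples without calls get
#'   all-FALSE rows).
#' @return `data.frame`, one row per sample.
#' @export
flagPpcnv <- function(classified, sample_ids) {
  f <- data.frame(sample_id = sample_ids, any_cnv = FALSE,
                  multiple_cnv = FALSE, ppcnv = FALSE, aneuploidy = FALSE,
                  del22q11_or_dup = FALSE, other_syndrome = FALSE,
                  stringsAsFactors = FALSE)
  if (!nrow(classified)) return(f)
  nall <- table(classified$sample_id)
  f$any_cnv <- f$sample_id %in% names(nall)
  f$multiple_cnv <- f$sample_id %in% names(nall)[nall >= 2]
  pp <- classified[classified$is_ppcnv, , drop = FALSE]
  f$ppcnv <- f$sample_id %in% pp$sample_id
  f$aneuploidy <- f$sample_id %in%
    pp$sample_id[grepl("^ANEUPLOIDY", pp$svtype)]
  is22 <- !is.na(pp$matched_syndrome) &
    grepl("^22q11 (deletion|duplication) syndrome$", pp$matched_syndrome)
  f$del22q11_or_dup <- f$sample_id %in% pp$sample_id[is22]
  other <- pp[!grepl("^ANEUPLOIDY", pp$svtype) & !is22, , drop = FALSE]
  f$other_syndrome <- (f$sample_id %in% other$sample_id) & !f$aneuploidy &
    !f$del22q11_or_dup
  f
}

#' Control-cohort ppCNV burden
#'
#' A control individual is a carrier when any of its CNVs reciprocally
#' overlaps any case ppCNV region at or above `ro_threshold`.
#'
#' @param case_ppcnvs `data.frame` of case ppCNV intervals (`chrom`,
#'   `start`, `end`).
#' @param controls list of per-control `data.frame`s of CNV intervals
#'   (`chrom`, `start`, `end`; empty data frames allowed).
#' @param ro_threshold reciprocal-overlap threshold in `(0, 1]`
#'   (default 0.90).
#' @return list with `n_carrier_controls` and `carrier_fraction`.
#' @export
controlBurden <- function(case_ppcnvs, controls, ro_threshold = 0.90) {
  if (!length(controls)) stop("empty control set")
  if (ro_threshold <= 0 || ro_threshold > 1)
    stop("ro_threshold must lie in (0, 1]")
  carrier <- vapply(controls, function(cc) {
    if (is.null(cc) || !nrow(cc) || !nrow(case_ppcnvs)) return(FALSE)
    for (i in seq_len(nrow(cc))) {
      ro <- reciprocalOverlap(cc$chrom[i], cc$start[i], cc$end[i],
                              case_ppcnvs$chrom, case_ppcnvs$start,
                              case_ppcnvs$end)
      if (any(ro >= ro_threshold)) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(n_carrier_controls = sum(carrier),
       carrier_fraction = sum(carrier) / length(controls))
}
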
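## Recurrent microdeletion/microduplication syndrome loci (GRCh37), the
## named core regions of the default panel and knowledge base. Coordinates
## are approximate breakpoint-region boundaries of the commonly reported
## critical intervals.
.syndromeCatalog <- function() {
  tab <- rbind(
    c("22q11 deletion syndrome",                         "22", 18900000, 21500000, "DEL"),
    c("22q11 duplication syndrome",                      "22", 18900000, 21500000, "DUP"),
    c("Williams-Beuren syndrome",                        "7",  72700000, 74100000, "DEL"),
    c("7q11.23 duplication syndrome",                    "7",  72700000, 74100000, "DUP"),
    c("16p13.11 microdeletion or duplication syndrome",  "16", 15500000, 16300000, "both"),
    c("15q11.2 microdeletion syndrome",                  "15", 22800000, 23100000, "DEL"),
    c("1q21.1 TAR syndrome",                             "1", 145400000, 145800000, "DEL"),
    c("1q21.1 microduplication",                         "1", 146500000, 147800000, "DUP"),
    c("Charcot-Marie-Tooth syndrome type 1A",            "17", 14100000, 15400000, "DUP"),
    c("Hereditary neuropathy with pressure palsies",     "17", 14100000, 15400000, "DEL"),
    c("22q11.2 distal deletion syndrome",                "22", 21900000, 23700000, "DEL"),
    c("3q29 microdeletion syndrome",                     "3", 195700000, 197300000, "DEL"),
    c("2p21 microdeletion syndrome",                     "2",  44400000, 45000000, "DEL"),
    c("Miller-Dieker syndrome",                          "17",        1,  2500000, "DEL"),
    c("15q13.3 microdeletion syndrome",                  "15", 32000000, 32500000, "DEL"),
    c("15q24 microdeletion syndrome",                    "15", 74400000, 76200000, "DEL"),
    c("16p12.1 microdeletion syndrome",                  "16", 21950000, 22400000, "DEL"),
    c("Renal cysts and diabetes syndrome",               "17", 34800000, 36200000, "DEL"),
    c("Leri-Weill dyschondrosteosis",                    "X",    505000,   800000, "DEL"),
    c("Cri du Chat syndrome",                            "5",         1, 10000000, "DEL"),
    c("8p23.1 microdeletion syndrome",                   "8",   8100000, 11800000, "DEL"))
  data.frame(syndrome_name = tab[, 1], chrom = tab[, 2],
             start = as.numeric(tab[, 3]), end = as.numeric(tab[, 4]),
             effect = tab[, 5], stringsAsFactors = FALSE)
}

.mkGRanges <- function(chrom, start, end, ..., chrom_lengths = hg19ChromLengths()) {
  gr <- GRanges(factor(chrom, levels = CHROMS), IRanges(start, end))
  seqlengths(gr) <- chrom_lengths[seqlevels(gr)]
  mc <- list(...)
  if (length(mc)) mcols(gr) <- DataFrame(mc)
  gr
}

.sortPanelOrder <- function(gr) {
  order(match(as.character(seqnames(gr)), CHROMS), start(gr))
}

#' Build the default synthetic probe panel
#'
#' Constructs a panel mirroring the screening assay design: `n_core_regions`
#' recurrent CNV target regions each covered by `probes_per_region` probes
#' (the first regions are the named syndrome loci of the bundled catalog,
#' the remainder pseudo-random 1-3 Mb loci), telomeric probes at about 0,
#' 10 and 20 Mb from both ends of every chromosome, and backbone probes
#' spread across all 24 chromosomes -- either at `backbone_spacing`
#' intervals or, when `n_backbone` is given, that exact count allocated to
#' chromosomes proportionally to length. Channel assignment is round-robin
#' over 4 fluorophore channels and amplicon lengths are assigned
#' sequentially within each channel, so size-based separation is always
#' resolvable. Deterministic for a fixed `seed`.
#'
#' @param n_core_regions number of core CNV target regions (>= 1).
#' @param probes_per_region probes covering each core region (>= 4, the
#'   minimum probe support the assay design requires per locus).
#' @param backbone_spacing genomic spacing (bp) of backbone probes.
#' @param seed integer seed for placement of unnamed core regions.
#' @param n_backbone optional exact backbone probe count overriding
#'   `backbone_spacing`.
#' @return A validated [ProbePanel-class].
#' @export
makeDefaultPanel <- function(n_core_regions = 206, probes_per_region = 6,
                             backbone_spacing = 10e6, seed = 1,
                             n_backbone = NULL) {
  if (n_core_regions < 1) stop("n_core_regions must be >= 1")
  if (probes_per_region < 4)
    stop("probes_per_region must be >= 4: every core region needs at least ",
         "4 supporting probes")
  cl <- hg19ChromLengths()
  cat_tab <- .syndromeCatalog()
  ## unique genomic loci from the catalog (del/dup pairs share an interval)
  loci <- cat_tab[!duplicated(cat_tab[c("chrom", "start", "end")]), ]
  n_named <- min(nrow(loci), n_core_regions)
  reg <- data.frame(chrom = loci$chrom[seq_len(n_named)],
                    start = loci$start[seq_len(n_named)],
                    end = loci$end[seq_len(n_named)],
                    syndrome_name = loci$syndrome_name[seq_len(n_named)],
                    stringsAsFactors = FALSE)
  n_extra <- n_core_regions - n_named
  if (n_extra > 0) {
    ## draw extra loci, rejecting any within 2 Mb of a catalog locus or of
    ## an already accepted locus (keeps simulated tiers from cross-matching)
    rs <- .rngState(seed)
    n_draw <- 4 * n_extra + 40
    chrom <- sample(AUTOSOMES, n_draw, replace = TRUE,
                    prob = cl[AUTOSOMES] / sum(cl[AUTOSOMES]))
    width <- round(stats::runif(n_draw, 1e6, 3e6))
    start <- floor(stats::runif(n_draw, 5e6, cl[chrom] - 5e6 - width))
    .rngRestore(rs)
    cand <- data.frame(chrom = chrom, start = start, end = start + width,
                       stringsAsFactors = FALSE)
    acc <- reg[c("chrom", "start", "end")]
    keep <- integer(0)
    pad <- 2e6
    for (i in seq_len(n_draw)) {
      clash <- any(acc$chrom == cand$chrom[i] &
                   acc$start - pad <= cand$end[i] &
                   acc$end + pad >= cand$start[i])
      if (!clash) {
        keep <- c(keep, i)
        acc <- rbind(acc, cand[i, ])
        if (length(keep) == n_extra) break
      }
    }
    if (length(keep) < n_extra)
      stop("could not place ", n_extra, " non-overlapping core regions")
    cand <- cand[keep, ]
    reg <- rbind(reg, data.frame(chrom = cand$chrom, start = cand$start,
                                 end = cand$end, syndrome_name = NA,
                                 stringsAsFactors = FALSE))
  }
  reg$region_id <- sprintf("cnv_%03d", seq_len(nrow(reg)))
  reg$kind <- "core_cnv"

  ## core probes evenly spaced inside each region
  core <- do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
    pos <- round(seq(reg$start[i], reg$end[i],
                     length.out = probes_per_region + 2))[-c(1, probes_per_region + 2)]
    data.frame(chrom = reg$chrom[i], start = pos,
               region_id = reg$region_id[i], kind = "core_cnv",
               stringsAsFactors = FALSE)
  }))

  ## telomeric probes at ~0/10/20 Mb from both chromosome ends
  off <- c(0, 10e6, 20e6)
  telo <- do.call(rbind, lapply(CHROMS, function(ch) {
    p_start <- pmin(off + 5e5, cl[ch])
    p_end <- pmax(cl[ch] - off - 5e5, 1)
    data.frame(chrom = ch, start = c(p_start, p_end),
               region_id = sprintf("tel_%s%s_%dMb", ch,
                                   rep(c("p", "q"), each = 3), off / 1e6),
               kind = "telomeric", stringsAsFactors = FALSE)
  }))

  ## backbone probes across every chromosome
  if (is.null(n_backbone)) {
    bb <- do.call(rbind, lapply(CHROMS, function(ch) {
      pos <- seq(backbone_spacing / 2, cl[ch], by = backbone_spacing)
      data.frame(chrom = ch, start = round(pos), region_id = "backbone",
                 kind = "backbone", stringsAsFactors = FALSE)
    }))
  } else {
    n_per <- .apportion(n_backbone, cl[CHROMS])
    bb <- do.call(rbind, lapply(seq_along(CHROMS), function(i) {
      if (n_per[i] == 0) return(NULL)
      ch <- CHROMS[i]
      pos <- round(seq(cl[ch] / (n_per[i] + 1), cl[ch] * n_per[i] / (n_per[i] + 1),
                       length.out = n_per[i]))
      data.frame(chrom = ch, start = pos, region_id = "backbone",
                 kind = "backbone", stringsAsFactors = FALSE)
    }))
  }

  pr <- rbind(core, telo, bb)
  pr$start <- pmin(pmax(pr$start, 1), cl[pr$chrom] - 120)
  pr$end <- pr$start + 120  # nominal ligated-probe footprint
  ## avoid exact duplicate coordinates (telomeric/backbone collisions)
  dup <- duplicated(pr[c("chrom", "start")])
  while (any(dup)) {
    pr$start[dup] <- pr$start[dup] + 200
    pr$end[dup] <- pr$start[dup] + 120
    dup <- duplicated(pr[c("chrom", "start")])
  }
  o <- order(match(pr$chrom, CHROMS), pr$start)
  pr <- pr[o, ]
  n <- nrow(pr)
  pr$probe_id <- sprintf("P%04d", seq_len(n))
  pr$channel <- rep_len(1:4, n)
  pr$amplicon_length <- 100L + 2L * (ave(seq_len(n), pr$channel,
                                         FUN = seq_along) - 1L)

  probes <- .mkGRanges(pr$chrom, pr$start, pr$end, probe_id = pr$probe_id,
                       region_id = pr$region_id, kind = pr$kind,
                       channel = as.integer(pr$channel),
                       amplicon_length = as.integer(pr$amplicon_length))
  tel_reg <- telo
  reg_all <- rbind(reg[c("chrom", "start", "end", "region_id", "kind",
                         "syndrome_name")],
                   data.frame(chrom = tel_reg$chrom, start = tel_reg$start,
                              end = tel_reg$start + 120,
                              region_id = tel_reg$region_id,
                              kind = "telomeric", syndrome_name = NA))
  regions <- .mkGRanges(reg_all$chrom, reg_all$start, reg_all$end,
                        region_id = reg_all$region_id, kind = reg_all$kind,
                        syndrome_name = reg_all$syndrome_name)
  regions <- regions[.sortPanelOrder(regions)]
  methods::new("ProbePanel", probes = probes, regions = regions,
               chromLengths = cl)
}

#' Default 1,602-probe screening panel
#'
#' The bundled panel configuration: 206 core CNV regions with 6 probes
#' each, 144 telomeric probes (0/10/20 Mb from each telomere of the 24
#' chromosomes) and 222 backbone probes, totalling 1,602 probes.
#'
#' @param seed integer seed passed to [makeDefaultPanel()].
#' @return A [ProbePanel-class] of 1,602 probes.
#' @export
defaultPanel <- function(seed = 1) {
  makeDefaultPanel(n_core_regions = 206, probes_per_region = 6, seed = seed,
                   n_backbone = 222)
}

## largest-remainder apportionment of n slots proportional to w
.apportion <- function(n, w) {
  q <- n * w / sum(w)
  f <- floor(q)
  rem <- n - sum(f)
  if (rem > 0) {
    o <- order(q - f, decreasing = TRUE)
    f[o[seq_len(rem)]] <- f[o[seq_len(rem)]] + 1
  }
  as.integer(f)
}

## seeded RNG scoped to a function body
.rngState <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
.rngRestore <- function(old) {
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Validate a probe panel
#'
#' Checks the full panel design contract and returns human-readable
#' violation descriptions instead of throwing: probe coordinates valid and
#' sorted, every `region_id` resolvable, every chromosome covered, every
#' core CNV region covered by at least 4 probes, amplicon lengths unique
#' within a channel, telomeric regions near 0/10/20 Mb of a chromosome end.
#'
#' @param panel a [ProbePanel-class].
#' @return Character vector of violations; empty when the panel is valid.
#' @export
validatePanel <- function(panel) {
  v <- character()
  p <- panel@probes
  mc <- mcols(p)
  if (is.unsorted(.sortPanelOrder(p)))
    v <- c(v, "probes are not sorted by chromosome and start")
  if (anyDuplicated(mc$probe_id))
    v <- c(v, "duplicate probe ids")
  key <- paste(mc$channel, mc$amplicon_length)
  if (anyDuplicated(key))
    v <- c(v, "amplicon_length not unique within channel")
  known <- c(mcols(panel@regions)$region_id, "backbone")
  bad <- setdiff(unique(mc$region_id), known)
  if (length(bad))
    v <- c(v, paste("unresolved region ids:", paste(bad, collapse = ", ")))
  missing_chr <- setdiff(CHROMS, unique(as.character(seqnames(p))))
  if (length(missing_chr))
    v <- c(v, paste("chromosomes without probes:",
                    paste(missing_chr, collapse = ", ")))
  core <- mcols(panel@regions)$region_id[mcols(panel@regions)$kind == "core_cnv"]
  np <- table(mc$region_id[mc$kind == "core_cnv"])
  thin <- core[!(core %in% names(np)) | np[core] < 4]
  thin <- thin[!is.na(thin)]
  if (length(thin))
    v <- c(v, paste("core regions with fewer than 4 probes:",
                    paste(thin, collapse = ", ")))
  ## telomeric placement
  tel <- panel@regions[mcols(panel@regions)$kind == "telomeric"]
  if (length(tel)) {
    cl <- panel@chromLengths[as.character(seqnames(tel))]
    d_end <- pmin(start(tel), cl - end(tel))
    off <- abs(outer(d_end, c(0, 10e6, 20e6), "-"))
    if (any(apply(off, 1, min) > 2e6))
      v <- c(v, "telomeric regions not at ~0/10/20 Mb from a chromosome end")
  }
  v
}

PANEL_COLS <- c("probe_id", "chrom", "start", "end", "region_id", "kind",
                "channel", "amplicon_length")

#' Read and write panel files
#'
#' The panel TSV has header
#' `probe_id chrom start end region_id kind channel amplicon_length` with
#' 0-based half-open coordinates. `loadPanel()` validates the result and
#' fails on duplicate probe ids or on duplicate amplicon lengths within a
#' channel; target regions are reconstructed from the probe records (core
#' region intervals spanning their probes, using catalog syndrome names
#' when `region_id`s match the default panel).
#'
#' @param path panel TSV path.
#' @param panel a [ProbePanel-class].
#' @param syndrome_names optional named character vector mapping
#'   `region_id` to syndrome name, used when reconstructing regions.
#' @return `loadPanel()` a `ProbePanel`; `writePanel()` the path, invisibly.
#' @export
loadPanel <- function(path, syndrome_names = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(PANEL_COLS, colnames(tab))
  if (length(miss))
    stop("panel file lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(is.na(tab$start) | is.na(tab$end) | tab$start >= tab$end |
               !(tab$chrom %in% CHROMS))
  if (length(bad))
    stop("malformed panel rows (1-based data lines): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (anyDuplicated(tab$probe_id))
    stop("duplicate probe ids in panel file")
  if (anyDuplicated(paste(tab$channel, tab$amplicon_length)))
    stop("duplicate amplicon_length within a channel")
  probes <- .mkGRanges(tab$chrom, tab$start + 1, tab$end,
                       probe_id = tab$probe_id, region_id = tab$region_id,
                       kind = tab$kind, channel = as.integer(tab$channel),
                       amplicon_length = as.integer(tab$amplicon_length))
  probes <- probes[.sortPanelOrder(probes)]
  ## reconstruct regions from probe membership
  mc <- mcols(probes)
  idx <- mc$region_id != "backbone"
  sp <- split(seq_along(probes)[idx], mc$region_id[idx])
  reg <- do.call(rbind, lapply(names(sp), function(rid) {
    i <- sp[[rid]]
    data.frame(chrom = as.character(seqnames(probes))[i[1]],
               start = min(start(probes)[i]), end = max(end(probes)[i]),
               region_id = rid, kind = mc$kind[i[1]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(syndrome_names)) {
    cat_tab <- .syndromeCatalog()
    loci <- cat_tab[!duplicated(cat_tab[c("chrom", "start", "end")]), ]
    syndrome_names <- stats::setNames(
      loci$syndrome_name, sprintf("cnv_%03d", seq_len(nrow(loci))))
  }
  reg$syndrome_name <- unname(syndrome_names[reg$region_id])
  regions <- .mkGRanges(reg$chrom, reg$start, reg$end,
                        region_id = reg$region_id, kind = reg$kind,
                        syndrome_name = reg$syndrome_name)
  regions <- regions[.sortPanelOrder(regions)]
  methods::new("ProbePanel", probes = probes, regions = regions,
               chromLengths = hg19ChromLengths())
}

#' @rdname loadPanel
#' @export
writePanel <- function(panel, path) {
  p <- panel@probes
  tab <- data.frame(probe_id = mcols(p)$probe_id,
                    chrom = as.character(seqnames(p)),
                    start = start(p) - 1, end = end(p),
                    region_id = mcols(p)$region_id, kind = mcols(p)$kind,
                    channel = mcols(p)$channel,
                    amplicon_length = mcols(p)$amplicon_length)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export panel probes as BED6
#'
#' @param panel a [ProbePanel-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writePanelBed <- function(panel, path) {
  p <- panel@probes
  bed <- data.frame(chrom = as.character(seqnames(p)), start = start(p) - 1,
                    end = end(p), name = mcols(p)$probe_id, score = 0,
                    strand = "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
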
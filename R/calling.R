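CALL_COLS <- c("sample_id", "chrom", "start", "end", "svtype", "copy_number",
               "n_support_probes", "region_id", "mean_ratio")

.emptyCalls <- function() {
  data.frame(sample_id = character(), chrom = character(), start = integer(),
             end = integer(), svtype = character(), copy_number = integer(),
             n_support_probes = integer(), region_id = character(),
             mean_ratio = numeric(), stringsAsFactors = FALSE)
}

## expected ratio per probe given the sample's inferred sex: the reference
## panel carries two X copies (XX refs) and one Y copy (XY refs), so an XX
## sample expects 2.0 on X and 0 on Y, an XY sample 1.0 on X and 2.0 on Y.
.expectedRatio <- function(chr, sex) {
  e <- rep(2, length(chr))
  if (sex == "XX") {
    e[chr == "Y"] <- 0
  } else if (sex == "XY") {
    e[chr == "X"] <- 1
  } else {
    e[chr %in% c("X", "Y")] <- NA  # handled by the aneuploidy caller
  }
  e
}

#' Call per-probe copy states
#'
#' Thresholds each probe ratio into `LOSS` (ratio at or below `del_max`),
#' `GAIN` (at or above `dup_min`) or `NEUTRAL`, with `NOCALL` for missing
#' ratios. Thresholds are expressed on the diploid 2.0 scale and rescaled
#' by the sex-aware expected ratio on sex chromosomes (for an XY sample an
#' X probe expects 1.0, so its loss threshold is `del_max/2`). Probes whose
#' expectation is 0 (Y in XX) are `GAIN` when the ratio reaches 0.5. Sex
#' chromosomes of samples with indeterminate sex are left `NOCALL` here;
#' [callAneuploidies()] resolves them from median dose.
#'
#' @param rm a [RatioMatrix-class].
#' @param panel a [ProbePanel-class].
#' @param del_max,dup_min loss/gain thresholds; must satisfy
#'   `del_max < 2 < dup_min`. Defaults 1.5 and 2.5, the midpoints between
#'   the 1-, 2- and 3-copy ratio expectations.
#' @return Character matrix (probes x samples) of states.
#' @export
callProbeStates <- function(rm, panel, del_max = 1.5, dup_min = 2.5) {
  if (!(del_max < 2 && dup_min > 2))
    stop("thresholds must satisfy del_max < 2 < dup_min")
  r <- ratioMatrix(rm)
  chr <- as.character(seqnames(panel@probes))
  sex <- sampleSex(rm)
  states <- matrix("NOCALL", nrow = nrow(r), ncol = ncol(r),
                   dimnames = dimnames(r))
  for (j in seq_len(ncol(r))) {
    e <- .expectedRatio(chr, sex[j])
    x <- r[, j]
    s <- rep("NEUTRAL", length(x))
    pos <- !is.na(e) & e > 0
    s[pos & !is.na(x) & x <= del_max * e / 2] <- "LOSS"
    s[pos & !is.na(x) & x >= dup_min * e / 2] <- "GAIN"
    zero <- !is.na(e) & e == 0
    s[zero & !is.na(x) & x >= 0.5] <- "GAIN"
    s[is.na(x) | is.na(e)] <- "NOCALL"
    states[, j] <- s
  }
  states
}

#' Call CNVs at core target regions
#'
#' A core region is called in a sample when at least `min_probes` of its
#' probes share a non-neutral state and those probes make up at least
#' `region_fraction` of the region's probes. The call interval is the
#' region interval; the copy number is the rounded mean ratio over the
#' region's probes (dose scale, clipped to 0..4; for Y regions the rounded
#' half mean ratio, since the reference carries a single Y).
#'
#' @param states state matrix from [callProbeStates()].
#' @param rm a [RatioMatrix-class].
#' @param panel a [ProbePanel-class].
#' @param min_probes minimum concordant non-neutral probes (default 4).
#' @param region_fraction minimum concordant fraction of the region's
#'   probes (default 0.8).
#' @param exclude per-sample list of chromosomes to skip (aneuploid).
#' @return Calls `data.frame` (see [callCnvs()] for columns).
#' @export
callRegions <- function(states, rm, panel, min_probes = 4,
                        region_fraction = 0.8, exclude = list()) {
  if (min_probes < 1) stop("min_probes must be >= 1")
  r <- ratioMatrix(rm)
  p <- panel@probes
  reg <- panel@regions
  core <- reg[mcols(reg)$kind == "core_cnv"]
  chr_p <- as.character(seqnames(p))
  idx_by_region <- split(seq_along(p), mcols(p)$region_id)
  out <- list()
  for (k in seq_along(core)) {
    rid <- mcols(core)$region_id[k]
    i <- idx_by_region[[rid]]
    if (is.null(i)) next
    chrom <- as.character(seqnames(core))[k]
    st <- states[i, , drop = FALSE]
    nL <- colSums(st == "LOSS")
    nG <- colSums(st == "GAIN")
    nn <- pmax(nL, nG)
    hit <- which(nn >= min_probes & nn >= region_fraction * length(i))
    for (j in hit) {
      sid <- colnames(states)[j]
      if (chrom %in% exclude[[sid]]) next
      mr <- mean(r[i, j], na.rm = TRUE)
      cn <- if (chrom == "Y") round(mr / 2) else round(mr)
      cn <- max(0L, min(4L, as.integer(cn)))
      out[[length(out) + 1]] <- data.frame(
        sample_id = sid, chrom = chrom, start = start(core)[k],
        end = end(core)[k],
        svtype = if (nL[j] >= nG[j]) "DEL" else "DUP",
        copy_number = cn, n_support_probes = as.integer(nn[j]),
        region_id = rid, mean_ratio = mr, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else .emptyCalls()
}

#' Merge backbone probes into CNV segments
#'
#' Maximal runs of at least `min_run` consecutive backbone or telomeric
#' probes sharing a non-neutral state on one chromosome become a single
#' call spanning the first to last probe of the run.
#'
#' @inheritParams callRegions
#' @param min_run minimum run length (default 4).
#' @return Calls `data.frame` with `region_id = NA`.
#' @export
mergeBackboneSegments <- function(states, rm, panel, min_run = 4,
                                  exclude = list()) {
  r <- ratioMatrix(rm)
  p <- panel@probes
  bb <- which(mcols(p)$kind %in% c("backbone", "telomeric"))
  chr_bb <- as.character(seqnames(p))[bb]
  out <- list()
  for (j in seq_len(ncol(states))) {
    sid <- colnames(states)[j]
    for (ch in unique(chr_bb)) {
      if (ch %in% exclude[[sid]]) next
      i <- bb[chr_bb == ch]           # panel order = genomic order
      s <- states[i, j]
      rl <- rle(s)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1
      for (k in which(rl$values %in% c("LOSS", "GAIN") & rl$lengths >= min_run)) {
        run <- i[starts[k]:ends[k]]
        mr <- mean(r[run, j], na.rm = TRUE)
        cn <- if (ch == "Y") round(mr / 2) else round(mr)
        out[[length(out) + 1]] <- data.frame(
          sample_id = sid, chrom = ch, start = start(p)[run[1]],
          end = end(p)[run[length(run)]],
          svtype = if (rl$values[k] == "LOSS") "DEL" else "DUP",
          copy_number = max(0L, min(4L, as.integer(cn))),
          n_support_probes = length(run), region_id = NA_character_,
          mean_ratio = mr, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else .emptyCalls()
}

#' Call whole-chromosome aneuploidies and assemble karyotypes
#'
#' An autosome is called gained/lost in a sample when at least
#' `chrom_fraction` of its probes share the state. Sex-chromosome copy
#' counts are estimated from median dose (X on the two-copy reference
#' scale, Y on the one-copy scale) and compared with the nearest normal
#' complement (XX when no Y material, else XY). The ISCN-like designation
#' is assembled from the resulting counts, e.g. `"47,XX,+21"` or `"45,X"`.
#'
#' @inheritParams callRegions
#' @param chrom_fraction fraction of concordant probes required for an
#'   autosomal aneuploidy (default 0.8, in (0.5, 1]).
#' @return list with `calls` (aneuploidy calls `data.frame`) and
#'   `karyotypes` (`sample_id`, `total_count`, `sex_chromosomes`,
#'   `designation`).
#' @export
callAneuploidies <- function(states, rm, panel, chrom_fraction = 0.8) {
  if (chrom_fraction <= 0.5 || chrom_fraction > 1)
    stop("chrom_fraction must lie in (0.5, 1]")
  r <- ratioMatrix(rm)
  p <- panel@probes
  chr <- as.character(seqnames(p))
  cl <- panel@chromLengths
  calls <- list(); karyo <- list()
  for (j in seq_len(ncol(states))) {
    sid <- colnames(states)[j]
    aut_delta <- integer(0); suffix <- character(0)
    for (ch in AUTOSOMES) {
      i <- which(chr == ch)
      s <- states[i, j]
      known <- s != "NOCALL"
      if (!sum(known)) next
      fG <- sum(s == "GAIN") / sum(known)
      fL <- sum(s == "LOSS") / sum(known)
      if (fG >= chrom_fraction || fL >= chrom_fraction) {
        gain <- fG >= fL
        mr <- stats::median(r[i, j], na.rm = TRUE)
        cn <- max(0L, min(4L, as.integer(round(mr))))
        aut_delta <- c(aut_delta, if (gain) cn - 2L else cn - 2L)
        suffix <- c(suffix, paste0(if (gain) "+" else "-", ch))
        calls[[length(calls) + 1]] <- data.frame(
          sample_id = sid, chrom = ch, start = 1, end = unname(cl[ch]),
          svtype = if (gain) "ANEUPLOIDY_GAIN" else "ANEUPLOIDY_LOSS",
          copy_number = cn, n_support_probes = length(i),
          region_id = NA_character_, mean_ratio = mr,
          stringsAsFactors = FALSE)
      }
    }
    mX <- stats::median(r[chr == "X", j], na.rm = TRUE)
    mY <- stats::median(r[chr == "Y", j], na.rm = TRUE)
    if (is.na(mY)) mY <- 0
    xc <- max(0L, as.integer(round(mX)))
    yc <- max(0L, as.integer(round(mY / 2)))
    base <- if (yc >= 1) c(1L, 1L) else c(2L, 0L)  # XY vs XX baseline
    if (xc != base[1] || yc != base[2]) {
      sex_ch <- if (xc != base[1]) "X" else "Y"
      delta <- if (sex_ch == "X") xc - base[1] else yc - base[2]
      mr <- if (sex_ch == "X") mX else mY
      calls[[length(calls) + 1]] <- data.frame(
        sample_id = sid, chrom = sex_ch, start = 1,
        end = unname(cl[sex_ch]),
        svtype = if (delta > 0) "ANEUPLOIDY_GAIN" else "ANEUPLOIDY_LOSS",
        copy_number = if (sex_ch == "X") xc else yc,
        n_support_probes = sum(chr == sex_ch),
        region_id = NA_character_, mean_ratio = mr,
        stringsAsFactors = FALSE)
    }
    total <- 44L + sum(aut_delta) + xc + yc
    sexstr <- paste0(strrep("X", xc), strrep("Y", yc))
    desig <- paste(c(paste0(total, ",", sexstr), suffix), collapse = ",")
    karyo[[length(karyo) + 1]] <- data.frame(
      sample_id = sid, total_count = total, sex_chromosomes = sexstr,
      designation = desig, stringsAsFactors = FALSE)
  }
  list(calls = if (length(calls)) do.call(rbind, calls) else .emptyCalls(),
       karyotypes = do.call(rbind, karyo))
}

#' Full CNV calling on a ratio matrix
#'
#' Runs probe-state calling, aneuploidy calling, core-region calling and
#' backbone segmentation in order. Chromosomes called aneuploid in a sample
#' are excluded from that sample's region and backbone calls, and backbone
#' segments overlapping a region call are dropped, so per-sample calls
#' never overlap on the genome. Reference samples are not called.
#'
#' @param rm a [RatioMatrix-class].
#' @param panel a [ProbePanel-class].
#' @param del_max,dup_min probe-state thresholds (see [callProbeStates()]).
#' @param min_probes,region_fraction core-region rule (see [callRegions()]).
#' @param min_run backbone rule (see [mergeBackboneSegments()]).
#' @param chrom_fraction aneuploidy rule (see [callAneuploidies()]).
#' @param include_references also call the reference samples.
#' @return list with `calls` (columns `sample_id chrom start end svtype
#'   copy_number n_support_probes region_id mean_ratio`) and `karyotypes`.
#' @export
callCnvs <- function(rm, panel, del_max = 1.5, dup_min = 2.5, min_probes = 4,
                     region_fraction = 0.8, min_run = 4, chrom_fraction = 0.8,
                     include_references = FALSE) {
  if (!include_references) {
    keep <- !SummarizedExperiment::colData(rm)$is_reference
    rm <- rm[, keep]
  }
  states <- callProbeStates(rm, panel, del_max = del_max, dup_min = dup_min)
  an <- callAneuploidies(states, rm, panel, chrom_fraction = chrom_fraction)
  excl <- split(an$calls$chrom, an$calls$sample_id)
  regc <- callRegions(states, rm, panel, min_probes = min_probes,
                      region_fraction = region_fraction, exclude = excl)
  bbc <- mergeBackboneSegments(states, rm, panel, min_run = min_run,
                               exclude = excl)
  if (nrow(bbc) && nrow(regc)) {
    drop <- logical(nrow(bbc))
    for (i in seq_len(nrow(bbc))) {
      same <- regc$sample_id == bbc$sample_id[i] & regc$chrom == bbc$chrom[i]
      drop[i] <- any(same & regc$start <= bbc$end[i] & regc$end >= bbc$start[i])
    }
    bbc <- bbc[!drop, , drop = FALSE]
  }
  calls <- rbind(an$calls, regc, bbc)
  if (nrow(calls)) {
    calls <- calls[order(calls$sample_id, match(calls$chrom, CHROMS),
                         calls$start), ]
    rownames(calls) <- NULL
  }
  list(calls = calls, karyotypes = an$karyotypes)
}

#' Convert a calls table to GRanges
#'
#' @param calls calls `data.frame` from [callCnvs()].
#' @return `GRanges` with the call annotations as metadata columns.
#' @export
callsAsGRanges <- function(calls) {
  .mkGRanges(calls$chrom, calls$start, calls$end,
             sample_id = calls$sample_id, svtype = calls$svtype,
             copy_number = calls$copy_number,
             n_support_probes = calls$n_support_probes,
             region_id = calls$region_id, mean_ratio = calls$mean_ratio)
}

#' Read and write calls tables
#'
#' @param calls calls `data.frame`; `path` a TSV path.
#' @param path file path.
#' @return `writeCalls()` the path invisibly; `readCalls()` the table.
#' @export
writeCalls <- function(calls, path) {
  utils::write.table(calls[CALL_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeCalls
#' @export
readCalls <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(region_id = "character"))
}
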
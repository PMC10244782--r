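#' Intra-sample normalization
#'
#' Divides every probe's peak by the sample's median autosomal backbone
#' peak, removing the per-sample scale factor (exactly so at zero noise).
#' Peaks that are missing (`NA`) or non-positive at autosomal probes count
#' as missing; a sample with more than `max_missing` missing autosomal
#' probes is flagged as QC failure and excluded downstream. Zero signal at
#' Y probes is expected for XX samples and never counts as missing.
#'
#' @param peaks probes x samples matrix of raw peak heights.
#' @param panel a [ProbePanel-class] matching the rows.
#' @param max_missing maximum tolerated fraction of missing autosomal
#'   probes per sample (default 0.10).
#' @return list with `relvals` (probes x samples relative values, `NA` where
#'   missing) and `qc_fail` (named logical per sample).
#' @export
intraSampleNormalize <- function(peaks, panel, max_missing = 0.10) {
  p <- panel@probes
  ids <- mcols(p)$probe_id
  if (!all(ids %in% rownames(peaks)))
    stop("peak table lacks columns for some panel probes")
  peaks <- peaks[ids, , drop = FALSE]
  chr <- as.character(seqnames(p))
  auto <- chr %in% AUTOSOMES
  backbone <- auto & mcols(p)$kind %in% c("backbone", "telomeric")
  missing <- is.na(peaks) | peaks <= 0
  frac_miss <- colMeans(missing[auto, , drop = FALSE])
  qc_fail <- frac_miss > max_missing
  denom <- apply(peaks[backbone, , drop = FALSE], 2, function(x)
    stats::median(x[!is.na(x) & x > 0]))
  relvals <- sweep(peaks, 2, denom, "/")
  relvals[missing & auto] <- NA  # autosomal no-calls; sex-chromosome zeros stand
  relvals[missing & !auto & is.na(peaks)] <- NA
  relvals[!is.na(relvals) & relvals < 0] <- NA
  ## a sex-chromosome zero is a legitimate dose of 0
  sexrow <- !auto
  z <- !is.na(peaks) & peaks == 0 & sexrow
  relvals[z] <- 0
  list(relvals = relvals, qc_fail = stats::setNames(qc_fail, colnames(peaks)))
}

## classify reference samples as XY when they carry clear Y signal
.refIsMale <- function(relvals, panel) {
  chr <- as.character(seqnames(panel@probes))
  ymed <- apply(relvals[chr == "Y", , drop = FALSE], 2, stats::median,
                na.rm = TRUE)
  amed <- apply(relvals[chr %in% AUTOSOMES, , drop = FALSE], 2,
                stats::median, na.rm = TRUE)
  ymed > 0.25 * amed
}

#' Inter-sample (reference) normalization
#'
#' Scales every probe's relative value by the median relative value of the
#' reference samples at that probe and multiplies by 2, so a copy-neutral
#' diploid locus reads about 2.0 (exactly 2.0 at zero noise: the reference
#' median cancels the probe efficiency). X probes are normalized against
#' the XX references only and Y probes against the XY references only
#' (reference sex determined from their own Y signal), so the ratio scale
#' on sex chromosomes is dose-relative to the reference complement: an XX
#' sample reads 2.0 on X and 0 on Y, an XY sample 1.0 on X and 2.0 on Y.
#'
#' When no designated references are supplied the cohort-wide per-probe
#' median is used (self-normalization) with a warning; this is safe when
#' events are rare.
#'
#' @param relvals,qc_fail output of [intraSampleNormalize()].
#' @param panel a [ProbePanel-class].
#' @param reference_ids ids of the designated diploid reference samples
#'   (at least 3), or `NULL` for self-normalization.
#' @return A [RatioMatrix-class]; QC-failed samples are dropped.
#' @export
interSampleNormalize <- function(relvals, panel, reference_ids = NULL,
                                 qc_fail = NULL) {
  if (is.null(qc_fail))
    qc_fail <- stats::setNames(rep(FALSE, ncol(relvals)), colnames(relvals))
  keep <- colnames(relvals)[!qc_fail[colnames(relvals)]]
  self_norm <- is.null(reference_ids)
  if (self_norm) {
    warning("no reference samples designated; using cohort-wide per-probe ",
            "medians (self-normalization)")
    reference_ids <- keep
  }
  reference_ids <- intersect(reference_ids, keep)
  if (length(reference_ids) < 3)
    stop("inter-sample normalization requires at least 3 reference samples")
  rv <- relvals[, keep, drop = FALSE]
  chr <- as.character(seqnames(panel@probes))
  refs <- rv[, reference_ids, drop = FALSE]
  male <- .refIsMale(refs, panel)
  med_for <- function(cols, rows) {
    if (!length(cols)) return(NULL)
    apply(refs[rows, cols, drop = FALSE], 1, stats::median, na.rm = TRUE)
  }
  refmed <- apply(refs, 1, stats::median, na.rm = TRUE)
  xx_med <- med_for(which(!male), chr == "X")
  xy_medX <- med_for(which(male), chr == "X")
  y_med <- med_for(which(male), chr == "Y")
  if (!is.null(xx_med)) refmed[chr == "X"] <- xx_med
  else if (!is.null(xy_medX)) {
    ## only male references: their X carries one copy, rescale to two
    refmed[chr == "X"] <- 2 * xy_medX
    warning("no XX reference samples; X normalized against rescaled XY references")
  }
  if (!is.null(y_med)) refmed[chr == "Y"] <- y_med
  else {
    refmed[chr == "Y"] <- NA
    warning("no XY reference samples; Y-probe ratios set to no-call")
  }
  refmed[!is.na(refmed) & refmed <= 0] <- NA
  ratios <- 2 * sweep(rv, 1, refmed, "/")
  ratios[!is.na(ratios) & ratios < 0] <- NA
  cd <- DataFrame(sample_id = keep, is_reference = keep %in% reference_ids,
                  qc_fail = FALSE)
  dropped <- names(qc_fail)[qc_fail]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ratio = ratios), rowRanges = panel@probes, colData = cd)
  rm <- methods::new("RatioMatrix", se)
  sx <- inferSex(rm, panel)
  SummarizedExperiment::colData(rm)$sex <- sx
  S4Vectors::metadata(rm)$qc_failed_samples <- dropped
  S4Vectors::metadata(rm)$self_normalized <- self_norm
  rm
}

#' Infer sample sex from probe ratios
#'
#' Template match on median ratios: `XY` when the median Y ratio is at
#' least half the median autosomal ratio and the median X ratio is about
#' half autosomal; `XX` when Y signal is near zero and X is about
#' autosomal; otherwise `indeterminate`, which routes the sample to
#' whole-chromosome aneuploidy evaluation (45,X, 47,XXX, 47,XXY, ...).
#'
#' @param x a [RatioMatrix-class] or a named per-sample ratio vector.
#' @param panel a [ProbePanel-class].
#' @param tol relative tolerance of the X-dose template match.
#' @return Character vector (`XX`, `XY`, `indeterminate`) per sample.
#' @export
inferSex <- function(x, panel, tol = 0.2) {
  r <- if (methods::is(x, "RatioMatrix")) ratioMatrix(x) else
    matrix(x, ncol = 1, dimnames = list(names(x), "sample"))
  chr <- as.character(seqnames(panel@probes))
  if (sum(chr == "X") < 2 || sum(chr == "Y") < 2)
    stop("sex inference needs at least 2 X probes and 2 Y probes")
  med <- function(rows) apply(r[rows, , drop = FALSE], 2, stats::median,
                              na.rm = TRUE)
  mA <- med(chr %in% AUTOSOMES)
  mX <- med(chr == "X")
  mY <- med(chr == "Y")
  mY[is.na(mY)] <- 0
  is_xy <- mY >= 0.5 * mA & abs(mX - 0.5 * mA) <= tol * mA
  is_xx <- mY <= 0.25 * mA & abs(mX - mA) <= tol * mA
  out <- ifelse(is_xy, "XY", ifelse(is_xx, "XX", "indeterminate"))
  stats::setNames(out, colnames(r))
}

#' One-step quantification
#'
#' Convenience wrapper running [intraSampleNormalize()] then
#' [interSampleNormalize()].
#'
#' @param peaks probes x samples raw peak matrix.
#' @param panel a [ProbePanel-class].
#' @param reference_ids reference sample ids (or `NULL`).
#' @param max_missing QC threshold, see [intraSampleNormalize()].
#' @return A [RatioMatrix-class].
#' @export
quantifyRatios <- function(peaks, panel, reference_ids = NULL,
                           max_missing = 0.10) {
  intra <- intraSampleNormalize(peaks, panel, max_missing = max_missing)
  interSampleNormalize(intra$relvals, panel, reference_ids = reference_ids,
                       qc_fail = intra$qc_fail)
}
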
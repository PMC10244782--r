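#' Score pipeline calls against simulation truth
#'
#' Computes region-call sensitivity and false-positive rate of a
#' simulate -> quantify -> call run. A spiked core-region CNV is eligible
#' when it changes the sample's expected local dose and its chromosome is
#' not also aneuploid in that sample; it counts as recovered when a region
#' call with the same sample, region and CNV type exists. A region call is
#' a false positive when no truth event exists for that sample and region.
#' Aneuploidy truth (autosomal trisomies/monosomies and sex-complement
#' deviations) is scored against the karyotype designations.
#'
#' @param truth genotype truth (as extended by [simulateSignals()]).
#' @param called output of [callCnvs()].
#' @param rm the [RatioMatrix-class] that was called (defines which samples
#'   survived QC).
#' @return list with `n_events`, `n_recovered`, `sensitivity`,
#'   `n_false_positive`, `fp_per_sample`, `n_samples`, and
#'   `aneuploidy_sensitivity`.
#' @export
benchmarkRecovery <- function(truth, called, rm) {
  cases <- setdiff(colnames(rm),
                   colnames(rm)[SummarizedExperiment::colData(rm)$is_reference])
  tv <- truth$cnvs[truth$cnvs$sample_id %in% cases, , drop = FALSE]
  samp <- truth$samples
  ## expected baseline dose at the event locus
  nx <- vapply(strsplit(samp$sex_chromosomes, ""),
               function(s) sum(s == "X"), integer(1))
  base <- ifelse(tv$chrom == "X", nx[match(tv$sample_id, samp$sample_id)], 2)
  an_ch <- paste(truth$aneuploidies$sample_id, truth$aneuploidies$chrom)
  eligible <- tv$copy_number != base &
    !(paste(tv$sample_id, tv$chrom) %in% an_ch)
  tv <- tv[eligible, , drop = FALSE]
  reg_calls <- called$calls[!is.na(called$calls$region_id), , drop = FALSE]
  key_call <- paste(reg_calls$sample_id, reg_calls$region_id, reg_calls$svtype)
  key_truth <- paste(tv$sample_id, tv$region_id, tv$svtype)
  recovered <- key_truth %in% key_call
  key_truth_any <- paste(tv$sample_id, tv$region_id)
  fp <- !(paste(reg_calls$sample_id, reg_calls$region_id) %in% key_truth_any)
  ## karyotype check: expected designation from truth
  k_truth <- .expectedKaryotypes(truth)
  k_truth <- k_truth[k_truth$sample_id %in% cases, , drop = FALSE]
  k_called <- called$karyotypes
  an_truth <- k_truth[k_truth$designation != paste0("46,", k_truth$sex_chromosomes) |
                        k_truth$total_count != 46, , drop = FALSE]
  an_ok <- an_truth$designation ==
    k_called$designation[match(an_truth$sample_id, k_called$sample_id)]
  list(n_events = nrow(tv), n_recovered = sum(recovered),
       sensitivity = if (nrow(tv)) sum(recovered) / nrow(tv) else NA,
       n_false_positive = sum(fp),
       fp_per_sample = sum(fp) / length(cases),
       n_samples = length(cases),
       aneuploidy_sensitivity = if (nrow(an_truth)) mean(an_ok) else NA)
}

## ISCN-like designation implied by a truth set
.expectedKaryotypes <- function(truth) {
  samp <- truth$samples
  out <- lapply(seq_len(nrow(samp)), function(i) {
    sid <- samp$sample_id[i]
    sx <- samp$sex_chromosomes[i]
    an <- truth$aneuploidies[truth$aneuploidies$sample_id == sid, ,
                             drop = FALSE]
    delta <- if (nrow(an)) sum(an$copy_count - 2) else 0
    total <- 44 + nchar(sx) + delta
    suffix <- if (nrow(an))
      paste0(ifelse(an$copy_count > 2, "+", "-"), an$chrom) else character(0)
    data.frame(sample_id = sid, total_count = total, sex_chromosomes = sx,
               designation = paste(c(paste0(total, ",", sx), suffix),
                                   collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
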
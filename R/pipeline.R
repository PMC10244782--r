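#' Pipeline configuration
#'
#' Builds a validated configuration list for [runPipeline()]. Every entry
#' mirrors a stage parameter; the whole object round-trips through YAML
#' ([writePipelineConfig()] / [readPipelineConfig()]).
#'
#' @param seed master seed; stage seeds derive from it deterministically.
#' @param n_samples number of case samples to simulate.
#' @param n_references diploid reference samples per run.
#' @param noise_cv multiplicative lognormal noise CV of the signal model.
#' @param panel list of [makeDefaultPanel()] arguments (or `panel_path` to
#'   load one).
#' @param panel_path optional panel TSV to load instead of simulating one.
#' @param del_max,dup_min,min_probes,region_fraction,min_run,chrom_fraction
#'   calling thresholds.
#' @param match_ro,min_obs,benign_freq classification thresholds.
#' @param yates,fisher_rule statistics options.
#' @param outdir output directory.
#' @return Named list with class `"hlpa_config"`.
#' @export
pipelineConfig <- function(seed = 1, n_samples = 200, n_references = 20,
                           noise_cv = 0.05,
                           panel = list(n_core_regions = 206,
                                        probes_per_region = 6,
                                        n_backbone = 222),
                           panel_path = NULL,
                           del_max = 1.5, dup_min = 2.5, min_probes = 4,
                           region_fraction = 0.8, min_run = 4,
                           chrom_fraction = 0.8,
                           match_ro = 0.90, min_obs = 3, benign_freq = 0.01,
                           yates = FALSE, fisher_rule = "never",
                           outdir = NULL) {
  cfg <- list(seed = seed, n_samples = n_samples, n_references = n_references,
              noise_cv = noise_cv, panel = panel, panel_path = panel_path,
              del_max = del_max, dup_min = dup_min, min_probes = min_probes,
              region_fraction = region_fraction, min_run = min_run,
              chrom_fraction = chrom_fraction, match_ro = match_ro,
              min_obs = min_obs, benign_freq = benign_freq, yates = yates,
              fisher_rule = fisher_rule, outdir = outdir)
  class(cfg) <- c("hlpa_config", "list")
  validatePipelineConfig(cfg)
  cfg
}

#' @rdname pipelineConfig
#' @param cfg a configuration list.
#' @export
validatePipelineConfig <- function(cfg) {
  if (!(cfg$del_max < 2 && cfg$dup_min > 2))
    stop("invalid thresholds: need del_max < 2 < dup_min")
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0")
  if (cfg$match_ro <= 0 || cfg$match_ro > 1)
    stop("match_ro must lie in (0, 1]")
  if (cfg$chrom_fraction <= 0.5 || cfg$chrom_fraction > 1)
    stop("chrom_fraction must lie in (0.5, 1]")
  if (cfg$n_references < 3) stop("need at least 3 reference samples")
  if (!cfg$fisher_rule %in% c("never", "expected_lt5"))
    stop("unknown fisher_rule")
  invisible(cfg)
}

#' @rdname pipelineConfig
#' @param path YAML path.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(pipelineConfig()), cfg,
                           keep.null = TRUE)
  class(cfg) <- c("hlpa_config", "list")
  validatePipelineConfig(cfg)
  cfg
}

#' Run the full screening pipeline
#'
#' Executes simulate -> quantify -> call -> classify -> cohort statistics
#' in order on a synthetic cohort defined by the configuration, returning
#' all stage objects; when `cfg$outdir` is set, also writes the stage
#' artifacts (panel, cohort files, ratio matrix TSV, calls, karyotypes,
#' classified calls, flags and the JSON report). Deterministic for a fixed
#' configuration.
#'
#' @param cfg configuration from [pipelineConfig()].
#' @return list with `panel`, `truth`, `peaks`, `clinical`, `ratios`
#'   ([RatioMatrix-class]), `called`, `classified`, `flags`, `report` and
#'   `benchmark` (truth-recovery summary from [benchmarkRecovery()]).
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  validatePipelineConfig(cfg)
  panel <- if (!is.null(cfg$panel_path)) loadPanel(cfg$panel_path)
    else do.call(makeDefaultPanel, c(cfg$panel, list(seed = cfg$seed)))
  stopifnot(length(validatePanel(panel)) == 0)
  events <- defaultEventFrequencies(panel)
  truth <- simulateGenotypes(cfg$n_samples, events, panel,
                             seed = cfg$seed)
  sim <- simulateSignals(truth, panel,
                         model = list(noise_cv = cfg$noise_cv,
                                      seed = cfg$seed + 1L),
                         n_references = cfg$n_references)
  clinical <- simulateClinical(sim$truth, seed = cfg$seed + 2L,
                               exclude_ids = sim$samples$sample_id[
                                 sim$samples$is_reference])
  rm <- quantifyRatios(sim$peaks, panel,
                       reference_ids = sim$samples$sample_id[
                         sim$samples$is_reference])
  called <- callCnvs(rm, panel, del_max = cfg$del_max,
                     dup_min = cfg$dup_min, min_probes = cfg$min_probes,
                     region_fraction = cfg$region_fraction,
                     min_run = cfg$min_run,
                     chrom_fraction = cfg$chrom_fraction)
  kb <- makeDefaultKnowledgeBase(panel)
  classified <- classifyCalls(called$calls, kb, match_ro = cfg$match_ro,
                              min_obs = cfg$min_obs,
                              benign_freq = cfg$benign_freq)
  case_ids <- sim$samples$sample_id[!sim$samples$is_reference]
  flags <- flagPpcnv(classified, case_ids)
  report <- buildReport(flags, clinical, fisher_rule = cfg$fisher_rule)
  bench <- benchmarkRecovery(sim$truth, called, rm)
  out <- list(panel = panel, truth = sim$truth, peaks = sim$peaks,
              clinical = clinical, ratios = rm, called = called,
              classified = classified, flags = flags, report = report,
              benchmark = bench)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    writePanel(panel, file.path(cfg$outdir, "panel.tsv"))
    writeCohort(sim, clinical, cfg$outdir)
    writeCalls(called$calls, file.path(cfg$outdir, "calls.tsv"))
    utils::write.table(called$karyotypes,
                       file.path(cfg$outdir, "karyotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(classified, file.path(cfg$outdir, "classified.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(flags, file.path(cfg$outdir, "flags.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeReport(report, cfg$outdir)
    writePipelineConfig(cfg, file.path(cfg$outdir, "config.yaml"))
  }
  out
}
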
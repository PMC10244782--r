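# hlpascreen

Simulation, quantification, calling, classification and cohort statistics
for targeted ligation-probe CNV screening — modeled on a high-throughput
ligation-dependent probe amplification (HLPA) study of 1,762 Chinese
pediatric congenital heart disease (CHD) surgical patients screened with a
1,602-probe panel.

## Background

Chromosomal abnormalities — whole-chromosome aneuploidies and recurrent
microdeletion/microduplication syndromes such as 22q11 deletion and
Williams–Beuren — are a major genetic contributor to congenital heart
disease and are associated with worse surgical outcomes. HLPA-style assays
interrogate the genome with ligation probe pairs amplified by multiplex
PCR and resolved by capillary electrophoresis: each probe's peak height is
proportional to the local DNA copy number times a probe-specific
efficiency and a sample-specific scale. Copy number is recovered by
two-stage normalization (within-sample, then against diploid reference
samples), giving a per-probe ratio on a scale where two copies read ~2.0,
a heterozygous deletion ~1.0 and a duplication ~3.0.

The package implements the full screening workflow on synthetic data:

- **Panel model** (`ProbePanel`, `defaultPanel()`): a 1,602-probe design —
  206 core CNV regions at 6 probes each (including 18 recurrent-syndrome
  loci at GRCh37 coordinates), 144 telomeric probes (0/10/20 Mb from both
  ends of all 24 chromosomes) and 222 genome-wide backbone probes, each
  probe carrying a unique (channel, amplicon length) for electrophoretic
  identification. TSV/BED import/export with validation.
- **Synthetic cohort** (`simulateGenotypes()`, `simulateSignals()`,
  `simulateClinical()`): abnormalities spiked at the published cohort
  frequencies (trisomy 21, sex-chromosome aneuploidies, 21 recurrent
  syndromes, plus benign/likely-benign/uncertain CNVs), a multiplicative
  lognormal peak model, and clinical covariates (surgery times,
  complications, CHD subgroups) drawn conditionally on carrier status.
- **Quantification** (`quantifyRatios()`, `RatioMatrix`): median-based
  intra-sample normalization, reference normalization with sex-partitioned
  X/Y handling, per-sample QC, sex inference.
- **Calling** (`callCnvs()`): per-probe LOSS/NEUTRAL/GAIN states at 1.5/2.5
  thresholds rescaled by sex-aware expectations; core-region calls
  (≥4 concordant probes and ≥80% of the region), backbone segmentation,
  whole-chromosome aneuploidy calls with ISCN-like karyotype designations
  (`47,XX,+21`, `45,X`, `47,XXY`, ...), with a per-sample no-overlap
  guarantee.
- **Classification** (`classifyCalls()`, `KnowledgeBase`): a five-tier
  cascade (pathogenic, likely pathogenic, benign, likely benign, VUS)
  driven by reciprocal overlap (≥0.90) with syndrome regions of compatible
  effect, gene dosage evidence, population frequency (>1% benign) and
  benign-listed intervals. ppCNV = pathogenic ∪ likely pathogenic.
- **Cohort statistics** (`buildReport()`): detection rates, uncorrected
  Pearson chi-squared and exact Fisher tests for carrier/non-carrier
  contrasts, Welch t-tests (from raw data or printed `mean/sd/n`
  summaries), and one-vs-rest CHD subgroup association.
- **Pipeline & I/O** (`pipelineConfig()`, `runPipeline()`): a YAML-configured
  end-to-end run writing all artifacts (panel, cohort, calls, karyotypes,
  classifications, flags, JSON report) plus a truth-recovery benchmark.

The classes follow Bioconductor idiom: `ProbePanel` and `KnowledgeBase`
wrap `GRanges` tracks, `RatioMatrix` extends `RangedSummarizedExperiment`.

## Worked example

```r
library(hlpascreen)

panel <- defaultPanel(seed = 1)
panel
#> ProbePanel with 1602 probes on 24 chromosomes
#>   probes by kind: backbone=222, core_cnv=1236, telomeric=144
#>   target regions: 350 (206 core CNV loci)

events <- defaultEventFrequencies(panel)   # published cohort frequencies
truth  <- simulateGenotypes(200, events, panel, seed = 7)
sim    <- simulateSignals(truth, panel,
                          model = list(noise_cv = 0.05, seed = 8),
                          n_references = 20)

ratios <- quantifyRatios(sim$peaks, panel,
                         reference_ids = sim$samples$sample_id[sim$samples$is_reference])
ratios
#> class: RatioMatrix
#> dim: 1602 220
#> metadata(2): qc_failed_samples self_normalized
#> assays(1): ratio
#> rownames(1602): P0001 P0002 ... P1601 P1602
#> rowData names(5): probe_id region_id kind channel amplicon_length
#> colnames(220): S0001 S0002 ... REF19 REF20
#> colData names(4): sample_id is_reference qc_fail sex

called <- callCnvs(ratios, panel)
head(called$calls[, c("sample_id", "chrom", "start", "end", "svtype",
                      "copy_number", "region_id")], 5)
#>   sample_id chrom     start       end svtype copy_number region_id
#> 1     S0032     2 165516946 166602718    DUP           3   cnv_117
#> 2     S0033     2  13044590  15333252    DEL           1   cnv_068
#> 3     S0033     2 165516946 166602718    DUP           3   cnv_117
#> 4     S0038     2 105643763 107036365    DUP           3   cnv_186
#> 5     S0039    22  18900000  21500000    DEL           1   cnv_001

subset(called$karyotypes, designation != paste0("46,", sex_chromosomes))
#>     sample_id total_count sex_chromosomes designation
#> 103     S0103          47             XXX      47,XXX
#> 141     S0141          47              XX   47,XX,+21

kb <- makeDefaultKnowledgeBase(panel)   # bundled synthetic evidence tracks
classified <- classifyCalls(called$calls, kb)
table(classified$category)
#>            benign     likely_benign likely_pathogenic        pathogenic
#>                11                 9                 3                11
#>               vus
#>                 4

flags    <- flagPpcnv(classified, sim$samples$sample_id[!sim$samples$is_reference])
clinical <- simulateClinical(sim$truth, seed = 9,
                             exclude_ids = sim$samples$sample_id[sim$samples$is_reference])
report   <- buildReport(flags, clinical)
report$rates
#>            metric numerator denominator percent
#> 1         any_cnv        33         200    16.5
#> 2    multiple_cnv         5         200     2.5
#> 3           ppcnv        14         200     7.0
#> 4      aneuploidy         2         200     1.0
#> 5 del22q11_or_dup         5         200     2.5
#> 6  other_syndrome         7         200     3.5

benchmarkRecovery(sim$truth, called, ratios)[c("n_events", "sensitivity",
                                               "fp_per_sample")]
#> $n_events
#> [1] 36
#> $sensitivity
#> [1] 1
#> $fp_per_sample
#> [1] 0
```

Or the one-call equivalent:

```r
res <- runPipeline(pipelineConfig(seed = 7, n_samples = 200,
                                  outdir = "run1"))
```

## Reproduction

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "hlpascreen", load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The acceptance script recomputes the headline statistics (detection
rates, case-control chi-squared, Welch p-values, subgroup association)
and benchmarks the simulate → quantify → call chain at zero and 5% noise,
writing everything to a flat JSON file. All randomness derives from
`--seed`; the published-statistics entries are seed-independent.

## Scope and limitations

- The bundled knowledge base is **synthetic**: the syndrome catalog uses
  real GRCh37 loci, but population frequencies, observation counts and
  most gene intervals are invented so that every classification tier is
  exercised. It is not a DGV/DECIPHER/ClinGen snapshot and must not be
  used for real variant interpretation.
- Mosaic aneuploidies and chimerism are not modeled or called.
- Copy numbers are integer; the caller clips to 0–4.
- Research/simulation use only; not a clinical device.
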
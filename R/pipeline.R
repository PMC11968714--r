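## End-to-end orchestration: simulate -> TMB -> neoantigen design ->
## peptide-bulk selection -> repertoire statistics, entirely in memory,
## with optional on-disk serialization of every stage in the package's
## plain-text formats.  Identical spec + seed gives an identical report.

#' Simulate a full synthetic cohort
#'
#' Generates transcripts, per-patient variants (with filter decoys), the
#' targeted region, HLA genotypes with expression weights, repertoires and
#' the surrogate binding scorer, all derived from the spec's single seed.
#'
#' @param spec A [CohortSpec-class] (see [defaultCohortSpec()]).
#' @param outDir Optional directory; when given, every component is also
#'   written out (per-patient VCFs, transcript FASTA + CDS TSV, target
#'   BED, HLA genotype and expression TSVs, clonotype TSV).
#' @param nTranscripts,meanCodons Transcript space of the synthetic
#'   reference.
#' @return Named list: `spec, transcripts, variants, target, genotypes,
#'   clones, scorer`.
#' @export
simulateCohort <- function(spec = defaultCohortSpec(), outDir = NULL,
                           nTranscripts = 300L, meanCodons = 300) {
  methods::validObject(spec)
  transcripts <- generateReferenceTranscripts(nTranscripts, meanCodons,
                                              sdCodons = 100,
                                              seed = spec@seed)
  ## hotspot positions must land inside their transcript's CDS; transcript
  ## lengths are random, so remap a too-short designation to the first
  ## transcript that accommodates the codon (deterministic given the seed)
  if (nrow(spec@hotspots)) {
    nCod <- (transcripts@cdsEnd - transcripts@cdsStart + 1L) %/% 3L - 1L
    for (h in seq_len(nrow(spec@hotspots))) {
      txi <- spec@hotspots$transcript[h]
      if (spec@hotspots$codon[h] > nCod[txi]) {
        txNew <- which(nCod >= spec@hotspots$codon[h])[1L]
        if (is.na(txNew)) stop("no transcript long enough for hotspot codon ",
                               spec@hotspots$codon[h])
        spec@hotspots$transcript[h] <- txNew
      }
    }
  }
  variants <- generatePatientVariants(transcripts, spec)
  target <- targetRegions(transcripts, spec)
  genotypes <- generateHlaGenotypes(spec@hlaFrequencies, spec@nPatients,
                                    seed = spec@seed)
  expr <- simulateHlaExpression(genotypes, seed = spec@seed)
  genotypes <- attachExpression(genotypes, expr)
  clones <- generateRepertoire(spec@repertoire, spec@nPatients,
                               seed = spec@seed)
  scorer <- SurrogateScorer(seed = childSeed(spec@seed, "binding"),
                            binderFraction = spec@binderFraction,
                            scoreRange = spec@scoreRange)
  cohort <- list(spec = spec, transcripts = transcripts,
                 variants = variants, target = target,
                 genotypes = genotypes, expression = expr,
                 clones = clones, scorer = scorer)
  if (!is.null(outDir)) writeCohort(cohort, outDir)
  cohort
}

#' Write a simulated cohort to a directory
#'
#' Plain-text formats only: `transcripts.fa` + `transcripts_cds.tsv`,
#' `target.bed`, `hla_genotypes.tsv`, `hla_expression.tsv`, `clones.tsv`,
#' and one `\{patient\}.vcf` per patient under `vcf/`.
#'
#' @param cohort As returned by [simulateCohort()].
#' @param outDir Output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeCohort <- function(cohort, outDir) {
  dir.create(file.path(outDir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  writeTranscripts(cohort$transcripts,
                   file.path(outDir, "transcripts.fa"),
                   file.path(outDir, "transcripts_cds.tsv"))
  rtracklayer::export(cohort$target, file.path(outDir, "target.bed"),
                      format = "BED")
  writeHlaGenotypes(cohort$genotypes, file.path(outDir, "hla_genotypes.tsv"))
  utils::write.table(cohort$expression,
                     file.path(outDir, "hla_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeClonotypes(cohort$clones, file.path(outDir, "clones.tsv"))
  contigs <- stats::setNames(Biostrings::width(cohort$transcripts@cdna),
                             transcriptIds(cohort$transcripts))
  contigs <- c(contigs, chrOffTarget = 2e6L)
  for (p in unique(cohort$variants$patient))
    writeSomaticVcf(cohort$variants[cohort$variants$patient == p, ],
                    file.path(outDir, "vcf", paste0(p, ".vcf")),
                    contigs = contigs)
  invisible(outDir)
}

#' Run the full profiling pipeline on a cohort
#'
#' Applies, in dependency order: population-frequency and target-region
#' filtering with per-patient TMB; per-patient neoantigen design; the
#' patient x peptide coverage matrix, sharing table and greedy bulk
#' selection; and the repertoire statistics (richness, length
#' distributions, sharing spectra, tumor-specific clonotypes, terminal
#' motifs, VJ pairing, compartment correlations).
#'
#' @param cohort A cohort bundle from [simulateCohort()] (or an equivalent
#'   list built from real inputs: `spec` is only consulted for the
#'   population-frequency threshold default and may be absent).
#' @param afThreshold Population allele-frequency cutoff (default 0.001).
#' @param binderThreshold Peptide combined-score cutoff (default 0).
#' @param sharingMinPatients Strict threshold for "shared / tumor-specific
#'   in more than k patients" (default 2).
#' @return A `CohortReport`: named list with elements `tmb`,
#'   `filteredVariants`, `neoantigens` (per-patient ranked lists),
#'   `neoCounts`, `coverage`, `sharing`, `bulk`, `repertoire` (nested
#'   statistics) and `provenance`.
#' @export
runPipeline <- function(cohort, afThreshold = 0.001, binderThreshold = 0,
                        sharingMinPatients = 2L) {
  variants <- cohort$variants
  target <- cohort$target
  ## stage 1: filtering + TMB
  tmb <- computeCohortTmb(variants, target, afThreshold)
  filtered <- restrictToTarget(
    filterPopulationFrequency(variants, afThreshold), target)
  ## stage 2: neoantigen design
  neo <- designCohort(filtered, cohort$transcripts, cohort$genotypes,
                      cohort$scorer, binderThreshold = binderThreshold)
  neoCounts <- vapply(neo, nrow, integer(1))
  ## stage 3: coverage + bulk selection
  coverage <- buildCoverageMatrix(neo)
  sharing <- sharingTable(coverage)
  bulk <- greedyCover(coverage)
  ## stage 4: repertoire statistics
  clones <- cohort$clones
  rich <- richness(clones)
  richWide <- function(comp, chain) {
    r <- rich[rich$compartment == comp & rich$chain == chain, ]
    stats::setNames(r$richness, r$patient)
  }
  pts <- sort(unique(rich$patient))
  corSafe <- function(x, y) tryCatch(richnessCorrelation(x, y),
                                     error = function(e) list(r = NA, p.value = NA))
  repertoire <- list(
    richness = rich,
    lengths = lengthDistribution(clones, normalize = TRUE),
    sharingTumorTRB = sharingSpectrum(clones, "tumor", "TRB"),
    sharingPbmcTRB = sharingSpectrum(clones, "PBMC", "TRB"),
    sharingTumorIGH = sharingSpectrum(clones, "tumor", "IGH"),
    sharingPbmcIGH = sharingSpectrum(clones, "PBMC", "IGH"),
    tumorSpecificTRB = tumorSpecific(clones, "TRB",
                                     minPatients = sharingMinPatients),
    motifs = terminalMotifs(clones),
    vjTumor = vjPairing(clones[clones$chain == "TRB", ], "tumor"),
    vjPbmc = vjPairing(clones[clones$chain == "TRB", ], "PBMC"),
    correlations = list(
      bcrTumorVsPbmc = corSafe(richWide("tumor", "IGH")[pts],
                               richWide("PBMC", "IGH")[pts]),
      tcrTumorVsPbmc = corSafe(richWide("tumor", "TRB")[pts],
                               richWide("PBMC", "TRB")[pts]),
      tcrVsBcrTumor = corSafe(richWide("tumor", "TRB")[pts],
                              richWide("tumor", "IGH")[pts]))
  )
  structure(list(
    tmb = tmb,
    filteredVariants = filtered,
    neoantigens = neo,
    neoCounts = neoCounts,
    coverage = coverage,
    sharing = sharing,
    bulk = bulk,
    repertoire = repertoire,
    provenance = list(
      seed = if (!is.null(cohort$spec)) cohort$spec@seed else NA_integer_,
      afThreshold = afThreshold,
      binderThreshold = binderThreshold,
      sharingMinPatients = sharingMinPatients,
      package = as.character(utils::packageVersion("neocohort")))
  ), class = "CohortReport")
}

#' @export
print.CohortReport <- function(x, ...) {
  cat("CohortReport over", nrow(x$tmb), "patients\n")
  cat(sprintf("  TMB: median %.2f Muts/Mb (max %.2f)\n",
              stats::median(x$tmb$total_tmb), max(x$tmb$total_tmb)))
  cat(sprintf("  neoantigens/patient: mean %.1f (range %d-%d)\n",
              mean(x$neoCounts), min(x$neoCounts), max(x$neoCounts)))
  cat(sprintf("  peptide bulk: %d peptide(s) covering %d/%d patients\n",
              length(selectedPeptides(x$bulk)),
              length(coveredPatients(x$bulk)), nrow(x$tmb)))
  invisible(x)
}

#' Write the per-patient neoantigen tables and report summaries
#'
#' @param report A `CohortReport` from [runPipeline()].
#' @param outDir Output directory.
#' @param topN Rows of each patient's ranked table to keep in the
#'   per-patient TSVs (`Inf` for all).
#' @return `outDir`, invisibly.
#' @export
writeReport <- function(report, outDir, topN = Inf) {
  dir.create(file.path(outDir, "neoantigens"), recursive = TRUE,
             showWarnings = FALSE)
  utils::write.table(report$tmb, file.path(outDir, "tmb.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (p in names(report$neoantigens)) {
    tab <- utils::head(report$neoantigens[[p]], topN)
    utils::write.table(tab,
                       file.path(outDir, "neoantigens", paste0(p, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(report$sharing, file.path(outDir, "sharing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bulk <- report$bulk
  jsonlite::write_json(
    list(selected = selectedPeptides(bulk),
         per_step_gain = perStepGain(bulk),
         covered = coveredPatients(bulk),
         uncovered = uncoveredPatients(bulk)),
    file.path(outDir, "bulk.json"), auto_unbox = FALSE, pretty = TRUE)
  utils::write.table(report$repertoire$richness,
                     file.path(outDir, "richness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outDir)
}
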
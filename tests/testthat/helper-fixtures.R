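## Shared fixtures and independent oracles.  Every oracle here is written
## naively (loops, string surgery) so it stays independent of the package's
## own code paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
BASES <- c("A", "C", "G", "T")

## deterministic tiny transcript: 5'UTR(6) + ATG + nCodons sense codons +
## TAA + 3'UTR(utr3).  Sequence drawn from the supplied RNG state.
randomTranscript <- function(nCodons = 60, utr3 = 60, id = "tx1") {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  orf <- paste0("ATG", paste(sample(sense, nCodons, replace = TRUE),
                             collapse = ""), "TAA")
  cdna <- paste0(paste(sample(BASES, 6, replace = TRUE), collapse = ""),
                 orf,
                 paste(sample(BASES, utr3, replace = TRUE), collapse = ""))
  TranscriptSet(stats::setNames(cdna, id), cdsStart = 7,
                cdsEnd = 6 + nchar(orf))
}

## brute-force enumeration oracle: all windows of all k containing >= 1
## mutant position (1-based), as a set of "start:k" strings
bruteWindows <- function(L, mutantPositions, kRange = 8:11) {
  out <- character()
  for (k in kRange) {
    if (L < k) next
    for (s in seq_len(L - k + 1)) {
      if (any(mutantPositions >= s & mutantPositions <= s + k - 1))
        out <- c(out, paste0(s, ":", k))
    }
  }
  out
}

## independent translation oracle: translate dna codon by codon from its
## first base, stopping before the first stop codon or at the last full codon
naiveTranslate <- function(dna) {
  gc <- Biostrings::GENETIC_CODE
  aas <- character()
  i <- 1
  while (i + 2 <= nchar(dna)) {
    aa <- gc[[substr(dna, i, i + 2)]]
    if (aa == "*") break
    aas <- c(aas, aa)
    i <- i + 3
  }
  paste(aas, collapse = "")
}

## a scorer returning a fixed score for every (peptide, allele) pair,
## built through the NetMHCpan-table adapter (score = 1 - rank/cutoff)
constantScorer <- function(peptides, alleles, score = 0.1, cutoff = 2) {
  grid <- expand.grid(peptide = unique(peptides), allele = unique(alleles),
                      stringsAsFactors = FALSE)
  grid$rank <- cutoff * (1 - score)
  RankTableScorer(grid, rankCutoff = cutoff)
}

## random small clonotype table with planted structure disabled
randomClones <- function(nPatients = 4, perSample = 30) {
  rows <- list()
  for (p in sprintf("P%02d", seq_len(nPatients)))
    for (comp in c("tumor", "PBMC"))
      for (chain in c("TRB", "IGH")) {
        cdr3 <- vapply(seq_len(perSample), function(i)
          paste(sample(AA20, sample(10:18, 1), replace = TRUE),
                collapse = ""), character(1))
        rows[[length(rows) + 1]] <- data.frame(
          patient = p, compartment = comp, chain = chain, cdr3aa = cdr3,
          vGene = sample(paste0("V", 1:5), perSample, replace = TRUE),
          jGene = sample(paste0("J", 1:3), perSample, replace = TRUE),
          count = sample(1:20, perSample, replace = TRUE),
          stringsAsFactors = FALSE)
      }
  do.call(rbind, rows)
}

## shared small simulated cohort for cross-file reuse (built lazily once)
.smallCohortEnv <- new.env()
smallCohort <- function() {
  if (is.null(.smallCohortEnv$cohort)) {
    spec <- defaultCohortSpec(nPatients = 6L, meanSites = 40, seed = 11,
                              outlierFactor = 4)
    .smallCohortEnv$cohort <- simulateCohort(spec, nTranscripts = 60L,
                                             meanCodons = 200)
  }
  .smallCohortEnv$cohort
}
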
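test_that("generated transcripts are self-consistent ORFs and deterministic", {
  tx <- generateReferenceTranscripts(1, meanCodons = 100, seed = 7)
  cds <- substr(as.character(tx@cdna[[1]]), tx@cdsStart[1], tx@cdsEnd[1])
  expect_identical(substr(cds, 1, 3), "ATG")
  expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                c("TAA", "TAG", "TGA"))
  expect_identical(nchar(cds) %% 3L, 0L)
  expect_identical(naiveTranslate(cds), as.character(tx@protein[[1]]))
  expect_false(grepl("*", as.character(tx@protein[[1]]), fixed = TRUE))

  tx2 <- generateReferenceTranscripts(1, meanCodons = 100, seed = 7)
  expect_identical(as.character(tx@cdna), as.character(tx2@cdna))

  expect_error(generateReferenceTranscripts(3, meanCodons = -5),
               "non-positive mean")
})

test_that("transcript CDS lengths recover the requested distribution", {
  tx <- generateReferenceTranscripts(50, meanCodons = 300, sdCodons = 100,
                                     seed = 21)
  codons <- (tx@cdsEnd - tx@cdsStart + 1) / 3
  se <- 100 / sqrt(50)
  expect_lt(abs(mean(codons) - 300), 3 * se)
})

test_that("per-patient variant counts are Poisson with the requested mean", {
  tx <- generateReferenceTranscripts(20, meanCodons = 150, sdCodons = 30,
                                     seed = 5)
  mean0 <- 60
  counts <- integer()
  for (rep in 1:12) {
    spec <- defaultCohortSpec(nPatients = 12L, meanSites = mean0,
                              seed = 100 + rep, outlierFactor = 1,
                              hotspots = data.frame(transcript = integer(),
                                                    codon = integer(),
                                                    fraction = numeric()),
                              decoyCommonMean = 0, decoyOffTargetMean = 0)
    v <- generatePatientVariants(tx, spec)
    counts <- c(counts, as.integer(table(factor(v$patient,
                                                sprintf("P%02d", 1:12)))))
  }
  se <- sqrt(mean0 / length(counts))
  expect_lt(abs(mean(counts) - mean0), 3 * se)
  ## Poisson dispersion sanity: variance/mean within [0.5, 2]
  disp <- stats::var(counts) / mean(counts)
  expect_gt(disp, 0.5)
  expect_lt(disp, 2)
})

test_that("hotspots are carried by exactly round(fraction * n) patients", {
  tx <- generateReferenceTranscripts(10, meanCodons = 180, sdCodons = 10,
                                     seed = 9)
  spec <- defaultCohortSpec(nPatients = 24L, meanSites = 8, seed = 4,
                            hotspots = data.frame(transcript = 1L,
                                                  codon = 132L,
                                                  fraction = 5 / 24),
                            decoyCommonMean = 0, decoyOffTargetMean = 0)
  v <- generatePatientVariants(tx, spec)
  siteCounts <- table(v$id)
  hotId <- names(which.max(siteCounts))
  expect_identical(as.integer(max(siteCounts)), 5L)
  expect_identical(length(unique(v$patient[v$id == hotId])), 5L)
  ## hotspot is one shared missense site
  expect_true(all(v$class[v$id == hotId] == "missense"))
})

test_that("variant generation is deterministic and rejects bad input", {
  tx <- generateReferenceTranscripts(5, meanCodons = 250, sdCodons = 20,
                                     seed = 2)
  spec <- defaultCohortSpec(nPatients = 4L, meanSites = 10, seed = 8)
  expect_identical(generatePatientVariants(tx, spec),
                   generatePatientVariants(tx, spec))
  empty <- TranscriptSet(character(0), integer(0), integer(0))
  expect_error(generatePatientVariants(empty, spec), "empty")
  ## hotspot outside the transcript CDS is rejected, not silently moved
  short <- generateReferenceTranscripts(2, meanCodons = 40, sdCodons = 1,
                                        seed = 3)
  expect_error(generatePatientVariants(short, spec), "hotspot codon")
})

test_that("an almost-zero site intensity yields almost no variants", {
  tx <- generateReferenceTranscripts(5, meanCodons = 100, seed = 2)
  spec <- defaultCohortSpec(nPatients = 20L, meanSites = 1e-9, seed = 3,
                            outlierFactor = 1,
                            hotspots = data.frame(transcript = integer(),
                                                  codon = integer(),
                                                  fraction = numeric()),
                            decoyCommonMean = 0, decoyOffTargetMean = 0)
  v <- generatePatientVariants(tx, spec)
  expect_true(is.null(v) || nrow(v) == 0)
})

test_that("HLA genotype sampling recovers the frequency table", {
  ## degenerate table: everyone homozygous
  gt <- generateHlaGenotypes(list(A = c("A*30:01" = 1),
                                  B = c("B*13:02" = 1),
                                  C = c("C*06:02" = 1)), 10, seed = 1)
  expect_true(all(hlaAlleles(gt)[, c("A1", "A2")] == "A*30:01"))

  ## default table: the table heads are the modal sampled alleles
  gt <- generateHlaGenotypes(defaultHlaFrequencies(), 500, seed = 2)
  freqs <- alleleFrequencies(gt)
  expect_true(names(freqs$A)[1] %in% c("A*30:01", "A*11:01"))
  expect_identical(names(freqs$B)[1], "B*13:02")
  expect_identical(names(freqs$C)[1], "C*06:02")

  ## binomial 3 SE recovery at n = 1000
  tab <- defaultHlaFrequencies()
  gt <- generateHlaGenotypes(tab, 1000, seed = 3)
  freqs <- alleleFrequencies(gt)
  for (locus in c("A", "B", "C")) {
    for (al in names(tab[[locus]])) {
      p <- tab[[locus]][[al]]
      se <- sqrt(p * (1 - p) / 2000)
      obs <- freqs[[locus]][al]
      if (is.na(obs)) obs <- 0
      expect_lt(abs(obs - p), 3 * se + 1e-12)
    }
  }
  expect_error(generateHlaGenotypes(list(A = numeric(), B = numeric(),
                                         C = numeric()), 5), "non-empty")
})

test_that("surrogate scorer is pure, deterministic and calibrated", {
  sc <- SurrogateScorer(seed = 5, binderFraction = 0.02)
  p <- c("SIINFEKL", "KVAELVHFL", "SIINFEKL")
  s1 <- bindingScore(sc, p, "A*30:01")
  s2 <- bindingScore(sc, p, "A*30:01")
  expect_identical(s1, s2)
  expect_identical(s1[1], s1[3])
  expect_true(all(s1 >= 0 & s1 <= 1))
  ## different allele or seed gives a different random function (checked
  ## at a binder fraction high enough that scores are mostly nonzero)
  scHi <- SurrogateScorer(seed = 5, binderFraction = 0.9)
  hi <- bindingScore(scHi, p, "A*30:01")
  expect_false(identical(hi, bindingScore(scHi, p, "A*11:01")))
  expect_false(identical(hi, bindingScore(SurrogateScorer(seed = 6,
                                                          binderFraction = 0.9),
                                          p, "A*30:01")))

  ## binder fraction recovered within 3 SE over 1e4 random peptides
  set.seed(42)
  peps <- vapply(seq_len(10000), function(i)
    paste(sample(AA20, 9, replace = TRUE), collapse = ""), character(1))
  frac <- mean(bindingScore(sc, peps, "B*13:02") > 0)
  se <- sqrt(0.02 * 0.98 / 10000)
  expect_lt(abs(frac - 0.02), 3 * se)

  ## score distribution is stationary under permutation of the peptide set
  s <- bindingScore(sc, peps, "C*06:02")
  expect_identical(sort(s), sort(bindingScore(sc, rev(peps), "C*06:02")))
})

test_that("planted cover instances have the planted optimum", {
  for (k in c(1L, 4L, 11L)) {
    inst <- plantCoverInstance(24, k, decoys = 6, seed = k)
    expect_identical(exactMinCover(inst$matrix)$size, k)
    sel <- greedyCover(inst$matrix)
    expect_identical(length(selectedPeptides(sel)), k)
  }
  ## all-private instance: minimum = n
  inst <- plantCoverInstance(5, 5, decoys = 0, seed = 1)
  expect_identical(exactMinCover(inst$matrix)$size, 5L)
  expect_error(plantCoverInstance(4, 5), "optimumK")
})

test_that("repertoire generator plants clones exactly as specified", {
  rs <- defaultRepertoireSpec()
  rs$nClones <- c(tumor.TRB = 50, PBMC.TRB = 80, tumor.IGH = 30,
                  PBMC.IGH = 40)
  rs$publicPool <- c(TRB = 20L, IGH = 10L)
  clones <- generateRepertoire(rs, nPatients = 8, seed = 3)

  ## universal clone in the PBMC of every patient
  sh <- sharingSpectrum(clones, "PBMC", "TRB")
  expect_identical(length(sh$carriers[["CASSLEETQYF"]]), 8L)

  ## tumor-only clones recovered with their planted carrier counts
  ts <- tumorSpecific(clones, "TRB", minPatients = 2)
  planted <- rs$tumorOnlyClones
  for (i in seq_len(nrow(planted))) {
    if (planted$nPatients[i] > 2)
      expect_identical(
        ts$n_tumor_patients[ts$cdr3aa == planted$cdr3aa[i]],
        planted$nPatients[i])
  }

  ## invalid alphabet in a planted clone is rejected
  rs$universalClones$cdr3aa <- "CASSB1X"
  expect_error(generateRepertoire(rs, 4, seed = 1), "alphabet")

  ## determinism
  rs <- defaultRepertoireSpec()
  rs$nClones <- c(tumor.TRB = 40, PBMC.TRB = 40, tumor.IGH = 20,
                  PBMC.IGH = 20)
  expect_identical(generateRepertoire(rs, 4, seed = 9),
                   generateRepertoire(rs, 4, seed = 9))
})

test_that("private-only repertoires give a pure singleton sharing spectrum", {
  rs <- defaultRepertoireSpec()
  rs$nClones <- c(tumor.TRB = 60, PBMC.TRB = 60)
  rs$universalClones <- rs$universalClones[0, ]
  rs$tumorOnlyClones <- rs$tumorOnlyClones[0, ]
  rs$publicPool <- c(TRB = 0L, IGH = 0L)
  rs$publicProb <- c(tumor = 0, PBMC = 0)
  clones <- generateRepertoire(rs, nPatients = 6, seed = 2)
  sh <- sharingSpectrum(clones, "PBMC", "TRB")
  expect_identical(sh$spectrum$n_patients, 1L)
  expect_equal(sh$spectrum$fraction, 1)
})
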
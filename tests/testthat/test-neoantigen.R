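test_that("a missense variant yields a full-length protein with one mutant residue", {
  set.seed(1)
  tx <- randomTranscript(nCodons = 98) # ATG + 98 + stop = 100 codons
  prot <- as.character(tx@protein[[1]])
  L <- nchar(prot) # 99 residues incl. the initial M
  ## substitute the middle base of codon 50
  codon50Start <- tx@cdsStart[1] + 3 * 49
  cdna <- as.character(tx@cdna[[1]])
  refBase <- substr(cdna, codon50Start + 1, codon50Start + 1)
  alt <- setdiff(c("A", "C", "G", "T"), refBase)[1]
  mp <- applyVariant(tx, list(chrom = "tx1", pos = codon50Start + 1,
                              ref = refBase, alt = alt))
  if (!is.null(mp)) { # the substitution might be synonymous or a stop gain
    expect_identical(nchar(mp@sequence), L)
    expect_identical(mp@mutantPositions, 50L)
    expect_false(mp@frameshift)
    ## all but the mutant residue equal the reference
    expect_identical(substr(mp@sequence, 1, 49), substr(prot, 1, 49))
    expect_identical(substr(mp@sequence, 51, L), substr(prot, 51, L))
  }
  ## reference mismatch is an error naming the position
  expect_error(applyVariant(tx, list(chrom = "tx1", pos = codon50Start + 1,
                                     ref = setdiff(BASES, refBase)[1],
                                     alt = refBase)),
               "reference mismatch")
  ## outside the CDS: skipped with a message, returns NULL
  expect_message(
    out <- applyVariant(tx, list(chrom = "tx1", pos = 2, ref =
                                   substr(cdna, 2, 2), alt = "A")),
    "outside the CDS")
  expect_null(out)
})

test_that("synonymous and stop-gain changes yield no mutant protein", {
  ## hand-built transcript: ATG AAA TAT CTG ... TAA
  orf <- paste0("ATG", "AAA", "TAT", "CTG", "GGA", "TCC", "TAA")
  cdna <- paste0("GGGGGG", orf, strrep("ACGT", 10))
  tx <- TranscriptSet(c(tx1 = cdna), cdsStart = 7, cdsEnd = 6 + nchar(orf))
  ## AAA -> AAG is synonymous (Lys)
  expect_message(
    expect_null(applyVariant(tx, list(chrom = "tx1", pos = 12, ref = "A",
                                      alt = "G"))),
    "synonymous")
  ## TAT -> TAA is a stop gain
  expect_message(
    expect_null(applyVariant(tx, list(chrom = "tx1", pos = 15, ref = "T",
                                      alt = "A"))),
    "stop gain")
})

test_that("frameshift translation runs to the first shifted-frame stop", {
  ## engineered cDNA: after a 1-bp insertion at codon 10 the shifted frame
  ## reads 20 novel codons then a stop.
  set.seed(33)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  head9 <- paste(sample(sense, 9), collapse = "") # codons 2..10 of the ORF
  ## shifted tail: choose bases so that frame +1 yields 20 sense codons
  ## then TAA; build in the shifted frame and prepend one base
  shiftedCodons <- paste(sample(setdiff(sense, "ATG"), 20, replace = TRUE),
                         collapse = "")
  tail <- paste0(shiftedCodons, "TAA")
  orf <- paste0("ATG", head9, "G", tail) # "G" completes nothing: shift source
  cdna <- paste0("AAAAAA", orf, strrep("A", 30))
  tx <- TranscriptSet(c(tx1 = cdna), cdsStart = 7,
                      cdsEnd = 6 + 3 * ((nchar(orf)) %/% 3))
  ## insert one base right after codon 10 (cDNA position of codon 10 end)
  pos <- 6 + 30 # last base of codon 10
  ref <- substr(cdna, pos, pos)
  mp <- applyVariant(tx, list(chrom = "tx1", pos = pos, ref = ref,
                              alt = paste0(ref, "T")))
  expect_true(mp@frameshift)
  ## independent oracle: translate the edited cDNA from the CDS start
  mutCdna <- paste0(substr(cdna, 1, pos), "T",
                    substr(cdna, pos + 1, nchar(cdna)))
  oracle <- naiveTranslate(substr(mutCdna, 7, nchar(mutCdna)))
  expect_identical(mp@sequence, oracle)
  ## mutant suffix = positions where oracle differs from reference protein
  prot <- as.character(tx@protein[[1]])
  firstDiff <- which(strsplit(oracle, "")[[1]] !=
                       strsplit(substr(prot, 1, nchar(oracle)), "")[[1]])[1]
  expect_identical(min(mp@mutantPositions), as.integer(firstDiff))
  expect_identical(max(mp@mutantPositions), nchar(oracle))
})

test_that("frameshift with no downstream stop runs to the last complete codon", {
  ## ORF then a 3'UTR of pure A: shifted frame reads AAA (Lys) forever
  orf <- paste0("ATG", strrep("GCT", 12), "TAA")
  cdna <- paste0("CCCCCC", orf, strrep("A", 31))
  tx <- TranscriptSet(c(tx1 = cdna), cdsStart = 7, cdsEnd = 6 + nchar(orf))
  pos <- 6 + 9 # inside codon 3
  ref <- substr(cdna, pos, pos)
  mp <- applyVariant(tx, list(chrom = "tx1", pos = pos, ref = ref,
                              alt = paste0(ref, "GT")))
  mutCdna <- paste0(substr(cdna, 1, pos), "GT",
                    substr(cdna, pos + 1, nchar(cdna)))
  oracle <- naiveTranslate(substr(mutCdna, 7, nchar(mutCdna)))
  expect_identical(mp@sequence, oracle)
  ## no stop was found: translation used every complete codon
  expect_identical(nchar(oracle), as.integer((nchar(mutCdna) - 6) %/% 3))
})

test_that("random 1-2 bp indels match the independent translate oracle", {
  set.seed(17)
  for (i in 1:25) {
    tx <- randomTranscript(nCodons = sample(40:80, 1), utr3 = 45)
    cdna <- as.character(tx@cdna[[1]])
    cs <- tx@cdsStart[1]
    pos <- cs + sample.int(tx@cdsEnd[1] - cs - 6, 1) + 2
    width <- sample(1:2, 1)
    if (runif(1) < 0.5) { # insertion
      ref <- substr(cdna, pos, pos)
      alt <- paste0(ref, paste(sample(BASES, width, replace = TRUE),
                               collapse = ""))
      mutCdna <- paste0(substr(cdna, 1, pos), substr(alt, 2, nchar(alt)),
                        substr(cdna, pos + 1, nchar(cdna)))
    } else {
      ref <- substr(cdna, pos, pos + width)
      alt <- substr(ref, 1, 1)
      mutCdna <- paste0(substr(cdna, 1, pos),
                        substr(cdna, pos + width + 1, nchar(cdna)))
    }
    mp <- suppressMessages(
      applyVariant(tx, list(chrom = "tx1", pos = pos, ref = ref, alt = alt)))
    oracle <- naiveTranslate(substr(mutCdna, cs, nchar(mutCdna)))
    if (is.null(mp)) { # legitimately no novel residue
      prot <- as.character(tx@protein[[1]])
      expect_true(oracle == substr(prot, 1, nchar(oracle)))
      next
    }
    expect_identical(mp@sequence, oracle)
    ## first mutant residue is the first mismatch against the reference
    prot <- as.character(tx@protein[[1]])
    n <- min(nchar(oracle), nchar(prot))
    diffs <- which(strsplit(substr(oracle, 1, n), "")[[1]] !=
                     strsplit(substr(prot, 1, n), "")[[1]])
    firstDiff <- if (length(diffs)) diffs[1] else n + 1
    expect_identical(min(mp@mutantPositions), as.integer(firstDiff))
    expect_identical(max(mp@mutantPositions), nchar(mp@sequence))
  }
})

test_that("peptide enumeration matches brute force across the (L, p) sweep", {
  for (L in c(8, 12, 21, 40, 60)) {
    seqchars <- sample(AA20, L, replace = TRUE)
    for (p in seq_len(L)) {
      mp <- new("MutantProtein", transcriptId = "t", variantId = "v",
                sequence = paste(seqchars, collapse = ""),
                mutantPositions = as.integer(p), frameshift = FALSE)
      got <- enumeratePeptides(mp)
      expect_setequal(paste0(got$start, ":", got$k), bruteWindows(L, p))
      ## deterministic order: by start, then window length
      expect_false(is.unsorted(got$start))
      expect_true(all(diff(got$k[got$start == got$start[1]]) > 0) ||
                    sum(got$start == got$start[1]) <= 1)
      ## every emitted peptide covers the mutant residue
      expect_true(all(got$start <= p & p <= got$start + got$k - 1))
      ## windows lie inside the protein
      expect_true(all(got$start >= 1 & got$start + got$k - 1 <= L))
    }
  }
})

test_that("interior single sites give 38 peptides and boundary sites 4", {
  mp <- new("MutantProtein", transcriptId = "t", variantId = "v",
            sequence = strrep("A", 40), mutantPositions = 20L,
            frameshift = FALSE)
  expect_identical(nrow(enumeratePeptides(mp)), 38L)
  mp1 <- new("MutantProtein", transcriptId = "t", variantId = "v",
             sequence = strrep("A", 15), mutantPositions = 1L,
             frameshift = FALSE)
  expect_identical(nrow(enumeratePeptides(mp1)), 4L)
  ## protein shorter than 8: empty
  mpS <- new("MutantProtein", transcriptId = "t", variantId = "v",
             sequence = strrep("A", 7), mutantPositions = 3L,
             frameshift = FALSE)
  expect_identical(nrow(enumeratePeptides(mpS)), 0L)
})

test_that("frameshift suffixes enumerate the same windows as brute force", {
  set.seed(4)
  for (i in 1:10) {
    L <- sample(30:80, 1)
    sufStart <- sample(5:(L - 3), 1)
    mp <- new("MutantProtein", transcriptId = "t", variantId = "v",
              sequence = paste(sample(AA20, L, replace = TRUE), collapse = ""),
              mutantPositions = seq.int(sufStart, L), frameshift = TRUE)
    got <- enumeratePeptides(mp)
    want <- bruteWindows(L, seq.int(sufStart, L))
    expect_setequal(paste0(got$start, ":", got$k), want)
  }
})

test_that("peptide scores are the expression-weighted sum over six alleles", {
  alleles <- c("A*30:01", "A*11:01", "B*13:02", "B*40:01", "C*06:02",
               "C*07:02")
  peptides <- data.frame(peptide = c("ACDEFGHI", "KLMNPQRST"),
                         start = c(1L, 2L), k = c(8L, 9L),
                         nMutant = c(1L, 1L))
  ## all six scores 1.0 via the adapter (rank 0 -> score 1), uniform weights
  sc1 <- constantScorer(peptides$peptide, alleles, score = 1)
  got <- scorePeptides(peptides, alleles, sc1)
  expect_equal(got$combined, c(1, 1))

  ## scores (6,0,0,0,0,0) with uniform weights -> combined 1.0
  tab <- expand.grid(peptide = peptides$peptide, allele = alleles,
                     stringsAsFactors = FALSE)
  tab$rank <- ifelse(tab$allele == alleles[1], -10, 2) # score 6 resp. 0
  got <- scorePeptides(peptides, alleles, RankTableScorer(tab))
  expect_equal(got$combined, c(1, 1))

  ## random scores and weights equal an independent dot product
  set.seed(12)
  for (i in 1:10) {
    tab$rank <- runif(nrow(tab), 0, 2)
    w <- expressionProportions(runif(6))
    got <- scorePeptides(peptides, alleles, RankTableScorer(tab), weights = w)
    for (r in seq_len(nrow(peptides))) {
      manual <- 0
      for (j in seq_len(6)) {
        rk <- tab$rank[tab$peptide == peptides$peptide[r] &
                         tab$allele == alleles[j]]
        manual <- manual + w[j] * max(0, 1 - rk / 2)
      }
      expect_equal(got$combined[r], manual)
    }
  }
  ## scorer failure on a missing pair is an error, not a silent zero
  expect_error(scorePeptides(data.frame(peptide = "WWWWWWWW", start = 1L,
                                        k = 8L, nMutant = 1L),
                             alleles, RankTableScorer(tab)),
               "no rank entry")
})

test_that("neoantigen merging obeys the 25-AA window and score formula", {
  set.seed(2)
  mp <- new("MutantProtein", transcriptId = "t", variantId = "v",
            sequence = paste(sample(AA20, 60, replace = TRUE), collapse = ""),
            mutantPositions = 30L, frameshift = FALSE)
  pep <- enumeratePeptides(mp)
  expect_identical(nrow(pep), 38L)
  alleles <- rep(c("A*30:01", "B*13:02", "C*06:02"), each = 2)
  pep <- scorePeptides(pep, alleles, constantScorer(pep$peptide, alleles,
                                                    score = 0.1))
  neo <- mergeNeoantigens(pep, mp, rnaVaf = 0.4)
  expect_identical(nrow(neo), 1L)
  expect_equal(neo$score, 38 * 0.1 * 0.4)
  ## 25-AA window centered on the mutant residue
  expect_identical(neo$sequence, substr(mp@sequence, 18, 42))
  expect_identical(nchar(neo$sequence), 25L)

  ## missing VAF: warning and treated as 1
  expect_warning(neo1 <- mergeNeoantigens(pep, mp, rnaVaf = NA), "VAF")
  expect_equal(neo1$score, 38 * 0.1)

  ## terminal truncation of the 25-AA window
  mpEdge <- new("MutantProtein", transcriptId = "t", variantId = "v",
                sequence = paste(sample(AA20, 30, replace = TRUE),
                                 collapse = ""),
                mutantPositions = 3L, frameshift = FALSE)
  pepE <- enumeratePeptides(mpEdge)
  pepE <- scorePeptides(pepE, alleles, constantScorer(pepE$peptide, alleles))
  neoE <- mergeNeoantigens(pepE, mpEdge, rnaVaf = 1)
  expect_identical(neoE$sequence, substr(mpEdge@sequence, 1, 15))
})

test_that("non-overlapping clusters yield separate neoantigens (oracle check)", {
  set.seed(5)
  ## two mutant sites far apart on one frameshift-free protein
  mp <- new("MutantProtein", transcriptId = "t", variantId = "v",
            sequence = paste(sample(AA20, 80, replace = TRUE), collapse = ""),
            mutantPositions = c(15L, 60L), frameshift = FALSE)
  pep <- enumeratePeptides(mp)
  alleles <- rep(c("A*30:01", "B*13:02", "C*06:02"), each = 2)
  pep <- scorePeptides(pep, alleles, constantScorer(pep$peptide, alleles))
  neo <- mergeNeoantigens(pep, mp, rnaVaf = 1)
  expect_identical(nrow(neo), 2L)

  ## clustering equals the brute-force transitive closure of overlaps
  starts <- pep$start
  ends <- pep$start + pep$k - 1
  n <- length(starts)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    starts[i] <= ends[j] & starts[j] <= ends[i])
  reach <- adj
  for (k in seq_len(n))
    reach <- reach | (reach[, k] %o% reach[k, ] > 0)
  comp <- match(apply(reach, 1, function(r) paste(which(r), collapse = ",")),
                unique(apply(reach, 1, function(r)
                  paste(which(r), collapse = ","))))
  expect_identical(length(unique(comp)), nrow(neo))
  ## per-cluster score sums match
  oracle <- sort(vapply(split(pep$combined, comp), sum, numeric(1)))
  expect_equal(sort(neo$score), unname(oracle))
})

test_that("patient design ranks deterministically and respects the threshold", {
  co <- smallCohort()
  p <- hlaPatients(co$genotypes)[1]
  v <- co$variants[co$variants$patient == p, ]
  run <- function(thr = 0) designPatient(v, co$transcripts,
                                         hlaAlleles(co$genotypes, p),
                                         co$scorer,
                                         weights = hlaWeights(co$genotypes, p),
                                         binderThreshold = thr)
  neo1 <- run()
  neo2 <- run()
  expect_identical(neo1, neo2)
  expect_identical(neo1$rank, seq_len(nrow(neo1)))
  expect_true(all(diff(neo1$score) <= 0))
  ## infinite threshold: no candidates
  expect_identical(nrow(run(Inf)), 0L)
  ## every neoantigen score is positive (non-binders were dropped)
  expect_true(all(neo1$score > 0))
})

test_that("raising one peptide's binding never lowers its neoantigen's rank", {
  set.seed(21)
  tx <- randomTranscript(nCodons = 60)
  cdna <- as.character(tx@cdna[[1]])
  ## find a missense substitution at a given codon of tx1
  findMissense <- function(codon) {
    for (off in 0:2) for (b in BASES) {
      pos <- tx@cdsStart[1] + 3 * (codon - 1) + off
      ref <- substr(cdna, pos, pos)
      if (b == ref) next
      mp <- suppressMessages(applyVariant(tx, list(chrom = "tx1", pos = pos,
                                                   ref = ref, alt = b)))
      if (!is.null(mp))
        return(data.frame(chrom = "tx1", pos = pos, ref = ref, alt = b,
                          class = "missense", rnaVaf = 0.5, gene = "g",
                          id = paste0("v", codon), stringsAsFactors = FALSE))
    }
    stop("no missense found")
  }
  v <- rbind(findMissense(8), findMissense(42))
  alleles <- c("A*30:01", "A*11:01", "B*13:02", "B*40:01", "C*06:02",
               "C*07:02")
  peps1 <- enumeratePeptides(suppressMessages(applyVariant(tx, v[1, ])))$peptide
  peps2 <- enumeratePeptides(suppressMessages(applyVariant(tx, v[2, ])))$peptide
  mkScorer <- function(bump) {
    tab <- expand.grid(peptide = unique(c(peps1, peps2)), allele = alleles,
                       stringsAsFactors = FALSE)
    tab$rank <- 1.0            # baseline score 0.5 everywhere
    tab$rank[tab$peptide == peps1[1]] <- 1.0 - bump
    RankTableScorer(tab)
  }
  r0 <- designPatient(v, tx, alleles, mkScorer(0))
  r1 <- designPatient(v, tx, alleles, mkScorer(0.9))
  rank0 <- r0$rank[r0$variantId == v$id[1]]
  rank1 <- r1$rank[r1$variantId == v$id[1]]
  expect_lte(rank1, rank0)
  ## and the bumped neoantigen's score strictly increased
  expect_gt(r1$score[r1$variantId == v$id[1]],
            r0$score[r0$variantId == v$id[1]])
})
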
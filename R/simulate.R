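## Synthetic cohort generation.
##
## The generator emulates the statistical shape of a 24-patient
## glioblastoma vaccine cohort: per-patient somatic mutated-site counts
## Poisson with mean 200 and one ~10x outlier, mostly patient-private
## variants with one missense hotspot carried by 5/24 patients, HLA
## genotypes drawn from frequency tables headed by A*30:01/A*11:01,
## B*13:02 and C*06:02, and TCR/BCR repertoires peaking at CDR3 length
## 15 with a universal PBMC TCR clone.  Everything is driven by one seed;
## identical spec + seed reproduces the cohort byte for byte.

#' Default consequence-class mixture
#' @return Named probability vector over consequence classes.
#' @export
defaultClassProbs <- function() {
  c(missense = 0.55, synonymous = 0.20, frameshift = 0.07,
    nonsense = 0.05, inframe_indel = 0.02, splice_site = 0.04,
    noncoding = 0.07)
}

#' Default repertoire generator settings
#'
#' Clonotype counts per compartment/chain, CDR3 length distributions
#' (normal, rounded, truncated to \[8, 30\], both chains peaking at 15 AA),
#' the probability of a canonical "CA" N-terminal start, planted clones
#' (a universal PBMC TCR clone present in every patient; four tumor-only
#' TCR clones each in 4-6 patients), and a public clone pool that creates
#' a realistic cross-patient sharing tail.
#'
#' @return Named list of settings consumed by [generateRepertoire()].
#' @export
defaultRepertoireSpec <- function() {
  list(
    nClones = c(tumor.TRB = 1200, PBMC.TRB = 2500,
                tumor.IGH = 600, PBMC.IGH = 1200),
    lengthMean = c(TRB = 15, IGH = 15),
    lengthSd = c(TRB = 1.6, IGH = 3.2),
    caProb = 0.92,
    universalClones = data.frame(
      cdr3aa = "CASSLEETQYF", compartment = "PBMC", chain = "TRB",
      stringsAsFactors = FALSE),
    tumorOnlyClones = data.frame(
      cdr3aa = c("CASSFGTEAFF", "CASSPDRGGYTF", "CASSLAGNTIYF",
                 "CASRGDSSYEQYF"),
      nPatients = c(6L, 5L, 4L, 4L),
      stringsAsFactors = FALSE),
    publicPool = c(TRB = 400L, IGH = 150L),
    publicProb = c(tumor = 0.20, PBMC = 0.35)
  )
}

#' Default synthetic cohort specification
#'
#' The emulation defaults: 24 patients, Poisson mean 200 mutated sites per
#' patient with patient 24 scaled 10x, one missense hotspot carried by
#' 5/24 of the cohort, the class mixture of [defaultClassProbs()], the HLA
#' tables of [defaultHlaFrequencies()], a 40-Mb targeted region, and a
#' surrogate binder fraction calibrated so the mean per-patient candidate
#' neoantigen count lands near 107.  These mirror printed cohort summaries
#' and are emulation defaults, not ground truth.
#'
#' @param nPatients,meanSites,seed Frequently varied settings.
#' @param ... Further slot overrides (see [CohortSpec-class]).
#' @return A validated [CohortSpec-class].
#' @export
defaultCohortSpec <- function(nPatients = 24L, meanSites = 200,
                              seed = 1L, ...) {
  args <- list(
    nPatients = as.integer(nPatients),
    meanSites = meanSites,
    outlierPatient = as.integer(nPatients),
    outlierFactor = 10,
    hotspots = data.frame(transcript = 1L, codon = 132L,
                          fraction = 5 / 24),
    classProbs = defaultClassProbs(),
    hlaFrequencies = defaultHlaFrequencies(),
    repertoire = defaultRepertoireSpec(),
    targetSizeBp = 60e6,
    decoyCommonMean = 15,
    decoyOffTargetMean = 10,
    binderFraction = 0.0045,
    scoreRange = c(0, 1),
    seed = as.integer(seed)
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(new, c(list("CohortSpec"), args))
}

## all 9 single-base substitutions of a codon, with their translations
.codonSubs <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      gc <- Biostrings::GENETIC_CODE
      rows <- list()
      for (codon in mkAllCodons()) {
        for (p in 1:3) for (b in .BASES) {
          if (substr(codon, p, p) == b) next
          alt <- codon
          substr(alt, p, p) <- b
          rows[[length(rows) + 1L]] <- data.frame(
            codon = codon, offset = p, refBase = substr(codon, p, p),
            altBase = b, refAA = unname(gc[codon]), altAA = unname(gc[alt]),
            stringsAsFactors = FALSE)
        }
      }
      memo <<- do.call(rbind, rows)
    }
    memo
  }
})

.codonSubsByCodon <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- split(.codonSubs(), .codonSubs()$codon)
    memo
  }
})

## draw one substitution of the requested effect at a random CDS codon;
## returns NULL if the drawn codon admits none (caller resamples)
.drawSub <- function(cdna, cs, ce, codonIdx, effect) {
  codonStart <- cs + 3L * (codonIdx - 1L)
  codon <- substr(cdna, codonStart, codonStart + 2L)
  cand <- .codonSubsByCodon()[[codon]]
  if (is.null(cand)) return(NULL)
  cand <- switch(effect,
    missense = cand[cand$altAA != cand$refAA & cand$altAA != "*" &
                    cand$refAA != "*", , drop = FALSE],
    synonymous = cand[cand$altAA == cand$refAA, , drop = FALSE],
    nonsense = cand[cand$altAA == "*" & cand$refAA != "*", , drop = FALSE],
    stop("unknown substitution effect: ", effect))
  if (!nrow(cand)) return(NULL)
  pick <- cand[sample.int(nrow(cand), 1L), ]
  list(pos = codonStart + pick$offset - 1L, ref = pick$refBase,
       alt = pick$altBase)
}

## one synthetic variant row of the requested class on a random transcript
.drawVariant <- function(transcripts, class) {
  txi <- sample.int(length(transcripts), 1L)
  cdna <- as.character(transcripts@cdna[[txi]])
  cs <- transcripts@cdsStart[txi]
  ce <- transcripts@cdsEnd[txi]
  nCodons <- (ce - cs + 1L) %/% 3L - 1L # excludes the stop codon
  txid <- transcriptIds(transcripts)[txi]
  if (class == "noncoding") {
    utrPos <- c(seq_len(cs - 1L), seq.int(ce + 1L, nchar(cdna)))
    pos <- utrPos[sample.int(length(utrPos), 1L)]
    ref <- substr(cdna, pos, pos)
    alt <- sample(setdiff(.BASES, ref), 1L)
    return(data.frame(chrom = txid, pos = pos, ref = ref, alt = alt,
                      class = class, stringsAsFactors = FALSE))
  }
  if (class %in% c("frameshift", "inframe_indel")) {
    codonIdx <- sample.int(nCodons - 2L, 1L) + 1L # keep off ATG and stop
    pos <- cs + 3L * (codonIdx - 1L)
    ref <- substr(cdna, pos, pos)
    width <- if (class == "frameshift") sample(1:2, 1L) else 3L
    if (stats::runif(1) < 0.5) { # insertion
      ins <- paste(sample(.BASES, width, replace = TRUE), collapse = "")
      return(data.frame(chrom = txid, pos = pos, ref = ref,
                        alt = paste0(ref, ins), class = class,
                        stringsAsFactors = FALSE))
    }
    ref <- substr(cdna, pos, pos + width)
    return(data.frame(chrom = txid, pos = pos, ref = ref,
                      alt = substr(ref, 1L, 1L), class = class,
                      stringsAsFactors = FALSE))
  }
  effect <- if (class %in% c("missense", "synonymous", "nonsense")) class
            else "missense" # splice_site et al.: any coding substitution
  for (try in 1:50) {
    codonIdx <- sample.int(nCodons - 1L, 1L) + 1L # skip the ATG codon
    sub <- .drawSub(cdna, cs, ce, codonIdx, effect)
    if (!is.null(sub))
      return(data.frame(chrom = txid, pos = sub$pos, ref = sub$ref,
                        alt = sub$alt, class = class,
                        stringsAsFactors = FALSE))
  }
  stop("could not construct a ", effect, " substitution on ", txid)
}

#' Generate per-patient somatic variants
#'
#' Per-patient on-target somatic site counts are Poisson with mean
#' `meanSites` (`meanSites * outlierFactor` for the designated outlier
#' patient); consequence classes follow `classProbs`; RNA VAF is uniform
#' on (0.05, 1\].  Each hotspot is carried by `round(fraction * nPatients)`
#' patients (replacing one of the carrier's Poisson draws, so counts stay
#' Poisson) as an identical missense variant across carriers.  On top of
#' the somatic sites, decoy variants with common population AF (>= the
#' 0.001 filter threshold) and off-target decoys are added so the
#' filtering stages have real work; both decoy kinds are removed by the
#' standard filters.
#'
#' @param transcripts A [TranscriptSet-class].
#' @param spec A [CohortSpec-class].
#' @return Cohort variant `data.frame`: `patient, id, chrom, pos, ref,
#'   alt, gene, class, populationAf, rnaVaf` (gene = transcript id).
#' @export
generatePatientVariants <- function(transcripts, spec) {
  if (!length(transcripts)) stop("empty transcript set")
  methods::validObject(spec)
  set.seed(childSeed(spec@seed, "variants"))
  n <- spec@nPatients
  patients <- sprintf("P%02d", seq_len(n))
  counts <- stats::rpois(n, spec@meanSites)
  counts[spec@outlierPatient] <- stats::rpois(1L, spec@meanSites *
                                                spec@outlierFactor)
  ## hotspot carriers and their shared variant records
  hot <- spec@hotspots
  hotVariants <- list()
  hotCarriers <- list()
  if (nrow(hot)) for (h in seq_len(nrow(hot))) {
    nCarr <- as.integer(round(hot$fraction[h] * n))
    hotCarriers[[h]] <- sort(sample.int(n, nCarr))
    txi <- hot$transcript[h]
    if (is.na(txi) || txi < 1L || txi > length(transcripts))
      stop("hotspot transcript index out of range: ", hot$transcript[h])
    cdna <- as.character(transcripts@cdna[[txi]])
    nCod <- (transcripts@cdsEnd[txi] - transcripts@cdsStart[txi] + 1L) %/%
      3L - 1L
    codonIdx <- hot$codon[h]
    if (codonIdx < 2L || codonIdx > nCod)
      stop(sprintf("hotspot codon %d outside the CDS of transcript %s (codons 2..%d)",
                   codonIdx, transcriptIds(transcripts)[txi], nCod))
    sub <- .drawSub(cdna, transcripts@cdsStart[txi],
                    transcripts@cdsEnd[txi], codonIdx, "missense")
    if (is.null(sub))
      stop("no missense substitution available at the hotspot codon")
    hotVariants[[h]] <- data.frame(
      chrom = transcriptIds(transcripts)[txi], pos = sub$pos,
      ref = sub$ref, alt = sub$alt, class = "missense",
      stringsAsFactors = FALSE)
  }
  classes <- names(spec@classProbs)
  rows <- list()
  for (i in seq_len(n)) {
    k <- counts[i]
    inHot <- which(vapply(hotCarriers, function(cc) i %in% cc, logical(1)))
    kRandom <- max(k - length(inHot), 0L)
    drawn <- if (kRandom) {
      cls <- sample(classes, kRandom, replace = TRUE, prob = spec@classProbs)
      do.call(rbind, lapply(cls, function(cl) .drawVariant(transcripts, cl)))
    } else NULL
    pv <- rbind(drawn, if (length(inHot)) do.call(rbind, hotVariants[inHot]))
    if (is.null(pv) || !nrow(pv)) next
    pv$patient <- patients[i]
    pv$populationAf <- ifelse(stats::runif(nrow(pv)) < 0.8, NA_real_,
                              stats::runif(nrow(pv), 0, 0.0009))
    pv$rnaVaf <- stats::runif(nrow(pv), 0.05, 1)
    ## decoys: common population AF (on-target) and off-target contig
    nCommon <- stats::rpois(1L, spec@decoyCommonMean)
    if (nCommon) {
      dc <- do.call(rbind, lapply(
        sample(classes, nCommon, replace = TRUE, prob = spec@classProbs),
        function(cl) .drawVariant(transcripts, cl)))
      dc$patient <- patients[i]
      dc$populationAf <- stats::runif(nCommon, 0.001, 0.5)
      dc$rnaVaf <- stats::runif(nCommon, 0.05, 1)
      pv <- rbind(pv, dc)
    }
    nOff <- stats::rpois(1L, spec@decoyOffTargetMean)
    if (nOff) {
      off <- data.frame(
        chrom = "chrOffTarget",
        pos = sample.int(1e6, nOff),
        ref = sample(.BASES, nOff, replace = TRUE),
        alt = NA_character_, class = "other",
        patient = patients[i],
        populationAf = NA_real_,
        rnaVaf = stats::runif(nOff, 0.05, 1),
        stringsAsFactors = FALSE)
      off$alt <- vapply(off$ref, function(r) sample(setdiff(.BASES, r), 1L),
                        character(1), USE.NAMES = FALSE)
      pv <- rbind(pv, off)
    }
    rows[[i]] <- pv
  }
  if (!length(rows))
    return(data.frame(patient = character(), id = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gene = character(), class = character(),
                      populationAf = numeric(), rnaVaf = numeric()))
  out <- do.call(rbind, rows)
  out$gene <- out$chrom
  out$id <- sprintf("%s:%d%s>%s", out$chrom, out$pos, out$ref, out$alt)
  rownames(out) <- NULL
  out[, c("patient", "id", "chrom", "pos", "ref", "alt", "gene", "class",
          "populationAf", "rnaVaf")]
}

#' Synthetic targeted-region intervals
#'
#' One interval per transcript contig covering the whole cDNA, plus a
#' filler interval on a separate contig padding the total size to
#' `spec@targetSizeBp` -- the targeted design covers far more sequence
#' than the handful of transcripts that happen to be mutated, and the TMB
#' denominator must reflect that.
#'
#' @param transcripts A [TranscriptSet-class].
#' @param spec A [CohortSpec-class].
#' @return A [GenomicRanges::GRanges] of target intervals.
#' @export
targetRegions <- function(transcripts, spec) {
  w <- Biostrings::width(transcripts@cdna)
  filler <- spec@targetSizeBp - sum(w)
  if (filler < 0) stop("targetSizeBp smaller than the transcript space")
  gr <- GenomicRanges::GRanges(
    c(transcriptIds(transcripts), "chrFiller"),
    IRanges::IRanges(start = 1L, end = c(w, filler)))
  GenomicRanges::reduce(gr, ignore.strand = TRUE)
}

## random CDR3s: canonical "C A ..." start with prob caProb, F/W C-terminus
.randomCdr3 <- function(k, lengths, caProb) {
  n <- length(lengths)
  starts <- ifelse(stats::runif(n) < caProb, "CA",
                   paste0(sample(.AA20, n, replace = TRUE),
                          sample(.AA20, n, replace = TRUE)))
  ends <- sample(c("F", "W"), n, replace = TRUE, prob = c(0.85, 0.15))
  mid <- vapply(pmax(lengths - 3L, 1L), function(m)
    paste(sample(.AA20, m, replace = TRUE), collapse = ""), character(1))
  paste0(starts, mid, ends)
}

.vGenes <- list(TRB = sprintf("TRBV%d", 1:30), IGH = sprintf("IGHV%d-1", 1:7))
.jGenes <- list(TRB = sprintf("TRBJ%d-%d", rep(1:2, c(6, 7)),
                              c(1:6, 1:7)),
                IGH = sprintf("IGHJ%d", 1:6))

#' Generate synthetic TCR/BCR repertoires
#'
#' Per patient x compartment (tumor, PBMC) x chain (TRB, IGH) clonotype
#' tables with the configured richness, CDR3 length distribution (rounded
#' normal, truncated to \[8, 30\]), "CA" N-terminal motif probability,
#' geometric clone sizes, skewed V/J usage, a shared public clone pool,
#' and exactly placed planted clones: universal clones inserted in the
#' stated compartment of every patient, and tumor-only clones inserted in
#' the tumors of the stated numbers of patients and no PBMC.
#'
#' @param repertoireSpec Settings list (see [defaultRepertoireSpec()]).
#' @param nPatients Number of patients.
#' @param seed Integer seed.
#' @param patients Optional patient ids.
#' @return Clonotype `data.frame` (see [richness()] for the contract).
#' @export
generateRepertoire <- function(repertoireSpec, nPatients, seed = 1L,
                               patients = NULL) {
  rs <- repertoireSpec
  if (any(rs$nClones < 1L)) stop("clonotype counts must be >= 1")
  planted <- c(rs$universalClones$cdr3aa, rs$tumorOnlyClones$cdr3aa)
  if (length(planted) && any(!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", planted)))
    stop("invalid amino-acid alphabet in planted clones")
  if (is.null(patients)) patients <- sprintf("P%02d", seq_len(nPatients))
  set.seed(childSeed(seed, "repertoire"))
  pool <- lapply(c(TRB = "TRB", IGH = "IGH"), function(ch) {
    len <- pmin(pmax(round(stats::rnorm(rs$publicPool[[ch]],
                                        rs$lengthMean[[ch]],
                                        rs$lengthSd[[ch]])), 8L), 30L)
    .randomCdr3(rs$publicPool[[ch]], len, rs$caProb)
  })
  rows <- list()
  for (p in patients) {
    ## per-patient immune "size" factor shared across a patient's samples
    ## plus an equal-variance per-sample factor: couples sample richness
    ## within a patient only moderately (r around 0.5), as real cohorts show
    patientFactor <- stats::rlnorm(1L, 0, 0.15)
    for (nm in names(rs$nClones)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
      comp <- parts[1L]
      chain <- parts[2L]
      sampleFactor <- patientFactor * stats::rlnorm(1L, 0, 0.15)
      nc <- max(1L, stats::rpois(1L, rs$nClones[[nm]] * sampleFactor))
      nPublic <- stats::rbinom(1L, length(pool[[chain]]),
                               rs$publicProb[[comp]])
      publicSeqs <- sample(pool[[chain]], nPublic)
      nPriv <- max(nc - nPublic, 0L)
      len <- pmin(pmax(round(stats::rnorm(nPriv, rs$lengthMean[[chain]],
                                          rs$lengthSd[[chain]])), 8L), 30L)
      cdr3 <- c(publicSeqs, .randomCdr3(nPriv, len, rs$caProb))
      nTot <- length(cdr3)
      rows[[length(rows) + 1L]] <- data.frame(
        patient = p, compartment = comp, chain = chain, cdr3aa = cdr3,
        vGene = sample(.vGenes[[chain]], nTot, replace = TRUE,
                       prob = seq(2, 1, length.out = length(.vGenes[[chain]]))),
        jGene = sample(.jGenes[[chain]], nTot, replace = TRUE,
                       prob = seq(2, 1, length.out = length(.jGenes[[chain]]))),
        count = stats::rgeom(nTot, 0.35) + 1L,
        stringsAsFactors = FALSE)
    }
  }
  clones <- do.call(rbind, rows)
  ## planted universal clones: the stated compartment/chain of EVERY patient
  uc <- rs$universalClones
  if (!is.null(uc) && nrow(uc)) for (u in seq_len(nrow(uc))) {
    rows <- data.frame(patient = patients, compartment = uc$compartment[u],
                       chain = uc$chain[u], cdr3aa = uc$cdr3aa[u],
                       vGene = .vGenes[[uc$chain[u]]][1L],
                       jGene = .jGenes[[uc$chain[u]]][1L],
                       count = stats::rgeom(length(patients), 0.2) + 1L,
                       stringsAsFactors = FALSE)
    clones <- rbind(clones, rows)
  }
  ## planted tumor-only clones: stated carrier counts, never in PBMC
  ## planted tumor-only carrier counts cannot exceed the cohort size
  toc <- rs$tumorOnlyClones
  if (!is.null(toc) && nrow(toc)) for (u in seq_len(nrow(toc))) {
    carriers <- sample(patients, min(toc$nPatients[u], length(patients)))
    rows <- data.frame(patient = carriers, compartment = "tumor",
                       chain = "TRB", cdr3aa = toc$cdr3aa[u],
                       vGene = .vGenes$TRB[2L], jGene = .jGenes$TRB[2L],
                       count = stats::rgeom(length(carriers), 0.2) + 1L,
                       stringsAsFactors = FALSE)
    clones <- rbind(clones, rows)
  }
  ## planted sequences could collide with random ones: remove any random
  ## occurrence that breaks the exact placement of tumor-only clones
  if (!is.null(toc) && nrow(toc)) {
    drop <- clones$cdr3aa %in% toc$cdr3aa & clones$compartment == "PBMC"
    clones <- clones[!drop, , drop = FALSE]
  }
  ## collapse duplicate (sample, cdr3, V, J) keys
  key <- paste(clones$patient, clones$compartment, clones$chain,
               clones$cdr3aa, clones$vGene, clones$jGene, sep = "\r")
  agg <- tapply(clones$count, key, sum)
  clones <- clones[!duplicated(key), , drop = FALSE]
  clones$count <- as.integer(agg[paste(clones$patient, clones$compartment,
                                       clones$chain, clones$cdr3aa,
                                       clones$vGene, clones$jGene,
                                       sep = "\r")])
  clones <- clones[order(clones$patient, clones$compartment, clones$chain,
                         clones$cdr3aa, clones$vGene, clones$jGene), ,
                   drop = FALSE]
  rownames(clones) <- NULL
  clones
}
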
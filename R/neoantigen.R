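## Mutant-peptide and neoantigen design.
##
## The chain is: apply one somatic variant to its transcript (MutantProtein),
## enumerate every 8-11-mer window containing a mutant residue, score each
## window against the patient's six class-I alleles through a BindingScorer
## with allele-expression weighting, drop non-binders, merge intersecting
## windows into one <= 25-AA neoantigen per overlap cluster, and score the
## neoantigen as (sum of constituent peptide scores) x RNA VAF.

#' Apply a somatic variant to a transcript
#'
#' Builds the mutant protein and the set of altered residue positions.
#' Substitutions yield a single mutant residue; in-frame indels a short
#' altered region (located by longest common prefix/suffix); frameshift
#' indels a neo-ORF translated in the shifted frame from the first altered
#' codon until the first stop codon, or to the last complete codon of the
#' cDNA when no stop occurs before its end.  Variants that create no novel
#' residue (synonymous changes, stop gains, truncations) yield `NULL`:
#' there is no mutant residue to center a peptide window on.
#'
#' @param transcripts A [TranscriptSet-class].
#' @param variant One-row variant `data.frame` (or list) with fields
#'   `chrom` (transcript id), `pos` (1-based cDNA position), `ref`, `alt`,
#'   and optionally `id`.
#' @return A [MutantProtein-class], or `NULL` when the variant is outside
#'   the CDS or alters no residue (the reason is attached as
#'   `attr(, "reason")` on `NULL` via a message).
#' @export
applyVariant <- function(transcripts, variant) {
  txi <- match(variant$chrom, transcriptIds(transcripts))
  if (is.na(txi)) stop("unknown transcript: ", variant$chrom)
  cdna <- as.character(transcripts@cdna[[txi]])
  cs <- transcripts@cdsStart[txi]
  ce <- transcripts@cdsEnd[txi]
  pos <- as.integer(variant$pos)
  ref <- as.character(variant$ref)
  alt <- as.character(variant$alt)
  vid <- if (!is.null(variant$id) && !is.na(variant$id)) as.character(variant$id)
         else sprintf("%s:%d%s>%s", variant$chrom, pos, ref, alt)
  obs <- substr(cdna, pos, pos + nchar(ref) - 1L)
  if (!identical(obs, ref))
    stop(sprintf("reference mismatch at %s:%d (expected %s, transcript has %s)",
                 variant$chrom, pos, ref, obs))
  if (pos < cs || pos > ce - 3L) { # last codon is the stop
    message("variant ", vid, " outside the CDS; skipped")
    return(NULL)
  }
  refProt <- as.character(transcripts@protein[[txi]])
  d <- nchar(alt) - nchar(ref)

  if (d == 0L && nchar(ref) == 1L) {
    ## SNV: swap the base, retranslate its codon
    codonIdx <- (pos - cs) %/% 3L + 1L
    codonStart <- cs + 3L * (codonIdx - 1L)
    codon <- substr(cdna, codonStart, codonStart + 2L)
    substr(codon, pos - codonStart + 1L, pos - codonStart + 1L) <- alt
    newAA <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                                no.init.codon = TRUE))
    if (codonIdx > nchar(refProt)) { # edit inside the stop codon
      message("variant ", vid, " alters the stop codon only; skipped")
      return(NULL)
    }
    oldAA <- substr(refProt, codonIdx, codonIdx)
    if (newAA == oldAA) {
      message("variant ", vid, " is synonymous; skipped")
      return(NULL)
    }
    if (newAA == "*") {
      message("variant ", vid, " is a stop gain (no novel residue); skipped")
      return(NULL)
    }
    mut <- refProt
    substr(mut, codonIdx, codonIdx) <- newAA
    return(new("MutantProtein", transcriptId = variant$chrom, variantId = vid,
               sequence = mut, mutantPositions = codonIdx, frameshift = FALSE))
  }

  ## indel: edit the cDNA and retranslate from the CDS start
  ## VCF anchor convention: ref and alt share their first base at pos
  mutCdna <- paste0(substr(cdna, 1L, pos),
                    substr(alt, 2L, nchar(alt)),
                    substr(cdna, pos + nchar(ref), nchar(cdna)))
  frameshift <- (d %% 3L) != 0L
  mutProt <- .translateToStop(substr(mutCdna, cs, nchar(mutCdna)))
  mutProt <- as.character(mutProt)
  if (!frameshift) {
    cmp <- .diffRegion(refProt, mutProt)
    if (is.null(cmp)) {
      message("variant ", vid, " alters no residue; skipped")
      return(NULL)
    }
    return(new("MutantProtein", transcriptId = variant$chrom, variantId = vid,
               sequence = mutProt,
               mutantPositions = seq.int(cmp[1L], cmp[2L]),
               frameshift = FALSE))
  }
  firstDiff <- .firstMismatch(refProt, mutProt)
  if (firstDiff > nchar(mutProt)) {
    message("variant ", vid, " truncates without novel residues; skipped")
    return(NULL)
  }
  new("MutantProtein", transcriptId = variant$chrom, variantId = vid,
      sequence = mutProt,
      mutantPositions = seq.int(firstDiff, nchar(mutProt)),
      frameshift = TRUE)
}

## first position at which two strings differ (1-based); length(shorter)+1
## when one is a prefix of the other; Inf when identical.
.firstMismatch <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n > 0L) {
    av <- utf8ToInt(substr(a, 1L, n))
    bv <- utf8ToInt(substr(b, 1L, n))
    w <- which(av != bv)
    if (length(w)) return(w[1L])
  }
  if (nchar(a) == nchar(b)) Inf else n + 1L
}

## altered region of an in-frame edit: c(first, last) positions in the
## mutant string after trimming the longest common prefix and suffix.
.diffRegion <- function(refProt, mutProt) {
  first <- .firstMismatch(refProt, mutProt)
  if (is.infinite(first)) return(NULL)
  ra <- rev(utf8ToInt(refProt))
  ma <- rev(utf8ToInt(mutProt))
  n <- min(length(ra), length(ma))
  suf <- 0L
  while (suf < n && ra[suf + 1L] == ma[suf + 1L]) suf <- suf + 1L
  last <- nchar(mutProt) - suf
  first <- min(first, nchar(mutProt))
  if (last < first) last <- first # pure deletion: mark the junction residue
  c(first, last)
}

#' Enumerate mutant 8-11-mer peptides
#'
#' All windows of each length in `kRange` that lie fully inside the mutant
#' protein and contain at least one mutant residue, in deterministic order
#' (by start, then window length).
#'
#' @param mp A [MutantProtein-class].
#' @param kRange Integer vector of window lengths (default 8:11).
#' @return `data.frame` with columns `peptide`, `start` (1-based), `k`,
#'   `nMutant` (mutant residues covered).  Empty when the protein is
#'   shorter than the smallest window.
#' @export
enumeratePeptides <- function(mp, kRange = 8:11) {
  L <- nchar(mp@sequence)
  mut <- mp@mutantPositions
  rows <- list()
  for (k in sort(kRange)) {
    if (L < k) next
    lo <- max(1L, min(mut) - k + 1L)
    hi <- min(max(mut), L - k + 1L)
    if (hi < lo) next
    starts <- lo:hi
    nMut <- vapply(starts, function(s) sum(mut >= s & mut <= s + k - 1L),
                   integer(1))
    keep <- nMut > 0L
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = substring(mp@sequence, starts[keep], starts[keep] + k - 1L),
      start = starts[keep], k = k, nMutant = nMut[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(peptide = character(), start = integer(),
                      k = integer(), nMutant = integer()))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$k), , drop = FALSE]
  out <- out[!duplicated(out[c("peptide", "start", "k")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score peptides against a patient's six alleles
#'
#' Per-allele scores come from the [BindingScorer-class]; the combined score
#' is the allele-expression-weighted sum over the six allele slots (with
#' uniform weights 1/6 when no expression information is available).
#'
#' @param peptides `data.frame` from [enumeratePeptides()].
#' @param alleles Character vector of six allele names (slots `A1..C2`).
#' @param scorer A [BindingScorer-class].
#' @param weights Numeric vector of six expression weights (summing to 1).
#' @return `peptides` with a `combined` column appended and the 6-column
#'   per-allele score matrix attached as `attr(, "alleleScores")`.
#' @export
scorePeptides <- function(peptides, alleles, scorer,
                          weights = rep(1 / 6, 6)) {
  stopifnot(length(alleles) == 6L, length(weights) == 6L)
  if (abs(sum(weights) - 1) > 1e-6)
    stop("expression weights must sum to 1")
  m <- matrix(0, nrow(peptides), 6L,
              dimnames = list(NULL, paste0(alleles, ".", seq_len(6L))))
  if (nrow(peptides))
    for (j in seq_len(6L))
      m[, j] <- bindingScore(scorer, peptides$peptide, alleles[j])
  peptides$combined <- as.numeric(m %*% weights)
  attr(peptides, "alleleScores") <- m
  peptides
}

#' Merge intersecting peptides into scored 25-AA neoantigens
#'
#' Peptide windows from one mutant protein are clustered by transitive
#' interval overlap on protein coordinates.  Each cluster yields one
#' neoantigen: its sequence is the window of up to 25 residues centered on
#' the cluster's leftmost mutant residue (12 flanking residues each side,
#' truncated at the protein termini), and its score is the sum of the
#' cluster's combined peptide scores multiplied by the RNA mutation
#' frequency at the site.
#'
#' @param scored Scored peptide `data.frame` (see [scorePeptides()]).
#' @param mp The [MutantProtein-class] the peptides derive from.
#' @param rnaVaf RNA VAF in (0, 1\]; `NA` is treated as 1 with a warning.
#' @param flank Flanking residues each side of the mutant center
#'   (default 12, i.e. 25-AA neoantigens).
#' @return `data.frame` with one row per cluster: `sequence, score,
#'   nPeptides, clusterStart, clusterEnd, truncated, frameshift`.
#' @export
mergeNeoantigens <- function(scored, mp, rnaVaf, flank = 12L) {
  if (!nrow(scored))
    return(data.frame(sequence = character(), score = numeric(),
                      nPeptides = integer(), clusterStart = integer(),
                      clusterEnd = integer(), truncated = logical(),
                      frameshift = logical()))
  if (is.na(rnaVaf)) {
    warning("missing RNA VAF for ", mp@variantId, "; treated as 1.0")
    rnaVaf <- 1
  }
  ord <- order(scored$start, scored$k)
  s <- scored$start[ord]
  e <- scored$start[ord] + scored$k[ord] - 1L
  comb <- scored$combined[ord]
  ## sweep-line transitive closure of pairwise interval overlap
  cluster <- integer(length(s))
  cur <- 1L
  maxEnd <- e[1L]
  cluster[1L] <- 1L
  for (i in seq_along(s)[-1L]) {
    if (s[i] > maxEnd) cur <- cur + 1L
    cluster[i] <- cur
    maxEnd <- max(maxEnd, e[i])
  }
  L <- nchar(mp@sequence)
  rows <- lapply(split(seq_along(s), cluster), function(ix) {
    lo <- min(s[ix]); hi <- max(e[ix])
    center <- min(mp@mutantPositions[mp@mutantPositions >= lo &
                                     mp@mutantPositions <= hi])
    ws <- max(1L, center - flank)
    we <- min(L, center + flank)
    data.frame(sequence = substr(mp@sequence, ws, we),
               score = sum(comb[ix]) * rnaVaf,
               nPeptides = length(ix),
               clusterStart = lo, clusterEnd = hi,
               truncated = (hi - lo + 1L) > (2L * flank + 1L),
               frameshift = mp@frameshift,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Design a patient's ranked neoantigen list
#'
#' Full per-patient pipeline: apply each protein-altering variant, enumerate
#' 8-11-mer mutant peptides, drop peptides containing unknown residues,
#' score against the patient's alleles, drop peptides whose combined score
#' does not exceed `binderThreshold`, merge into 25-AA neoantigens, and
#' rank by score (descending; ties by sequence).
#'
#' @param variants Variant `data.frame` for one patient (`chrom, pos, ref,
#'   alt, class, rnaVaf`, optional `gene`, `id`).
#' @param transcripts A [TranscriptSet-class].
#' @param alleles,weights The patient's six alleles and expression weights.
#' @param scorer A [BindingScorer-class].
#' @param binderThreshold Combined-score threshold a peptide must exceed to
#'   enter a neoantigen (default 0: any positive weighted binding).
#' @param kRange Peptide lengths (default 8:11).
#' @param flank Neoantigen flank (default 12 -> 25-AA).
#' @return `data.frame` ranked by score: `rank, sequence, gene, variantId,
#'   transcriptId, nPeptides, vaf, score, frameshift, truncated`.  Zero
#'   rows when the patient has no candidate.
#' @export
designPatient <- function(variants, transcripts, alleles, scorer,
                          weights = rep(1 / 6, 6), binderThreshold = 0,
                          kRange = 8:11, flank = 12L) {
  proteinAltering <- c("missense", "frameshift", "inframe_indel")
  out <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    if (!v$class %in% proteinAltering) next
    mp <- suppressMessages(applyVariant(transcripts, v))
    if (is.null(mp)) next
    pep <- enumeratePeptides(mp, kRange)
    pep <- pep[!grepl("X", pep$peptide, fixed = TRUE), , drop = FALSE]
    if (!nrow(pep)) next
    pep <- scorePeptides(pep, alleles, scorer, weights)
    pep <- pep[pep$combined > binderThreshold, , drop = FALSE]
    if (!nrow(pep)) next
    vaf <- if (!is.null(v$rnaVaf)) v$rnaVaf else NA_real_
    neo <- mergeNeoantigens(pep, mp, vaf, flank)
    neo$gene <- if (!is.null(v$gene)) v$gene else NA_character_
    neo$variantId <- mp@variantId
    neo$transcriptId <- mp@transcriptId
    neo$vaf <- if (is.na(vaf)) 1 else vaf
    out[[length(out) + 1L]] <- neo
  }
  if (!length(out))
    return(data.frame(rank = integer(), sequence = character(),
                      gene = character(), variantId = character(),
                      transcriptId = character(), nPeptides = integer(),
                      vaf = numeric(), score = numeric(),
                      frameshift = logical(), truncated = logical()))
  neo <- do.call(rbind, out)
  neo <- neo[order(-neo$score, neo$sequence), , drop = FALSE]
  neo$rank <- seq_len(nrow(neo))
  rownames(neo) <- NULL
  neo[, c("rank", "sequence", "gene", "variantId", "transcriptId",
          "nPeptides", "vaf", "score", "frameshift", "truncated")]
}

#' Design neoantigens for every patient in a cohort
#'
#' @param variants Cohort variant `data.frame` with a `patient` column
#'   (already population-frequency and target filtered, or not -- the
#'   protein-altering check in [designPatient()] governs inclusion).
#' @param transcripts A [TranscriptSet-class].
#' @param genotypes An [HLAGenotypeSet-class] covering all patients.
#' @param scorer A [BindingScorer-class].
#' @inheritParams designPatient
#' @return Named list (one ranked `data.frame` per patient).
#' @export
designCohort <- function(variants, transcripts, genotypes, scorer,
                         binderThreshold = 0, kRange = 8:11, flank = 12L) {
  patients <- hlaPatients(genotypes)
  out <- lapply(patients, function(p) {
    designPatient(variants[variants$patient == p, , drop = FALSE],
                  transcripts,
                  alleles = hlaAlleles(genotypes, p),
                  scorer = scorer,
                  weights = hlaWeights(genotypes, p),
                  binderThreshold = binderThreshold,
                  kRange = kRange, flank = flank)
  })
  names(out) <- patients
  out
}
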
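#' @import methods
#' @importFrom Biostrings DNAStringSet AAStringSet
NULL

## ---------------------------------------------------------------------------
## CohortSpec
## ---------------------------------------------------------------------------

#' Synthetic cohort specification
#'
#' Holds every constant of the synthetic cohort generator: cohort size,
#' per-patient mutated-site intensity and the single high-burden outlier,
#' recurrent-hotspot definitions, the consequence-class mixture, per-locus HLA
#' allele frequencies, the repertoire layout, the surrogate binding model, and
#' the global seed.  The defaults (see [defaultCohortSpec()]) emulate a
#' 24-patient glioblastoma vaccine cohort: a mean of 200 mutated sites per
#' patient with one ~10x outlier, one missense hotspot carried by 5/24
#' patients, HLA frequency tables headed by A*30:01/A*11:01, B*13:02 and
#' C*06:02, and repertoires with a universal PBMC TCR clone.
#'
#' @slot nPatients Number of patients.
#' @slot meanSites Poisson mean of somatic mutated sites per patient
#'   (post-filter, on-target).
#' @slot outlierPatient Index of the designated high-burden patient.
#' @slot outlierFactor Multiplier applied to `meanSites` for that patient.
#' @slot hotspots `data.frame` with columns `transcript` (index), `codon`,
#'   `fraction` (carrier fraction of the cohort).
#' @slot classProbs Named probability vector over consequence classes.
#' @slot hlaFrequencies List with elements `A`, `B`, `C`: named per-locus
#'   allele frequency vectors, each summing to at most 1 (residual mass is
#'   spread over placeholder rare alleles at sampling time).
#' @slot repertoire Named list of repertoire generator settings
#'   (see [defaultRepertoireSpec()]).
#' @slot targetSizeBp Total size of the targeted exon region in bp (the TMB
#'   denominator); the synthetic BED pads to this size with a filler contig.
#' @slot decoyCommonMean,decoyOffTargetMean Poisson means of the per-patient
#'   decoy variants carrying common population AF, resp. lying off target.
#' @slot binderFraction Fraction of random (peptide, allele) pairs the
#'   surrogate scorer classifies as binders.
#' @slot scoreRange Numeric length-2: binding-score range for binders.
#' @slot seed Global integer seed; all component seeds derive from it.
#' @seealso [defaultCohortSpec()], [simulateCohort()]
#' @export
setClass("CohortSpec", representation(
  nPatients = "integer",
  meanSites = "numeric",
  outlierPatient = "integer",
  outlierFactor = "numeric",
  hotspots = "data.frame",
  classProbs = "numeric",
  hlaFrequencies = "list",
  repertoire = "list",
  targetSizeBp = "numeric",
  decoyCommonMean = "numeric",
  decoyOffTargetMean = "numeric",
  binderFraction = "numeric",
  scoreRange = "numeric",
  seed = "integer"
))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
  if (object@meanSites <= 0) msg <- c(msg, "meanSites must be positive")
  if (object@outlierFactor <= 0) msg <- c(msg, "outlierFactor must be positive")
  if (abs(sum(object@classProbs) - 1) > 1e-9)
    msg <- c(msg, "classProbs must sum to 1")
  if (any(object@classProbs < 0)) msg <- c(msg, "classProbs must be nonnegative")
  if (nrow(object@hotspots) &&
      (any(object@hotspots$fraction < 0) || any(object@hotspots$fraction > 1)))
    msg <- c(msg, "hotspot carrier fractions must lie in [0, 1]")
  for (locus in c("A", "B", "C")) {
    f <- object@hlaFrequencies[[locus]]
    if (is.null(f) || !length(f))
      msg <- c(msg, sprintf("hlaFrequencies$%s is missing or empty", locus))
    else if (any(f < 0) || sum(f) > 1 + 1e-9)
      msg <- c(msg, sprintf("hlaFrequencies$%s must be nonnegative and sum to <= 1", locus))
  }
  if (object@binderFraction <= 0 || object@binderFraction >= 1)
    msg <- c(msg, "binderFraction must lie in (0, 1)")
  if (length(object@scoreRange) != 2L || diff(object@scoreRange) <= 0)
    msg <- c(msg, "scoreRange must be (low, high) with low < high")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nPatients, "patients, mean",
      object@meanSites, "sites/patient (outlier x",
      object@outlierFactor, ")\n", sep = " ")
  cat("  hotspots:", nrow(object@hotspots),
      " | target:", object@targetSizeBp / 1e6, "Mb",
      " | binder fraction:", object@binderFraction,
      " | seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## TranscriptSet
## ---------------------------------------------------------------------------

#' A set of transcript models
#'
#' cDNA sequences with their CDS coordinates and translated proteins.  cDNA
#' coordinates are 1-based; the CDS runs `[cdsStart, cdsEnd]` inclusive,
#' starts with ATG, ends with a stop codon, and has length divisible by 3.
#'
#' @slot cdna A [Biostrings::DNAStringSet] of cDNA sequences (named).
#' @slot cdsStart,cdsEnd Integer vectors, 1-based inclusive CDS bounds.
#' @slot protein An [Biostrings::AAStringSet] of translations (stop removed).
#' @export
setClass("TranscriptSet", representation(
  cdna = "DNAStringSet",
  cdsStart = "integer",
  cdsEnd = "integer",
  protein = "AAStringSet"
))

setValidity("TranscriptSet", function(object) {
  n <- length(object@cdna)
  msg <- character()
  if (length(object@cdsStart) != n || length(object@cdsEnd) != n ||
      length(object@protein) != n)
    msg <- c(msg, "cdna, cdsStart, cdsEnd and protein must have equal length")
  if (n && (is.null(names(object@cdna)) || anyDuplicated(names(object@cdna))))
    msg <- c(msg, "cdna must have unique names")
  if (n && any((object@cdsEnd - object@cdsStart + 1L) %% 3L != 0L))
    msg <- c(msg, "CDS lengths must be divisible by 3")
  if (n && any(object@cdsEnd > Biostrings::width(object@cdna)))
    msg <- c(msg, "CDS must lie inside the cDNA")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object@cdna), "transcripts;",
      "mean CDS", round(mean(object@cdsEnd - object@cdsStart + 1L) / 3), "codons\n")
})

#' @describeIn TranscriptSet-class Number of transcripts.
#' @param x A `TranscriptSet`.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@cdna))

#' Transcript identifiers
#' @param x A [TranscriptSet-class].
#' @return Character vector of transcript ids.
#' @export
transcriptIds <- function(x) names(x@cdna)

## ---------------------------------------------------------------------------
## MutantProtein
## ---------------------------------------------------------------------------

#' A mutated protein with its altered residues
#'
#' Result of applying one protein-altering somatic variant to a transcript.
#' `mutantPositions` are 1-based residue indices; for a frameshift they form
#' the contiguous suffix from the first altered residue to the end of the
#' neo-ORF translation.
#'
#' @slot transcriptId Source transcript id.
#' @slot variantId Identifier of the source variant.
#' @slot sequence Mutant protein sequence (single string, no stop).
#' @slot mutantPositions Sorted 1-based indices of altered residues.
#' @slot frameshift Logical; `TRUE` for frameshift neo-ORFs.
#' @export
setClass("MutantProtein", representation(
  transcriptId = "character",
  variantId = "character",
  sequence = "character",
  mutantPositions = "integer",
  frameshift = "logical"
))

setValidity("MutantProtein", function(object) {
  msg <- character()
  L <- nchar(object@sequence)
  mp <- object@mutantPositions
  if (!length(mp)) msg <- c(msg, "mutantPositions must be non-empty")
  if (length(mp) && (min(mp) < 1L || max(mp) > L))
    msg <- c(msg, "mutantPositions must lie within the protein")
  if (isTRUE(object@frameshift) && length(mp) &&
      !identical(mp, seq.int(min(mp), L)))
    msg <- c(msg, "frameshift mutantPositions must be a suffix range")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MutantProtein", function(object) {
  cat(sprintf("MutantProtein [%s | %s] length %d, %s, %d mutant residue(s) from %d\n",
              object@transcriptId, object@variantId, nchar(object@sequence),
              if (object@frameshift) "frameshift" else "substitution/in-frame",
              length(object@mutantPositions), min(object@mutantPositions)))
})

## ---------------------------------------------------------------------------
## Binding scorers
## ---------------------------------------------------------------------------

#' Binding scorer interface
#'
#' Virtual parent of peptide-MHC binding scorers.  A scorer is a pure
#' function of (peptide sequence, allele name): repeated calls with the same
#' arguments always return the same nonnegative score, higher = stronger
#' predicted binding, 0 = non-binder.
#'
#' @seealso [SurrogateScorer()], [RankTableScorer()], [bindingScore()]
#' @export
setClass("BindingScorer", representation("VIRTUAL"))

#' @rdname SurrogateScorer
#' @export
setClass("SurrogateScorer", contains = "BindingScorer", representation(
  seed = "integer",
  binderFraction = "numeric",
  scoreRange = "numeric"
))

setValidity("SurrogateScorer", function(object) {
  msg <- character()
  if (object@binderFraction <= 0 || object@binderFraction >= 1)
    msg <- c(msg, "binderFraction must lie in (0, 1)")
  if (length(object@scoreRange) != 2L || diff(object@scoreRange) <= 0 ||
      object@scoreRange[1] < 0)
    msg <- c(msg, "scoreRange must be nonnegative (low, high), low < high")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SurrogateScorer", function(object) {
  cat(sprintf("SurrogateScorer(seed = %d, binder fraction = %g, score range [%g, %g])\n",
              object@seed, object@binderFraction,
              object@scoreRange[1], object@scoreRange[2]))
})

#' @rdname RankTableScorer
#' @export
setClass("RankTableScorer", contains = "BindingScorer", representation(
  ranks = "numeric",   # named by "peptide|allele"
  rankCutoff = "numeric"
))

setMethod("show", "RankTableScorer", function(object) {
  cat(sprintf("RankTableScorer with %d (peptide, allele) entries, %%rank cutoff %g\n",
              length(object@ranks), object@rankCutoff))
})

#' Binding score of peptides against one HLA allele
#'
#' @param scorer A [BindingScorer-class] implementation.
#' @param peptides Character vector of peptide sequences (8-11 AA).
#' @param allele Single HLA allele name, e.g. `"A*30:01"`.
#' @return Numeric vector of nonnegative scores, one per peptide.
#' @export
setGeneric("bindingScore", function(scorer, peptides, allele)
  standardGeneric("bindingScore"))

## ---------------------------------------------------------------------------
## HLAGenotypeSet
## ---------------------------------------------------------------------------

#' HLA class-I genotypes (with optional expression weights) for a cohort
#'
#' Six two-field class-I alleles per patient (two per locus, A/B/C) plus an
#' optional per-slot expression weight matrix.  When present, the six weights
#' of a patient sum to 1 and feed into neoantigen scoring.
#'
#' @slot patients Character vector of patient ids.
#' @slot alleles Character matrix `n x 6` with columns `A1,A2,B1,B2,C1,C2`,
#'   entries normalized to two-field names (`"A*30:01"`).
#' @slot weights Numeric matrix `n x 6` of expression weights (rows sum to 1),
#'   or a 0-row matrix when no expression information is attached.
#' @export
setClass("HLAGenotypeSet", representation(
  patients = "character",
  alleles = "matrix",
  weights = "matrix"
))

.hlaSlotNames <- c("A1", "A2", "B1", "B2", "C1", "C2")

setValidity("HLAGenotypeSet", function(object) {
  msg <- character()
  n <- length(object@patients)
  if (anyDuplicated(object@patients)) msg <- c(msg, "duplicate patient ids")
  if (!identical(colnames(object@alleles), .hlaSlotNames) ||
      nrow(object@alleles) != n)
    msg <- c(msg, "alleles must be an n x 6 matrix with columns A1,A2,B1,B2,C1,C2")
  else {
    for (j in seq_len(6L)) {
      locus <- substr(.hlaSlotNames[j], 1L, 1L)
      bad <- !grepl(paste0("^", locus, "\\*[0-9]+:[0-9]+$"), object@alleles[, j])
      if (any(bad))
        msg <- c(msg, sprintf("malformed or wrong-locus allele in column %s: %s",
                              .hlaSlotNames[j],
                              paste(unique(object@alleles[bad, j]), collapse = ", ")))
    }
  }
  if (nrow(object@weights)) {
    if (nrow(object@weights) != n || ncol(object@weights) != 6L)
      msg <- c(msg, "weights must be n x 6")
    else if (any(abs(rowSums(object@weights) - 1) > 1e-9) ||
             any(object@weights < 0))
      msg <- c(msg, "weights must be nonnegative and sum to 1 per patient")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "HLAGenotypeSet", function(object) {
  cat("HLAGenotypeSet:", length(object@patients), "patients,",
      length(unique(as.vector(object@alleles))), "distinct alleles,",
      if (nrow(object@weights)) "with" else "without", "expression weights\n")
})

#' @describeIn HLAGenotypeSet-class Number of patients.
#' @param x An `HLAGenotypeSet`.
#' @export
setMethod("length", "HLAGenotypeSet", function(x) length(x@patients))

#' Accessors for HLAGenotypeSet
#'
#' @param x An [HLAGenotypeSet-class].
#' @param patient Optional single patient id to subset to.
#' @return `hlaAlleles()`: character matrix (or vector for one patient);
#'   `hlaWeights()`: numeric matrix (or vector), uniform 1/6 when no
#'   expression information is attached; `hlaPatients()`: patient ids.
#' @export
hlaAlleles <- function(x, patient = NULL) {
  if (is.null(patient)) return(x@alleles)
  x@alleles[match(patient, x@patients), ]
}

#' @rdname hlaAlleles
#' @export
hlaWeights <- function(x, patient = NULL) {
  w <- if (nrow(x@weights)) x@weights else
    matrix(1 / 6, length(x@patients), 6L,
           dimnames = list(x@patients, .hlaSlotNames))
  if (is.null(patient)) return(w)
  w[match(patient, x@patients), ]
}

#' @rdname hlaAlleles
#' @export
hlaPatients <- function(x) x@patients

## ---------------------------------------------------------------------------
## CoverageMatrix / BulkSelection
## ---------------------------------------------------------------------------

#' Patient-by-peptide incidence matrix
#'
#' Boolean incidence of candidate neoantigen sequences across patients, the
#' input of the peptide-bulk set-cover selection.  Construction drops
#' all-false columns and collapses duplicate sequences; see
#' [buildCoverageMatrix()].
#'
#' @slot incidence Logical matrix, rows = patients, columns = peptide
#'   sequences; every column has at least one `TRUE`.
#' @export
setClass("CoverageMatrix", representation(incidence = "matrix"))

setValidity("CoverageMatrix", function(object) {
  m <- object@incidence
  msg <- character()
  if (!is.logical(m)) msg <- c(msg, "incidence must be a logical matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "incidence must have row (patient) and column (peptide) names")
  if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate peptide columns")
  if (ncol(m) && any(colSums(m) == 0L)) msg <- c(msg, "all-false peptide column")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CoverageMatrix", function(object) {
  m <- object@incidence
  cat("CoverageMatrix:", nrow(m), "patients x", ncol(m), "peptides;",
      sum(colSums(m) > 1L), "peptides shared by >1 patient\n")
})

#' @describeIn CoverageMatrix-class Dimensions (patients, peptides).
#' @param x A `CoverageMatrix`.
#' @export
setMethod("dim", "CoverageMatrix", function(x) dim(x@incidence))

#' Incidence matrix of a CoverageMatrix
#' @param x A [CoverageMatrix-class].
#' @return The underlying logical matrix.
#' @export
incidence <- function(x) x@incidence

#' Result of a greedy peptide-bulk selection
#'
#' @slot selected Peptide sequences in greedy pick order.
#' @slot covered,uncovered Patient ids covered by the selection / impossible
#'   to cover (patients with no candidate peptide at all).
#' @slot perStepGain Number of newly covered patients at each pick (always
#'   positive).
#' @seealso [greedyCover()]
#' @export
setClass("BulkSelection", representation(
  selected = "character",
  covered = "character",
  uncovered = "character",
  perStepGain = "integer"
))

setMethod("show", "BulkSelection", function(object) {
  cat(sprintf("BulkSelection: %d peptide(s) covering %d patient(s)%s\n",
              length(object@selected), length(object@covered),
              if (length(object@uncovered))
                sprintf(" (%d uncoverable)", length(object@uncovered)) else ""))
  if (length(object@selected))
    cat("  gains:", paste(object@perStepGain, collapse = ", "), "\n")
})

#' Accessors for BulkSelection
#' @param x A [BulkSelection-class].
#' @return `selectedPeptides()`: picks in order; `coveredPatients()` /
#'   `uncoveredPatients()`: patient ids; `perStepGain()`: newly covered
#'   patients per pick.
#' @export
selectedPeptides <- function(x) x@selected

#' @rdname selectedPeptides
#' @export
coveredPatients <- function(x) x@covered

#' @rdname selectedPeptides
#' @export
uncoveredPatients <- function(x) x@uncovered

#' @rdname selectedPeptides
#' @export
perStepGain <- function(x) x@perStepGain
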
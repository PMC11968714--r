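## HLA class-I genotypes, cohort allele frequencies, and allele-specific
## expression weights.  Genotypes are consumed (e.g. OptiType-style output),
## never inferred; expression comes in as per-allele measurements (reads or
## TPM -- the normalization is metric-agnostic) and leaves as weights summing
## to 1 per patient.

#' Normalize an HLA allele name to two-field resolution
#'
#' Accepts names with or without the `*` separator and with higher-field
#' suffixes (`"A*30:01:01"`, `"A30:01"`) and returns the canonical two-field
#' form (`"A*30:01"`).
#'
#' @param x Character vector of allele names.
#' @return Character vector of normalized names.
#' @examples
#' normalizeAllele(c("A*30:01:01", "B13:02"))
#' @export
normalizeAllele <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^(HLA-)?([ABC])\\*?([0-9]+):([0-9]+)", x))
  bad <- lengths(m) == 0L
  if (any(bad))
    stop("malformed HLA allele name: ", paste(unique(x[bad]), collapse = ", "))
  vapply(m, function(g) paste0(g[3], "*", g[4], ":", g[5]), character(1))
}

#' Construct an HLA genotype set
#'
#' @param patients Character vector of patient ids.
#' @param alleles Character matrix or data.frame `n x 6` with columns
#'   `A1,A2,B1,B2,C1,C2` (any allele spelling accepted by
#'   [normalizeAllele()]).
#' @param weights Optional `n x 6` numeric matrix of per-slot expression
#'   weights; rows are renormalized to sum to 1.
#' @return An [HLAGenotypeSet-class].
#' @export
HLAGenotypeSet <- function(patients, alleles, weights = NULL) {
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != 6L)
    stop("exactly 6 allele slots per patient are required (got ",
         ncol(alleles), "); missing locus?")
  colnames(alleles) <- .hlaSlotNames
  norm <- matrix(normalizeAllele(alleles), nrow(alleles), 6L,
                 dimnames = list(as.character(patients), .hlaSlotNames))
  ## canonical within-locus order so genotype identity is slot-order free
  for (loc in c(1L, 3L, 5L)) {
    pair <- norm[, c(loc, loc + 1L), drop = FALSE]
    norm[, loc] <- pmin(pair[, 1L], pair[, 2L])
    norm[, loc + 1L] <- pmax(pair[, 1L], pair[, 2L])
  }
  if (is.null(weights)) {
    weights <- matrix(numeric(0), 0L, 6L)
  } else {
    weights <- as.matrix(weights)
    weights <- weights / rowSums(weights)
    dimnames(weights) <- dimnames(norm)
  }
  new("HLAGenotypeSet", patients = as.character(patients),
      alleles = norm, weights = weights)
}

#' Read HLA genotypes from a TSV file
#'
#' Expects columns `patient, A1, A2, B1, B2, C1, C2`; an optional expression
#' TSV with columns `patient, allele, measurement` attaches expression
#' weights via [expressionProportions()].
#'
#' @param file Genotype TSV path.
#' @param expressionFile Optional per-allele expression TSV path.
#' @return An [HLAGenotypeSet-class].
#' @export
readHlaGenotypes <- function(file, expressionFile = NULL) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("patient", .hlaSlotNames)
  if (!all(need %in% names(tab)))
    stop("genotype TSV needs columns: ", paste(need, collapse = ", "))
  gt <- HLAGenotypeSet(tab$patient, tab[, .hlaSlotNames])
  if (!is.null(expressionFile)) {
    ex <- utils::read.delim(expressionFile, stringsAsFactors = FALSE)
    gt <- attachExpression(gt, ex)
  }
  gt
}

#' Attach per-allele expression measurements to genotypes
#'
#' Long-format measurements (`patient, allele, measurement`) are matched to
#' the six allele slots of each patient and normalized to weights via
#' [expressionProportions()].  A measurement reported once for a homozygous
#' locus is split evenly between the two identical slots.
#'
#' @param genotypes An [HLAGenotypeSet-class].
#' @param measurements `data.frame` with columns `patient, allele,
#'   measurement` (nonnegative; reads or TPM).
#' @return The genotype set with expression weights attached.
#' @export
attachExpression <- function(genotypes, measurements) {
  w <- matrix(NA_real_, length(genotypes@patients), 6L,
              dimnames = list(genotypes@patients, .hlaSlotNames))
  measurements$allele <- normalizeAllele(measurements$allele)
  for (i in seq_along(genotypes@patients)) {
    p <- genotypes@patients[i]
    mi <- measurements[measurements$patient == p, , drop = FALSE]
    x <- numeric(6L)
    al <- genotypes@alleles[i, ]
    for (j in seq_len(6L)) {
      hit <- mi$measurement[mi$allele == al[j]]
      if (!length(hit))
        stop("no expression measurement for patient ", p, " allele ", al[j])
      ## homozygous locus reported jointly: split across the two slots
      x[j] <- sum(hit) / sum(al == al[j])
    }
    w[i, ] <- expressionProportions(x)
  }
  methods::initialize(genotypes, weights = w)
}

#' Cohort allele frequencies per locus
#'
#' The frequency of an allele at a locus is its slot count divided by
#' `2 * n_patients`, so each per-locus table sums to 1.
#'
#' @param genotypes An [HLAGenotypeSet-class].
#' @return Named list with elements `A`, `B`, `C`, each a named numeric
#'   vector of frequencies sorted decreasingly.
#' @export
alleleFrequencies <- function(genotypes) {
  n2 <- 2L * length(genotypes@patients)
  lapply(c(A = 1L, B = 3L, C = 5L), function(loc) {
    tab <- table(as.vector(genotypes@alleles[, c(loc, loc + 1L)]))
    sort(stats::setNames(as.numeric(tab) / n2, names(tab)), decreasing = TRUE)
  })
}

#' Normalize per-allele expression measurements to weights
#'
#' Converts six nonnegative per-slot measurements into weights
#' `w_i = x_i / sum(x)`.  Weights are invariant to rescaling of the raw
#' measurements; alleles with zero expression keep weight 0 (they contribute
#' nothing to neoantigen scoring but the six-slot structure is preserved).
#'
#' @param x Numeric vector of nonnegative measurements (length 6 in the
#'   class-I setting, but any length >= 1 is accepted).
#' @return Numeric vector of weights summing to 1.
#' @export
expressionProportions <- function(x) {
  if (any(x < 0) || anyNA(x)) stop("measurements must be nonnegative")
  s <- sum(x)
  if (s <= 0) stop("all-zero measurements carry no expression information")
  x / s
}

#' Genotype identity groups
#'
#' Groups patients carrying the same genotype, where "same" means multiset
#' equality of all six two-field alleles.
#'
#' @param genotypes An [HLAGenotypeSet-class].
#' @return Integer vector (one entry per patient) of genotype group ids.
#' @export
genotypeGroups <- function(genotypes) {
  key <- apply(genotypes@alleles, 1L, paste, collapse = "/")
  match(key, unique(key))
}

#' Default per-locus HLA allele frequency table
#'
#' An emulation table for cohort simulation, headed by the most frequent
#' alleles observed in East-Asian glioblastoma cohorts: A*30:01 and A*11:01,
#' B*13:02, and C*06:02.  Frequencies at each locus sum to less than 1; the
#' residual mass is spread over placeholder rare alleles at sampling time.
#'
#' @return Named list with per-locus named frequency vectors `A`, `B`, `C`.
#' @export
defaultHlaFrequencies <- function() {
  list(
    A = c("A*30:01" = 0.17, "A*11:01" = 0.17, "A*02:01" = 0.12,
          "A*24:02" = 0.11, "A*02:07" = 0.07, "A*33:03" = 0.06,
          "A*01:01" = 0.04, "A*26:01" = 0.03),
    B = c("B*13:02" = 0.15, "B*46:01" = 0.10, "B*40:01" = 0.09,
          "B*58:01" = 0.08, "B*15:01" = 0.07, "B*51:01" = 0.06,
          "B*35:01" = 0.05, "B*44:03" = 0.04),
    C = c("C*06:02" = 0.18, "C*01:02" = 0.13, "C*07:02" = 0.12,
          "C*03:04" = 0.10, "C*08:01" = 0.07, "C*03:02" = 0.06,
          "C*15:02" = 0.04, "C*04:01" = 0.04)
  )
}

#' Sample HLA genotypes from a frequency table
#'
#' Draws two alleles per locus per patient, independently across loci and
#' slots, so cohort allele frequencies converge to the table as the cohort
#' grows.  If a locus's frequencies sum to less than 1 the residual mass is
#' split across three placeholder rare alleles (`"A*97:01"` etc.).
#'
#' @param freqTable Per-locus named frequency list as returned by
#'   [defaultHlaFrequencies()].
#' @param nPatients Number of patients.
#' @param seed Integer seed.
#' @param patients Optional patient ids (default `P01`, `P02`, ...).
#' @return An [HLAGenotypeSet-class] (no expression weights).
#' @export
generateHlaGenotypes <- function(freqTable, nPatients, seed = 1L,
                                 patients = NULL) {
  if (!all(c("A", "B", "C") %in% names(freqTable)) ||
      any(!lengths(freqTable[c("A", "B", "C")])))
    stop("freqTable must supply non-empty frequencies for loci A, B and C")
  if (is.null(patients))
    patients <- sprintf("P%02d", seq_len(nPatients))
  al <- matrix("", nPatients, 6L, dimnames = list(patients, .hlaSlotNames))
  set.seed(childSeed(seed, "hla"))
  for (locus in c("A", "B", "C")) {
    f <- freqTable[[locus]]
    resid <- 1 - sum(f)
    if (resid > 1e-9) {
      filler <- stats::setNames(rep(resid / 3, 3L),
                                paste0(locus, "*", 97:99, ":01"))
      f <- c(f, filler)
    }
    draws <- sample(names(f), 2L * nPatients, replace = TRUE, prob = f)
    cols <- match(paste0(locus, 1:2), .hlaSlotNames)
    al[, cols] <- matrix(draws, nPatients, 2L)
  }
  HLAGenotypeSet(patients, al)
}

#' Simulate per-allele expression measurements
#'
#' Log-normal raw measurements per allele slot (heavily unequal across the
#' six slots, as observed for allele-specific HLA expression), with a small
#' probability of a silenced (zero-expression) allele.
#'
#' @param genotypes An [HLAGenotypeSet-class].
#' @param seed Integer seed.
#' @param sdlog Log-sd of the measurement distribution.
#' @param zeroProb Probability that an allele slot is silenced.
#' @return Long `data.frame` with columns `patient, allele, measurement`
#'   (joint value per distinct allele, suitable for [attachExpression()]).
#' @export
simulateHlaExpression <- function(genotypes, seed = 1L, sdlog = 0.9,
                                  zeroProb = 0.02) {
  set.seed(childSeed(seed, "hlaexpr"))
  out <- list()
  for (i in seq_along(genotypes@patients)) {
    al <- genotypes@alleles[i, ]
    x <- stats::rlnorm(6L, meanlog = 5, sdlog = sdlog)
    x[stats::runif(6L) < zeroProb] <- 0
    if (sum(x) == 0) x[1L] <- 1 # keep at least one expressed allele
    agg <- tapply(x, al, sum)
    out[[i]] <- data.frame(patient = genotypes@patients[i],
                           allele = names(agg),
                           measurement = round(as.numeric(agg), 3),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write genotypes (and weights) to TSV
#'
#' @param genotypes An [HLAGenotypeSet-class].
#' @param file Output TSV path.
#' @return `file`, invisibly.
#' @export
writeHlaGenotypes <- function(genotypes, file) {
  tab <- data.frame(patient = genotypes@patients,
                    genotypes@alleles, stringsAsFactors = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
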
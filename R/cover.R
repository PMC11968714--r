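## Peptide-bulk selection: patient x peptide incidence, classic greedy set
## cover with deterministic tie-breaking, an exact branch-and-bound oracle
## for small instances, and entropy / mutual-information sharing
## diagnostics.

#' Build the patient-by-peptide coverage matrix
#'
#' @param neoLists Named list: one character vector (or a design
#'   `data.frame` with a `sequence` column) of candidate neoantigen
#'   sequences per patient.  Patients with zero candidates keep their row
#'   (all false) and are reported as uncoverable by [greedyCover()].
#' @return A [CoverageMatrix-class].  Duplicate sequences within a patient
#'   collapse to one cell; sequences carried by no patient cannot occur.
#'   Columns are ordered by decreasing carrier count, then sequence.
#' @examples
#' m <- buildCoverageMatrix(list(P1 = "A", P2 = c("A", "B"), P3 = "B"))
#' incidence(m)
#' @export
buildCoverageMatrix <- function(neoLists) {
  if (is.null(names(neoLists)) || anyDuplicated(names(neoLists)))
    stop("neoLists must be a named list with unique patient ids")
  seqs <- lapply(neoLists, function(x) {
    if (is.data.frame(x)) x <- x$sequence
    unique(as.character(x))
  })
  peptides <- sort(unique(unlist(seqs, use.names = FALSE)))
  m <- matrix(FALSE, length(seqs), length(peptides),
              dimnames = list(names(seqs), peptides))
  for (p in names(seqs))
    m[p, seqs[[p]]] <- TRUE
  if (ncol(m)) {
    ord <- order(-colSums(m), colnames(m))
    m <- m[, ord, drop = FALSE]
  }
  new("CoverageMatrix", incidence = m)
}

#' Greedy minimum peptide-bulk cover
#'
#' Classic greedy set cover: repeatedly pick the peptide covering the most
#' not-yet-covered patients until every coverable patient is covered.  Ties
#' are broken by higher total prevalence, then by lexicographically smaller
#' peptide sequence, making the selection fully deterministic.
#'
#' @param matrix A [CoverageMatrix-class].
#' @return A [BulkSelection-class]: picks in order, per-step gains, covered
#'   patients and uncoverable patients (those with no candidate at all).
#' @export
greedyCover <- function(matrix) {
  m <- incidence(matrix)
  coverable <- rownames(m)[rowSums(m) > 0L]
  uncovered <- coverable
  prevalence <- colSums(m)
  selected <- character()
  gains <- integer()
  while (length(uncovered)) {
    gain <- colSums(m[uncovered, , drop = FALSE])
    best <- max(gain)
    if (best == 0L) break # cannot happen for coverable patients, guard anyway
    cand <- names(gain)[gain == best]
    cand <- cand[order(-prevalence[cand], cand)][1L]
    selected <- c(selected, cand)
    gains <- c(gains, as.integer(best))
    uncovered <- uncovered[!m[uncovered, cand]]
  }
  new("BulkSelection",
      selected = selected,
      covered = setdiff(coverable, uncovered),
      uncovered = setdiff(rownames(m), coverable),
      perStepGain = gains)
}

#' Exact minimum set cover (branch and bound)
#'
#' Exhaustive oracle for validating the greedy selection on small
#' instances.  Branches on the uncovered patient with the fewest covering
#' peptides and prunes with the greedy upper bound; refuses instances
#' larger than both limits rather than silently falling back.
#'
#' @param matrix A [CoverageMatrix-class].
#' @param maxCols,maxPatients Size guard: the instance must have at most
#'   `maxCols` peptides or at most `maxPatients` patients.
#' @return List with `size` (minimum number of peptides covering all
#'   coverable patients) and `witness` (one optimal selection; verified
#'   cover).
#' @export
exactMinCover <- function(matrix, maxCols = 20L, maxPatients = 16L) {
  m <- incidence(matrix)
  if (ncol(m) > maxCols && nrow(m) > maxPatients)
    stop(sprintf("instance too large for the exact solver (%d patients x %d peptides); raise maxCols/maxPatients deliberately",
                 nrow(m), ncol(m)))
  coverable <- rownames(m)[rowSums(m) > 0L]
  if (!length(coverable)) return(list(size = 0L, witness = character()))
  m <- m[coverable, , drop = FALSE]
  greedy <- greedyCover(matrix)
  best <- list(size = length(selectedPeptides(greedy)),
               witness = selectedPeptides(greedy))
  cols <- colnames(m)
  covers <- lapply(seq_along(cols), function(j) which(m[, j]))
  rowCols <- lapply(seq_len(nrow(m)), function(i) which(m[i, ]))

  recurse <- function(uncoveredMask, chosen) {
    if (!any(uncoveredMask)) {
      if (length(chosen) < best$size)
        best <<- list(size = length(chosen), witness = cols[chosen])
      return(invisible())
    }
    if (length(chosen) + 1L >= best$size) return(invisible())
    ## branch on the hardest patient (fewest covering peptides)
    open <- which(uncoveredMask)
    nOpts <- vapply(open, function(i) length(rowCols[[i]]), integer(1))
    pivot <- open[which.min(nOpts)]
    for (j in rowCols[[pivot]]) {
      if (j %in% chosen) next
      nm <- uncoveredMask
      nm[covers[[j]]] <- FALSE
      recurse(nm, c(chosen, j))
    }
  }
  recurse(rep(TRUE, nrow(m)), integer())
  stopifnot(all(rowSums(m[, best$witness, drop = FALSE]) > 0L))
  best
}

#' Per-peptide carrier entropy
#'
#' Shannon entropy (bits) of each peptide's carrier indicator across
#' patients: `H = -q log2 q - (1-q) log2 (1-q)` with `q` the carrier
#' fraction.  A redundancy/ranking diagnostic alongside the greedy
#' selection.
#'
#' @param matrix A [CoverageMatrix-class].
#' @return Named numeric vector of entropies, one per peptide.
#' @export
peptideEntropy <- function(matrix) {
  m <- incidence(matrix)
  q <- colSums(m) / nrow(m)
  .h2 <- function(p) ifelse(p <= 0 | p >= 1, 0,
                            -p * log2(p) - (1 - p) * log2(1 - p))
  stats::setNames(.h2(q), colnames(m))
}

#' Mutual information between two peptides' carrier indicators
#'
#' MI in bits from the 2x2 joint carrier table over patients, with the
#' convention `0 log 0 = 0`.
#'
#' @param matrix A [CoverageMatrix-class].
#' @param i,j Peptide column names or indices.
#' @return Single nonnegative number (bits).
#' @export
pairMutualInformation <- function(matrix, i, j) {
  m <- incidence(matrix)
  x <- m[, i]
  y <- m[, j]
  n <- length(x)
  mi <- 0
  for (a in c(FALSE, TRUE)) for (b in c(FALSE, TRUE)) {
    pxy <- sum(x == a & y == b) / n
    if (pxy > 0) {
      px <- sum(x == a) / n
      py <- sum(y == b) / n
      mi <- mi + pxy * log2(pxy / (px * py))
    }
  }
  max(mi, 0)
}

#' Cohort sharing table of candidate neoantigens
#'
#' How many patients carry each candidate sequence, with its carrier
#' entropy -- the tabular counterpart of a sharing histogram.
#'
#' @param matrix A [CoverageMatrix-class].
#' @return `data.frame` with columns `sequence, n_patients, entropy`,
#'   ordered by decreasing carrier count.
#' @export
sharingTable <- function(matrix) {
  m <- incidence(matrix)
  ent <- peptideEntropy(matrix)
  out <- data.frame(sequence = colnames(m),
                    n_patients = as.integer(colSums(m)),
                    entropy = as.numeric(ent),
                    stringsAsFactors = FALSE)
  out[order(-out$n_patients, out$sequence), , drop = FALSE]
}

#' Plant a set-cover instance with known optimum
#'
#' Oracle construction for validating the cover machinery: patients are
#' partitioned into `optimumK` blocks, each block sharing one planted
#' peptide; decoy peptides are each private to a single patient, and every
#' block keeps at least one decoy-free patient, so the exact minimum cover
#' size is `optimumK` by construction (each block's decoy-free patient
#' forces its block peptide; the `optimumK` block peptides suffice).
#'
#' @param nPatients Number of patients.
#' @param optimumK Planted minimum cover size, `1 <= optimumK <= nPatients`.
#' @param decoys Number of private decoy peptides.
#' @param seed Integer seed.
#' @return List with `matrix` (a [CoverageMatrix-class]), `planted`
#'   (the block peptides) and `optimum` (= `optimumK`).
#' @export
plantCoverInstance <- function(nPatients, optimumK, decoys = 6L, seed = 1L) {
  if (optimumK < 1L || optimumK > nPatients)
    stop("optimumK must lie in [1, nPatients]")
  set.seed(childSeed(seed, "plantcover"))
  patients <- sprintf("P%02d", seq_len(nPatients))
  block <- sort(rep_len(seq_len(optimumK), nPatients))
  block <- block[sample.int(nPatients)]
  planted <- vapply(seq_len(optimumK), function(b)
    paste(sample(.AA20, 25L, replace = TRUE), collapse = ""), character(1))
  lists <- stats::setNames(lapply(block, function(b) planted[b]), patients)
  ## protected decoy-free patient per block
  protected <- vapply(seq_len(optimumK),
                      function(b) which(block == b)[1L], integer(1))
  eligible <- setdiff(seq_len(nPatients), protected)
  if (decoys > 0L && length(eligible)) {
    hosts <- sample(eligible, decoys, replace = TRUE)
    for (d in seq_len(decoys)) {
      decoySeq <- paste(sample(.AA20, 25L, replace = TRUE), collapse = "")
      lists[[hosts[d]]] <- c(lists[[hosts[d]]], decoySeq)
    }
  }
  list(matrix = buildCoverageMatrix(lists), planted = planted,
       optimum = as.integer(optimumK))
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
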
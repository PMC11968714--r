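## Synthetic reference transcripts: cDNA with a short 5'UTR, an open reading
## frame (ATG ... stop, no internal stop), and a 3'UTR long enough for
## frameshift neo-ORFs to either find a downstream stop or run off the cDNA
## end.  Translation everywhere goes through Biostrings and the standard
## genetic code.

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

## translate an arbitrary DNA string codon-by-codon from its first base up
## to (and excluding) the first stop codon, or the last complete codon.
## Returns the AA string; attribute "stopped" says whether a stop was hit.
.translateToStop <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) {
    out <- ""
    attr(out, "stopped") <- FALSE
    return(out)
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1L, 3L * n)),
    no.init.codon = TRUE))
  stopAt <- regexpr("*", aa, fixed = TRUE)
  stopped <- stopAt > 0L
  out <- if (stopped) substr(aa, 1L, stopAt - 1L) else aa
  attr(out, "stopped") <- stopped
  out
}

#' Construct a transcript set from explicit sequences
#'
#' @param cdna Named character vector (or `DNAStringSet`) of cDNA sequences.
#' @param cdsStart,cdsEnd 1-based inclusive CDS bounds per transcript.
#' @return A [TranscriptSet-class]; proteins are derived by translating the
#'   CDS (stop codon excluded).
#' @examples
#' TranscriptSet(c(tx1 = "AAATGGCTTCTTGGTAAGG"), cdsStart = 3, cdsEnd = 17)
#' @export
TranscriptSet <- function(cdna, cdsStart, cdsEnd) {
  cdna <- Biostrings::DNAStringSet(cdna)
  cdsStart <- as.integer(cdsStart)
  cdsEnd <- as.integer(cdsEnd)
  prot <- vapply(seq_along(cdna), function(i)
    .translateToStop(substr(as.character(cdna[[i]]), cdsStart[i], cdsEnd[i])),
    character(1))
  pr <- Biostrings::AAStringSet(prot)
  names(pr) <- names(cdna)
  new("TranscriptSet", cdna = cdna, cdsStart = cdsStart, cdsEnd = cdsEnd,
      protein = pr)
}

#' Generate synthetic reference transcript models
#'
#' Draws `n` transcripts whose CDS lengths (in codons, incl. the stop) are
#' normal with the given mean and sd (truncated below at 30 codons).  Each
#' cDNA is `5'UTR + ATG ... stop + 3'UTR`; the ORF contains no internal stop
#' codon, so the translated protein is exactly the CDS translation.
#'
#' @param n Number of transcripts (>= 1).
#' @param meanCodons,sdCodons CDS length distribution in codons.
#' @param seed Integer seed; identical inputs give byte-identical output.
#' @param utr5,utr3 5'/3' UTR lengths in bp.
#' @return A [TranscriptSet-class] with transcripts named `TX0001`, ...
#' @examples
#' tx <- generateReferenceTranscripts(3, meanCodons = 100, seed = 7)
#' @export
generateReferenceTranscripts <- function(n, meanCodons = 300, sdCodons = 100,
                                         seed = 1L, utr5 = 30L, utr3 = 150L) {
  if (n < 1L) stop("n must be >= 1")
  if (meanCodons <= 0) stop("invalid length distribution: non-positive mean")
  set.seed(childSeed(seed, "transcripts"))
  nCodons <- pmax(30L, as.integer(round(stats::rnorm(n, meanCodons, sdCodons))))
  cdna <- character(n)
  cdsStart <- integer(n)
  cdsEnd <- integer(n)
  protein <- character(n)
  sense <- setdiff(mkAllCodons(), .STOPS)
  for (i in seq_len(n)) {
    ## nCodons[i] counts ATG + internal codons + stop
    internal <- sample(sense, nCodons[i] - 2L, replace = TRUE)
    orf <- paste0("ATG", paste(internal, collapse = ""),
                  sample(.STOPS, 1L))
    utr5seq <- paste(sample(.BASES, utr5, replace = TRUE), collapse = "")
    utr3seq <- paste(sample(.BASES, utr3, replace = TRUE), collapse = "")
    cdna[i] <- paste0(utr5seq, orf, utr3seq)
    cdsStart[i] <- utr5 + 1L
    cdsEnd[i] <- utr5 + 3L * nCodons[i]
    protein[i] <- .translateToStop(orf)
  }
  ids <- sprintf("TX%04d", seq_len(n))
  cd <- Biostrings::DNAStringSet(cdna)
  names(cd) <- ids
  pr <- Biostrings::AAStringSet(protein)
  names(pr) <- ids
  new("TranscriptSet", cdna = cd, cdsStart = cdsStart, cdsEnd = cdsEnd,
      protein = pr)
}

mkAllCodons <- local({
  memo <- NULL
  function() {
    if (is.null(memo))
      memo <<- apply(expand.grid(.BASES, .BASES, .BASES), 1L, paste,
                     collapse = "")
    memo
  }
})

#' Write / read transcript models
#'
#' The on-disk form is a cDNA FASTA plus a TSV of CDS coordinates
#' (`transcript, cds_start, cds_end`, 1-based inclusive).
#'
#' @param transcripts A [TranscriptSet-class].
#' @param fastaFile,cdsFile Output/input paths.
#' @return `writeTranscripts()`: the paths, invisibly;
#'   `readTranscripts()`: a [TranscriptSet-class] (proteins re-derived by
#'   translation).
#' @export
writeTranscripts <- function(transcripts, fastaFile, cdsFile) {
  Biostrings::writeXStringSet(transcripts@cdna, fastaFile)
  utils::write.table(
    data.frame(transcript = transcriptIds(transcripts),
               cds_start = transcripts@cdsStart,
               cds_end = transcripts@cdsEnd),
    cdsFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fastaFile, cdsFile))
}

#' @rdname writeTranscripts
#' @export
readTranscripts <- function(fastaFile, cdsFile) {
  cdna <- Biostrings::readDNAStringSet(fastaFile)
  names(cdna) <- sub("\\s.*$", "", names(cdna))
  tab <- utils::read.delim(cdsFile, stringsAsFactors = FALSE)
  ord <- match(names(cdna), tab$transcript)
  if (anyNA(ord)) stop("CDS table is missing transcripts present in the FASTA")
  prot <- vapply(seq_along(cdna), function(i) {
    .translateToStop(substr(as.character(cdna[[i]]), tab$cds_start[ord[i]],
                            tab$cds_end[ord[i]]))
  }, character(1))
  pr <- Biostrings::AAStringSet(prot)
  names(pr) <- names(cdna)
  new("TranscriptSet", cdna = cdna,
      cdsStart = as.integer(tab$cds_start[ord]),
      cdsEnd = as.integer(tab$cds_end[ord]), protein = pr)
}
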
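## Peptide-MHC binding scorers.
##
## The package never predicts binding itself: prediction is delegated either
## to an external NetMHCpan-style result table (RankTableScorer) or to a
## deterministic surrogate (SurrogateScorer) used for simulation and testing.
## Both return scores on the same scale: nonnegative, higher = stronger,
## 0 = non-binder, so downstream code is agnostic to the source.

#' Deterministic surrogate binding scorer
#'
#' A stand-in binding predictor whose score is a pure hash of
#' `(peptide, allele, seed)`: identical inputs give identical scores across
#' runs and platforms, and scores for distinct inputs behave like independent
#' draws.  A fraction `binderFraction` of (peptide, allele) pairs is
#' classified as binders and receives a score uniform on `scoreRange`; all
#' other pairs score 0.
#'
#' @param seed Integer seed defining the (fixed) random function.
#' @param binderFraction Fraction of pairs classified as binders, in (0, 1).
#' @param scoreRange Numeric `(low, high)` score range for binders.
#' @return A [SurrogateScorer-class] object.
#' @examples
#' sc <- SurrogateScorer(seed = 1)
#' bindingScore(sc, c("SIINFEKL", "KVAELVHFL"), "A*30:01")
#' @export
SurrogateScorer <- function(seed = 1L, binderFraction = 0.02,
                            scoreRange = c(0, 1)) {
  new("SurrogateScorer", seed = as.integer(seed),
      binderFraction = as.numeric(binderFraction),
      scoreRange = as.numeric(scoreRange))
}

#' @rdname bindingScore
setMethod("bindingScore", "SurrogateScorer", function(scorer, peptides, allele) {
  stopifnot(length(allele) == 1L)
  key <- paste0(peptides, "|", allele, "|", scorer@seed)
  isBinder <- hashUnit(key, salt = "bind") < scorer@binderFraction
  u <- hashUnit(key, salt = "score")
  score <- scorer@scoreRange[1] + u * diff(scorer@scoreRange)
  ifelse(isBinder, score, 0)
})

#' NetMHCpan result-table adapter
#'
#' Wraps a table of externally predicted percentile ranks (NetMHCpan-style
#' output with columns `peptide`, `allele`, `rank`) as a [BindingScorer-class].
#' The \%rank `r` is mapped to a score `max(0, 1 - r / rankCutoff)`, so
#' peptides at or beyond the conventional binder cutoff contribute 0 and the
#' strongest binders approach 1.
#'
#' @param table A `data.frame` with columns `peptide`, `allele`, `rank`
#'   (percentile rank, lower = stronger), or a path to such a tab-separated
#'   file with a header line.
#' @param rankCutoff \%rank at which the score reaches 0 (default 2.0, the
#'   conventional weak-binder threshold).
#' @return A [RankTableScorer-class] object.  Scoring a (peptide, allele)
#'   pair absent from the table is an error, never a silent zero.
#' @export
RankTableScorer <- function(table, rankCutoff = 2.0) {
  if (is.character(table) && length(table) == 1L)
    table <- utils::read.delim(table, stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "rank")
  if (!all(need %in% names(table)))
    stop("rank table needs columns: ", paste(need, collapse = ", "))
  key <- paste0(table$peptide, "|", table$allele)
  if (anyDuplicated(key))
    stop("duplicate (peptide, allele) entries in rank table")
  ranks <- as.numeric(table$rank)
  names(ranks) <- key
  new("RankTableScorer", ranks = ranks, rankCutoff = as.numeric(rankCutoff))
}

#' @rdname bindingScore
setMethod("bindingScore", "RankTableScorer", function(scorer, peptides, allele) {
  stopifnot(length(allele) == 1L)
  key <- paste0(peptides, "|", allele)
  r <- scorer@ranks[key]
  if (anyNA(r))
    stop("no rank entry for: ",
         paste(utils::head(key[is.na(r)], 3L), collapse = ", "))
  unname(pmax(0, 1 - r / scorer@rankCutoff))
})
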
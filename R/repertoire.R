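## TCR/BCR repertoire statistics over clonotype tables.
##
## A clonotype table is a data.frame with columns
##   patient, compartment ("tumor" | "PBMC"), chain ("TRB" | "IGH"),
##   cdr3aa, vGene, jGene, count
## (MiXCR-style export, one row per distinct clonotype per sample).
## Sharing identity is the CDR3 amino-acid sequence alone by default,
## matching sequence-level cohort statements; a strict mode additionally
## requires identical V and J genes.

.checkClones <- function(clones) {
  need <- c("patient", "compartment", "chain", "cdr3aa", "vGene", "jGene",
            "count")
  if (!all(need %in% names(clones)))
    stop("clonotype table needs columns: ", paste(need, collapse = ", "))
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", clones$cdr3aa)
  if (any(bad))
    stop("invalid amino-acid alphabet in CDR3: ",
         paste(utils::head(unique(clones$cdr3aa[bad]), 3L), collapse = ", "))
  if (any(clones$count < 1L)) stop("clonotype counts must be >= 1")
  invisible(clones)
}

.cloneKey <- function(clones, strict = FALSE) {
  if (strict) paste(clones$cdr3aa, clones$vGene, clones$jGene, sep = "|")
  else clones$cdr3aa
}

#' Clonotype richness per sample
#'
#' Richness is the number of distinct clonotypes (unique
#' `cdr3aa + vGene + jGene` keys) in each patient x compartment x chain
#' sample -- the raw clone/type count, without rarefaction or depth
#' normalization.
#'
#' @param clones Clonotype table (see module header for columns).
#' @return `data.frame`: `patient, compartment, chain, richness`.
#' @export
richness <- function(clones) {
  .checkClones(clones)
  key <- paste(clones$patient, clones$compartment, clones$chain, sep = "\r")
  uniq <- !duplicated(paste(key, .cloneKey(clones, strict = TRUE), sep = "\r"))
  tab <- table(key[uniq])
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  out <- data.frame(patient = parts[, 1L], compartment = parts[, 2L],
                    chain = parts[, 3L], richness = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$patient, out$compartment, out$chain), , drop = FALSE]
}

#' CDR3 length distribution per compartment and chain
#'
#' @param clones Clonotype table.
#' @param normalize Return frequencies summing to 1 per group instead of
#'   clonotype counts.
#' @return `data.frame`: `compartment, chain, length, value`.
#' @export
lengthDistribution <- function(clones, normalize = FALSE) {
  .checkClones(clones)
  len <- nchar(clones$cdr3aa)
  grp <- paste(clones$compartment, clones$chain, sep = "\r")
  out <- list()
  for (g in sort(unique(grp))) {
    tab <- table(len[grp == g])
    val <- as.numeric(tab)
    if (normalize) val <- val / sum(val)
    parts <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    out[[g]] <- data.frame(compartment = parts[1L], chain = parts[2L],
                           length = as.integer(names(tab)), value = val,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-patient CDR3 sharing spectrum
#'
#' For one compartment and chain, counts for each distinct CDR3 sequence
#' the number of patients carrying it (a CDR3 counts once per patient
#' regardless of clone size), and summarizes the spectrum: the fraction of
#' distinct CDR3s carried by exactly `k` patients.
#'
#' @param clones Clonotype table.
#' @param compartment,chain Sample stratum to analyse.
#' @param strict Use `cdr3aa + V + J` identity instead of CDR3 alone.
#' @return List with `spectrum` (`data.frame`: `n_patients, n_cdr3,
#'   fraction`) and `carriers` (named list: CDR3 -> patient ids, only for
#'   sequences shared by more than one patient, largest first).
#' @export
sharingSpectrum <- function(clones, compartment, chain, strict = FALSE) {
  .checkClones(clones)
  sel <- clones[clones$compartment == compartment & clones$chain == chain, ,
                drop = FALSE]
  if (!nrow(sel))
    return(list(spectrum = data.frame(n_patients = integer(),
                                      n_cdr3 = integer(),
                                      fraction = numeric()),
                carriers = list()))
  key <- .cloneKey(sel, strict)
  carrierSets <- lapply(split(sel$patient, key), unique)
  nCarr <- lengths(carrierSets)
  tab <- table(nCarr)
  spectrum <- data.frame(n_patients = as.integer(names(tab)),
                         n_cdr3 = as.integer(tab),
                         fraction = as.numeric(tab) / length(nCarr))
  shared <- carrierSets[nCarr > 1L]
  shared <- shared[order(-lengths(shared), names(shared))]
  list(spectrum = spectrum, carriers = shared)
}

#' Tumor-specific clonotypes shared across patients
#'
#' CDR3 sequences present in the tumor of strictly more than `minPatients`
#' patients and absent from every patient's PBMC sample (cohort-level
#' exclusion: one PBMC occurrence anywhere disqualifies the sequence).
#'
#' @param clones Clonotype table with paired tumor/PBMC samples.
#' @param chain Chain to analyse (`"TRB"` or `"IGH"`).
#' @param minPatients Strict lower bound on tumor carrier count
#'   (default 2, i.e. "more than two patients").
#' @param strict Use `cdr3aa + V + J` identity.
#' @return `data.frame`: `cdr3aa, n_tumor_patients`, ordered by decreasing
#'   carrier count then sequence.
#' @export
tumorSpecific <- function(clones, chain, minPatients = 2L, strict = FALSE) {
  .checkClones(clones)
  sel <- clones[clones$chain == chain, , drop = FALSE]
  key <- .cloneKey(sel, strict)
  inPbmc <- unique(key[sel$compartment == "PBMC"])
  tum <- sel[sel$compartment == "tumor", , drop = FALSE]
  tumKey <- .cloneKey(tum, strict)
  carriers <- lengths(lapply(split(tum$patient, tumKey), unique))
  keep <- names(carriers)[carriers > minPatients & !(names(carriers) %in% inPbmc)]
  out <- data.frame(cdr3aa = if (strict) sub("\\|.*$", "", keep) else keep,
                    n_tumor_patients = as.integer(carriers[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$n_tumor_patients, out$cdr3aa), , drop = FALSE]
}

#' N- and C-terminal CDR3 motif frequencies
#'
#' Per-position amino-acid frequency matrices for the first and last
#' `nTerminal` residues of the CDR3s; per position the 20 frequencies sum
#' to 1.  CDR3s shorter than `nTerminal` are excluded and counted.
#'
#' @param clones Clonotype table (filter to one compartment/chain upstream
#'   if a stratified motif is wanted).
#' @param nTerminal Number of terminal positions (default 4).
#' @return List with `n` and `c` (20 x `nTerminal` frequency matrices,
#'   rows = amino acids, columns = positions) and `nExcluded`.
#' @export
terminalMotifs <- function(clones, nTerminal = 4L) {
  .checkClones(clones)
  cdr3 <- clones$cdr3aa
  short <- nchar(cdr3) < nTerminal
  cdr3 <- cdr3[!short]
  mkMat <- function(seqs) {
    m <- matrix(0, 20L, nTerminal, dimnames = list(.AA20, seq_len(nTerminal)))
    for (p in seq_len(nTerminal)) {
      tab <- table(factor(substr(seqs, p, p), levels = .AA20))
      m[, p] <- as.numeric(tab) / length(seqs)
    }
    m
  }
  nterm <- mkMat(cdr3)
  cterm <- mkMat(vapply(cdr3, function(s)
    substr(s, nchar(s) - nTerminal + 1L, nchar(s)), character(1),
    USE.NAMES = FALSE))
  list(n = nterm, c = cterm, nExcluded = sum(short))
}

#' V x J rearrangement matrix
#'
#' @param clones Clonotype table.
#' @param compartment Optional compartment filter.
#' @param weight `"clonotypes"` (default: each distinct clonotype counts 1,
#'   so the matrix total equals the number of clonotypes) or `"counts"`
#'   (clone-size weighted).
#' @return Integer matrix V genes x J genes.
#' @export
vjPairing <- function(clones, compartment = NULL,
                      weight = c("clonotypes", "counts")) {
  .checkClones(clones)
  weight <- match.arg(weight)
  if (!is.null(compartment))
    clones <- clones[clones$compartment == compartment, , drop = FALSE]
  if (any(!nzchar(clones$vGene)) || any(!nzchar(clones$jGene)))
    stop("empty V or J gene name")
  w <- if (weight == "counts") clones$count else rep(1L, nrow(clones))
  tab <- tapply(w, list(clones$vGene, clones$jGene), sum, default = 0L)
  matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
}

#' Correlation between two per-patient richness vectors
#'
#' Pearson (default) or Spearman correlation with the two-sided p-value
#' from [stats::cor.test()] (t-distribution with n - 2 df for Pearson).
#'
#' @param x,y Equal-length numeric vectors (>= 3 complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r` and `p.value`.
#' @export
richnessCorrelation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L || anyNA(x) || anyNA(y))
    stop("x and y must be complete, equal-length vectors of length >= 3")
  ct <- stats::cor.test(x, y, method = method)
  list(r = unname(ct$estimate), p.value = ct$p.value)
}

#' Read / write clonotype tables
#'
#' @param file TSV path with the clonotype column contract
#'   (`patient, compartment, chain, cdr3aa, vGene, jGene, count`).
#' @param columns Optional named character vector remapping nonstandard
#'   input column names, e.g. `c(cdr3aa = "aaSeqCDR3")` for MiXCR exports.
#' @return `readClonotypes()`: the validated `data.frame`.
#' @export
readClonotypes <- function(file, columns = NULL) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!is.null(columns))
    for (std in names(columns))
      names(tab)[names(tab) == columns[[std]]] <- std
  .checkClones(tab)
  tab
}

#' @rdname readClonotypes
#' @param clones Clonotype table to write.
#' @export
writeClonotypes <- function(clones, file) {
  utils::write.table(clones, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
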
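## Somatic-variant filtering and tumor mutational burden.
##
## Variants travel as a data.frame with columns
##   chrom, pos (1-based), ref, alt, gene, class, populationAf, rnaVaf
## plus optional patient / id columns.  `populationAf = NA` means "absent
## from population databases" and is treated as novel (retained by the
## frequency filter).  BED intervals are 0-based half-open on disk and
## become 1-based closed GRanges at parse time (rtracklayer convention).

.consequenceClasses <- c("missense", "nonsense", "frameshift", "inframe_indel",
                         "splice_site", "start_lost", "stop_lost",
                         "synonymous", "noncoding", "other")

.functionalClasses <- c("missense", "nonsense", "frameshift", "inframe_indel",
                        "splice_site", "start_lost", "stop_lost")

#' Filter variants on population allele frequency
#'
#' Retains variants whose population allele frequency is strictly below
#' `threshold`; variants with unknown frequency (`NA`) are retained, since a
#' truly novel somatic variant has no population record.  Order is preserved
#' and the filter is idempotent.
#'
#' @param variants Variant `data.frame` with a `populationAf` column.
#' @param threshold Frequency cutoff in (0, 1\]; default 0.001.
#' @return The retained rows of `variants`.
#' @export
filterPopulationFrequency <- function(variants, threshold = 0.001) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- is.na(variants$populationAf) | variants$populationAf < threshold
  variants[keep, , drop = FALSE]
}

#' Restrict variants to a targeted region
#'
#' Keeps variants whose (1-based) position falls inside the targeted exon
#' region.  A position `p` on the half-open 0-based disk interval
#' `[start, end)` is kept iff `start < p <= end`.
#'
#' @param variants Variant `data.frame` with `chrom` and `pos` columns.
#' @param region A [GenomicRanges::GRanges] of target intervals (as returned
#'   by [readTargetBed()]), or anything coercible via `GRanges()`.
#' @return The retained rows of `variants`.
#' @export
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits
#' @importFrom GenomeInfoDb seqlevels "seqlevels<-"
restrictToTarget <- function(variants, region) {
  if (!nrow(variants)) return(variants)
  q <- GenomicRanges::GRanges(variants$chrom,
                              IRanges::IRanges(variants$pos, variants$pos))
  ## variants legitimately live on contigs outside the target design
  lev <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(region))
  GenomeInfoDb::seqlevels(q) <- lev
  GenomeInfoDb::seqlevels(region) <- lev
  hits <- GenomicRanges::findOverlaps(q, region, ignore.strand = TRUE)
  variants[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Is a variant protein-altering ("functional")?
#'
#' A variant is functional when its consequence class can change the coding
#' protein; synonymous, noncoding and unclassified variants are not.  The
#' classifying set is configurable and the function is total over the
#' consequence-class vocabulary.
#'
#' @param class Character vector of consequence classes.
#' @param functionalClasses Classes counted as protein-altering.
#' @return Logical vector.
#' @examples
#' isFunctional(c("missense", "synonymous"))
#' @export
isFunctional <- function(class, functionalClasses = .functionalClasses) {
  class %in% functionalClasses
}

#' Total and functional tumor mutational burden
#'
#' `Total TMB = number of variants / size of targeted exon region` and
#' `Functional TMB = number of functional somatic variants / size of targeted
#' exon region`, both in mutations per megabase.  The variants are assumed to
#' have already passed the population-frequency and target-region filters;
#' the region size is the summed width of the merged target intervals.
#'
#' @param variants Variant `data.frame` with a `class` column.
#' @param region Target [GenomicRanges::GRanges]; overlapping intervals are
#'   merged before the size is taken.
#' @param functionalClasses Passed to [isFunctional()].
#' @return One-row `data.frame`: `n_total, n_functional, target_mb,
#'   total_tmb, functional_tmb`.
#' @examples
#' region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50e6))
#' v <- data.frame(class = c(rep("missense", 60), rep("synonymous", 40)))
#' computeTmb(v, region) # 2.0 total, 1.2 functional Muts/Mb
#' @export
#' @importFrom GenomicRanges reduce width
computeTmb <- function(variants, region,
                       functionalClasses = .functionalClasses) {
  sizeBp <- sum(GenomicRanges::width(GenomicRanges::reduce(region,
                                                           ignore.strand = TRUE)))
  if (sizeBp <= 0) stop("target region has zero size")
  nTotal <- nrow(variants)
  nFunc <- sum(isFunctional(variants$class, functionalClasses))
  data.frame(n_total = nTotal, n_functional = nFunc,
             target_mb = sizeBp / 1e6,
             total_tmb = nTotal / (sizeBp / 1e6),
             functional_tmb = nFunc / (sizeBp / 1e6))
}

#' Per-patient TMB over a cohort
#'
#' Applies the population-frequency filter, the target-region restriction
#' and [computeTmb()] to each patient's variants.
#'
#' @param variants Cohort variant `data.frame` with a `patient` column.
#' @param region Target [GenomicRanges::GRanges].
#' @param afThreshold Population-frequency cutoff (default 0.001).
#' @return `data.frame` with one row per patient: `patient, n_total,
#'   n_functional, target_mb, total_tmb, functional_tmb`.
#' @export
computeCohortTmb <- function(variants, region, afThreshold = 0.001) {
  patients <- unique(variants$patient)
  rows <- lapply(patients, function(p) {
    v <- variants[variants$patient == p, , drop = FALSE]
    v <- filterPopulationFrequency(v, afThreshold)
    v <- restrictToTarget(v, region)
    cbind(patient = p, computeTmb(v, region))
  })
  do.call(rbind, rows)
}

#' Read a targeted-region BED file
#'
#' BED3, 0-based half-open on disk; intervals are merged (reduced) so the
#' region size is well defined even when input intervals overlap.
#'
#' @param file BED path.
#' @return A merged [GenomicRanges::GRanges].
#' @export
#' @importFrom rtracklayer import
readTargetBed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  GenomicRanges::reduce(gr, ignore.strand = TRUE)
}

#' Read somatic variants from a VCF file
#'
#' Minimal VCF 4.2 dialect with configurable INFO keys for population
#' frequency, consequence class and RNA VAF.  Multi-allelic records are
#' split into one variant per ALT allele before any filtering.
#'
#' @param file VCF path (uncompressed or bgzipped).
#' @param patient Patient id attached to every row (default: file base name).
#' @param afKey,classKey,vafKey,geneKey INFO keys holding population AF,
#'   consequence class, RNA VAF and gene symbol.
#' @return Variant `data.frame` (see [filterPopulationFrequency()] for the
#'   column contract).
#' @export
#' @importFrom VariantAnnotation readVcf info ref alt
readSomaticVcf <- function(file, patient = NULL, afKey = "AF_POP",
                           classKey = "CSQCLASS", vafKey = "RNAVAF",
                           geneKey = "GENE") {
  if (is.null(patient))
    patient <- sub("\\.vcf(\\.gz)?$", "", basename(file))
  vcf <- VariantAnnotation::readVcf(file)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  inf <- VariantAnnotation::info(vcf)
  getKey <- function(key, default) {
    if (key %in% names(inf)) {
      v <- inf[[key]]
      if (is(v, "List")) v <- vapply(v, function(z)
        if (length(z)) z[[1L]] else default, default)
      v
    } else rep(default, length(rr))
  }
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  ids <- names(rr) # expand() drops rownames; fall back to coordinates
  if (is.null(ids) || length(ids) != length(rr))
    ids <- sprintf("%s:%d%s>%s", chrom, pos, ref, alt)
  data.frame(
    patient = patient,
    id = ids,
    chrom = chrom,
    pos = pos,
    ref = ref,
    alt = alt,
    gene = as.character(getKey(geneKey, NA_character_)),
    class = as.character(getKey(classKey, "other")),
    populationAf = suppressWarnings(as.numeric(getKey(afKey, NA_real_))),
    rnaVaf = suppressWarnings(as.numeric(getKey(vafKey, NA_real_))),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write somatic variants as a minimal VCF 4.2 file
#'
#' Serializes one patient's variants into the fixed dialect this package
#' reads back with [readSomaticVcf()]: INFO keys `GENE`, `CSQCLASS`,
#' `AF_POP` (omitted when unknown) and `RNAVAF`.
#'
#' @param variants Variant `data.frame` for one patient.
#' @param file Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header (recommended so readers can validate coordinates).
#' @return `file`, invisibly.
#' @export
writeSomaticVcf <- function(variants, file, contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=AF_POP,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=RNAVAF,Number=1,Type=Float,Description=\"RNA variant allele frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- paste0(
    ifelse(is.na(variants$gene), "", sprintf("GENE=%s;", variants$gene)),
    "CSQCLASS=", variants$class,
    ifelse(is.na(variants$populationAf), "",
           sprintf(";AF_POP=%.6g", variants$populationAf)),
    ifelse(is.na(variants$rnaVaf), "",
           sprintf(";RNAVAF=%.6g", variants$rnaVaf))
  )
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                  variants$chrom, variants$pos,
                  if (!is.null(variants$id)) variants$id else ".",
                  variants$ref, variants$alt, info)
  writeLines(c(hdr, body), file)
  invisible(file)
}
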
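Package: neocohort
Title: Neoantigen Vaccine Cohort Profiling from Somatic Variants, HLA
    Genotypes, and Immune Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling a tumor cohort for personalised and
    shared neoantigen vaccine design. Implements somatic-variant
    filtering (population frequency, targeted region) and total and
    functional tumor mutational burden (TMB); enumeration of 8-11-mer
    mutant peptides around missense, in-frame indel and frameshift
    neo-ORF sites; HLA class-I allele-expression-weighted binding
    scores behind a pluggable scorer interface (deterministic
    surrogate or NetMHCpan result-table adapter); merging of
    intersecting peptides into scored 25-AA neoantigens; greedy
    minimum peptide-bulk selection over a patient-by-peptide coverage
    matrix with an exact branch-and-bound oracle and entropy and
    mutual-information diagnostics; HLA genotype and expression
    summaries; and TCR and BCR repertoire statistics (richness, CDR3
    length distributions, terminal motifs, sharing spectra,
    tumor-specific clonotypes, VJ pairing, compartment correlations).
    A fully deterministic synthetic-cohort generator provides
    transcripts, variants, genotypes, repertoires and planted
    set-cover instances so the whole pipeline is testable without
    access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
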
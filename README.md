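# neocohort

Cohort profiling for neoantigen vaccine design: from annotated somatic
variants, HLA class-I genotypes and immune-repertoire clonotype tables to
per-patient tumor mutational burden, ranked 25-AA neoantigen candidates, a
minimal shared peptide bulk, and TCR/BCR repertoire statistics.

The package is aimed at translational immuno-oncology groups who have run
the standard upstream tools (variant calling and annotation, OptiType-style
HLA typing, MiXCR-style clonotype extraction, NetMHCpan-style binding
prediction) and need the cohort-level analysis layer on top — reproducibly,
and testable without access to restricted patient data, via a fully
deterministic synthetic-cohort generator.

## What it computes

- **TMB** — variants are filtered to population allele frequency < 10⁻³
  (unknown frequency = novel, retained) and to the targeted exon region
  (BED, 0-based half-open, converted once at parse); then
  `Total TMB = n_variants / target_Mb` and
  `Functional TMB = n_protein_altering / target_Mb`.
- **Neoantigen design** — each protein-altering variant is applied to its
  transcript (missense substitution, in-frame indel, or frameshift neo-ORF
  translated in the shifted frame to the first stop or the cDNA end); every
  8–11-mer window containing a mutant residue is scored against the
  patient's six HLA class-I alleles through a pluggable scorer (NetMHCpan
  %rank table adapter mapping rank *r* to `max(0, 1 − r/2)`, or a
  deterministic surrogate), combined as the allele-expression-weighted sum;
  intersecting windows merge into one ≤25-AA neoantigen with
  `score = Σ(peptide scores) × RNA_VAF`.
- **Shared peptide bulk** — a patient × peptide incidence matrix feeds
  classic greedy set cover (with the H(d) guarantee), validated by an exact
  branch-and-bound solver on small instances; carrier entropy and pairwise
  mutual information are reported as redundancy diagnostics.
- **HLA summaries** — per-locus cohort allele frequencies (slot counts over
  2n) and per-allele expression proportions normalized to weights that feed
  the scoring.
- **Repertoire statistics** — clonotype richness, CDR3 length
  distributions, N/C-terminal 4-AA motifs, cross-patient sharing spectra,
  strictly tumor-only clonotypes shared by more than k patients, V×J
  rearrangement matrices, and Pearson richness correlations (`cor.test`).

See `vignettes/neocohort-methods.Rmd` for the full model description,
parameter table and design decisions.

## Worked example

```r
library(neocohort)

spec   <- defaultCohortSpec(seed = 1)   # 24 patients, mean 200 sites, 1 outlier
cohort <- simulateCohort(spec)          # transcripts, VCF-shaped variants, HLA,
                                        # repertoires, surrogate binding scorer
report <- runPipeline(cohort)
report
#> CohortReport over 24 patients
#>   TMB: median 3.37 Muts/Mb (max 33.22)
#>   neoantigens/patient: mean 109.9 (range 63-718)
#>   peptide bulk: 17 peptide(s) covering 24/24 patients
```

Reading the output: every non-outlier patient sits below 5 Muts/Mb with one
extreme-burden patient (33 Muts/Mb); the mean candidate-neoantigen count per
patient is ~110 with one patient above 700; and because candidates are
almost entirely patient-private, the greedy selection needs 17 peptides to
give each of the 24 simulated patients at least one covered neoantigen.
Per-patient ranked candidate tables are in `report$neoantigens`, the
selection in `report$bulk`, repertoire statistics (including the universal
PBMC TCR clone planted in the simulation, `CASSLEETQYF`, found in 24/24
patients) in `report$repertoire`.

With real data, build the same bundle from files instead:
`readSomaticVcf()` + `readTargetBed()` for TMB, `readTranscripts()`,
`readHlaGenotypes()` (plus an expression TSV) and `RankTableScorer()` on a
NetMHCpan result table for `designCohort()`, and `readClonotypes()` for the
repertoire functions. A thin command-line front end is installed at
`inst/scripts/neocohort.R` (`simulate`, `tmb`, `repertoire`, `run`).

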
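---
title: "Methods: cohort profiling for neoantigen vaccine design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort profiling for neoantigen vaccine design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neocohort)
```

# Scope and model

`neocohort` profiles a tumor cohort for personalised and shared neoantigen
vaccine design. It consumes annotated somatic variants (VCF), targeted-region
intervals (BED), transcript models (cDNA FASTA + CDS coordinates), HLA
class-I genotypes with optional per-allele expression, and MiXCR-style
clonotype tables; it produces per-patient tumor mutational burden (TMB),
ranked 25-AA neoantigen candidates, a minimal shared peptide bulk, and
repertoire statistics. Upstream steps — variant calling, RNA quantification,
HLA typing, clonotype assembly, and MHC binding prediction itself — are out
of scope: their outputs are inputs here.

## Tumor mutational burden

Variants are filtered in two steps before counting. First a population
allele-frequency filter retains variants with frequency strictly below a
threshold (default $10^{-3}$); variants with *unknown* frequency are
retained, because a genuinely novel somatic variant has no population
record. Second, variants outside the targeted exon region are removed.
Then

$$\mathrm{TMB}_{\mathrm{total}} = \frac{\#\,\mathrm{variants}}{\mathrm{target\ size\ (Mb)}},
\qquad
\mathrm{TMB}_{\mathrm{functional}} = \frac{\#\,\mathrm{protein\text{-}altering\ variants}}{\mathrm{target\ size\ (Mb)}}$$

where protein-altering covers missense, nonsense, frameshift, in-frame
indel, splice-site, start-lost and stop-lost classes (configurable), and
the target size is the summed width of the *merged* BED intervals.

**Coordinate conventions.** BED intervals are 0-based half-open on disk and
are converted once at parse time (via `rtracklayer`) to 1-based closed
ranges, so the interval `chr1 100 200` covers 1-based positions 101–200. A
1-based VCF position $p$ is on target iff $\mathrm{start} < p \le
\mathrm{end}$ in the 0-based bounds. Multi-allelic VCF records are split
into one variant per ALT allele before any filtering, since burden counts
mutated sites per allele.

## Neoantigen design

For each protein-altering variant on a transcript:

1. **Mutant protein.** A missense change substitutes one residue; an
   in-frame indel alters a short region (located by longest common
   prefix/suffix against the reference protein); a frameshift indel opens a
   neo-ORF translated in the shifted frame from the first altered codon
   until the first stop codon, or to the last complete codon of the cDNA
   when no stop occurs before its end. Stop gains and synonymous changes
   create no novel residue and yield no candidate (they still count as
   functional for TMB, where applicable).
2. **Peptide enumeration.** Every 8–11-mer window that lies inside the
   protein and contains at least one mutant residue. For a single mutant
   position $p$ in a protein of length $L$, the number of $k$-windows is
   $\min(k,\,p,\,L-p+1,\,L-k+1)$ when positive — 38 windows for an interior
   site. Peptides containing unknown residues are dropped.
3. **Scoring.** A pluggable scorer returns a nonnegative binding score per
   (peptide, allele); higher = stronger, 0 = non-binder. The bundled
   adapter maps an externally computed percentile rank $r$ (NetMHCpan-style
   tables) to $\max(0,\,1 - r/R)$ with $R = 2.0$, the conventional
   weak-binder cutoff, so the score lives on $[0, 1]$. The combined peptide
   score is the expression-weighted sum over the patient's six allele
   slots, $\sum_a w_a\, s_a$, with weights from allele-specific expression
   (uniform $1/6$ when unavailable). Peptides whose combined score does not
   exceed the binder threshold (default 0) are discarded.
4. **Merging.** Surviving windows are clustered by transitive interval
   overlap on protein coordinates; each cluster yields one neoantigen whose
   sequence is the ≤25-AA window centered on the cluster's leftmost mutant
   residue (12 flanks each side, truncated at termini, flagged when the
   cluster spans more than 25 residues — long frameshift tails), and whose
   score is

   $$\mathrm{score} = \Big(\sum_{\mathrm{peptides}} \mathrm{combined}\Big) \times \mathrm{VAF}_{\mathrm{RNA}}$$

   A missing RNA VAF is treated as 1 with a warning. Candidates are ranked
   by score, ties broken lexicographically by sequence, which makes the
   output fully deterministic.

Design choices worth naming: expression weighting uses the weighted *sum*
across alleles (a max- or unweighted-sum aggregation would also be
defensible; the weighted sum preserves the contribution of every expressed
allele and reduces to the plain sum under uniform expression). Multiple
variants on one transcript are applied independently — compound haplotypes
are not modelled. An optional expressed-transcript filter is deliberately
absent: expression enters through the per-allele weights and the RNA VAF.

## Shared peptide bulk (set cover)

The patient × peptide incidence matrix holds, per patient, the candidate
25-AA sequences designed *for that patient* — HLA compatibility is thereby
encoded implicitly, and no extra HLA check happens at cover time. Sharing
identity is exact 25-AA sequence equality. The minimal bulk is approximated
by classic greedy set cover (pick the peptide covering the most uncovered
patients; ties by higher total prevalence, then lexicographically), which
carries the $H(d)$ guarantee with $d$ the largest column sum. An exact
branch-and-bound solver (branching on the hardest uncovered patient,
pruned by the greedy upper bound) validates the greedy result on instances
up to ~20 peptides or ~16 patients and refuses larger ones explicitly.
Per-peptide carrier entropy and pairwise mutual information are reported
as redundancy diagnostics; selection itself is pure greedy. Patients with
zero candidates are reported as uncoverable rather than failing the run.

## Repertoire statistics

Richness is the raw distinct-clonotype count (`CDR3 + V + J`) per sample —
no rarefaction, matching the clone/type definition. Sharing identity is
the CDR3 amino-acid sequence alone (a strict mode adds V/J); a CDR3 counts
once per patient regardless of clone size. Tumor-specific clonotypes are
sequences in the tumor of strictly more than $k$ patients (default 2) and
in nobody's PBMC. Terminal motifs are per-position frequency profiles of
the first/last four residues; CDR3s shorter than four residues are
excluded and counted. Correlations between per-patient richness vectors
use Pearson's $r$ with the two-sided $t$-test $p$-value
($t = r\sqrt{(n-2)/(1-r^2)}$, via `cor.test`); Spearman is available by
flag.

# The synthetic cohort generator

Restricted-access patient data cannot ship with an analysis package, so
every stage is exercised against a generator that emulates the cohort's
statistical shape. The defaults describe a 24-patient glioblastoma vaccine
cohort:

| parameter | default | what it emulates |
|---|---|---|
| `nPatients` | 24 | cohort size |
| `meanSites` | 200 | Poisson mean of on-target somatic sites per patient |
| `outlierFactor` | 10 (patient 24) | one extreme-burden patient |
| hotspot | codon 132 of transcript 1, carried by 5/24 | a recurrent missense hotspot |
| `classProbs` | missense .55, synonymous .20, frameshift .07, nonsense .05, splice .04, noncoding .07, in-frame .02 | exome consequence mixture |
| HLA tables | headed by A\*30:01/A\*11:01, B\*13:02, C\*06:02 | East-Asian allele frequencies |
| `targetSizeBp` | 60 Mb | extended-exome capture design |
| `binderFraction` | 0.0045 | surrogate binder rate, set so the mean candidate count per patient lands near 107 |
| RNA VAF | Uniform(0.05, 1] | no stated distribution exists; any positive VAF is plausible post-filter |
| repertoire | TRB 1200/2500 and IGH 600/1200 clonotypes (tumor/PBMC), CDR3 lengths peaking at 15 AA, 92% "CA" starts, a universal PBMC TRB clone, four tumor-only TRB clones in 4–6 patients | repertoire richness, motifs, sharing |

The 60-Mb target size is the one free parameter the burden shape pins
down: with a mean of 200 sites per patient it places every non-outlier
patient below 5 Muts/Mb with realistic headroom, and the outlier an order
of magnitude above. Decoy variants — common-population-frequency records
and off-target records — are generated *on top of* the Poisson site
counts, so the two filters remove real records and the post-filter counts
recover the Poisson intensity exactly. Hotspot variants replace one of a
carrier's Poisson draws rather than being appended, keeping per-patient
counts exactly Poisson.

Per-sample clonotype counts are Poisson around the spec mean scaled by the
product of a per-patient and a per-sample log-normal factor of equal
log-variance ($\sigma = 0.15$ each); the shared factor couples a patient's
samples only moderately, reproducing richness correlations around 0.5
rather than near-perfect coupling.

**The surrogate binding scorer** is a pure function of (peptide, allele,
seed): a polynomial string hash mod $2^{32}$ with a multiplicative
avalanche, computed in exact double arithmetic so results are identical
across platforms and independent of R's RNG state. A fraction
`binderFraction` of pairs is classified as binders (score uniform on the
score range), all others score 0. It preserves the scorer interface shape
and the score scale of the rank-table adapter; it is *not* a binding
predictor, and nothing about real peptide-MHC affinity should be read into
it.

**Determinism.** One global seed drives everything; each component derives
a child seed by a fixed hash, so components are independent yet the whole
cohort — and the whole pipeline report — is byte-identical across reruns
with the same seed.

**What passing tests do and do not show.** The generator reproduces
marginal shapes (count distributions, sharing spectra, motif frequencies,
planted ground truth); it does not model linkage between mutations,
real HLA linkage disequilibrium, codon usage, sequencing error, clonal
phylogenies, or true binding physics. Tests against it validate the
*computations*, not biological claims about real cohorts.

# Numerical and degenerate-input choices

- Population-frequency comparison is strict `<`; unknown AF is retained.
- Zero-expression alleles keep weight 0 (the six-slot structure is
  preserved); all-zero expression is an error, as is a scorer miss on any
  (peptide, allele) pair — never a silent zero.
- Proteins shorter than 8 residues enumerate no peptides; a patient with
  zero candidates yields an empty (valid) design and is marked
  uncoverable in the bulk stage.
- The exact cover solver refuses instances beyond its size guard instead
  of silently approximating.
- Entropy and mutual information use $0 \log 0 = 0$; MI is clamped at 0
  against floating-point droop.
- Reference-mismatch between a variant's REF field and the transcript is
  an error naming the position; variants outside the CDS are skipped with
  a message.

# Problem sizes used by the test-suite

Unit and property tests run on purpose-built miniatures (transcripts of
40–100 codons, cohorts of 4–12 patients, repertoires of tens to a few
thousand clonotypes) with oracle cross-checks: brute-force window
enumeration, naive codon-by-codon translation, exhaustive/branch-and-bound
set cover, hand-tallied frequencies, and closed-form correlation tests.
The end-to-end checks simulate the full default 24-patient cohort (300
transcripts, mean 200 sites/patient) and run the complete pipeline twice
to verify byte-identical reports. Poisson-recovery checks use 12
replicate 12-patient cohorts at mean 60 — enough for 3-standard-error
bounds while keeping the default test run fast.

# Known limitations

- Binding prediction quality is entirely inherited from the external
  table; the surrogate only exercises plumbing.
- The 25-AA window centering on the leftmost mutant residue truncates
  information for very long frameshift neo-ORFs (flagged per candidate).
- Compound haplotypes, phased multi-variant peptides and splicing-derived
  neoantigens are not modelled.
- Richness is depth-sensitive; no rarefaction is applied, so cross-sample
  comparisons assume comparable sequencing depth.
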
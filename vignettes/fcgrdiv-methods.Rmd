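---
title: "Methods: genotyping and isoform profiling of FcγR amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotyping and isoform profiling of FcγR amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgrdiv)
```

## The problem

Fcγ receptors (FcγRs) couple IgG immune complexes to effector-cell
signaling, and coding polymorphisms in their IgG-contact regions are known
to modulate antibody-dependent functions. In rhesus macaques — the central
preclinical model for vaccines and antibody therapeutics — FcγR diversity
is surveyed by RT-PCR amplifying each receptor gene (FcγRI, FcγRIIa,
FcγRIIb, FcγRIII) from PBMC RNA and sequencing the full-length amplicons
with high-accuracy long reads, one barcoded library per animal. `fcgrdiv`
implements the downstream analysis as a reusable, tested pipeline:
per-animal diploid genotyping of SNPs and small indels, coding-effect
annotation in two numbering systems, cohort carrier statistics with a
retention filter, isoform relative-abundance estimation, and
domain/Fc-interface classification — together with a synthetic cohort
generator that produces CCS-like reads from known truth, since simulation
is the only way to validate the whole chain end to end.

## Gene models and coordinates

Each gene is described by a `gene_model`: exon intervals of the principal
transcript in both transcript and genomic coordinates, the ORF offset, the
signal-peptide length, a mature-protein domain map, the Fc-contact residue
set (with its source complex), and the splice structures of annotated
isoforms.

Three coordinate systems coexist and all appear in the reports:

* **Genomic** — 1-based, plus-strand (VCF convention). Three of the four
  genes are minus-strand, so transcript alleles are reverse complements of
  genomic ones.
* **ORF numbering** — nucleotide/residue 1 at the start codon (the
  convention of genome annotation tools). Within each exon the mapping is
  affine: `gpos + tpos` is constant for minus-strand genes, `gpos − tpos`
  for plus-strand ones.
* **Mature numbering** — residue 1 is the first residue after
  signal-peptide cleavage; signal residues are negative, with no residue
  zero (so ORF residue `L` maps to −1, not 0). Nucleotides shift by `3L`.

Insertions are anchored VCF-style at the base preceding the inserted
sequence on the genomic plus strand, and are left-normalized independently
on the transcript strand (for ORF-numbered notation) and the plus strand
(for the genomic key). This dual normalization is why a minus-strand
duplication's genomic anchor sits one base "off" from the per-exon SNP
constant — both placements describe the same molecule.

The packaged models are synthetic in their invented parts (exon boundary
padding, filler codons) but exact in everything the published tables
determine: per-exon affine constants (over-determined by multiple rows per
exon), signal-peptide offsets (17/35/45/54 residues), reference and
alternate alleles and codons of all 37 reported variants, exon labels,
domain labels, and the cassette/extension arithmetic. The 5′ UTR of FcγRIII
(ORF begins at transcript position 54) exercises the ORF-offset machinery.
One structural tension is resolved deliberately: the reported FcγRIIb table
places ORF nt 846 in exon 7 while the 19-residue cytoplasmic insertion
begins at codon 302 (ORF 904); these are incompatible with a cassette
between exons 5 and 7, so the packaged model labels its principal exons
1–5, 7, 8 and stores the 57-nt cassette under the label "6" between exons
7 and 8. Labels are treated as annotation-inherited names, not ordinals;
only the affine constants are observable.

## The caller

Reads are aligned end-to-end against the principal transcript with a
three-state (Gotoh) affine-gap dynamic program: match +2, mismatch −4, gap
open −4, gap extend −2 (a gap of length *L* costs 4 + 2*L*). Global rather
than local alignment is appropriate because the amplicons span the whole
transcript, so terminal bases are informative. The implementation runs over
a diagonal band (half-width 48 by default, widened automatically by the
length difference); for consensus-grade reads, whose optimal path never
drifts more than a few bases off the diagonal, the banded result is
identical to the exhaustive DP — an equivalence the test suite checks
directly, alongside agreement of the exhaustive mode with an independent
plain-R oracle on random sequence pairs. Reads scoring below 1 point per
base are marked invalid and excluded from pileups, the single-reference
analogue of a mapping-quality filter.

Pileups count, per transcript position, the observed bases plus insertion
alleles (`+SEQ`, attributed to the position they follow) and deletion
alleles (`-SEQ`, at the first deleted position). Genotypes are called by
thresholds chosen for consensus-read accuracy: minimum depth 10, minimum 3
supporting reads, heterozygous for allele fractions in [0.25, 0.75],
homozygous at ≥ 0.8, at most the two most frequent alternate alleles per
position. Positions below the depth floor are reported as uncallable
rather than silently dropped. With a per-base error rate of 0.002 the
expected support for a spurious allele at depth 50 is ≈ 0.03 reads, so the
3-read floor suppresses essentially all false calls while a heterozygous
variant expects ≈ 25. Indel calls are left-normalized before reporting;
an insertion that duplicates the preceding reference base(s) is rendered
with `dup` notation.

## Effect annotation

SNP effects are decided codon-by-codon with the standard genetic code.
Indel protein effects are **not** derived from positional arithmetic:
the full mutant ORF is translated and diffed against the reference
protein, so frameshift names (`p.V23fs`: reference residue at the first
changed position) and in-frame insertion names
(`p.R299delinsDR`: new residues preceding the anchored residue) fall out
of the actual translation. All four notations — ORF-numbered
nucleotide/protein and mature-numbered nucleotide/protein — are rendered in
the tables' dialect: single-letter residues, `fs` without an extension
length, `delins` for insertions anchored at an existing residue. This
dialect is intentionally not strict HGVS, because the reporting surface is
the published tables. One reported row is internally inconsistent
(nucleotide 184 is codon 62, but the printed ORF protein index is 61); the
annotator follows the nucleotide coordinate and reports codon 62 / mature
residue 8, and the tests pin this divergence explicitly rather than
special-casing it.

## Cohort statistics

A carrier is an animal with at least one alternate allele, irrespective of
zygosity; carrier counts count animals, never alleles. Variants are
retained when detected in at least 2% of the cohort — in a 206-animal
cohort the smallest retained carrier count is 5 (4/206 = 1.94%). Percent
display rounds half-to-even to one decimal and drops a trailing `.0`
(140/206 prints as `68`). A couple of published percentages were truncated
rather than rounded; the package treats counts as ground truth and the
formatted string as presentation.

## Isoform quantification

Reads are scored against every configured isoform transcript; a read's
compatibility weight on isoform *j* is `exp(score_ij − best_i)`, which for
full-length consensus reads acts as a soft indicator — structurally
decisive reads weight one isoform, reads equally consistent with several
isoforms weight them equally and are retained with fractional weights
rather than discarded. Per-animal relative abundances maximize the mixture
log-likelihood `Σ_i log Σ_j θ_j w_ij` by EM; the likelihood is
non-decreasing per iteration (a property the tests assert on random
matrices, together with dominance over an exhaustive 0.01-step grid
search). No read-length bias correction is applied: all amplicons of one
gene are near-identical in length, which is the regime where such
corrections are negligible.

Isoforms are reported when their abundance exceeds 1% in at least one
animal; the filter is a display mask and does not renormalize θ. The rule
by which an animal counts as an isoform *carrier* is not externally
defined; the package defaults to the same 1% threshold and exposes it as a
parameter.

## Interface classification

Nonsynonymous variants are mapped onto the mature-protein domain map and
classified against the configured Fc-contact residue sets (read from
receptor–Fc co-crystal complexes; the FcγRIII set is a single configured
residue, 158, extendable in the config). Adjacency is sequence-position
distance with a window of 2 — the smallest window under which the
narrated "adjacent to the interface" cases (FcγRIIb I125K at distance 1,
N133D at distance 2) come out adjacent. No 3-D structure is computed; this
is a deliberate sequence-level embodiment, and one residue (FcγRIIa N128K,
distance 1 from contacts 127/129) is classified adjacent by the rule even
though the narrative calls it outside the interface — the rule is applied
uniformly and the divergence documented. A sequon scan (N-X-S/T, X ≠ P)
reports glycosylation sites destroyed by a variant, which reproduces the
N128K glycan-site loss.

## The synthetic cohort generator

The generator is the package's stand-in for the study inputs: per animal it
draws diploid genotypes (Hardy–Weinberg from allele frequencies, or an
exact-carrier-count mode in which the configured number of animals is
heterozygous — the mode used to reproduce published tables, which report
only carrier counts), draws or fixes an isoform mixture (Dirichlet or fixed
weights), builds haplotype × isoform source sequences, and emits
full-length reads with independent per-base substitutions (default 0.002)
and rare 1-bp indels (default 1e-4). Defaults for depth (50) and error
rates are simulator choices in the range of barcoded HiFi amplicon data,
not published values. What the model omits — homopolymer-biased errors,
chimeric reads, barcode hopping, PCR allele imbalance beyond binomial
sampling, linkage between variants (each variant is phased independently,
so no allotype structure) — bounds what passing tests demonstrate: the
pipeline's logic is validated exactly, but recovery rates on real
instrument data may differ. Read names carry no truth; truth is returned
as a separate object and sidecar file, and a fixed seed reproduces the
FASTQ byte-for-byte.

## Numerical and degenerate-input choices

EM starts uniform, converges when no proportion moves by more than 1e-8,
and returns the current estimate with a warning after 1000 iterations.
Reads aligning validly to no isoform are dropped and counted. Alignment of
empty sequences is an error; degenerate (junk) reads become invalid
alignments rather than errors. Indel normalization is idempotent.
Tie-breaking in the caller takes the two most frequent alternate alleles
per position. All file writers are atomic (temp file + rename), and VCF
output is one multi-sample file with `GT:AD:DP` per animal.

## Problem sizes used in the tests

The suite validates the full 206-animal, depth-50 FCGR1 cohort end to end
(carrier counts recovered exactly at the study error rate). Properties
that do not need cohort scale run on a 300-nt three-isoform synthetic gene:
error-free recovery on 10–12 animals, isoform recovery on 8–12 animals at
depth 100 (per-animal mean absolute error below 0.03), alignment oracles on
30–80-nt random pairs, and EM oracles on 30–50-read random weight matrices.
These sizes were chosen as the smallest at which each property is
non-trivially exercised. One calibration note: at depth *d*, the
composition of the reads actually drawn deviates from the generating
mixture by binomial noise of order `sqrt(theta (1 − theta) / d)` (≈ 0.04
per isoform at *d* = 100 for moderate θ), which bounds any estimator's
per-animal accuracy against the generating truth; the unit tests therefore
also measure the estimator against the realized read composition, the
quantity it can in principle recover exactly.

## Limitations

Paralog cross-mapping (FcγRIIa vs FcγRIIb extracellular identity) is
handled only by per-gene amplicon references, not read reassignment; novel
isoform discovery is out of scope (the compatibility matrix is restricted
to configured reference isoforms); zygosity is validated against simulation
truth only, since published cohorts report carriers, not genotypes; and the
packaged reference transcripts are synthetic scaffolds constrained by the
published coordinates, suitable for validating the pipeline's arithmetic
but not substitutes for the real rheMac10 sequences.
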
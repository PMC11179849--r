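---
title: "Methods: comparing the phases of a diploid assembly and linking variation to expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing the phases of a diploid assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diploscan)
```

# The problem

A haplotype-resolved ("phased") diploid assembly represents each
chromosome twice, once per haplotype. In a highly heterozygous outcrossing
species the two phases differ at hundreds of thousands of positions, and
those differences are not noise: heterozygous transposable-element (TE)
insertions, presence–absence genes and coding variants segregate within a
single individual and can drive allele-specific expression (ASE).
`diploscan` implements the analytical chain from the two phase sequences to
those biological conclusions:

1. **Variant extraction** — SNPs, short indels (1–39 bp) and structural
   variants (SVs, ≥ 40 bp) from a pairwise phase-0 vs phase-1 alignment.
2. **TE zygosity** — classification of TE annotations as heterozygous
   (present in one phase) or homozygous by reciprocal overlap with the SV
   deletion set, validated by the target-site duplication (TSD) and dated
   from intra-element LTR divergence.
3. **Coding impact** — snpEff-style effect terms and impact levels on gene
   models, including presence–absence (PAV) genes.
4. **ASE** — a per-gene, per-organ beta-binomial test of allelic balance
   with FDR control, profile clustering, and association of ASE with
   nearby heterozygous SVs and TE insertions.

A seeded synthetic-diploid generator produces genome pairs with planted,
truth-tracked variation so that every stage can be tested for exact
recovery.

# Coordinates and variant representation

All tibbles use 0-based half-open coordinates on phase-0; writers emit the
standard dialect of each file format (VCF and GFF3 1-based, BED 0-based).
A variant row stores the material difference directly: an `INS` row holds
sequence present only in phase-1, a `DEL` row sequence present only in
phase-0. Indels and SVs are stored **left-normalised** (shifted to their
leftmost equivalent placement), which makes breakpoint equality a
well-defined test. The 39/40 bp boundary between `INDEL` and `SV` is the
size convention adopted throughout, applied after merging adjacent
insertion/deletion alignment operations so that one biological event split
at an anchor seam is classified once.

# The anchor aligner

`anchor_align()` is a minimal assembly-to-assembly aligner sufficient for
two phases of the same genome (it is not a general aligner). It indexes
k-mers (default k = 15) that occur exactly once in each sequence, chains
the shared ones with a longest-increasing-subsequence pass (ties resolved
toward the leftmost chain, so output is deterministic), collapses
overlapping anchors into exact-match runs, and closes the gaps between
runs: equal-length gaps by direct base comparison, unequal gaps up to
10 kb by global alignment (affine gap penalties, match 2 / mismatch −4 /
gap open 6 / extend 1), and larger gaps as paired deletion + insertion
operations. Every gap of ≥ 500 bp with roughly equal sides is first tested
in reverse-complement orientation; if unique-k-mer anchors support the
reverse orientation, the segment is emitted as a separate minus-strand
block, which `extract_variants()` reports once as an inversion with
reference-span length. A minus-strand block covering a whole sequence is
treated as an orientation artefact, not variation. Externally produced
alignments enter through `read_paf()` (standard PAF with a `cg:Z:` tag).

Duplication refinement: an SV insertion whose sequence matches the
adjacent reference interval at ≥ 90 % identity is reported `DUP_TANDEM`;
one matching a distant locus (found by an exact 21-mer seed from the
insertion's midpoint, then verified at ≥ 90 % identity) is `DUP_INT`.

# TE zygosity, TSD detection and LTR dating

The reciprocal-overlap rule matches each TE annotation against the SV
deletion set: heterozygous requires the overlap to exceed 50 % of the
deletion's length (strictly) and to cover at least 80 % of the TE. The
published wording says "spanned more than 50 %", so the deletion-fraction
comparison is strict even though the equivalent `bedtools -F 0.5` flag is
inclusive; with realistic intervals the distinction almost never binds,
but the wording wins here. A TE with some overlap failing the thresholds
is `partial`; a TE with no deletion overlap whose interval is fully
covered by the alignment is `homozygous`; otherwise `unresolved`.
Alignment coverage keeps deletions shorter than the SV boundary inside the
covered region — a small heterozygous indel inside a TE does not break
"completely covered by the alignment".

`detect_tsd()` reports the largest k ≤ 20 for which the k-mer immediately
5′ of the insertion breakpoint equals the terminal k-mer of the inserted
sequence, exact match only. One subtlety: that rule holds at the
*biological* placement of the insertion, and left-normalisation rotates an
insertion through its own TSD. The detector therefore right-normalises
each call before comparing flanks. Chance matches extend the detected
length beyond the planted one with probability about 1/4 per side, so on
planted 5-nt TSDs the distribution of detected lengths has its mode at 5
with a geometric tail; tests assert the mode and the ≥ 5 nt floor rather
than exact equality.

LTR retrotransposons are dated from their two long terminal repeats, which
are identical at insertion. After global alignment (gapped columns
dropped) the mismatch proportion p is corrected with the Jukes–Cantor
model, d = −(3/4)·ln(1 − 4p/3), and the age is d / (2µ) because both LTRs
accumulate substitutions independently. Jukes–Cantor is the simplest model
consistent with an intra-element comparison; Kimura two-parameter is
available via `model = "K2P"`. The default substitution rate is
µ = 1.3 × 10⁻⁸ substitutions/site/year, a conventional value for woody
plants, and is configurable everywhere it is used. Estimates saturate at
p ≥ 0.75 and error out rather than returning a finite age. At realistic
LTR lengths (300–400 bp) the binomial sampling noise of p dominates the
error budget: a single pair planted at 0.5 My carries only ~4 expected
mismatches, so per-element ages scatter with a coefficient of variation
near 50 % while remaining unbiased; accuracy claims in the tests are
therefore made on means over replicate pairs.

Zygosity-group age comparisons use the two-sided Wilcoxon rank-sum test
(exact for small samples), reported unavailable below n = 3 per group.

# Coding impact

Each variant is paired with every gene whose span ± 1 kb it touches, and
classified by the most severe region touched (CDS > intron > upstream >
downstream), the convention snpEff uses for boundary-spanning variants.
CDS SNPs are translated in frame through the gene's CDS coordinate map
(strand-aware) and compared codon-wise: synonymous (LOW), missense
(MODERATE), stop gained or lost (HIGH). A CDS indel is frameshift (HIGH)
exactly when its net length change is not a multiple of 3, otherwise
inframe (MODERATE). A gene wholly contained in an SV deletion is a PAV
gene, reported `gene_deleted` (HIGH). Non-coding regions map to MODIFIER.
Stop-loss requires the reference stop in the annotated final codon; an
internal reference stop triggers a model warning and classification
proceeds. The regulatory window is fixed at 1 kb on both sides. The
simulator emits one transcript per gene; for real multi-isoform
annotations the most-severe-effect convention applies but is untested
against multi-isoform data.

# Allele-specific expression

Informative SNPs are coding SNPs with no indel breakpoint within 50 bp
(coordinate distance, exclusive boundary: a SNP exactly 50 bp from an
indel edge is kept). Allele counts per gene, organ and replicate are sums
over the gene's informative SNPs of reads carrying the phase-0 or phase-1
base; other bases are discarded.

The ASE test pools replicates per gene × organ and tests the phase-0
proportion against 0.5 with an exact two-sided beta-binomial test
(minimum-likelihood two-sided rule). The intra-class correlation ρ is
estimated per organ by a method-of-moments comparison of replicate-level
variance around each gene's own pooled proportion with its binomial
expectation, pooled across genes and floored at 0 — with ρ = 0 the test
reduces to the exact binomial. Estimating ρ around each gene's own mean
keeps genuinely imbalanced genes from inflating it. P-values are
Benjamini–Hochberg adjusted across genes within each organ ("FDR 5 %"),
and a gene is called ASE when flagged in at least one organ. Reported ASE
percentages are truncated (not rounded) to one decimal, matching the
convention that makes 579 / 6182 print as 9.3 %.

This beta-binomial test replaces a negative-binomial count-model contrast
used in comparable studies; it is self-contained, handles replicate
overdispersion explicitly, and its null calibration and power are
verified by simulation in the test suite (≤ 1 % of 1000 null genes flagged
at q ≤ 0.05; sensitivity ≥ 0.9 for a 0.8 allelic ratio at depth 200 × 3
replicates).

Profile clustering takes genes that are ASE in ≥ 1 organ and have ≥ 10
total reads in *every* replicate (the published filter is ambiguous
between per-SNP and per-gene and between > 10 and ≥ 10; this package
applies ≥ 10 to the per-replicate gene total and exposes the threshold as
`min_reads`). The gene × organ matrix of mean phase-0 proportions is
clustered with Ward linkage on Euclidean distances and cut at k = 4 by
default. SV association uses a two-sided Fisher exact test on the 2 × 2
table of (ASE / non-ASE) × (heterozygous SV within 1 kb of the gene span /
absent). TE–expression comparisons are rank-based (Wilcoxon) on
log2(1 + CPM) expression, so any monotone expression transform gives the
same answer.

# The synthetic diploid

`generate_reference()` builds uniform-composition chromosomes, paints one
three-exon protein-coding gene (a real open reading frame, so codon
arithmetic behaves) per 50 kb, and places one resident homozygous TE copy
per 20 kb of intergenic space from a small synthetic consensus library
(Gypsy- and Copia-like LTR elements, a CACTA-like TIR element and a MITE;
random sequences, no real genome content). Resident LTR copies are aged
forward in time: each LTR accumulates Jukes–Cantor substitutions
independently at µ per site per year for a uniform age from 2–12 My, so
dating has a truth to recover.

`plant_variants()` derives the two phases. Phase-0 is the reference plus
newly inserted TE copies — heterozygous phase-0-specific insertions
(young, 0–5 My) and planted homozygous ones — each flanked by its TSD
(5 nt for LTR elements; TIR TSD lengths are not fixed by the source
material, so the map defaults to none and is configurable). Phase-1 is
then edited: SNPs at 1/350 bp, short indels at 1/921 bp (geometric
lengths, capped at 39), generic SVs at 1/15 432 bp (log-uniform 40 bp–8 kb,
half insertions), fresh phase-1-specific TE insertions, and the precise
deletion of every phase-0-specific element (element plus one TSD copy —
the biological empty allele). About a third of SVs are realised as
heterozygous TE insertions, reflecting the TE-related fraction of
heterozygous structural variation in highly heterozygous perennials.
Event counts are Poisson draws at those rates; events are placed by
rejection sampling with a 50 bp separation buffer so truth coordinates
stay unambiguous, and the truth table is left-normalised with the same
function the extractor uses. All randomness flows from one run seed;
identical parameters give byte-identical fixture files.

Realisation detail: because every non-TE event edits phase-1 only, gene
and TE annotations remain in phase-0 coordinates without interval
truncation, and the conservation invariant — applying the truth edit
script to phase-0 reproduces phase-1 exactly — is testable by string
equality. The representation is observationally symmetric (insertions and
deletions are balanced between phases); which phase is "edited" is not
recoverable from the sequence pair.

Allele counts are simulated per gene × organ × replicate: totals are
negative binomial (default mean 100, dispersion 0.1, i.e. variance
µ + 0.1µ²), split binomially at the gene's true phase-0 fraction; 10 % of
genes carry a 0.8 allelic ratio (favoured allele randomised per gene) and
the rest sit at 0.5, over 3 organs × 3 replicates.

What the generator does **not** emulate: read-level sequencing (no FASTQ,
no mapping bias), realistic base composition or codon usage, nested or
truncated TE copies, segmental duplications, and reference-bias effects on
allele counting. Passing recovery tests therefore demonstrate correctness
of the algorithms under clean breakpoints and unique flanks, not
performance on real assemblies with repeat-dense breakpoint neighbourhoods.

# Numerical choices and degenerate inputs

* Anchor k = 15 balances uniqueness (random 15-mers are unique in
  multi-Mb genomes) against sensitivity near planted events; k < 11 is
  rejected.
* Gap closure uses affine-gap global alignment only below 10 kb; beyond
  that a gap becomes a deletion + insertion pair, which the SV classes
  absorb.
* `variant_density()` omits zero-count classes instead of dividing by
  zero; `window_density()` includes the final partial window.
* Zero-coverage gene × organ cells are untestable (`NA` p and q) rather
  than errors; an all-zero organ raises a warning.
* Ties in the beta-binomial two-sided sum are included with a 1e-7
  relative tolerance, matching exact-test convention.
* Left-normalisation is bounded by construction (events are separated by
  a buffer larger than any plausible shift in random sequence).

# Problem sizes in the tests

The test suite exercises a 300 kb diploid for unit-level recovery, a 2 Mb
pair with 50 planted LTR-RT insertions for TSD statistics, a 5 Mb pair for
full breakpoint-exact recovery, 1000-configuration interval oracles for
zygosity, and 1000-gene simulations for ASE calibration. These sizes were
chosen so the full suite runs comfortably on one CPU while keeping every
statistical check at a scale where its expected behaviour is unambiguous.

# Known limitations

* The aligner assumes high global collinearity; translocations are not
  modelled, and inversions are detected only when bracketed by
  same-strand anchors.
* `DUP_INT` detection needs one exact 21-mer shared with the source locus;
  highly diverged interspersed duplications fall back to plain `INS`.
* Effect classification handles one transcript per gene; UTRs and splice
  sites are out of scope (simulated exons are fully coding).
* The beta-binomial ρ is organ-global; gene-specific overdispersion is
  absorbed only on average.
* Real-data absolute counts (hundreds of thousands of SNPs on a 128 Mb
  assembly, TE-content tables, population frequencies) are outside what a
  desk-scale synthetic genome can or should reproduce; the package checks
  the arithmetic and the algorithms, not those totals.
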
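---
title: "Methods and design notes for tepan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for tepan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tepan` analyses transposable-element (TE) insertion polymorphisms at
population scale: it builds a pan-TE presence/absence map from per-assembly
TE annotations and structural-variant (SV) records, classifies pangenome
gene-cluster occupancy, dates LTR retrotransposon insertions, classifies TE
effects on adjacent gene expression, runs TE-based association scans with
LD clumping, and summarizes haplotype combinations of focal insertions.
This vignette records the models, the parameters that matter, and the
design decisions taken where several readings were defensible.

## Coordinate and genotype conventions

All intervals are 0-based half-open internally; BED I/O passes through
unchanged and GFF3 is shifted on import/export. This makes overlap length
`min(end) - max(start)` with no off-by-one cases.

Genotypes are diploid dosages of the TE-bearing (or SV ALT) allele:
0, 1, 2 or missing (`NA`). Minor allele frequency is computed over
non-missing calls only, counting alleles as the dosage sum over `2N`
chromosomes. "Carrier" status in the expression analyses uses dominant
coding (any non-zero dosage), because presence/absence of the insertion is
the analysis unit; a recessive reading can be obtained by recoding dosages
upstream.

## Pan-TE map

SV alleles are typed by length: deletion when len(REF) ≥ 50 bp and
len(ALT) = 1, insertion when len(REF) = 1 and len(ALT) ≥ 50 bp, complex
(MNP) for remaining alleles ≥ 50 bp, `small` otherwise (excluded from SV
genotyping). The 50-bp bound is inclusive.

A TE is associated with an SV when the SV's allele segment in the TE's
assembly covers **strictly more than half** of the TE's length — a TE
covered by exactly 50% is not linked. The overlap denominator is always
the TE length, not the segment length. The carrier allele of a link is the
allele whose sequence hosts the TE: ALT for insertion-borne TEs annotated
on a non-reference placement, REF for deletion-borne TEs annotated on the
reference.

When one TE is linked to several SVs, the merged per-accession genotype is
the **minimum carrier-allele dosage** over the linked SVs, with any
missing linked call making the merged call missing. The reasoning: a TE
spanning several hosting segments is only present on a haplotype carrying
*all* of them, so the conservative intersection is correct for presence
calls; the permissive union (`rule = "max"` in `merge_genotypes()`) is
available for sensitivity analyses, since a "merge" rule admits either
reading. Merging is idempotent for duplicate links and order-invariant.

A pan-TE locus is *fixed* when a single allele is observed among
non-missing calls (all dosage 2 or all dosage 0); any heterozygous call
therefore makes a locus polymorphic. Loci with no non-missing call are
flagged separately and excluded from the fixed/polymorphic fractions.

Variant filters follow population-genetics convention: missing ratio
≤ 0.5 (strict removal above), MAF strictly greater than the threshold
(default 0.05), heterozygote fraction strictly below the threshold
(default 0.5). Filtering only drops rows; genotype values are never
altered.

## LTR insertion clock

An intact LTR element has identical terminal repeats at insertion; each
repeat then accumulates substitutions at rate `r` per site per year, so
the pair diverges at `2r`. Divergence between aligned repeats is computed
as the mismatch fraction `p` over comparable sites (ambiguity codes
skipped) with Jukes–Cantor correction `K = -(3/4) ln(1 - 4p/3)`, and the
insertion age is `T = K / (2r)` with `r = 1.5e-8` by default. The JC
correction is the default because upstream structural annotators apply a
divergence correction that raw identity does not reproduce; `correction =
"raw"` exposes the uncorrected fraction for comparison with tools that
report raw identity. `p ≥ 0.75` is a saturation error, not a number.

Burst profiles bin ages per superfamily or subgenome; a pooled `Total`
group includes every element, and elements with unknown superfamily
contribute only to `Total`. The young-fraction summary uses a strict
`age < cutoff` with a 1 Myr default cutoff.

## Expression effects

Genes with TPM below 0.01 in more than 80% of samples are dropped before
any expression analysis. TMM scaling factors are computed by the standard
trimmed-mean-of-M-values procedure (reference column by upper-quartile
closest to the mean, 30% M-trim, 5% A-trim, inverse-variance weighting,
geometric mean 1), delegated to the edgeR implementation and cross-checked
in the test suite against a from-scratch evaluation of the formulas.

Nearest-gene assignment: distance 0 for gene-body overlap, otherwise the
gap to the closest gene boundary, with sign encoding upstream (negative)
versus downstream of the gene's transcription direction. Ties in gap are
broken deterministically by the smaller gap to the transcription start
site, then lexicographic gene id.

The effect classifier compares carrier and non-carrier group means of the
target gene: promotive when the ratio is at least the fold threshold
(1.5 by default, boundary inclusive), suppressive when at most its
reciprocal, otherwise none. Three numerical choices matter:

* `epsilon = 0.01` TPM is added to both means before forming the ratio to
  guard zero-expression groups. Note this makes a mean pair of exactly
  3.0 vs 2.0 fall marginally *below* 1.5 (3.01/2.01 ≈ 1.4975): the
  inclusive boundary is exact only at `epsilon = 0`. The offset is kept
  because zero denominators are common in sparse TPM data and the
  boundary case is measure-zero in practice; scale invariance holds when
  `epsilon` is scaled with the data.
* `min_group = 5` accessions per genotype class; smaller groups give an
  `unevaluable` call that is reported, never silently dropped. Constant
  genotypes are likewise unevaluable rather than errors.
* The rule is applied to raw TPM by default; normalized values can be
  passed instead, since the choice is not forced by the method.

The headline promotive percentage is computed among regulatory calls
(promotive + suppressive); the fraction of `none` calls over all evaluable
TEs is reported alongside, because the two denominators answer different
questions and published summaries have used both. Cross-stage consistency
means the same non-`none` class in every stage.

## Association scans

The association engine is ordinary least squares of the response on each
variant's dosage plus covariates (top principal components of the
expression or genotype matrix; 10 by default), with two-sided Wald
p-values. This is a deliberate methodological substitution for mixed-model
machinery (kinship-corrected GWAS, nominal-pass eQTL tools): at the
simulated scales the package targets there is no population structure
beyond what PCs capture, and OLS keeps the engine dependency-free and
exactly calibrated (the test suite checks type-I error at α = 0.05 within
[0.04, 0.06] and KS uniformity of null p-values). On structured real
panels a mixed model would be the better tool; the engine's interface
(matrix in, per-variant records out) was designed so such a backend could
be swapped in.

When the genotype matrix is complete the scan residualizes the response
and all dosage columns against the covariates once (Frisch–Waugh) and
obtains every test from vectorized cross-products; with missing dosages it
falls back to per-variant fits on pairwise-complete accessions.
Zero-variance dosages yield a flagged record with undefined p, not an
error.

The significance cutoff is `p = 1/n` (`-log10` threshold `log10(n)`) with
`n` the number of variants tested — the only multiple-testing rule
applied, by design; no FDR layer is added on top.

Cis/trans: a variant is cis to a gene when on the same contig with a gap
of at most 1 Mb between the intervals, measured gene-body boundary to
variant anchor boundary, overlap counting as distance 0. The boundary is
inclusive at exactly 1 Mb ("within 1 Mb" admits either endpoint
convention; inclusive was fixed once). The cis/trans percentage summary is
computed over whatever record set it is given (all records, or records
past a cutoff), since the denominator convention varies between reports.

Clumping is greedy and PLINK-like: the unassigned variant with the
smallest p ≤ 1e-5 indexes a clump and absorbs unassigned variants within
100 kb with r² ≥ 0.1 to the index (r² = squared Pearson correlation of
dosages over pairwise-complete accessions; undefined r² never absorbs).
Ties in p are broken by contig, position, then id, making the output a
deterministic partition of the significant variants. Clump spans are
merged per contig into loci; touching spans merge, matching the interval
union semantics of `IRanges::reduce`.

## Haplotype combinations

Only accessions with homozygous non-missing calls at every focal variant
are classifiable (heterozygous calls are excluded because phased states
for a presence/absence table are otherwise ambiguous); excluded accessions
are counted, not ignored. Combination frequency is over classifiable
accessions, and retention requires frequency strictly above 0.05.
Carried-variation percentages are **truncated** (floor) to integers — the
convention that makes 104 of 132 report as 78% — rather than rounded.

## Synthetic data: what it emulates and what it does not

The generators define the study conditions for every test:

* `simulate_genotypes()`: diploid biallelic Hardy–Weinberg sampling; a
  configurable fraction of loci fixed for the TE (default 0.8514,
  matching the conserved share typical of population TE panels);
  polymorphic minor allele frequencies drawn, by default, from a
  Beta(0.6, 4) scaled onto (0, 0.5] — chosen once because polymorphic TE
  insertions are dominated by low-frequency variants; a uniform law is
  available where a flat spectrum simplifies calibration arithmetic.
  Missingness is independent per entry. The pre-masking matrix is also
  returned: expression and phenotypes are simulated from true genotypes,
  missingness being a property of genotyping, not of biology.
* `simulate_expression()`: one target gene per TE (a nearest-gene
  assignment by construction), log-normal baselines, planted
  multiplicative fold effects in carriers, and log-normal noise with a
  stated coefficient of variation (mean-1, so folds are unbiased).
  Stages share effects and differ only in noise, which is exactly the
  assumption behind cross-stage consistency.
* `simulate_phenotype()`: additive genetic values plus Gaussian noise
  scaled to a stated heritability; ecotype labels follow the first
  planted QTL's dosage (0 → winter, 1 → semi-winter, 2 → spring), so
  haplotype-ecotype tests have a known genetic basis.
* `simulate_intervals()`: SV allele segments on a disjoint grid, linked
  TEs fully contained in a segment, decoys either in the gaps or
  straddling a boundary with exactly half their length inside — so the
  truth link set is unambiguous and the strict >50% rule is probed at
  its boundary by construction.
* `simulate_ltr_pairs()`: repeats diverged by per-site Bernoulli
  substitution at `p = 3/4 (1 - exp(-4K/3))` with `K = 2 r age`, i.e.
  exactly the Jukes–Cantor forward model the estimator inverts.

Deliberately **not** emulated: linkage disequilibrium beyond the planted
duplicated-variant blocks used in clump tests (variants are otherwise
independent, so clumping on fully realistic LD decay is untested);
population structure and kinship (the OLS engine is calibrated on
unstructured panels only); read-level noise, genotyping error models and
imputation; sequence context of TEs (superfamilies are labels, not
sequences). Passing tests therefore demonstrate correctness of the
algorithms under their stated models, not robustness to structured real
data.

## Problem sizes and runtime choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical checks are sharp: 100,000 null
p-values (200 responses × 500 variants of 100 accessions) for
calibration; 300 accessions × 400 TEs at MAF 0.3 and noise CV 0.2 for
classifier recovery; 100 random instances each for the oracle-equivalence
checks of interval association and clumping; 2-kb repeats for the LTR
round-trip (binomial SD ≈ 0.0039 on p, i.e. ≈ 15% of the 1 Myr age);
a 4-genome, 20-cluster toy for exhaustive growth-curve enumeration
(500 × 30 samples give Monte-Carlo error well below one cluster). The
end-to-end pipeline smoke runs use 80–200 accessions and a few hundred
loci.

## Known limitations

* The pipeline's eQTL/GWAS stages place simulated variants on a synthetic
  coordinate grid; genuine per-assembly coordinates flow through the
  lower-level functions but are not round-tripped by the demo pipeline.
* TMM factors assume count-like input; applying them to TPM matrices is
  supported (and common practice) but inherits TPM's within-sample
  normalization.
* The haplotype module treats heterozygous focal calls as unclassifiable
  rather than attempting statistical phasing.
* `-log10(1/n)` is a permissive multiple-testing rule; users wanting FDR
  control should apply `p.adjust` to the association records themselves.
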
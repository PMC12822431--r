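# tepan

Population-scale analysis of transposable-element (TE) insertion
polymorphisms, for researchers studying how TEs shape genome structure,
gene expression and phenotypes across a pangenome panel (the motivating
system is allotetraploid rapeseed, *Brassica napus*, with its winter,
semi-winter and spring ecotypes).

`tepan` implements, as tested R functions:

* **Pangenome occupancy and growth** — gene clusters are classified by the
  number of genomes containing them (core = *n*, softcore = *n−2..n−1*,
  dispensable = *2..n−3*, private = 1), and pan/core growth curves are
  estimated by totally-random genome resampling (by default 500
  combinations × 30 repeats per subset size).
* **Pan-TE map construction** — SV alleles are typed by length
  (DEL: len(REF) ≥ 50 & len(ALT) = 1; INS: len(REF) = 1 & len(ALT) ≥ 50;
  remaining ≥ 50 bp alleles complex), a TE is associated with an SV when
  the SV allele segment covers **more than half** of the TE, and a TE
  linked to several SVs gets the per-accession **minimum carrier-allele
  dosage** (missing-dominant) as its merged genotype. Variant filters:
  missing ratio ≤ 0.5, MAF > 0.05, heterozygosity < 0.5.
* **LTR insertion dating** — terminal-repeat divergence with Jukes–Cantor
  correction, K = −(3/4)·ln(1 − 4p/3), and insertion age T = K/(2r) with
  r = 1.5 × 10⁻⁸ substitutions per site per year; amplification-burst
  profiles by superfamily/subgenome with young-fraction summaries.
* **TE effects on adjacent gene expression** — expression filtering
  (TPM < 0.01 in > 80% of samples excluded), TMM normalization factors,
  nearest-gene assignment, and a 1.5-fold rule: carriers expressing
  ≥ 1.5× the non-carrier mean are *promotive*, ≤ 1/1.5× *suppressive*,
  with cross-stage consistency sets.
* **TE-GWAS / TE-eQTL** — per-variant OLS with principal-component
  covariates, the −log₁₀(1/n) genome-wide cutoff, cis/trans partitioning
  at an inclusive 1 Mb window, PLINK-style greedy LD clumping
  (p1 = 1e−5, 100 kb, r² ≥ 0.1) and locus merging.
* **Haplotype combinations** — presence/absence states over a few focal
  insertions, combination frequencies (retained when > 0.05), per-combo
  phenotype means and ecotype composition, and carried-variation counts
  with integer-truncated percentages.
* **Synthetic data** — generators for genotypes (Hardy–Weinberg with a
  configurable MAF spectrum and fixed fraction), expression with planted
  multiplicative effects, phenotypes with planted QTLs at a stated
  heritability, interval layouts with known TE↔SV links, and LTR pairs
  diverged at known ages — every stage is testable with full ground
  truth and no external data.

## Worked example

```r
library(tepan)

## simulate a 300-accession panel with 100 TEs doubling their target
## gene's expression in carriers
sim <- simulate_genotypes(300, 200, fixed_fraction = 0,
                          law = maf_law("uniform", min = 0.2999, max = 0.3001),
                          seed = 71)
planted <- setNames(rep(2.0, 100), rownames(sim$genotypes)[1:100])
ex <- simulate_expression(sim$genotypes, planted, noise_cv = 0.2,
                          stages = 1, seed = 72)
calls <- classify_stage_effects(sim$genotypes, ex$expression$stage_1,
                                ex$te_gene_map)
table(calls$effect[calls$te_id %in% names(planted)])
#> promotive
#>       100
mean(calls$effect[!calls$te_id %in% names(planted)] == "promotive")
#> [1] 0

## the fold-rule arithmetic on published stage counts
s <- effect_summary(data.frame(te_id = seq_len(10966),
                               effect = rep(c("promotive", "suppressive"),
                                            c(7319, 3647))))
round(s$per_stage$promotive_pct, 2)
#> [1] 66.74

## date an LTR element whose terminal repeats differ at 3% of sites
insertion_time(jc_divergence(ltr5, ltr3), r = 1.5e-8)   # years
insertion_time(0.03)
#> [1] 1e+06
```

Every planted promotive TE is recovered and no null TE is mis-called at
these settings; a 3% repeat divergence dates an insertion to one million
years under the default substitution rate.

An end-to-end run on synthetic data (all eight stages, with a manifest of
seeds, config hash and output checksums):

```r
res <- run_pipeline(pipeline_config(overrides = list(outdir = "tepan_out")))
```

A thin command-line wrapper with subcommands (`simulate`, `pangene`,
`pante`, `ltr-date`, `effects`, `gwas`, `eqtl`, `haplo`, `run`) is
installed at `inst/scripts/tepan.R`.

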
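# ipac

Integrative analysis of matched DNA copy-number and gene-expression
cohorts to find *in-trans process-associated and cis-correlated* (iPAC)
genes: genes that are recurrently gained or lost, whose expression is
driven by their own copy number, and whose expression is in addition
significantly associated with a biological process acting elsewhere in
the genome. Such genes are candidate drivers — for instance amplified
modulators of cell-cycle programs in breast carcinomas — as opposed to
passengers that merely ride along on the same amplicon.

The package is aimed at computational biologists working with matched
array-based copy-number (aCGH/SNP) and expression profiles of the same
tumor samples.

## Method

Given a probe-level log2 copy-number matrix and a log2 expression matrix
over the same samples, the workflow is:

1. **Segmentation.** Each sample's per-chromosome profile is fit by a
   piecewise-constant function minimizing
   `sum of squared residuals + gamma * (number of breakpoints)` subject
   to a minimum of `kmin` probes per segment, solved exactly by dynamic
   programming. Every probe inherits its segment mean (its *PCF value*).
2. **Gene matching.** Each expression probe with a gene symbol is paired
   with the nearest same-chromosome copy-number probe; values and
   positions are averaged per symbol, giving matched gene-level matrices.
3. **Common aberrations.** A gene is gained in a sample when its PCF
   value exceeds `tau` (lost below `-tau`). Genes are kept when more than
   10% of samples are aberrant *and* the gain/loss skew `D = G - L`
   passes an exact binomial sign test: `|D| >= c`, with `c` the least
   integer such that `P(|2X - m| >= c) <= alpha` for all observed
   aberration counts `m`, `X ~ Bin(m, 1/2)`.
4. **In-cis genes.** For each gene, expression is regressed on copy
   number, `e = a + b*c + eps` (log2 scale). Commonly aberrant genes
   with Pearson in-cis correlation `r > 0.6` (so at least 36% of
   expression variance explained by dosage) are the *in-cis* genes; the
   false discovery rate of that cutoff is estimated by shuffling the
   gene order of the copy-number matrix.
5. **In-trans associations.** For every gene the copy-number-adjusted
   *residual expression* is computed from the model above; using each
   in-cis gene as a pivot, all genes are ranked by the correlation
   between the pivot's observed expression and their residuals. Each
   gene set is scored in both tails with the exact minimum
   hypergeometric (mHG) test: `s = min_n HGT(b(n); N, B, n)` with its
   exact permutation p-value from the O(N·B) lattice dynamic program.
   Associations passing Bonferroni correction are called iPAC
   associations only if they also beat an empirical null obtained by
   shuffling the samples of the residual matrix and keeping, per gene
   set, the minimum score over all pivots and simulations.

A synthetic-cohort generator with planted amplicons, cis coupling and a
trans module provides ground truth for end-to-end validation, and a
two-gene co-amplification fixture isolates the confounding effect the
residual adjustment removes.

## Worked example

```r
library(ipac)

coh <- generate_cohort(synth_spec(), seed = 1)   # 3000 genes, 100 samples
cfg <- pipeline_config(n_shuffles = 200, n_sims = 20, seed = 1)
res <- run_ipac(coh$cn, coh$expr, coh$sets, cfg)

res$manifest$counts
#> $n_genes              3000
#> $n_commonly_aberrant    11
#> $n_cis                  11
#> $n_ipac                 11
res$cis_fdr$fdr_estimate
#> [1] 0.01727273
subset(res$associations, empirical_significant &
       pivot == coh$truth$driver)[, c("set_id", "mhg_score", "n_star", "b_star", "fold")]
#>     set_id     mhg_score n_star b_star fold
#>   MODULE_1 6.387524e-110     50     50   60
```

The funnel narrows from 3000 genes to the 11 genes on the planted
amplicon (all recurrently gained, all dosage-driven), and the planted
50-gene module is recovered at the top of the driver's ranking — all 50
members in the top 50 positions, a 60-fold enrichment — while none of
the 500 decoy sets is called. The shuffle-based FDR of the `r > 0.6`
cutoff is below 2%.

The same workflow runs from the shell:

```sh
Rscript inst/cli/ipac.R simulate --out data/ --seed 1
Rscript inst/cli/ipac.R run --cn data/cn.tsv --expr data/expr.tsv \
    --gmt data/sets.gmt --out results/ --seed 1 --shuffles 200 --sims 20
```

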
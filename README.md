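# cnvtrait

`cnvtrait` implements a complete analysis of copy-number variants (CNVs)
against **continuous reading- and language-related performance** in
family-structured (sibship) cohorts, of the kind collected by learning-
disability twin studies. It is aimed at statistical geneticists who have
PennCNV-style CNV calls, SNP-array intensity data (log R ratio, LRR), a
battery of standardized reading/language measures, and sibship pedigrees,
and who want to ask: *do CNVs — individually, in aggregate, or as
co-segregating family variants — shift a child's composite reading/language
score?*

## What it computes

**Composite phenotypes.** The first principal component (PC1) of six
reading/language measures (word reading, spelling, phonological decoding,
phoneme awareness, orthographic coding, nonword repetition), computed on the
trait correlation matrix per recruitment cohort, complete cases only;
`IQadjPC1`, the residual of PC1 on performance IQ; and case/control labels
from the first/tenth deciles of a discriminant score.

**CNV call QC** in the PennCNV convention: keep calls with confidence ≥ 10,
span ≥ 20 kb and ≥ 10 probes, and < 50 % overlap with exclusion regions;
join same-state calls whose gap is ≤ 20 % of the joint span; drop samples
with > 100 autosomal calls or LRR SD > 0.35; annotate to genes within a
50-kb flank and to exons; classify calls as *rare* when fewer than five
reference-database events overlap ≥ 50 % of the call.

**Burden tests.** Per-sample CNV count and total length (overall, gene,
exon, rare, and by length class), correlated with PC1/IQadjPC1 as the median
Spearman rho over repeated samplings of one individual per sibship, plus
logistic case/control burden regression under the same resampling.

**Probe-wise association.** A binary CNV+/CNV− state per probe (copy number
≠ 2; ≠ 1 for the male X, with sex-stratified X testing), tested against the
composite scores by an OLS slope with sibship-preserving permutations; a
dosage-sensitive complement regresses the score on raw LRR with LRR
principal components 1–2 as covariates. Cohorts are combined by
sample-size-weighted z-score meta-analysis

        Z = (√N₁·z₁ + √N₂·z₂) / √(N₁ + N₂),

and associated *regions of CNV overlap* are runs of consecutive probes with
p < 0.05 containing ≥ 2 consecutive probes below a core threshold (0.005
for the state scan, 0.001 for the intensity scan) plus ≥ 2 further probes.

**Co-segregation and enrichment.** Large (> 500 kb) CNVs in cases; CNVs
shared by ≥ 2 affected co-siblings and absent in all unaffected
participants (reciprocal overlap ≥ 50 %, same direction); candidate-gene
overlaps; and an interval-permutation gene-set enrichment test whose null
replaces each CNV interval with a random run of the same number of
consecutive CNV-covered probes.

**Synthetic data.** Because the motivating cohort is private, the package
ships a fully seeded generator for sibship cohorts, probe manifests, gene
models, reference/exclusion interval sets, ground-truth CNV landscapes with
plantable causal effects, LRR/BAF intensities, jittered call records, and
factor-structured phenotypes — so every pipeline stage is validated against
known ground truth.

## Worked example

```r
library(cnvtrait)

cfg <- pipeline_config(
  seed      = 7,
  landscape = landscape_config(carrier_frac = 0.08),   # 8% carry a deletion
  pheno     = pheno_config(causal_beta = -1.2))        # shifting F by -1.2 SD
res <- run_pipeline(cfg, out_dir = "results/run1")

res$summary
#>                stage count
#> 1            samples   336
#> 2             probes 20000
#> 3      true_segments  2911
#> 4          raw_calls  3059
#> 5           qc_calls  2278
#> 6       samples_kept   336
#> 7     covered_probes 12479
#> 8        meta_probes  2012
#> 9      state_regions     4
#> 10 intensity_regions     2
#> 11      lrr_outliers    22

res$state$regions$PC1[1, c("chrom", "start", "end", "n_probes",
                           "p_min", "cnv_plus_pct", "length_kb")]
#>   chrom    start      end n_probes        p_min cnv_plus_pct length_kb
#> 1     1 25036692 25168501       12 7.558493e-05     7.738095       132
```

336 children in 130 sibships are simulated on a 20,000-probe array; 3,059
raw calls shrink to 2,278 after QC; 2,012 probes are covered by CNVs in
both cohorts and meta-analyzed. The planted deletion (true interval
chr1:25,036,692–25,168,501) comes back as the top detected region of CNV
overlap: 12 probes, meta p = 7.6 × 10⁻⁵, CNV+ frequency 7.7 %, 132 kb —
the coordinates match the planted segment exactly. Burden correlations
(`res$burden$table`) stay null — nothing was planted on total CNV load —
e.g. rho = −0.007 (p = 0.55) for event count vs PC1 in the larger cohort.

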
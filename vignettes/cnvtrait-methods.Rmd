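---
title: "Methods: CNV association with continuous reading/language traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV association with continuous reading/language traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cnvtrait)
```

## The analysis problem

Copy-number variants (CNVs) are deletions and duplications of genomic
segments. In severe neurodevelopmental disorders they carry substantial
risk; whether they also shift *continuous* reading and language performance
in the general schooling population is much less clear. `cnvtrait`
implements the full analytical chain for asking that question in cohorts of
siblings recruited through a proband: composite trait derivation, CNV call
quality control, burden testing, two complementary probe-wise association
scans, cross-cohort meta-analysis, region calling, family co-segregation
screens, and gene-set enrichment — all exercised end-to-end on synthetic
data with planted ground truth, since no public cohort of this design
exists.

Two design commitments shape everything downstream:

* **Sibships, not unrelated samples.** Children come in sibling pairs or
  triples. Association uses permutations that preserve sibship structure;
  burden correlations resample one individual per sibship.
* **Two views of dosage.** A binary CNV+/CNV− state per probe captures
  effects of *having* a CNV irrespective of direction (reduced penetrance,
  variable expressivity), while a regression on the raw log R ratio (LRR)
  captures copy-number-*dependent*, dosage-additive effects. The two scans
  are deliberately complementary.

## Composite phenotypes

Six standardized measures (word reading, spelling, phonological decoding,
phoneme awareness, orthographic coding, nonword repetition) enter a PCA on
their correlation matrix, separately per recruitment cohort, using only
samples with no missing measure (listwise deletion; `derive_pc1()`). Only
the first component is used downstream, so the oblique rotation a factor
analysis would apply to multiple retained components is a no-op and PC1 is
taken unrotated. Components are sign-ambiguous; the sign is fixed so the
first trait loads positively, matching the convention that higher scores
mean better performance. Scores are standardized; loadings are reported as
trait–component correlations. `adjust_for_iq()` residualizes PC1 on
performance IQ (OLS with intercept), giving a score orthogonal to PIQ by
construction and idempotent under re-adjustment. Case/control labels come
from the first and tenth deciles of a discriminant composite
(`assign_case_control()`); boundary ties are included in the extreme groups,
and a fixed-threshold mode (−1.4 / 2.2 on the standardized scale) is
available.

## CNV call QC

`filter_calls()` retains calls with confidence ≥ 10 (treated as an opaque
score compared against the conventional cutoff), inclusive span
(end − start + 1) ≥ 20 kb, ≥ 10 probes, and < 50 % of the span covered by
the union of exclusion regions (immunoglobulin regions, pseudo-autosomal
regions, centromeres, large gaps). Thresholds on the call's own measures
are inclusive; the exclusion rule is strict. `join_adjacent_calls()` merges
same-sample, same-chromosome, same-copy-number neighbours whose gap is at
most 20 % of the span they would jointly cover, iterating left-to-right to
a fixed point; the merged probe count is the sum and the confidence the
maximum (preserving pass/fail of the confidence filter). Only same-copy-
number calls merge — joining a deletion to a duplication is not meaningful.
`filter_samples()` drops samples with > 100 autosomal calls or LRR SD
> 0.35 (both strict; X calls do not count). Gene annotation extends gene
spans by 50 kb on both sides to capture flanking regulatory territory;
exon overlap uses the exact exon intervals. Rarity counts reference-set
events whose intersection covers ≥ 50 % of the *call's* span (call-anchored,
not reciprocal — the natural reading of "the call shows substantial overlap
with a reference event"); fewer than five such events makes a call rare.

Coordinates are 1-based inclusive internally (the PennCNV convention); BED
I/O converts from 0-based half-open at the file boundary. One deliberate
wrinkle: the filtering span is end − start + 1, but the kb lengths printed
in report tables (`call_span_kb()`) follow the end − start convention of
the published tables this format imitates, rounded to the nearest kb.

## Burden

`compute_burden()` aggregates per-sample event counts and total bp of the
merged QC-passing calls, overall or restricted to gene-annotated, exonic,
rare, or length-class subsets (short < 100 kb, medium 100–500 kb inclusive,
large > 500 kb). Because burden measures are heavily non-normal and samples
are related, `resampled_correlation()` reports the median Spearman rho (and
median p) over draws that keep one random individual per sibship; the
number of draws defaults to 100. The median-p aggregate is deliberately a
*summary*, not a new test: since draws share roughly 40 % of their samples,
their p-values are positively correlated and the median-p rule is strictly
conservative under the null (its type-I error is well below the nominal
level — verified by simulation in the test suite). The calibrated
inferential unit is the single one-per-sibship draw. Case/control burden
uses logistic regression per draw, with the covariate standardized (odds
ratios are per SD of the burden measure); draws with complete separation
are excluded and counted.

## Probe-wise association with CNV state

`assign_probe_states()` codes a probe CNV+ for a sample iff a QC-passing
call covers it with copy number ≠ 2 (≠ 1 for males on the X); deletions and
duplications collapse into the single CNV+ state. Only probes covered by at
least one CNV are tested. The test statistic is the OLS slope of the score
on the 0/1 state. Significance comes from sibship-preserving permutations:
whole per-family score blocks are shuffled across families of equal size
and member order is shuffled within families, so the null preserves the
within-family correlation structure. We do not reproduce the internal
between/within-family decomposition of the family-QFAM machinery the design
is modeled on; the implemented contract — a linear score-on-state
association with family-respecting permutation — is the property that
machinery is invoked for. p = (1 + #{|b\*| ≥ |b|}) / (1 + n_perms), two-
sided. X probes are tested separately in males and females and the strata
combined by the same weighted-z scheme as cohorts, with single-stratum
probes passing through unchanged.

The per-probe engine (`permutation_scan()`) shares one permutation set
across probes and computes all slopes as centered cross-products via BLAS,
which is what makes genome-wide scans with thousands of permutations
tractable; the single-probe interface adds adaptive early stopping
(default: stop after 100 exceedances, cap 10,000 permutations — beyond 100
exceedances the p estimate no longer moves materially).

## Meta-analysis and region detection

`meta_analyze()` implements the sample-size-weighted scheme: each cohort's
two-sided p becomes a signed probit z (sign = slope direction), combined as
Z = Σ√Nᵢ·zᵢ / √(ΣNᵢ). Only probes tested in both cohorts are meta-analyzed;
single-cohort probes remain in per-cohort outputs. A p of exactly 0 cannot
arise from the permutation formula and is clamped with a warning.

`detect_regions()` formalizes "regions of CNV overlap with a shared
effect": a maximal run of consecutive tested probes with p < 0.05 that
contains ≥ 2 consecutive probes below the core threshold and at least 2
member probes beyond the core (so a region has ≥ 4 probes). The core
threshold is 0.005 for the state scan and 0.001 for the intensity scan,
whose raw-intensity noise warrants the stricter core. "Beyond the core" is
read as anywhere within the same sub-0.05 run, on either side in any split
— the reading that reproduces the four-probe minimum region. Untested
(uncovered or monomorphic) probes break runs: a region cannot jump over a
probe that could not have been tested. `bonferroni_alpha()` supplies the
genome-wide threshold for a given number of traits and probes.

## Intensity association

`lrr_pca()` computes SVD-based principal components of the sample-centered
LRR matrix (up to 100, for screening); `flag_lrr_outliers()` flags samples
beyond 6 scaled MADs on either of the first two components — the outlier
rule of the original analysis is unstated, so a robust default stands in.
On synthetic data, where CNVs rather than batch effects dominate the LRR
covariance, this rule flags more samples than it would on real arrays whose
700k probes dilute individual CNVs; that is a property of the simulation,
not of the rule. `intensity_association()` residualizes the score on LRR
PCs 1–2 (batch surrogates) and applies the same family permutation engine
to each probe's LRR column; the Spearman correlation between LRR and the
raw score is reported as the effect surrogate and direction. Only autosomes
are tested. The full variance-components family model this step emulates is
not publicly available; the implemented contract captures each property
stated for it (per-probe intensity regression, intensity-PC covariates,
family-respecting permutation, rho as direction) and is documented as a
simplification.

## Co-segregation and enrichment

Two calls in different individuals count as "the same CNV" when they
reciprocally overlap ≥ 50 % and have the same direction (loss vs gain) —
cross-sample CNV identity is never defined by the calling convention, so a
reciprocal-overlap rule is adopted and applied by single-linkage clustering
(order-independent). `find_shared_case_cnvs()` reports clusters carried by
≥ 2 affected co-siblings of a family and absent in unaffected participants;
"unaffected participant" is read cohort-wide by default (strict mode), with
a family-only mode available, since the source phrasing admits both.
`candidate_overlap()` applies the 50-kb gene flank to gene-type candidates
and attaches a per-family co-segregation verdict. Candidate lists are
user-supplied intervals — coordinates are data, not code, to avoid genome-
build baggage.

`target_enrichment()` tests whether case CNV intervals hit a gene set's
genes (50-kb flank) more often than chance: each permutation replaces every
interval with a random run of the same number of consecutive CNV-covered
probes, which matches the null to the probe content and size of the
observed intervals while ignoring gene density (a known simplification).
Overlapping intervals of one sample are merged and cross-sample duplicates
collapsed before testing — the test assumes independent intervals. The
two-stage bootstrap correction of the interval-enrichment tool this
emulates is simplified to the empirical p plus Bonferroni across sets; the
statistic and null construction are preserved, and the one-stage version is
what the calibration and monotonicity properties are proven against in the
test suite.

## The synthetic-data generator

The generator emulates the study conditions: 343 sibships of 2–3 children
(no parents), ~78 % recruited via a reading-disability proband, sexes
Bernoulli(0.5), SNP probes uniform over each chromosome, gene models with
exons, exclusion regions, and a reference CNV set whose loci carry event
counts. Background CNVs are seeded per sample (Poisson, mean 6/sample,
matching a median of ~6 QC calls per sample), mostly 10–25 probes long with
a 3 % long tail (40–80 probes), shared with siblings with probability 0.25;
half are placed at reference-CNV loci (weighted by event count) so that the
rare/common classification has signal. LRR means per copy number default to
(0: −3.5, 1: −0.66, 2: 0, 3: +0.40, 4: +0.68) — typical array behaviour;
the levels are configurable and were not fitted to anything. On the male X
the haploid baseline maps to 0 before the shift lookup. Phenotypes follow a
single-factor model: trait = λ·F + noise with unit trait variance, λ
patterned on the loading profile such batteries show (word reading highest,
nonword repetition lowest), within-sibship correlation of F of 0.4, and IQ
correlating 0.3 (performance) / 0.5 (verbal) with F. The discriminant
composite is a fixed weighted sum (0.5/0.3/0.2 of word reading, spelling,
orthographic coding) standing in for an empirical discriminant function
that is not reproducible from public sources. A planted effect shifts F by
`causal_beta` for carriers of a designated causal region.

What the generator does **not** emulate: MZ-twin duplication (cohorts are
post-selection, one child per MZ pair), batch/plate structure in LRR, GC
waves, genotype-level (B-allele) informativeness beyond cluster patterns,
and realistic linkage disequilibrium. Consequently, passing tests show the
*statistical machinery* behaves as specified under a faithful family/effect
structure — they do not certify performance under real-array artifacts.

## Numerical choices and degenerate inputs

* Permutation p-values use the add-one formula; they can never be 0.
* Exceedance comparisons use a relative tolerance (1e-8) so exact
  permutation ties count as ties in floating point.
* Monomorphic states: p = 1, direction 0; zero-variance LRR probes are
  dropped from intensity output; constant burden gives OR 1, p 1; a
  degenerate (all-equal) discriminant distribution labels everyone
  "neither"; constant PIQ is an error rather than a silent zero-adjustment.
* One-per-sibship resampling redraws case/control draws lacking both
  classes, up to a retry cap; separated logistic fits are excluded and
  counted rather than reported as huge odds ratios.
* All generators and resamplers are seeded; the pipeline derives stage
  seeds from one master seed by fixed offsets, so a run is byte-identical
  given the seed.

## Problem sizes used in validation

The validation suite runs at desk scale, chosen so the full pipeline and
its repeated-simulation properties complete comfortably on one CPU: four
chromosomes × 5,000 probes (50 Mb each), 130 sibships (~336 children) for
end-to-end runs; 1,999 permutations for genome-wide scans (9,999 with early
stopping for single-probe confirmations); 500 null replicates at 199
permutations for calibration checks; and 50 replicates for the planted-
effect recovery study (200 sibling-pair families, 400 samples, one 1,200-
probe chromosome). The planted-recovery study uses a 12-probe causal
deletion at 5 % carrier frequency and a −0.8 SD effect on the latent
factor; at these settings the per-probe power for the region scheme's core
threshold (p < 0.005, two-sided) is analytically capped near 0.75 even for
a perfectly measured trait — the slope z-statistic is ~N(3.49, 1) with 20
expected carriers — and is ~0.7 for the realistic trait battery, a known
property of this design rather than an implementation limit.

## Known limitations

* QFAM's between/within decomposition and the unreleased family-intensity
  model are represented by their stated contracts, not reproduced
  internally.
* Enrichment matches null intervals on probe count only, not gene density.
* The X chromosome is excluded from intensity association (as in the
  design followed) and from burden length classes only insofar as QC
  removes it from call counts.
* No liftover: all coordinates live in the build tag carried by the run
  configuration.
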
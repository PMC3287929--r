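---
title: "Methods: how raretag measures the tagging of rare variants by common SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how raretag measures the tagging of rare variants by common SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raretag)
```

## The question

Genome-wide association panels genotype common SNPs (minor allele
frequency, MAF, above 0.05) and rely on linkage disequilibrium (LD) to
pick up signals from variants that were never genotyped. Under the
common-disease/rare-variant hypothesis many causal alleles are rare
(MAF below 0.01), so two practical questions arise:

1. Within a genomic region, how much information do the common SNPs
   collectively carry about the *number of rare alleles* an individual
   carries?
2. When choosing common tag SNPs, should pairs in very strong LD
   (r² above 0.95) be pruned away — or do those near-redundant SNPs help
   capture rare alleles?

`raretag` implements both analyses as a reusable, fully tested pipeline,
together with a genotype simulator that provides datasets with known
tagging structure, because the cohorts such analyses were originally run
on are access-restricted.

## Data model

Genotypes are an N x M matrix of minor-allele dosages in {0, 1, 2}
(`genotype_matrix()`); LD is always the squared Pearson correlation of
dosage vectors (`pairwise_r2()`), i.e. composite genotypic LD on
unphased data — the natural measure when the SNPs are used as regression
predictors. Variants are classified by MAF (`classify_variants()`):
*rare* when 0 < MAF < 0.01, *common* when MAF > 0.05, *neither* in the
gap (the two analyses only ever reference the rare and common sets, so
intermediate-frequency SNPs take part in nothing; equality with a
threshold falls in the gap because the definitions are strict
inequalities). Any SNP in perfect LD (r² = 1, tolerance 1e-12) with an
earlier SNP — including perfect *negative* dosage correlation — is
excluded up front (`remove_perfect_ld()`), keeping the earliest by
(chromosome, position, id). This step matters beyond hygiene: duplicate
columns silently inflate the predictor count that the adjusted R²
penalises, biasing null results negative.

Missing genotype calls are imputed at load time to the per-variant
rounded mean dosage and counted (`read_vcf()`); all downstream formulas
then assume complete data. Dosages always count the minor allele:
columns whose counted allele is the major one are re-oriented on load.

## Stage 1: bin-level correlation with the rare-allele load

The genome is tiled into non-overlapping bins (`make_bins()`; default
1 Mb; a variant at 1-based position p goes to bin `floor((p-1)/bin_size)`).
Within a bin holding `n_r` rare and `n_c` common SNPs:

* Random subsets of `n_s = 5` rare SNPs are drawn
  (`sample_rare_replicates()`). If `n_r > n_s` the draw is repeated
  `round(n_r / n_s)` times (ties half-up), each an independent
  without-replacement sample; if `0 < n_r <= n_s` a single replicate
  uses every rare SNP (small bins stay in the analysis without invented
  resampling).
* The per-individual load `y_i` is the total number of rare alleles
  across the sampled SNPs (`rare_allele_load()`), or alternatively the
  burden-style presence indicator (`collapsing_indicator()`), selected
  by the `mode` parameter; both give the same qualitative picture.
* Two correlation summaries are computed against the bin's common SNPs:
  the maximum single-SNP r² (`max_single_r2()`) and the multiple R² of
  the least-squares fit of `y` on all common dosages with an intercept
  (`multiple_R2()`), plus the adjusted form
  `1 - (1 - R²)(N - 1)/(N - n_c - 1)` (`adjusted_R2()`), which can be
  negative and is the honest summary when `n_c` is large.

Everything is repeated per subpopulation stratum and per functional
stratum (synonymous / nonsynonymous rare SNPs), with MAF and classes
recomputed within each subpopulation by default — a rare allele in the
pooled cohort may be absent, or no longer rare, within one population.
Strata below 20 individuals are skipped with a warning.

The permutation null (`null_stage1()`) re-runs the identical pipeline
after shuffling each common SNP's column independently across
individuals within the bin (`permute_common_within_bin()`), which
preserves every SNP's MAF while destroying both SNP–load and SNP–SNP
association. Observed and null runs share their rare-SNP samples via
seed derivation, so rows are paired replicate-by-replicate and the
contrast is attributable purely to the permutation. Distributions are
compared by a two-sample Kolmogorov–Smirnov test and a Welch t test on
the means (`compare_distributions()`; Welch rather than pooled because
nothing guarantees equal variances).

Numerical conventions worth knowing:

* A constant `y` (no carriers in the stratum) defines all three
  correlation summaries as 0, with `constant_y_flag` set, rather than
  dropping the replicate — dropping would bias low-MAF strata.
* If `n_c >= N - 2` the regression is (nearly) saturated: the row is
  flagged degenerate and the adjusted R² is withheld, since the
  adjustment denominator must stay positive.

## Stage 2: do tags in strong LD help capture single rare alleles?

For each rare SNP, the common SNPs within a centred 1-Mb window
(`window_select()`; "within a 1-Mb region" is read as ±500 kb,
configurable) are pruned into two nested tag sets (`build_tag_sets()`):
set A with pairwise r² at most `threshold_A`, set B ⊇ A with pairwise r²
at most `threshold_B`, at ceiling pairs (0.80, 0.95) and (0.95, 0.99).
Choosing maximal pairwise-bounded sets exactly is NP-hard and no
selection rule is canonical, so the package uses deterministic greedy
forward selection in position order, the standard tag-SNP practice: one
pass builds A, a second pass over the rejects admits members of B \ A
against the current B.

The rare SNP's own dosage vector (0/1/2, not a carrier indicator) is
regressed on each set; the gain of B over A is tested with the
nested-model F statistic

F = [(R²_B − R²_A)/(n_B − n_A)] / [(1 − R²_B)/(N − n_B − 1)],

with df (n_B − n_A, N − n_B − 1) (`nested_F()`), evaluated two ways:

* analytically against the F distribution (`analytic_F_pvalue()`),
  which assumes normality; and
* by block permutation (`block_permutation_pvalue()`, default 1000
  replicates): one shared row permutation is applied jointly to all
  columns of B \ A, breaking their LD with `y` and with A while keeping
  the LD structure *within* B \ A intact — this is the only reading
  under which the added SNPs' internal redundancy is preserved under the
  null, so the test asks specifically whether the gain comes from their
  LD rather than from their number. The p-value uses the add-one
  estimator (1 + #{F_perm ≥ F_obs})/(1 + n_perm), which can never be 0.

Rank deficiency inside A or B (possible despite the pairwise ceilings,
since pairwise r² < 1 does not preclude multicollinearity) is handled by
pivoted-QR least squares: fitted values are still the projection onto
the column space, so R² is well defined and R²_B ≥ R²_A is guaranteed
because B's column space contains A's. R²_B = 1 yields an infinite-F
flag; `n_B = n_A` rows carry no test; `df2 < 1` rows are flagged
degenerate.

## The synthetic cohort

The simulator (`simulate_dataset()`) is a haplotype-mosaic model rather
than a coalescent: it produces controllable LD and explicit founder
segments to hang rare variants on, so ground truth is never obscured.

* **Founders** (`simulate_founders()`): 0/1 haplotypes over the common
  sites from a first-order Markov chain whose flip probability grows
  with inter-site distance (`0.5(1 - exp(-ld_decay * d))`), giving r²
  that decays with distance.
* **Subpopulations**: each founder's sampling weight per subpopulation
  is a Balding–Nichols draw
  (`simulate_subpopulation_frequencies()`; Beta with mean p and variance
  Fst·p(1−p)); acting on founder weights rather than per-SNP frequencies
  keeps within-population LD realistic.
* **Individuals** (`simulate_individuals()`): each haplotype copies
  founder templates with switches at rate `1 - exp(-rate * d)` per gap;
  two haplotypes sum to dosages.
* **Rare variants** (`place_rare_variants()`): in *linked* mode the
  carriers are drawn from individuals bearing a designated founder
  template at the common site nearest the rare position — the rare
  allele rides a common-haplotype background that common SNPs can tag;
  in *unlinked* mode carriers are uniform draws independent of all
  genotypes. Carriers are heterozygous only, consistent with MAF < 0.01
  in cohorts of a few hundred.

Defaults are the stated world of the analysis: 7 subpopulations × 90
individuals (≈ the 627-individual, 7-population cohort), Fst 0.1
(continental-scale human divergence), 40 common and 10 rare SNPs per Mb
over 10 Mb (≈ the genome-wide density of ~117k commons / ~14k rares),
ld_decay 1e-5 per bp (strong LD over ~100 kb), 20 founders, ~1 template
switch per Mb, and 5 carriers per rare variant (MAF ≈ 0.004). Realized
common MAFs at or below 0.05 are repaired by redrawing that column's
founder alleles (template structure, and hence mosaic LD, is kept);
columns are minor-oriented at the end so VCF round-trips are exact.

What the generator does **not** emulate: realistic demographic history,
recombination hotspots, genotyping error, multi-allelic sites, or any
calibration to a specific real cohort. A green signal-recovery test
therefore establishes that the pipeline detects the *kind* of structure
the analysis targets, not that it reproduces any particular cohort's
numbers.

## Reproducibility

All randomness flows from one master seed through `derive_seed()`, a
string-keyed splitter: every (stage, stratum, bin, replicate, rare SNP)
gets its own substream, so results are independent of evaluation order,
observed and null stage-1 runs can share their sampling streams, and two
runs of `run_pipeline()` with the same seed produce byte-identical
output files (none of which contain timestamps).

## Testing and scaled-down simulations

The test suite checks every statistic against independent oracles
(direct Pearson formula, explicit normal equations, RSS-based ANOVA F,
brute-force ECDF gaps, quadrature of the F density), verifies the
calibration of both null procedures (analytic F rejection rate at
nominal level; block-permutation type-I error inside the exact binomial
band), and demonstrates signal recovery on constructed tag-in-B\A
scenarios and on linked-vs-unlinked simulations. Simulated cohorts in
tests are scaled down (e.g. 150 individuals, 1 Mb, 25 commons) purely
for runtime; the generator's scientific defaults are unchanged. The
stage-1 calibration tests run after perfect-LD removal, in the same
order as the pipeline — the simulator can emit exactly duplicated
common columns, and leaving them in inflates the adjusted-R² penalty.

## Known limitations

* Greedy tag-set construction is order-dependent by design; a different
  scan order gives different (equally valid) maximal sets.
* The adjusted R² assumes independent predictors and over-adjusts when
  tags are correlated — which is precisely the regime stage 2 studies;
  gains of B over A are therefore conservative.
* Stage 2 uses the full cohort for LD and regression (no
  stratification); stage-1 subpopulation runs recompute classes within
  the stratum, so its bins are not directly comparable across strata
  with very different sizes.
* The permutation count bounds the smallest attainable p at
  1/(n_perm + 1).
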
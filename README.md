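# raretag

Can common SNPs tag rare variants? Genome-wide association panels
genotype common SNPs (MAF > 0.05) and rely on linkage disequilibrium
(LD) to pick up signals from ungenotyped variation — but many putative
causal alleles are rare (MAF < 0.01). `raretag` implements, as a tested
R pipeline, a two-stage answer for population geneticists and
statistical geneticists designing tag-SNP panels or interpreting burden
tests:

* **Stage 1 — regional tagging of the rare-allele load.** The genome is
  tiled into 1-Mb bins; for random subsets of `n_s = 5` rare SNPs the
  per-individual rare-allele count `y_i` (or a collapsing presence
  indicator) is correlated with the bin's common SNPs two ways — the
  maximum single-SNP r² and the multiple R² (with its adjusted form
  `1 − (1 − R²)(N − 1)/(N − n − 1)`) — per subpopulation and per
  functional class, against a within-bin permutation null compared by
  Kolmogorov–Smirnov and Welch t tests.
* **Stage 2 — do tags in strong LD help?** Around each rare SNP, common
  SNPs in a 1-Mb window are greedily pruned into nested tag sets A ⊆ B
  with pairwise r² ceilings (0.80, 0.95) or (0.95, 0.99). The gain of B
  over A in predicting the rare SNP's dosage is tested with the nested
  F statistic

  `F = [(R²_B − R²_A)/(n_B − n_A)] / [(1 − R²_B)/(N − n_B − 1)]`,

  both analytically and against a 1000-replicate block-permutation null
  that shuffles the B \ A SNPs jointly across individuals — preserving
  their internal LD while breaking their association with everything
  else, so the test isolates LD from mere predictor count.

Because the cohorts this analysis is usually run on are
access-restricted, the package ships a haplotype-mosaic simulator
(`simulate_dataset()`) — multi-subpopulation cohorts with
Balding–Nichols divergence, distance-decaying LD, and rare variants
whose carriers either ride (`linked`) or ignore (`unlinked`) common
founder-haplotype backgrounds — so every stage is testable end to end
with known ground truth. See `vignettes/methods.Rmd` for the model,
parameter choices and limitations.

## Worked example

```r
library(raretag)

cfg <- run_config(
  simulation = sim_config(n_per_subpop = 60, n_subpops = 3,
                          chromosome_length = 3e6, n_common = 120,
                          n_rare = 60, n_founders = 12,
                          rare_carrier_count = 3, seed = 42),
  n_perm = 200, seed = 42)
res <- run_pipeline(cfg, "demo_out")

# Stage 1: observed vs permutation-null adjusted R2, per stratum
res$stage1_comparison[res$stage1_comparison$functional == "all" &
  res$stage1_comparison$statistic_name == "adjusted_R2",
  c("stratum", "mean_observed", "mean_null", "ks_p", "t_p")]
#>    stratum mean_observed mean_null   ks_p    t_p
#> 3      all        0.0973    0.0322 0.0995 0.0358
#> 12    pop1        0.1224    0.0624 0.8730 0.7710
#> 21    pop2       -0.1146   -0.1788 0.9307 0.5840
#> 30    pop3       -0.1147    0.0205 0.0260 0.1447

# Stage 2 (ceilings 0.80 / 0.95): rare SNPs most helped by the extra
# strong-LD tags in B \ A
s2 <- res$stage2[["A080_B095"]]
head(s2[order(s2$p_permutation),
        c("rare_id", "n_A", "n_B", "adjR2_A", "adjR2_B", "F",
          "p_analytic", "p_permutation")], 4)
#>    rare_id n_A n_B  adjR2_A adjR2_B     F p_analytic p_permutation
#> 17   r0017  19  22 -0.01923   0.150 11.60   6.58e-07       0.00498
#> 25   r0025  22  27 -0.00568   0.102  4.77   4.42e-04       0.00498
#> 52   r0052  19  20  0.05380   0.103  9.86   2.01e-03       0.00498
#> 12   r0012  21  23  0.11496   0.153  4.52   1.24e-02       0.00995

compare_stage2_distributions(s2)
#>    n mean_adjR2_A mean_adjR2_B ks_statistic  ks_p   t_p
#> 1 60       0.0432       0.0468        0.117 0.808 0.392
```

Reading the output: in this linked-mode cohort the observed stage-1
adjusted R² exceeds its permutation null, and stage 2 flags individual
rare SNPs (e.g. `r0017`) whose adjusted R² rises by > 0.1 once the
strong-LD tags in B \ A are admitted, with block-permutation p ≈ 0.005
(the minimum attainable with 200 permutations) — the signature of a rare
allele riding a haplotype background that only near-redundant tags
capture. Distribution-level means across all 60 rare SNPs barely move,
which is the expected picture: the benefit of strong-LD tags is
concentrated in a minority of rare variants.

`run_pipeline()` also writes everything as TSV (`stage1_results.tsv`,
`stage1_null_comparison.tsv`, `stage2_results_*.tsv`,
`table1_summary.tsv`, `figure2_points.tsv`, ...) plus the resolved
`config.json` and a run `manifest.json`; two runs with the same seed are
byte-identical.

## Command line

```sh
Rscript inst/scripts/raretag.R all --config cfg.json --out run_dir --seed 7
# subcommands: simulate | stage1 | stage2 | report | all
```

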
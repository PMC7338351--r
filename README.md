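# epiboost

Case-control disease risk prediction from **networks of interacting
genetic variants (SNPs) and demographic risk factors**, discovered with a
gradient-boosted-tree wrapper around greedy forward feature selection.

## Who this is for

Statistical geneticists and biostatisticians working with case-control
cohorts that carry both a genotype matrix (additively coded SNPs) and
epidemiological covariates — e.g. breast-cancer cohorts with
familial-history ("group 1") and oestrogen-metabolism ("group 2") risk
factors — who want to move beyond per-feature association tests and
additive polygenic risk scores and ask which *combinations* of SNPs and
covariates jointly predict disease.

## The method

For every split of a repeated stratified cross-validation plan
(`k1` repetitions × `k2` folds; train / validation / test disjoint):

1. an XGBoost classifier (logistic loss) fit on all SNPs of the training
   set ranks them by total split-gain importance;
2. the top-`m` SNPs are concatenated with a demographic feature group to
   form an ordered candidate list;
3. a greedy adaptive search scans the candidates, refitting from scratch
   and keeping a candidate iff validation average precision improves —
   yielding one **network of interacting features** per split;
4. the network is refit on train + validation and scored on the test fold
   by average precision,

$$\mathrm{AP} = \sum_i (\mathrm{recall}_i - \mathrm{recall}_{i-1}) \times \mathrm{precision}_i ,$$

with the per-split APs aggregated into a mean average precision
(mAP ± sd). Cross-split selection counts identify stable features, and
leave-one-feature-out refitting prices each selected feature as the mean
relative change in test AP.

The package also ships the comparison systems (polygenic risk score
`score_s = Σ_j d_sj ln OR_j` from a published SNP/odds-ratio table;
fixed-feature and group-only boosted models), per-feature chi-squared /
t-test association tables, a synthetic cohort generator with known ground
truth (logistic disease model with main effects, SNP×SNP epistasis and
SNP×demographic interactions), and SNP→gene annotation within a ±5,000 bp
window with gene-network export (GraphML/TSV).

## Worked example

Simulate a cohort with one causal SNP (main effect + epistatic partner)
and one informative demographic feature, then discover the networks:

```r
library(epiboost)

dems <- list(
  list(name = "fam_cancer", kind = "categorical", group = "group1",
       probs = c(0.55, 0.45)),
  list(name = "oestrogen_exposure", kind = "continuous", group = "group2",
       mean = 50, sd = 15))
effects <- list(
  effect_term("main_snp", "snp0001", 0.8),
  effect_term("snp_snp", c("snp0001", "snp0002"), 0.8),
  effect_term("main_demog", "fam_cancer", 0.8))
spec <- synthetic_spec(n_subjects = 500, n_snps = 100,
                       demographics = dems, effects = effects,
                       fixed_mafs = c(snp0001 = 0.3, snp0002 = 0.3),
                       seed = 42)
g <- generate_cohort(spec)

fit <- epiboost(g$cohort, group = "both", m = 10, k1 = 2, k2 = 3,
                params = hyperparams(n_trees = 100, tree_depth = 3,
                                     learning_rate = 0.1,
                                     subsample_rate = 0.8,
                                     min_child_weight = 1, alpha = 0),
                seed = 1)
summary(fit)
#> epiboost fit over 6 splits
#>   mAP  train 0.8693 | validation 0.7339 | test 0.7133 +/- 0.0376
#>   network size: median 6 (range 3-7)
#>   most-selected features (selection counts):
#> fam_cancer    snp0001    snp0024    snp0002    snp0012    snp0017    snp0030
#>          5          5          4          2          2          2          2

head(leave_one_out_importance(fit), 4)
#>      feature      source n_selected mean_rel_change flagged
#> 1    snp0021         snp          1     -0.06916469   FALSE
#> 2 fam_cancer demographic          5     -0.05536352   FALSE
#> 3    snp0001         snp          5     -0.04848109   FALSE
#> 4    snp0002         snp          2     -0.01717953   FALSE
```

The planted features dominate: `fam_cancer` and the causal `snp0001` are
selected in 5 of 6 splits (its epistatic partner `snp0002` in 2), the test
mAP of 0.71 clearly exceeds the cohort prevalence of 0.63, and removing
either planted feature from its networks costs ~5% of test AP
(`mean_rel_change < 0` = performance drop). Train AP exceeding test AP by
~0.16 is the expected overfitting direction at this sample size.

Cohorts can equally be read from files: a genotype TSV (or VCF via
`read_genotypes(..., format = "vcf")`), a demographic TSV plus a schema TSV
declaring each feature's kind and group, and a labels TSV — see
`?read_cohort`. A thin command-line wrapper over these functions lives at
`inst/scripts/epiboost-cli.R` (subcommands `simulate`, `run`, `associate`,
`prs`, `annotate`).

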
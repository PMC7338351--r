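---
title: "Discovering interacting genetic and demographic risk-factor networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering interacting genetic and demographic risk-factor networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Case-control risk prediction from genotypes and epidemiological covariates
usually proceeds one feature family at a time: a polygenic risk score (PRS)
aggregates published risk alleles under an additive, independence-assuming
model, while demographic risk factors are assessed with per-feature
association tests or linear regressions. Neither construction can express
the joint, non-additive effects — SNP x SNP epistasis or SNP x environment
interplay — that a multifactorial disease plausibly involves.

`epiboost` implements a wrapper-style discovery procedure around a gradient
boosted decision-tree classifier (XGBoost with logistic loss). Boosted trees
natively model non-linear, non-additive structure, so the split-gain
importance of a fitted ensemble is a cheap screen for candidate predictive
SNPs, and refitting the ensemble on candidate subsets prices the marginal
value of each feature in the company of the others. One run of the central
fitting function `epiboost()` performs, for every split of a repeated
stratified cross-validation plan:

1. **Screening.** Fit one ensemble on all SNPs of the training set and rank
   them by total split-gain importance.
2. **Candidate formation.** Concatenate the top-`m` SNPs (rank order) with
   one demographic feature group (table order): familial-history features
   ("group 1"), oestrogen-metabolism features ("group 2"), or both.
3. **Adaptive search.** Greedy forward selection over the candidate list:
   start from the top candidate; admit each subsequent candidate iff
   refitting from scratch on the enlarged set improves validation average
   precision by more than `epsilon`. The selected subset is one *network of
   interacting features*: the features justify their place jointly, not
   marginally.
4. **Evaluation.** Refit on train + validation with the selected network and
   score average precision (AP) on the untouched test fold.

The per-split test APs aggregate into a mean average precision (mAP) with a
sample standard deviation, the cross-split selection counts identify stable
features, and `leave_one_out_importance()` prices each selected feature by
the mean relative change in test AP when it is removed and the model is
refit without it.

Average precision is used throughout because case/control cohorts are
typically imbalanced; AP is the recall-increment-weighted mean of precision
over score cut-offs,

$$\mathrm{AP} = \sum_i (\mathrm{recall}_i - \mathrm{recall}_{i-1})\,
\mathrm{precision}_i ,$$

a number in [0, 1] summarising the precision-recall curve.

## Cross-validation geometry

`make_splits(labels, k1, k2, seed)` builds `k1` independent stratified
`k2`-fold partitions. Within each repetition, each outer fold is the test
set once (so with `k2 = 5` the non-test portion is 80% of subjects, the
standard 80:20 geometry), and one stratified inner fold (1/`k2`) of the
non-test portion is withheld as the validation set that steers the adaptive
search. Train, validation and test are pairwise disjoint within every
(repetition, fold) pair — the search never sees test subjects, and min-max
scalers for continuous features are fitted on the training subjects only
and applied (with clipping to [0, 1]) elsewhere. The defaults `k1 = 10`,
`k2 = 5` give 50 networks per run; on a 445-case / 250-control cohort every
test fold has 139 +/- 1 subjects with 89 +/- 1 cases.

Hyperparameters can be tuned per repetition (default geometry of the
tuning-once-per-iteration protocol), per fold, or fixed. Sequential tuning
(`tune_sequential()`) first grid-searches the (trees, depth, learning-rate)
triple jointly with stratified 5-fold CV on the training set, then
optimises subsampling rate, minimum child weight, gamma, alpha and the
positive-class weight one at a time in that order, each stage holding
earlier winners fixed. The criterion is cross-validated AP (configurable to
log-likelihood; the reporting metric is the natural default). Ties break
deterministically towards the simpler model — fewer trees, shallower
trees, lower learning rate, then the larger (more regularising) candidate
in the single-parameter stages — so tuning is reproducible bit-for-bit.
The default search ranges are: trees {50..300 by 50}, depth {2, 4, 6, 8},
learning rate {0.001, 0.01, 0.1}, subsampling {0.1..1 by 0.1}, minimum
child weight {0..5}, gamma {0..9}, alpha {1e-5..100}, positive-class
weight {0.56, 1} — 0.56 being the control/case ratio of a 250/445 cohort.

## Tunable parameters that matter

* `m` (count, default 18; 15 when both demographic groups are used): the
  number of top-ranked SNPs admitted as candidates. Too small starves the
  search of genetic signal; too large dilutes it with ranking noise and
  multiplies refits. `sensitivity_sweep(axis = "top_m")` traces the curve.
* `epsilon` (AP units, default 0): the strict-improvement threshold of the
  greedy acceptance. Zero admits any genuine improvement; positive values
  buy sparser networks at the price of recall of weak interactors.
* `k1` (default 10): repetitions. The mAP's standard error shrinks roughly
  as `1/sqrt(k1 * k2)`; past ~10 repetitions the estimate plateaus
  (`sensitivity_sweep(axis = "repetitions")`).
* Booster settings (`hyperparams()`): defaults are a tuned setting found
  repeatedly on genotype data of this shape — 200 trees of depth 2,
  learning rate 0.01, 40% row subsampling (without replacement), alpha 2,
  no class reweighting. For small synthetic cohorts the test suite uses
  fewer, slightly deeper trees at learning rate 0.1, which the sequential
  tuner also reaches on such data.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws genotypes as Binomial(2, MAF) with per-SNP MAF
uniform on `maf_range` (optionally pinned per SNP via `fixed_mafs`, and
optionally correlated in equicorrelated Gaussian-copula blocks to mimic
linkage disequilibrium). Demographics follow declared categorical or normal
distributions. Disease labels follow a logistic model whose linear
predictor sums main effects and *products of mean-centred* feature values
for interaction terms; centring keeps interactions orthogonal to main
effects in expectation, so a planted pure-epistasis term carries almost no
marginal single-SNP signal — exactly the signal class the pipeline exists
to find. Main-effect features are also centred, which keeps the intercept
interpretable as the population logit prevalence; `calibrate_intercept()`
root-finds the intercept against a Monte-Carlo prevalence estimate when
`intercept = "auto"`. The default target prevalence is 445/695 ≈ 0.64,
mirroring the motivating cohort's class balance.

`emulate_kbcp_margins()` draws the 9 familial-history and 11
oestrogen-metabolism features class-conditionally from their published
case/control marginals (category proportions; mean/sd normals for
continuous features), plus label-independent null genotypes. It reproduces
*marginals only*: the joint dependence among demographic features (e.g.
between contraceptive use and its duration) is not modelled, continuous
features are unbounded normals rather than non-negative durations, and the
null genotypes carry no population structure. Consequently, passing tests
on emulated cohorts validate bookkeeping, association-test output and the
direction of group-level signal — not any published performance number,
which would require the restricted original data.

The reference planted-signal design used by the acceptance checks is: 700
subjects, 500 null SNPs plus 3 causal SNPs at MAF 0.3 with per-allele
log-odds 0.8 (OR ≈ 2.2) and all three pairwise epistatic terms at 0.8, and
4 demographic features of which 2 are informative (a familial-history
indicator at log-odds 0.8 and a continuous oestrogen-exposure feature at
0.045 per unit, ≈ 0.68 per SD), one of them also interacting with a causal
SNP. Effect sizes sit at the strong end of what interaction-detection
simulation studies use, by design: with ~310 training subjects per split
and only 9 selection rounds (k1 = k2 = 3), a per-allele OR around 2 is what
gives a marginal detection z-statistic near 4 — comfortably above the
expected extreme of 500 null association statistics — so that recovery
failures indict the implementation rather than the power of the design.
These problem sizes (and the reduced k1, k2) are also what keeps a full
acceptance run in the seconds-to-minutes range.

## Numerical choices and degenerate inputs

* **Missing genotypes.** Any SNP column containing a missing call is
  excluded before modelling (reported, not imputed); per-call imputation is
  out of scope. Missing demographic values become an explicit extra
  category (categorical) or the training-subset median (continuous).
* **Precision at zero predicted positives** is defined as 1. It anchors the
  PR curve at (0, 1); its recall-increment weight is 0, so AP is unchanged.
* **Tied scores** collapse into a single cut-off, making AP invariant to
  the ordering of ties and to strictly monotone score transforms.
* **Constant scores** yield a single cut-off with precision = prevalence,
  recall = 1, hence AP = prevalence — also the baseline reported when
  leave-one-out removal empties a single-feature network (flagged).
* **Association tests** use the chi-squared test with Yates continuity
  correction for 2x2 tables (none for larger ones) and the Welch t-test
  for continuous features; both configurable, no multiplicity adjustment.
  Features with a single observed category are skipped with a note.
* **Mis-declared minor alleles** (empirical MAF > 0.5) are reported via
  warning, never silently flipped.
* **Gene windows.** A gene maps to a SNP when at most `window` (default
  5,000) bases lie strictly between them — boundary included, strand
  ignored, since the window is defined around the SNP. BED input is
  converted from 0-based half-open to the 1-based inclusive convention at
  the boundary.
* **Degenerate min-max scalers** (constant training column) map everything
  to 0; out-of-range values clip to [0, 1].

## Open design points, resolved

* The adaptive search is fixed as *greedy forward selection in rank order
  with strict-improvement acceptance* — the simplest procedure consistent
  with "iterative search maximising validation accuracy", auditable
  against an exhaustive-subset oracle on small candidate lists (the test
  suite does exactly that). Backward elimination steps are deliberately
  not taken: whether the original procedure removed previously accepted
  features is not decidable from its description, and forward-only keeps
  the acceptance trace monotone and the runtime bounded by one refit per
  examined candidate.
* Importance for screening is *total split gain* (configurable to cover or
  frequency): gain is the loss-reduction notion that matches "importance to
  prediction accuracy"; zero-importance features keep their input order at
  the tail of the ranking.
* Tuning happens once per repetition by default (one setting per
  iteration), not per fold; `tune = "per_fold"` is available.
* The final per-split model is refit on train + validation before test
  scoring — the standard use of all non-test data once model selection is
  finished.
* The PRS is the raw weighted dosage sum `sum_j d_j ln(OR_j)` evaluated as
  a ranking statistic, with the dosage flipped (`2 - code`) when the effect
  allele is the declared major allele; no centring, standardisation or
  refitting, matching a score that is *derived* rather than trained.

## Known limitations

* Runtime grows linearly in candidates x splits (one refit per examined
  candidate per split, by design — no warm starts); genome-scale panels
  are screened once per split but the search should stay at tens of
  candidates.
* The synthetic generator is not a population-genetic simulator: no
  Hardy-Weinberg violations, no realistic LD decay (only block
  equicorrelation), no covariate-genotype confounding.
* Selection counts are descriptive; no formal significance is attached to
  a feature being selected in many splits.
* The greedy search can miss interacting sets whose members help only
  jointly and never singly from the scan order; the exhaustive-oracle gap
  is reported in the tests for small candidate lists.
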
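---
title: "Benchmarking and interpreting OTU-based classifiers"
author: "otubench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking and interpreting OTU-based classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otubench)
```

# The task and the evaluation model

`otubench` evaluates binary classifiers on samples-by-OTU abundance
tables, the setting typified by screening colonoscopy cohorts: a few
hundred subjects, thousands of OTUs (p ≫ n), sparse non-negative counts,
and a clinically defined positive class (screen relevant neoplasia, SRN =
advanced adenoma or carcinoma; everyone else, including nonadvanced
adenomas, counts as healthy). The class encoding is fixed package-wide:
`healthy` is the first factor level, `SRN` the second, and every score,
weight sign and AUROC refers to that orientation.

A single train/test split estimates generalization performance with high
variance — one lucky or unlucky split can move the held-out AUROC by more
than 0.2. The protocol therefore repeats the entire model-selection
procedure over many random splits:

1. **Stratified holdout.** Per class, `ceiling(trainFraction * n_c)`
   samples go to training. Ceiling allocation is deliberate: applied to a
   261/229 cohort at 0.8 it produces the canonical 393-sample training set
   with 184 SRN and 97-sample test set with 45 SRN, which round-half
   allocation would not (it would assign 183 cases).
2. **Grid search by cvAUC.** Every hyperparameter setting is scored by the
   unweighted mean AUROC over `k × repeats` stratified CV folds (folds
   differ by at most one sample, so unweighted and weighted means agree to
   rounding, and averaging over folds-then-repeats or all folds at once is
   identical — which is why unweighted averaging is mandated). Exact ties
   are broken toward the more regularized setting — smaller cost, narrower
   RBF kernel, shallower tree, fewer features per split, smaller learning
   rate — on the principle that equal evidence should not buy complexity.
3. **Final fit and held-out evaluation.** The chosen setting is refit on
   the full training set and scored once on the untouched test set.

Split `s` runs under seed `baseSeed + s`. No state is shared between
splits, so results are identical whether splits run sequentially or
concurrently, and any single split can be re-derived alone.

The CV repeat count is configurable (`cvRepeats`, default 10); the
protocol's source only states that five-fold CV was "repeated". All
examples below and the package defaults use `k = 5`.

# Preprocessing and its known caveat

Counts are rarefied once per sample (without replacement, seeded) to a
common depth — by default the smallest sample total — and each OTU is then
min-max scaled so its largest abundance across samples is 1 and its
smallest 0. Constant OTU columns cannot satisfy "highest → 1" and are
mapped to all zeros, keeping them inert rather than erroring on real
sparse tables.

Following the original protocol, normalization statistics are computed on
the **whole** table before splitting. This leaks test-sample minima/maxima
into training — a mild but real optimism — and is recorded in the run
manifest. `normalizeWithinTrain = TRUE` switches to computing min/max on
each split's training rows and applying them (clipped to [0, 1]) to that
split's test rows; we expose rather than default to it so that results
remain comparable with the published protocol.

# The seven families and their scores

| name | linearity | tuned |
|---|---|---|
| `l2_logistic` | linear | cost |
| `l1_svm_linear` | linear | cost |
| `l2_svm_linear` | linear | cost |
| `svm_rbf` | nonlinear | cost, sigma |
| `decision_tree` | nonlinear | maxdepth |
| `random_forest` | nonlinear | mtryFactor |
| `xgboost` | nonlinear | eta, subsample |

All families must emit a *continuous* decision score per sample (margin,
link or probability — AUROC is invariant to any strictly increasing
transform, so these are interchangeable); hard 0/1 predictions are never
fed to the AUROC. Linear families additionally expose a signed weight per
OTU.

Implementation notes and conventions:

- `cost` follows the "larger C = weaker regularization" convention. For
  the ridge logistic model the glmnet penalty is set to
  `lambda = 1/(n · cost)`, which makes the two parameterizations of the
  penalized likelihood coincide.
- The linear SVMs minimize the squared-hinge loss with an L1 or L2 weight
  penalty (the LiblineaR-style primal), solved internally by proximal
  gradient (FISTA, soft-thresholding, unpenalized intercept) for L1 and
  L-BFGS for L2. The squared hinge keeps the loss differentiable; the L1
  path yields exactly-zero weights, which the weight-rank interpretation
  treats as sign 0.
- The RBF kernel is `exp(-sigma · ||u − v||²)`; beware that some libraries
  call `1/(2σ²)` by the same name. Decision-value orientation from the
  underlying libsvm fit is resolved explicitly against the positive class.
- The forest's features-per-split grid is expressed relative to the usual
  default, `mtry = round(mtryFactor · sqrt(p))`, so one grid serves any
  table width. Forest and boosting fits receive the split seed and a
  single thread, making every `SplitResult` exactly re-derivable.
- Exact default grid values (log-ladders `1e-4..1e2` for cost,
  `1e-4..1` for sigma, depths 1–8, `mtryFactor` {0.5, 1, 2}, `eta`
  {0.01, 0.1, 0.3} × `subsample` {0.5, 0.75, 1}) are package choices
  — published protocols of this kind tune by starting granular and
  narrowing — and every grid is overridable per run (`grids =`).

# Interpretation

**Weight ranks (linear models).** Within each split, features are ranked
by descending |w| (average ranks on exact ties); a feature's aggregate
rank is the median across splits, and reporting order on tied medians is
alphabetical by feature id, so outputs are deterministic. Signs are read
directly from the weights: negative = associated with the healthy class,
positive = with SRN.

**Grouped permutation importance (any model).** Microbial abundance
tables contain OTUs in perfect lockstep (sub-OTUs of one organism,
plasmid/chromosome copies, artifacts of clustering). Permuting such
columns one at a time understates their joint importance because the
model can lean on the intact twin. The package therefore first partitions
features with `findPerfectGroups()`: Spearman correlation (midranks on
ties) equal to 1 within `1e-12`, p-value below 0.01, merged by transitive
closure (exact ρ = 1 is transitive, so the closure is consistent).
With ρ = 1 and n ≥ 5 the p-value — `2/n!` exactly for n ≤ 10, the
t-approximation beyond — is always far below 0.01, so the operative
filter is the correlation tolerance; the p-threshold only matters when
the correlation threshold is lowered (`correlationThreshold`, a knob we
expose but default to 1). Two all-zero columns have no defined rank
correlation and stay singletons by decision. Anticorrelated pairs
(ρ = −1) are never grouped.

Each group is then permuted jointly — one row shuffle applied to all
member columns of the held-out test rows, preserving within-group
alignment — the model rescored, and the AUROC drop recorded; `nPerms`
(default 30; the source protocol does not state its count) permutation
draws are summarized by their median, and medians are aggregated across
splits. Negative drops occur by chance on small test sets and are
reported as is. With all-singleton groups the procedure reduces exactly
to classic permutation importance.

# Model comparison

Two models are compared by their per-split AUROC differences, paired by
`split_id` (mismatched split sets are an error — silent intersection
would quietly change the statistic). The empirical p-value is
`min(1, 2 × min(frac(diff ≥ 0), frac(diff ≤ 0)))`; zeros count toward
both tails exactly as the formula reads, so a model compared with itself
yields p = 1 (capped). The statistic's resolution is `2/n_splits`; a
computed 0 is printed as "< 2/n" in human-readable output and left as 0
in machine-readable tables.

# The synthetic generator

`generateSyntheticOtus()` emulates the statistical structure the pipeline
assumes, at any scale:

- a log-normal baseline mean profile (meanlog 0, sdlog 1.5) gives
  heavy-tailed abundances: a few dominant OTUs, a long tail of rare ones;
- reads are allocated multinomially at a per-sample depth drawn uniformly
  from [0.8, 1.2] × `depthMean`, so rarefaction has real work to do and
  counts inherit a compositional constraint;
- informative features have their expected abundance multiplied by
  `effectSize` in cases (`effectSize = 1` makes the class-conditional
  distributions identical by construction);
- each entry of `blockSizes` replicates one source feature into exact
  monotone copies (parent × distinct positive integers), guaranteeing
  pairwise Spearman ρ = 1, so the grouping stage is exactly testable;
  `blockNoise > 0` weakens this for robustness experiments. Block parents
  are drawn from the informative features first, so collinearity
  interacts with the class signal — the situation grouped permutation
  importance exists for;
- `sparsity` zeroes non-block entries independently, on top of the
  structural zeros the multinomial already produces;
- exactly `round(caseFraction × nSamples)` samples are cases; everything
  is reproducible from `seed`.

Defaults mirror the motivating cohort: 490 samples, 6,920 OTUs, case
fraction 229/490, 432 OTUs inside perfect-correlation blocks (144 blocks
of 3), mean depth 10,000. Where the motivating study fixes no value
(`nInformative = 50`, `effectSize = 4`, `sparsity = 0.5`) we chose once
what we consider realistic for a moderate clinical signal and do not
tune these to outcomes.

What the generator does **not** emulate: phylogenetic correlation
structure, over-dispersion beyond the log-normal mixing, batch effects,
and sub-perfect correlation blocks. Passing tests on synthetic data
therefore demonstrate the *machinery* — calibration on null data, signal
recovery, grouping, determinism — not performance on any real cohort.

# Numerical conventions and degenerate inputs

- Quartiles and IQRs use linear interpolation (R's quantile type 7)
  throughout, so summaries are reproducible across implementations.
- AUROC is the rank-based (Mann–Whitney) form with midrank ties; it
  errors on single-class inputs rather than returning NA.
- Rarefaction errors, naming the offending samples, when any sample total
  is below the requested depth; dropping such samples is the caller's
  explicit decision.
- Tables never reorder samples or features implicitly; score vectors
  follow their input order, and feature-name mismatches are reconciled by
  name or rejected.
- Outlier flagging for plots (outside 1.5 × IQR) never feeds back into
  any computation.

# Problem sizes used in the shipped tests

The test suite exercises the full pipeline at desk scale — tables of
50–400 samples and 10–200 features, 2–10 splits, reduced grids — chosen
so the statistical claims under test (null calibration within
[0.40, 0.60], signal recovery above 0.9 AUROC, a median cv/test gap below
0.05 at n = 400, exact block recovery) are decidable in minutes on one
CPU. The acceptance checks of the protocol's printed cohort arithmetic
are exact and instantaneous.

# Known limitations

- The default global normalization leaks test extrema by design fidelity
  (see above); use `normalizeWithinTrain = TRUE` for leakage-free runs.
- Empirical p-values cannot resolve below `2/n_splits`; with 100 splits
  the floor is 0.02, and no continuity correction is applied.
- The grouping stage is quadratic in the number of features (a full
  Spearman matrix); at ~7,000 OTUs this is a few hundred MB of doubles —
  fine on a workstation, but not streaming-scale.
- No multiclass or regression targets, no deep learning, no AUPRC or
  calibration analysis; grouped/blocked splitting for repeated-measures
  designs is out of scope.
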
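---
title: "Methods: cross-ancestry signature-gene discovery for statin response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-ancestry signature-gene discovery for statin response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(statinsig)
```

## Overview

`statinsig` discovers genes whose statin-induced expression change
separates clinical high from low LDL-cholesterol responders, validates the
signature across ancestry cohorts with a kernel classifier, and tests the
panel against lipid phenotypes. This vignette records the statistical model
behind each stage, the tunable parameters and their defaults, the
synthetic-data generator's design, and the numerical conventions — the
things a maintainer would otherwise have to reverse-engineer from the code.

The pipeline assumes its input is already variance stabilized (an
approximately log2-scale transform of RNA-seq counts with stabilized
variance) for the same samples under two exposures, statin and control.
Alignment, library-size adjustment and variance stabilization are upstream
of this package.

## Delta expression and normalization

The unit of analysis is the per-sample difference
`delta = statin − control` of variance-stabilized values
(`compute_delta()`), a within-sample contrast that cancels each sample's
baseline expression. The stages then run in a fixed order:

1. quantile normalization of the delta matrix across samples,
2. least-squares regression of each gene on the experiment batch factor
   (residuals re-centered to the gene's mean),
3. PCA of the between-sample covariance,
4. regression of each gene on the leading k score columns,
5. quantile re-normalization of the residuals.

`quantile_normalize()` maps every column onto the mean of the column-wise
order statistics. Ties within a column receive the **mean of the reference
values their ranks span** — the common convention; note this differs
slightly from interpolation-at-average-rank implementations on three-way
and larger ties. The operation is idempotent, column-exchangeable, and
preserves within-column rank order; the test suite cross-checks it against
`limma::normalizeQuantiles()` on tie-free data.

## PC correction of hidden confounders

Expression changes carry structure from unmeasured technical and biological
sources. `pca_samples()` gene-centers the matrix and eigendecomposes the
sample × sample covariance; the leading score columns serve as confounder
proxies. Two rules are provided:

* `select_n_pcs()` — keep components while each still explains ≥ 0.5 % of
  variance (`threshold = 0.005`), capped at 25;
* `pc_correction_sweep()` — produce all corrected datasets for
  k = 1..k_max and let the downstream cross-ancestry AUC pick k
  empirically (`pc_sweep_eval()`).

Design choices that were genuinely open:

* **One PCA, reused for every k.** "Progressive" removal is implemented as
  a single joint regression on score columns 1..k per dataset; because the
  score columns are orthogonal this equals sequential removal, and it is
  deterministic and fast. Re-estimating the PCA after each removal is
  available (`recompute_pca = TRUE` / `recompute_pca_per_k`), off by
  default.
* **PCA on the combined cohorts** (both ancestries), before any split:
  the confounders are shared by design of the assay, and the validation
  cohort is too small (26 samples) to estimate its own rotation.
* **Gene-wise centering** before the covariance: an uncentered covariance
  would let gene-level mean differences masquerade as a leading component.
* `remove_pcs(..., k = 0)` returns the quantile-normalized input without
  touching gene means (no intercept-only regression), so "no correction"
  is exactly the normalized data.

`pc_covariate_diagnostics()` quantifies residual confounding: Spearman
correlation of each leading PC with numeric covariates, Kruskal–Wallis for
categorical ones. On well-corrected data these associations collapse toward
the null; constant covariates are flagged rather than tested.

## The signature statistic

For gene *i* with high/low responder means `x̄_H(i)`, `x̄_L(i)` and pooled
two-sample standard error

```
s(i) = sqrt( (1/n_H + 1/n_L) · (SS_H + SS_L) / (n_H + n_L − 2) ),
```

the moderated relative difference is

```
d(i) = (x̄_H(i) − x̄_L(i)) / (s(i) + s0).
```

With `s0 = 0`, `d(i)` is exactly the pooled two-sample t statistic (the
suite asserts equality to 1e-10 against `stats::t.test`). The fudge factor
`s0` keeps low-variance genes from dominating the ranking: it is chosen by
coefficient-of-variation minimisation (`estimate_s0()`, method
`"cv_min"`): candidates are the 0, 5, …, 100th percentiles of `{s(i)}`;
for each, genes are binned into ~100 equal-count windows by `s(i)` (never
fewer than 20 genes per window at realistic sizes) and the candidate
minimising the CV of the per-window median absolute deviation of `d` wins,
ties to the smallest candidate. Percentile and fixed overrides
(`method = "percentile"`, `"fixed"`) are provided because the recipe is a
convention, not a law.

### Permutation p-values

`permutation_pvalues()` permutes the high/low labels uniformly over the
**labeled samples only** (unlabeled "none" samples never enter the
statistic), recomputes `d` for every gene with `s0` held at its
observed-data value (so the statistic's scale is comparable across
permutations), and reports

```
p(i) = #{ b : |d_b(i)| ≥ |d_obs(i)| } / B .
```

Two-sided inference via |d| throughout. A gene whose observed |d| exceeds
all B permuted values is reported at `p_empirical = 0` with
`floor_flag = TRUE`: its p-value is below the scheme's resolution floor
`1/B` (0.0002 at the default B = 5000), which is stored as the `p_floor`
attribute. When fewer than B distinct label assignments exist the function
warns and resamples with repetition. `pool_null = TRUE` optionally compares
each gene against the null values pooled across all genes (resolution
`1/(B·n_genes)`), at the cost of assuming exchangeable null distributions
across genes; it is off by default.

Ranking is by |d| descending with ties broken by gene id, so `top_k_genes()`
is fully deterministic.

## Cross-ancestry classification

The validation question is whether the discovery-cohort signature separates
high from low responders in the *other* ancestry. `repeated_split_eval()`
draws, per repeat, a fresh class-stratified partition of the validation
samples into 10 folds, trains a radial-basis-kernel SVM (`kernlab::ksvm`,
C-classification, cost 1) on nine folds and scores the held-out fold;
decision scores and labels accumulate over `n_repeats` test folds into one
pool, summarised by a single ROC curve and AUC. Conventions:

* **Kernel width.** `kpar = "automatic"` subsamples and is therefore not
  reproducible; instead the RBF inverse-width defaults to the median
  heuristic, `sigma = 1 / median(pairwise squared Euclidean distance)`,
  computed once per evaluation. Cost and sigma are exposed.
* **One test fold per repeat**, not a full 10-fold pass; `n_repeats`
  counts pooled test folds.
* **Pooling** of scores across repeats (rather than averaging per-repeat
  AUCs) uses every score exactly as produced and keeps the ROC estimate
  stable for 26-sample cohorts, where single-fold ROCs would rest on 2–3
  samples.
* **Stratification** is enforced (12 vs 14 is small enough that unlucky
  unstratified folds would be single-class); with classes smaller than the
  fold count the function falls back to plain random partitions with a
  warning.
* Decision scores are oriented so larger = more "high responder",
  regardless of factor-level order.
* `train_on_discovery = TRUE` switches to the alternative reading of
  cross-ancestry validation — train once on the discovery tails, score the
  validation cohort — and is off by default, matching the repeated-split
  description of the evaluation.

`roc_curve()` sweeps thresholds from high to low, advancing both
coordinates jointly on tied scores; `auc()` is the tie-corrected rank
(Mann–Whitney) statistic, identical to the trapezoidal area under the
curve. Both are asserted against brute-force oracles (exhaustive threshold
enumeration; all-pairs counting) and against `pROC` in the suite.

`pc_sweep_eval()` and `gene_count_sweep()` wrap the evaluation into the two
model-refinement loops (AUC vs correction depth at a fixed 100-gene panel;
AUC vs panel size at the chosen depth, signature computed once and panels
nested). Arg-max ties resolve to the smaller k or n.

## Phenotype association

Clinical changes enter as delta-log measures,
`ln(mean(on-treatment)) − ln(mean(pre-treatment))`
(`delta_log_phenotype()`; natural log — every downstream use is rank-based,
so the base is inert). `panel_phenotype_scan()` computes Spearman's rho
between each panel gene's delta expression and a per-sample phenotype, with
the two-sided p from the t-approximation
`t = rho·sqrt((n−2)/(1−rho²))` (exact-permutation and Edgeworth variants
differ only in the second decimal at n ≈ 100), then Bonferroni-adjusts over
the panel size. `group_difference_test()` (pooled two-sample t) covers the
high-vs-low phenotype contrasts, and `residualize()` provides the optional
covariate pre-adjustment (e.g. LDLC change on age and smoking) as
least-squares residuals re-centered to the mean.

## The synthetic-data generator

The real study data are controlled-access, so the generator is the
package's test bed. It emulates the study design, not the biology:

* **Cohorts** (`simulate_cohort()`): 25/25 European American high/low tails
  (LDLC change −59.1 ± 3.9 % vs −22.2 ± 8.0 %), 12/14 African American
  tails (−57.5 ± 3.2 % vs −21.5 ± 6.5 %), plus 54 non-tail EA samples
  drawn uniformly between the tail ranges so the EA cohort totals 104. The
  tail invariants (every high value below every low value) are guaranteed;
  at the default spreads the enforcement path triggers with probability
  ~1e-8, leaving class means effectively unbiased.
* **Expression** (`simulate_expression()`): paired control/statin matrices
  whose difference follows
  `delta_gi = β_g z_i + Σ_k λ_gk f_ki + b_batch(i),g + ε_gi` with
  `z = ±1` for high/low (0 otherwise), `β_g = ±effect_size/2` at the
  planted genes (one shared sign and magnitude across ancestries — the
  premise of cross-ancestry replication), latent factors `f`, batch
  offsets `b`, and Gaussian noise `ε`. This linear latent-factor model is
  the simplest structure under which PC correction is both necessary and
  sufficient. Gene-level mean shifts are omitted (they are removed by
  quantile normalization and cancel in the class contrast).
* **Covariates**: age, sex, smoking and batch each share a latent liability
  with one of the confounding factors at correlation
  `covariate_confounder_corr` (default 0.5), so the PC–covariate
  diagnostic has something real to detect and to watch fade with
  correction.
* **Cholesterol phenotypes** (`simulate_cholesterol()`): the
  cholesterol-ester delta is coupled to the designated signature gene's
  *biological* statin response (its class effect plus biological noise,
  excluding technical confounder and batch components — a lab-measured
  lipid shares the gene's biology, not the RNA-seq assay's artifacts),
  plus a responder-class offset (high responders deplete stored
  cholesterol ester more) and noise; the free-cholesterol delta is pure
  noise and serves as the negative control.

Default parameters, chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 2000 | enough for stable s0 windows and permutation nulls at desk scale |
| `n_signature` | 80 | the panel-size scale at which refinement operates |
| `effect_size` | 1.5 (× `noise_sd`) | clearly detectable at 25v25 after correction, invisible under the confounders without it |
| `noise_sd` | 1 | sets the variance-stabilized unit scale |
| `n_confounders` | 3 | few dominant hidden factors, the regime PC correction addresses |
| `confounder_loading_sd` | 3 | each factor carries ~9× the noise variance per gene, so the leading PCs each explain ~30 % of variance — strong technical structure, making the uncorrected analysis genuinely confounded |
| `batch_effect_sd` | 0.5 | a visible but secondary batch term for the regression stage |
| `ce_coupling` | −0.55 | with `ce_noise_sd = 1` and the class offset, the observable corrected-data association has median \|rho\| ≈ 0.43, inside the 0.25–0.45 calibration band; the upper half of the band is needed for the coupled gene to out-rank 81 near-null competitor correlations at n ≈ 104 with high probability |
| `ce_class_offset` | 0.25 | reproduces the high-vs-low group difference in cholesterol-ester change without handing every signature gene a dominant shared association path |

What the generator does **not** emulate: count-level sampling (data are
Gaussian on the variance-stabilized scale), gene–gene correlation beyond
the shared factors, heavy-tailed or heteroskedastic noise, ancestry-specific
effect sizes, and any pharmacokinetics. Passing tests therefore demonstrate
that the pipeline recovers planted structure under its own model
assumptions — not that those assumptions hold for any particular real
dataset.

## Numerical conventions and degenerate inputs

* Ties: quantile normalization — mean of spanned reference values;
  ranking — |d| then gene id; tail labelling — lexicographic sample id;
  arg-max over sweeps — smallest k / n; `estimate_s0` — smallest candidate.
* `s + s0 = 0` genes are flagged and carry `NA` statistics rather than
  infinities; constant covariates and constant association inputs are
  flagged, not tested.
* Identical groups give `t = 0, p = 1` in `group_difference_test()`;
  `|rho| = 1` maps to `p = 0` in the Spearman t-approximation.
* All generator stages restore the caller's RNG state and derive their
  streams from `config$seed`, so every operation is a pure function of
  (inputs, seed) and `run_pipeline()` bundles are byte-reproducible (logs
  carry no timestamps).

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` exercise the pipeline at the
study's design scale where it matters — 2000 genes × 130 samples for the
25-dataset sweep, B = 5000 permutations for the p-value floor, 2000 pooled
test folds for the null AUC band — and at reduced sizes elsewhere (e.g.
200-fold repeated splits per sweep point, 400-gene studies for replicated
simulations), sizes chosen so the full suite completes in minutes on one
CPU while keeping every assertion statistically meaningful. The acceptance
script's own evaluation uses 200 pooled test folds per configuration.

## Known limitations

* The s0 recipe is one member of a family; published empirical-Bayes
  variants will rank borderline genes slightly differently.
* Permutation p-values are per-gene by default; the pooled-null option
  trades per-gene exactness for resolution.
* The SVM stage deliberately avoids hyperparameter search ("default
  settings"); AUC comparisons across configurations share those defaults,
  so they measure the features, not tuning.
* With 26 validation samples, pooled AUCs still carry non-trivial Monte
  Carlo error; sweeps should be read as coarse model selection, not
  precise effect estimates.
* The generator's Gaussian, factor-structured world is favourable to PCA;
  real confounders need not be linear or low-rank.
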
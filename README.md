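# statinsig

Cross-ancestry discovery of transcriptomic signature genes for statin
LDL-cholesterol response.

## The problem

Statins lower plasma LDL cholesterol (LDLC), but the response varies widely
between individuals. One way to look for transcriptomic predictors is to
expose patient-derived lymphoblastoid cell lines to statin or control buffer,
measure RNA-seq before and after, and ask which genes' *statin-induced
expression changes* differ between clinical **high responders** and **low
responders** (the tails of the LDLC percent-change distribution). Signature
genes discovered in one ancestry cohort (European American, 25 high / 25 low)
are then validated as classifier features in a second, independent ancestry
cohort (African American, 12 high / 14 low) — replication across ancestries
being far stronger evidence than a within-cohort fit.

`statinsig` implements that full analysis as a tested, reusable R pipeline:

1. **Delta expression** — statin minus control variance-stabilized values
   per gene and sample, quantile normalized and batch-regressed.
2. **PC correction** — the leading principal components of the
   between-sample covariance serve as proxies for hidden confounders and are
   progressively regressed out (k = 1..25 corrected datasets, each
   re-quantile-normalized), with PC–covariate diagnostics.
3. **Signature statistic** — the moderated relative difference

   d(i) = (x̄_H(i) − x̄_L(i)) / (s(i) + s₀),

   where x̄_H, x̄_L are the high/low group means of gene *i*'s delta
   expression, s(i) the pooled two-sample standard error, and s₀ a fudge
   factor chosen by coefficient-of-variation minimisation so that |d| is
   comparable across expression levels. Empirical p-values come from
   label permutations (floor 1/B with B = 5000: p < 0.0002).
4. **Cross-ancestry classification** — radial-basis-kernel SVMs
   (`kernlab`) on the top signature genes, evaluated by 5000 repeated
   stratified 9:1 splits of the validation cohort; pooled decision scores
   give one ROC curve and AUC per (number of PCs, panel size)
   configuration, from which the best correction depth and panel size are
   selected.
5. **Phenotype association** — Spearman correlation of each panel gene's
   delta expression with lipid phenotype changes (cellular cholesterol-ester
   delta, delta-log plasma lipids), Bonferroni-adjusted over the panel.

Because the original clinical data are controlled-access, the package ships
a synthetic-data generator (`simulate_study()`) that reproduces the study's
statistical structure — tail-selected two-ancestry cohorts, planted
signature genes, latent confounders correlated with covariates, a batch
effect, and one signature gene whose biological statin response is
negatively coupled to the cholesterol-ester change — so every stage is
testable end to end.

## Worked example

```r
library(statinsig)

cfg <- run_config(
  simulation  = simulation_config(seed = 1),   # 2000 genes, 104 EA + 26 AA
  k_max       = 10L,                           # correction depths 1..10
  B           = 1000L,                         # label permutations
  n_repeats   = 200L,                          # pooled test folds per AUC
  n_gene_grid = seq(60L, 100L, by = 5L))       # panel-size refinement
run <- run_pipeline(cfg)
#> run_pipeline: seed 1, simulation mode
#> PCA: 130 components; 0.5%-rule selects k = 3
#> PC sweep: 10 corrected datasets
#> best correction depth: k = 3 (AUC = 1.000)
#> best panel size: n = 60 (AUC = 1.000)
#> signature: s0 = 0.2727, 70 genes at the empirical-p floor 0.001
#> association: top gene g00015 (rho = -0.580, adjusted p = 6.62e-09)
```

The generator plants three latent confounders; the 0.5 %-of-variance rule
and the AUC sweep both recover depth k = 3, where the cross-ancestry
classifier separates the African American responder classes perfectly
(AUC = 1.000 — the planted effect, 1.5 noise SD per gene over a 60-gene
panel, is strong once confounders are removed). With too little correction
the same analysis fails:

```r
tidy(run$pc_sweep)
#> # A tibble: 10 × 3
#>    n_pcs n_genes   auc
#>  1     1     100 0.649
#>  2     2     100 0.895
#>  3     3     100 1
#>  4     4     100 0.908
#>  ...
```

The signature table carries the per-gene statistic and permutation p-values
(`tidy()`/`glance()` follow broom conventions):

```r
glance(run$signature)
#> # A tibble: 1 × 6
#>      s0 n_high n_low n_genes     B p_floor
#> 1 0.273     25    25    2000  1000   0.001
```

and the panel–phenotype scan identifies the planted cholesterol-ester
coupled gene as its only Bonferroni-significant hit:

```r
head(run$association, 3)
#> # A tibble: 3 × 7
#>   gene_id phenotype     n    rho    p_raw    p_adjusted m_tests
#> 1 g00015  ce_delta    104 -0.580 1.10e-10 0.00000000662      60
#> 2 g01728  ce_delta    104  0.247 1.15e- 2 0.691              60
#> 3 g01936  ce_delta    104 -0.240 1.40e- 2 0.840              60
```

`autoplot(run$pc_sweep)`, `autoplot(run$gene_sweep)` and
`autoplot(run$pc_sweep$evals[[run$best_k]])` draw the AUC sweeps and the
pooled ROC curve; `plot_gene_phenotype()` draws the association scatter.

All stages are exported individually (`compute_delta()`,
`quantile_normalize()`, `regress_out_batch()`, `pca_samples()`,
`remove_pcs()`, `compute_signature()`, `permutation_pvalues()`,
`repeated_split_eval()`, `pc_sweep_eval()`, `gene_count_sweep()`,
`panel_phenotype_scan()`, ...) and compose with the pipe; see the methods
vignette (`vignettes/signature-discovery.Rmd`) for the statistical details
and design choices.

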
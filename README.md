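# psionic

Patient-specific transcription-factor (TF) activity inference by multitask
regression of tumor expression on chromatin-accessibility-derived motif
features.

## The problem

Bulk RNA-seq measures what genes a tumor expresses but not which regulators
drive that expression. ATAC-seq on matched cell-line models maps the
accessible regulatory DNA, and motif scanning inside those accessible regions
says which TFs could act there. `psionic` connects the two: it summarizes,
for every gene, the best motif hit of each TF across the accessible regions
assigned to that gene (a gene x TF feature matrix **X**), and then regresses
each tumor's normalized expression profile **y**_t on **X**. The fitted
coefficient vector **w**_t is the tumor's inferred TF activity profile.

Fitting each tumor separately wastes the shared structure across tumors and
tumor types. `psionic` therefore fits all samples jointly: every tumor model
is a sparse linear combination of **K** shared *latent regulatory programs*,

```
W = L S,    w_t = L s_t
minimize over L, S:   sum_t (1/N) || y_t - X L s_t ||^2  +  mu ||S||_1  +  lambda ||L||_F^2
```

where **L** (TF x K) holds the programs, **S** (K x T) the per-tumor program
weights, `mu` controls how many programs each tumor uses, and `lambda` keeps
the program coefficients small. The model is fitted by alternating
minimization: the S-step is an exact per-task lasso (cyclic coordinate
descent), the L-step a closed-form ridge solve; the objective decreases
monotonically. A per-sample ridge baseline ("single-task learning", STL) is
included for comparison, along with held-out-gene cross-validation, two
feature-randomization negative controls, a promoter-only feature ablation,
downstream TF statistics (tumor-type associations with FDR, hierarchical
clustering of activities, phenotype correlations), and Kolmogorov-Smirnov
motif-shift enrichment on differential accessibility.

Everything is testable without external downloads: a seeded generator builds
synthetic regulatory genomes (gene models, peak atlases, motif hits) and
expression cohorts with planted (L, S) ground truth.

## Who it is for

Computational biologists with (a) a peak atlas (BED), (b) a gene table,
(c) FIMO-style motif hits per peak, and (d) a gene x sample expression
matrix, who want per-sample TF activities and the shared regulatory programs
of a multi-group cohort.

## Worked example

```r
library(psionic)

# a fully synthetic study: 1000 genes, 100 motifs, 60 samples in 5 groups,
# 4 planted latent programs, per-sample signal R^2 = 0.5
study <- simulate_default_study(seed = 1)

fit <- fit_psionic(study$X, study$Y, K = 4, seed = 1)
fit
#> <psionic_model> 100 TFs x 60 samples, K = 4 programs
#>   mu = 0.001, lambda = 0.001; 135 iterations (converged); objective 0.0393251
#>   nonzero S entries: 116 / 240

recovery_report(fit, study)$mean_task_cor
#> [1] 0.9938930

folds <- make_gene_folds(rownames(study$X), n_folds = 10, seed = 1)
cv <- crossvalidate(study$X, study$Y, "psionic", folds, K = 4, seed = 1)
cv
#> <psionic_cv> method = psionic, 60 samples, 10 folds
#>   mean Spearman rho = 0.682 +/- 0.019 (s.d.; s.e. 0.002)

cv_stl <- crossvalidate(study$X, study$Y, "stl", folds, seed = 1)
compare_methods(cv$rho$rho, cv_stl$rho$rho)
#> # A tibble: 1 x 4
#>   statistic  p_value     n n_nonzero
#>       <dbl>    <dbl> <int>     <int>
#> 1      1830 8.36e-12    60        60
```

The fitted per-sample correlations (0.68 multitask vs 0.65 single-task,
paired one-sided Wilcoxon p ~ 1e-11) show the benefit of sharing latent
programs across samples; `recovery_report()` confirms the planted activities
are recovered (mean per-sample Pearson r = 0.994 against ground truth).
`infer_activities(fit)` returns the TF x sample activity matrix **W** for
downstream statistics (`onevsrest_scan()`, `cluster_activities()`,
`activity_phenotype_correlation()`), and `tidy()`/`glance()`/`autoplot()`
expose fits as tibbles and ggplots.

A thin command-line front end over the same functions lives at
`inst/cli/psionic.R` (subcommands `simulate`, `features`, `fit`, `cv`,
`activities`, `associate`, `enrich`).

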
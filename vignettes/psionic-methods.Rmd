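---
title: "Methods: multitask inference of TF activities from accessibility-derived motif features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multitask inference of TF activities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, how the feature matrix is built, the numerical choices inside
the solver, what the synthetic-data generator does and does not emulate, and
the design decisions that were genuinely open.

## 1. The model

Each sample (tumor, cell line) is one regression task. Expression of gene
*i* in sample *t* is modeled as a linear function of the gene's TF-motif
feature vector:

$$\min_{L, S}\;\sum_{t=1}^{T} \frac{1}{N}\,\lVert y_t - X L s_t \rVert^2
\;+\; \mu \lVert S \rVert_1 \;+\; \lambda \lVert L \rVert_F^2 .$$

* $X$ (genes $\times$ TFs) holds, for every gene, the strongest motif hit of
  each TF across the accessible regions assigned to that gene.
* $L$ (TFs $\times$ K) holds *latent regulatory programs*: TF coefficient
  vectors shared by all samples.
* $S$ (K $\times$ T) holds per-sample program weights; $w_t = L s_t$ is the
  sample's inferred TF activity vector, and $W = LS$ the activity matrix.

The L1 penalty on $S$ makes each sample use few programs, so samples that
load on the same programs form (possibly overlapping) groups without any
hard group assignment; the Frobenius penalty on $L$ keeps the activity
scale bounded and the L-step strictly convex.

Assumptions worth stating explicitly: expression is (after normalization)
approximately linear in motif strength; one atlas of accessible regions
applies to all samples (accessibility is *not* sample-specific input); the
model has no intercept, so only variation around what the feature columns
can span is explained; activities are regression coefficients — correlated
TF features (similar motifs) make individual coefficients partially
exchangeable, which is why a Jaccard redundancy filter over target sets is
applied before fitting.

## 2. Feature construction

1. **Atlas.** Reproducible peak sets are merged: two peaks merge into their
   union when the overlap exceeds 75% of the *shorter* interval, repeated to
   a fixpoint. The denominator choice was open; fraction-of-shorter is
   symmetric and conservative, and a reciprocal mode is available
   (`reciprocal = TRUE`). Merging is made deterministic by always merging
   the first qualifying pair in coordinate order.
2. **Assignment.** A peak is a candidate for a gene when it overlaps the
   transcription unit extended by 100 kb on both sides (the upstream-of-TSS
   and downstream-of-3'-end flanks together make the window
   strand-symmetric). Among candidates the peak goes to the gene with the
   smallest peak-midpoint-to-TSS distance; ties break to the smaller gene
   id for determinism. The midpoint-to-TSS metric was an open choice (the
   nearest-gene convention in annotation packages does not pin down a
   metric).
3. **Aggregation.** $X_{g,m}$ is the maximum hit score of motif $m$ over the
   peaks assigned to $g$, zero when there is none. Scores default to
   $-\log_{10} p$ of the motif hit; a raw-match-score mode is a
   user decision, since aggregation is agnostic to the score's meaning.
4. **TF filters.** Motifs are kept only if their TF gene is expressed
   (> 0 on the pre-normalization scale) in at least 50% of samples of at
   least one sample group, and redundant motifs are removed by iterating:
   while any retained pair has Jaccard index > 0.5 over target-peak sets,
   drop the motif with the largest mean Jaccard against all retained motifs
   (ties to the lexicographically smallest id).
5. **Standardization.** Feature columns are z-scored by default
   (`standardize = TRUE`) because both penalties are scale-sensitive and
   motif score scales are arbitrary; the transform is estimated on training
   genes only and stored in the model, so held-out predictions never leak
   test information. Zero-variance columns are dropped with a warning.

Expression is normalized per sample: $\log_{10}(x + 1)$ on linear-scale
input (the pseudocount 1 is a documented default; set `log_input = TRUE`
for already-log data), then scaling to unit Euclidean norm. Unit L2
normalization was chosen over z-scoring for "unit-normalized" because it
preserves nonnegativity of log expression and makes per-task losses
comparable across samples; this interpretation is flagged for users whose
upstream pipelines differ.

## 3. Solver

Alternating minimization with both subproblems solved exactly:

* **S-step.** With $L$ fixed the tasks decouple into lasso problems in
  $Z = XL$. Cyclic coordinate descent with soft-thresholding runs to a
  $10^{-12}$ coordinate-change tolerance (warm-started across outer
  iterations); with $\mu = 0$ and full-rank $Z$ the exact least-squares
  solution is used directly.
* **L-step.** The stationarity condition is the two-sided linear system
  $(X^\top X/N)\,L\,(SS^\top) + \lambda L = (X^\top Y/N)S^\top$. It is
  solved exactly by diagonalizing the two symmetric matrices (a Sylvester
  solve), costing $O(d^3 + K^3)$ instead of the $dK \times dK$ Kronecker
  system; $\lambda > 0$ guarantees solvability, and a rank-deficient system
  at $\lambda = 0$ is an error advising a positive penalty.

Because each step is an exact minimization of its subproblem, the objective
trace is non-increasing; the implementation treats two consecutive relative
increases above $10^{-8}$ as a solver defect and stops with an error rather
than returning a silently wrong fit. Convergence is declared at a relative
objective change below `tol = 1e-6` (default), capped at `max_iter = 200`
outer iterations.

**Initialization** is the SVD split of the single-task ridge solution:
$W_{\text{stl}} = U D V^\top$, $L_0 = U_K D_K^{1/2}$,
$S_0 = D_K^{1/2} V_K^\top$ — the best rank-K approximation of the no-sharing
solution, which makes the first objective value already meaningful. A seeded
random initialization (`init = "random"`) exists for robustness checks.
$K$ above $\min(d, T)$ is clamped with a warning.

## 4. Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K` | 7 | latent programs; prediction is stable from K = 4 up, larger K separates sample groups better, 7 is the compromise default |
| `mu` | 0.001 | L1 penalty on S (per-task sparsity) |
| `lambda` | 0.001 | Frobenius penalty on L |
| `lambda_ridge` | 0.1 | single-task ridge penalty (baseline and initializer) |
| `flank` | 100000 bp | peak-to-gene assignment window around the transcription unit |
| `promoter_window` | 2000 bp | TSS window for the promoter-only ablation |
| `overlap_frac` | 0.75 | merge threshold, fraction of the shorter peak |
| `min_expressed_frac` | 0.5 | expression filter threshold within a group |
| `jaccard_threshold` | 0.5 | redundancy filter threshold |
| `n_folds` | 10 | held-out-gene cross-validation folds |
| `tol`, `max_iter` | 1e-6, 200 | solver convergence |

The penalties are the one place where no external value exists. They were
calibrated once with the package's own machinery
(`select_hyperparams()`, a grid search scored by mean per-sample Spearman
correlation on a held-out fifth of the genes) on the default synthetic
study: the validation surface is flat across
$\mu \in \{10^{-4}, 10^{-3}\}$, $\lambda \in \{10^{-3}, 10^{-2}, 10^{-1}\}$
(differences under one standard error), so the sparsest configuration on
the plateau was adopted — a one-standard-error-style rule. For real data
the grid search should be re-run inside training folds
(`select_hyperparams()` is designed to be called on training genes only).

## 5. Evaluation machinery

Cross-validation splits **genes**, not samples: each fold's model is trained
on the other folds' genes and predicts the held-out genes in every sample;
predictions are pooled across folds and scored per sample by Spearman
correlation (average-rank ties). "mean ± x" summaries report the standard
deviation across samples, with the standard error also emitted, since either
convention appears in the literature. A constant predicted vector is
recorded as $\rho = 0$ with a warning.

Two negative controls destroy the biological signal while conserving the
marginal structure of the hit table: *motif shuffling* redraws each peak's
motif labels uniformly (per-peak hit counts kept), and *peak-location
shuffling* redraws each motif's hit-bearing peaks uniformly from the atlas
(per-motif counts kept), after which features are rebuilt through the real
assignment/aggregation code. Both use a canonical score-to-label pairing so
that a peak (or motif) with no freedom is returned bit-identically. The
promoter-only ablation keeps only peaks within `promoter_window` of a TSS.

Method comparison uses the paired one-sided Wilcoxon signed-rank test. For
up to 25 nonzero differences the tail probability is computed exactly by
dynamic programming over the (doubled, hence integer) average ranks — valid
under ties, and identical to the classical exact distribution without them;
larger samples use the normal approximation with continuity correction.

`scan_K()` reports, per K, the cross-validated mean correlation and a
sample-separation proxy: mean silhouette width of samples in W-space under
correlation distance on TF-mean-centered activities, grouped by the known
type labels. The silhouette is a stated proxy — the choice of separation
metric was open, and clustering heatmaps do not define one.

## 6. Downstream statistics

Per-TF group associations use Welch's unequal-variance t-test (a robust
default where only "t-test" is conventional; the pooled-variance variant is
available), effect size = difference of group means, and Benjamini-Hochberg
FDR across TFs. Hierarchical clustering of samples uses average linkage on
1 − Pearson correlation of TF-mean-centered activities (both configurable;
correlation distance is undefined for a constant sample and errors with
advice to use Euclidean). Phenotype correlations are Spearman with a seeded
permutation p value — enumerated exhaustively whenever $n! \le$
`n_perm`, so small-sample p values are exact.

Motif-shift enrichment compares the log2 fold-change distribution of a
motif's peaks against the full differential-accessibility background with a
one-sided two-sample KS test in each direction. The background *includes*
the member peaks by default (the background is defined as all differential
peaks); a disjoint-background mode exists because the convention is
ambiguous. The occurrence counts use the 5000 most-opened and most-closed
peaks (ties at the boundary broken by peak id), and the volcano effect size
is $\log_2$ of the foreground/background frequency ratio with a 0.5
pseudocount on both counts — a package choice, since no effect-size formula
is conventional. One-sided KS p values come from the asymptotic Smirnov
tail $e^{-2d^2 mn/(m+n)}$, switching to the exact distribution below 30
members when the data are tie-free; Bonferroni correction is applied per
comparison.

## 7. The synthetic-data generator

`simulate_regulatory_genome()` lays out genes on synthetic chromosomes with
transcription units spaced so that their ±100 kb windows are disjoint,
draws Poisson(5) peaks per gene uniformly inside the gene's window, places
decoy peaks (default 10%) in the inter-window gaps, and draws motif hits as
independent Bernoulli(0.1) events with Uniform(5, 10) scores (the range of
$-\log_{10} p$ above a typical motif-scan threshold). The feature matrix is
then built through the *real* assignment and aggregation code.

`simulate_cohort()` plants ground truth on such features: unit-norm program
columns $L_0$, group supports in which program 1 is shared by every group
and the remaining programs are group-specific (support size 2 by default),
positive per-task weights, and Gaussian noise calibrated per task so the
noise-free signal explains a target fraction of variance (default
$R^2 = 0.5$); the noisy profiles are then unit-normalized, in the same
order as the real pipeline. The default study uses 1000 genes, 100 motifs
and 60 samples in five groups with sizes proportional to
(92, 255, 57, 272, 47) — the tumor-type proportions of the kind of cohort
the package targets, scaled to desk size — with $K_{\text{true}} = 4$.
Options cover orthogonal (no shared program) supports and a fully
independent regime in which every task has its own iid model vector, used
as the no-sharing control.

What the generator does **not** emulate: tumor purity and stromal
admixture, sample-specific accessibility, correlated motif occurrences
(paralogous TFs), heteroscedastic or non-Gaussian expression noise, and
any nonlinearity between motif strength and expression. Passing tests
therefore demonstrate correctness of the machinery and recoverability under
the stated statistical assumptions — not performance on real tumors.

`recovery_report()` scores a fit against the planted truth: per-task Pearson
correlation of activity vectors (computed on the original feature scale by
inverting the stored standardization) and matched-program correlations,
where programs are paired by the permutation maximizing total absolute
correlation — sign and order of programs are gauge freedoms of the
factorization and are never asserted directly.

## 8. Problem sizes used by the test suite

The property suite runs at desk scale, chosen once as the package's
reference conditions: solver-vs-oracle checks on 20-50 random instances of
25-30 genes; monotonicity on 20 seeded cohorts of 150 genes; recovery and
the multitask-vs-single-task ordering (with both randomization controls) at
the default study scale of 1000 genes x 100 TFs x 60 samples; enrichment
calibration with 500 null simulations on a 20,000-peak atlas with 500
member peaks, and power against odds-ratio-4 enrichment over 60
simulations. The no-sharing control runs at 300 genes x 20 samples over 5
seeds. `scripts/acceptance.R` recomputes the headline quantities at the
full default-study scale from a single seed.

## 9. Known limitations

* Activities are linear-model coefficients on standardized features; their
  absolute scale is not comparable across differently-filtered feature
  sets.
* The factorization is identified only up to program permutation and sign;
  only $W = LS$ and matched-program quantities are stable.
* With `mu = 0` the factorization penalty can be driven to zero by
  rescaling ($L \to \epsilon L$, $S \to S/\epsilon$), so sparsity (and
  interpretability of $S$) relies on a positive `mu`.
* The exact Wilcoxon path enumerates up to $2^{25}$ sign patterns via
  dynamic programming, but the normal approximation used beyond n = 25 is
  the standard large-sample one and may be slightly conservative near
  p = 0.01.
* The KS shift test's default background contains the foreground; for very
  large motif families this makes the test slightly conservative.
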
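---
title: "Methods: models, procedures and parameter choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, procedures and parameter choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical methods implemented in `t1grslab`,
the default parameter values, and the reasoning behind the less obvious
design choices. Code chunks are illustrative and not evaluated when the
vignette is built.

## 1. Synthetic cohort generator

`simulate_cohort()` draws genotypes, an MHC-analog haplotype locus,
case-control labels and clinical outcomes from a single integer seed. All
stage-level seeds are derived with `child_seed(master, op)`, a
deterministic polynomial string hash reduced modulo a 31-bit prime, so
any two stages never share an RNG stream and every draw is reproducible
from the master seed alone.

**Linkage disequilibrium.** Within each block, genotypes are generated
from an *exchangeable* Gaussian copula: one shared standard-normal factor
per block plus independent noise, giving every within-block pair the same
latent correlation `ld_rho`. Each latent variable is thresholded at Hardy-
Weinberg genotype boundaries for the variant's allele frequency. The
exchangeable structure (rather than AR(1)) makes the within-block r²
roughly flat, which is what the fine-mapping calibration harness assumes
when it defines linkage sets by an r² cutoff.

**MHC-analog locus.** `mhc_spec()` defines three haplotype classes
(`DR3`, `DR4`, `X`) with population frequencies (default 0.15/0.15/0.70).
Diplotypes are drawn under Hardy-Weinberg equilibrium; each haplotype copy
contributes its per-copy log odds ratio, and DR3/DR4 heterozygotes receive
an extra `het_bonus` on the log-odds scale. This is the canonical
non-additive effect in the package: a genotype-*class* odds ratio that
cannot be represented as a sum of per-allele effects.

**Phenotypes.** The liability is a logistic model:
intercept + additive dosage (or carrier) terms + pairwise interaction
terms + MHC class terms + covariate effects. Onset ages are truncated-
normal per subtype; complications are Bernoulli with per-subtype odds
multipliers applied to a baseline probability on the odds scale.

## 2. Association testing

`firth_logistic()` implements Firth's penalized likelihood (Jeffreys
prior): the Newton score is corrected with hat-matrix leverages and
step-halving guards each iteration. Firth's correction keeps estimates
finite under separation, which matters for rare variants (MAF ~0.001) and
near-deterministic genotype classes. P-values are Wald by default with a
penalized-likelihood-ratio option.

`ivw_meta()` combines per-cohort estimates by fixed-effects inverse-
variance weighting: `beta = sum(b_i/se_i^2) / sum(1/se_i^2)`,
`se = sqrt(1/sum(1/se_i^2))`.

`clump_and_define_loci()` follows two-round clumping: round one greedily
assigns variants with p < 0.05 and r² > 0.1 within 10 Mb to the most
significant unclaimed index (indexes require p < 5e-8); round two merges
clumps whose indexes have any LD (r² > 0) within 500 kb; loci are the
merged clump spans extended by ±500 kb.

`stepwise_conditional()` re-tests a region's variants conditioning on all
previously selected signals until no variant passes the threshold; ties
are broken by p, then |z|, then variant id. `build_precondition_covariates()`
constructs the 90 fixed covariates (70 allele dosages plus 20 pairwise
carrier indicators) used to precondition scans of non-MHC regions on the
MHC background.

## 3. Fine-mapping

`wakefield_bf()` computes the approximate Bayes factor
`BF = sqrt(V/(V+W)) * exp(z^2/2 * W/(V+W))` with `V = se^2` and prior
effect variance `W = 0.04`. PIPs are Bayes factors normalized over the
*linkage set* (variants with r² > 0.1 with the lead), and `credible_set()`
adds variants in decreasing PIP order until cumulative mass reaches 95%
(greedy, so the set can overshoot the mass).

`coverage_experiment()` is the calibration harness: it simulates regions
with one causal variant whose effect is drawn from the same Normal(0, W)
prior, recomputes per-variant summary statistics by logistic fits, and
reports how often the causal variant lands inside the 95% set. With a
matched prior the construction is conservative (coverage at or above the
nominal mass) because the greedy set overshoots.

## 4. Risk models and evaluation

`train_gbdt_cv()` trains gradient-boosted trees (254 trees, depth 5,
learning rate 0.12) with stratified 10-fold cross-validation; each
individual's score comes from the model that never saw them
(out-of-fold discipline, audited in the tests). Two regularization
defaults are set beyond the three headline hyperparameters: L2 leaf
penalty `lambda = 30` and a minimum leaf hessian weight of 1% of the
training rows. These were calibrated on held-out synthetic cohorts so the
ensemble matches the strongly regularized behavior of the boosting
frameworks this configuration is normally run in; without them a depth-5,
254-tree model memorizes genotype noise at n = 10,000 and loses to the
linear baseline even when real interactions are present. The calibration
criterion was qualitative (nonlinear model at least matches the linear
baseline on *additive* data) and was fixed before any acceptance
assertions were written.

`train_logreg_cv()` is the ridge logistic baseline: `glmnet` with
`alpha = 0` and `lambda = 1/(C * n_train)`, `C = 0.001`, unstandardized
features, same folds. `additive_grs()` is a weighted dosage sum with
optional genotype-class weights.

Evaluation: rank-based AUC, step-integral average precision, DeLong's
test for paired AUCs, McNemar's test (exact binomial for up to 15
discordant pairs, continuity-corrected chi-square above) overall and per
MHC diplotype class via `mcnemar_strata()`, and `youden_scale()`, which
thresholds at case-score centiles {5,10,...,50,75,95} (type-1 quantiles,
so thresholds are observed scores) and reports sensitivity, specificity
and Youden's J per row.

## 5. SHAP interpretation

`compute_shap()` returns exact TreeSHAP attributions from the per-fold
(out-of-fold rows) or full model, satisfying local accuracy: base value
plus attributions equals the prediction margin. Importance is mean |SHAP|
per feature. `compute_interactions()` computes the SHAP interaction
tensor on a seeded subsample (`max_rows`, default 400) because the tensor
is cubic in features and quadratic memory per row; the subsample is drawn
once per seed so results are reproducible.

`interaction_significance()` scores each pair by its mean |interaction|
across individuals and standardizes it against the mean and SD of *all
other pairs* (the cross-pair background), converting to a normal z and
p, with Benjamini-Hochberg correction. Pairs are categorized as MHC-MHC,
MHC-nonMHC or nonMHC-nonMHC from the feature groups.

**Known limitation.** Under purely additive truth this cross-pair z test
is anti-conservative: tree ensembles encode incidental interactions
whenever marginal splits co-occur on a path, and the across-pair
distribution of mean |interaction| is heavy-tailed, so its SD understates
the null spread of the largest pairs. In our additive-only experiments a
majority of replicates produced at least one q < 0.05 pair, and widening
the panel makes it worse. The test is useful for *ranking* (planted
interactions reliably top the list and dominate the background by z
margins of 9+), but a significant q alone should not be read as evidence
of epistasis; replication across independent cohorts or a permutation
null is required. We kept the pinned test because it reproduces the
intended analysis; the limitation is inherent to that analysis, not to
the implementation.

`complexity_scores()` is the per-individual sum of |SHAP| values, cut
into balanced deciles; `performance_by_complexity()` reports per-decile
AUCs and model deltas, which is where the nonlinear model's advantage
concentrates when interactions are present.

## 6. Subtype discovery

`embed_shap()` projects (case) SHAP profiles onto up to 175 principal
components and builds an exact kNN graph (k = 120, chunked distance
computation). `cluster_shap()` runs Leiden community detection (modularity
objective, resolution 0.05); labels are renumbered by descending cluster
size. `choose_k()` scans resolutions and picks the silhouette-optimal
partition. `layout_2d()` offers a PCA or Fruchterman-Reingold layout (no
UMAP dependency; layouts are for plotting only and carry no inferential
weight). `project_validation()` assigns held-out individuals to the
nearest discovery centroid in PC space.

Clinical contrasts: `onset_logrank()` (log-rank test on onset age across
clusters plus per-cluster medians), `complication_assoc()` (2x2 odds
ratio with Woolf CI, continuity-corrected when a cell is zero),
`celltype_enrichment()` (permutation test of PIP-weighted annotation
mass with an add-one floor so p >= 1/(n_perm+1)), and `t2d_enrichment()`
(logistic regression of locus labels on per-cluster attribution shares).

## 7. Pipeline

`run_pipeline()` chains simulate, assoc, finemap, train, interpret and
subtype; every stage writes its artifacts (VCF/TSV/JSON) before the next
starts and a manifest records per-stage output MD5 hashes, wall times and
the seed. Re-running a config reproduces identical hashes. `make_report()`
renders a plain-text summary and is idempotent.

```{r example}
library(t1grslab)
cfg <- default_config(n = 2000, n_variants = 40, seed = 7)
manifest <- run_pipeline(cfg, "run1")
make_report("run1")
```
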
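# triomics

Molecular subtype discovery from matched multi-omic expression profiles,
and characterisation of the discovered subtypes — differential
expression, gene-set enrichment, classifier evaluation, miRNA-mediated
lncRNA–mRNA crosstalk, and survival/clinical association.

## The problem

Tumor cohorts profiled on several transcriptomic layers at once (mRNA and
lncRNA as FPKM-like values, mature miRNA as RPM-like values) often hide a
small number of molecular subtypes with distinct biology and prognosis —
for bladder and breast cancer, the basal/luminal split is the canonical
example. `triomics` is for analysts who want to (1) find those subtypes
reproducibly from all layers jointly, (2) quantify how confident the
K choice is, and (3) trace subtype biology down to concrete
miRNA–lncRNA–mRNA regulatory candidates with database support and
survival relevance.

## The method

**Subtype discovery.** Each layer is reduced (drop the lowest 25% of
genes by mean, keep the top 3000/300/3000 by MAD of log2 values) and
consensus-clustered (Monti procedure: 50 subsampled replicates at 80% of
samples, complete-linkage hierarchical clustering of the Pearson distance
1 − r, K = 2..6). The consensus entry `M(i,j)` estimates the probability
that samples i and j belong together. Per-layer labels are re-encoded as
a binary cluster-of-clusters matrix (one indicator block per layer) and
consensus-clustered again; the final K is chosen by a four-statistic
vote — average silhouette width (argmax), cophenetic correlation of each
consensus tree against the data distances (argmax), relative change in
the area under the consensus CDF Δ(K) (largest K with Δ ≥ 0.1), and the
proportion of ambiguous clustering PAC = CDF(0.9) − CDF(0.1) (argmin) —
with majority rule and ties to the smallest K.

**Characterisation.** Tumor-vs-normal differential expression uses a
per-gene F test on log2(x+1) with BH correction (`q < 0.05`,
`|log2FC| > 0.57`); subtype contrasts are ranked by Signal2Noise
`(μ₁−μ₂)/(σ₁+σ₂)` and tested by the weighted GSEA running-sum statistic
with 1000 gene-set permutations; classification of subtypes is evaluated
with a 60/40 stratified split, 10-fold cross-validation, and
trapezoidal ROC/AUC over an injectable classifier backend. Feature genes
∩ DEGs (the "DEFGs") feed a co-expression analysis: pairs with
`|r| ≥ 0.4` and `p < 0.05` across tumors define miRNA-dependent
lncRNA–mRNA triplets (a co-expressed lncRNA–mRNA pair whose members are
both co-expressed with the same miRNA), validated against a
miRNA-target evidence table (≥ 4 of 6 databases for mRNA targets, ≥ 1 of
3 designated databases for lncRNA targets). Survival is compared by
mean-split Kaplan–Meier curves and the log-rank test; clinical
covariates by Pearson's χ².

**Validation.** A seeded synthetic generator plants subtypes, DE genes,
correlation triplets (via a shared latent factor with controlled signs),
subtype-linked exponential survival and clinical covariates — and emits
the ground truth, so every stage is tested by recovery, calibration, and
exact hand-checked oracles. See the methods vignette
(`vignettes/multiomic-subtyping.Rmd`) for the model details and design
decisions.

## Worked example

```r
library(triomics)

sim <- sim_config(n_tumor = 50, n_normal = 12,
                  n_genes = c(mrna = 120, mirna = 40, lncrna = 60),
                  n_triplets = 5)
report <- run_pipeline(sim, out_dir = tempfile("run"), seed = 3,
                       reps = 20, n_perm = 100)

report$selected_k       # 2      -- all four statistics vote K = 2
report$subtype_ari      # 1      -- perfect agreement with planted subtypes
unlist(report$n_deg)    # mrna 36, mirna 15, lncrna 18 DEGs called
unlist(report$auc)      # 1 1 1  -- held-out subtype classification AUC
report$n_validated      # 3      -- database-validated crosstalk triplets
report$triplet_precision  # 1    -- every validated triplet was planted
report$logrank_chisq    # 31.97  -- subtype survival separation (p = 1.6e-08)
```

The run directory contains every stage artifact (expression and
annotation TSVs, consensus K metrics, DE tables, GSEA table, network
edge list and SIF, report.json) plus `manifest.json` with per-stage
parameters, seeds and md5 checksums; re-running with the same seed
reproduces the manifest byte for byte.

The numbers above read as: the four K-selection statistics agree on two
subtypes and the labels match the planted truth exactly; the classifier
separates the subtypes perfectly on held-out samples; of the hundreds of
co-expressed candidate triplets, validation keeps three, all planted
(recall is limited here by the preprocessing funnel — low-expression
planted genes can be filtered before the classifier stage); and the two
subtypes differ strongly in survival, as planted.

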
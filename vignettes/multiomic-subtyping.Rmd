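---
title: "Multi-omic consensus subtyping and miRNA-mediated crosstalk: methods"
author: "triomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omic consensus subtyping and miRNA-mediated crosstalk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomics)
```

# Scope

`triomics` implements a complete tumor-subtyping workflow for three
co-measured transcriptomic layers — mRNA and lncRNA on an FPKM-like scale,
miRNA on an RPM-like scale — together with the downstream analyses that
characterise the discovered subtypes: differential expression, gene-set
enrichment, classifier-based separability, miRNA-mediated lncRNA–mRNA
co-expression triplets validated against a target database, and
survival/clinical association. Because the workflow is intended to be
validated end-to-end rather than on any particular cohort, the package
ships a fully seeded synthetic generator that plants every structure the
analysis is supposed to find, and the test suite measures recovery of that
planted truth.

# Subtype discovery

## Consensus clustering per layer

Each layer is reduced to its most informative genes before clustering:

* **Mean filter.** The lowest 25% of genes by arithmetic mean (linear
  scale) are removed — low-abundance features carry mostly noise in
  FPKM/RPM data. The count removed is `floor(fraction * n_genes)`, with
  ties broken in favour of earlier input rows.
* **Top-MAD selection.** The remaining genes are ranked by the median
  absolute deviation of `log2(x + 1)` values and the top 3000 (mRNA,
  lncRNA) or 300 (miRNA) are kept. The MAD scale constant (1.4826) is
  omitted; it cannot change a top-N ranking. The reference workflow does
  not state the scale on which either statistic is computed; we filter on
  linear means (an "arithmetic mean" is most naturally read on the scale
  of the data) and rank variability on the log scale, where MAD is not
  dominated by the heavy right tail.
* **Transform.** Clustering input is per-gene median-centered
  `log2(x + 1)`; centering prevents absolute expression level from
  dominating the Pearson distance between samples.

Subtype structure is then assessed by Monti-style consensus clustering
(`build_consensus()`): 50 replicates, each drawing 80% of samples without
replacement, clustered by complete-linkage hierarchical clustering of the
Pearson distance `1 - r`, cut at each candidate K in 2..6. The consensus
matrix entry `M(i, j)` is the fraction of replicates in which samples i
and j were assigned the same cluster, among replicates where both were
drawn. The replicate count, linkage, inner algorithm, distance, and K
range follow the conventional published settings for this analysis; the
80% item fraction is the wrapped tool's usual default (the source
workflow does not print one). Feature subsampling is disabled. One seed
governs all replicates, consumed in replicate order, so results are
reproducible regardless of evaluation order. Pairs never co-sampled
(vanishingly rare at 50 × 80%) get `M = 0` with a warning. Final labels
at each K re-cluster `1 - M` with the same linkage.

## Cluster-of-clusters integration

Per-layer labelings are combined by encoding each sample as a binary
vector of length `sum(K_i)`: one indicator block per layer, a single 1
per block (`encode_coc()`). Each layer's own K is chosen by the same
four-metric vote described below, applied to that layer's consensus run.
The binary encoding is consensus-clustered again (Pearson distance on the
binary rows is well-defined because every row sums to the number of
layers), and the final K is selected on that run.

## Choosing K

Four statistics vote (`select_k()`):

* **ASW** (average silhouette width, in [-1, 1]): argmax. Singleton
  clusters score 0, as does the degenerate all-coincident case `a = b = 0`.
* **CPCC** (cophenetic correlation): argmax. Per K, the correlation
  between the *base* distance matrix (Pearson distance of the clustering
  input) and the cophenetic distances of that K's final consensus
  dendrogram. Correlating each consensus dendrogram against its own
  `1 - M` was considered and rejected: a consensus matrix from
  hierarchical inner clustering is itself near-ultrametric, so that form
  sits near 1 for every K and casts an uninformative vote. Measuring how
  faithfully each consensus tree represents the observed distances is the
  standard use of CPCC for model selection and discriminates between
  candidate K.
* **Δ(K)** (relative change in the area under the consensus CDF): the
  empirical CDF is taken over the `n(n-1)/2` lower-triangular consensus
  entries, `A(K)` is the exact area under that step function on [0, 1],
  `Δ(2) = A(2)` and `Δ(K+1) = (A(K+1) - A(K)) / A(K)`. The vote is the
  largest K with `Δ(K) >= 0.1` — a declared, configurable elbow rule in
  place of visual inspection.
* **PAC** (proportion of ambiguous clustering): argmin of
  `CDF(0.9) - CDF(0.1)`, the standard thresholds for that method.

The selected K is the majority vote; ties go to the smallest voted K.
This deterministic rule reproduces the common situation in which three of
the four statistics agree and a lone ASW maximum at large K is outvoted.

# Differential expression

Tumor-vs-normal calling uses a per-gene one-way ANOVA F test on
`log2(x + 1)` (for two groups, exactly the squared pooled-variance t
statistic, df = (1, n-2)), Benjamini–Hochberg adjustment across genes,
and a fold change `log2((mean_T + 1) / (mean_N + 1))` on linear values —
the pseudocount guards against the zeros that FPKM data contain. Calls
use strict thresholds as conventionally printed: `q < 0.05` and
`|log2FC| > 0.57` (about 1.49-fold). Degenerate genes with zero
within-group variance get `F = 0, p = 1` when the means also coincide and
`F = Inf, p = 0` otherwise.

# Gene-set enrichment

The subtype contrast is ranked by the Signal2Noise statistic
`(mu1 - mu2) / (sigma1 + sigma2)` with each standard deviation floored at
`0.2 |mu|` (0.2 when the mean is zero) — the canonical convention, exposed
as parameters. The weighted running-sum enrichment score walks the ranked
list, adding `|s|^w / N_R` on set hits (w = 1) and subtracting
`1/(N - N_H)` on misses; the ES is the signed maximal deviation. Nulls
come from 1000 random same-size gene sets drawn from the ranked universe
("gene_set" permutation — an anticonservative but conventional choice
that this package deliberately mirrors; phenotype permutation is out of
scope). `NES = ES / mean(|null ES| of the matching sign)`; the FDR q is
the standard ratio of null-NES to observed-NES tail fractions on the
pooled signed null. Sets are filtered to 15–500 members after
intersection with the universe. A generic hypergeometric
over-representation test (`ora_enrich()`) with BH correction covers the
annotation of gene lists against any GMT collection.

# Classification protocol

The evaluation protocol is generic over an injected classifier backend
(`fit` / `score` / `importance`), because the object of interest is the
protocol — 60/40 stratified split by largest remainder, 10-fold
stratified cross-validation at a 0.5 score threshold, trapezoidal
ROC/AUC (equal to Mann–Whitney with ties at one half) — not any tree
learner's internals. A deterministic signal-to-noise-weighted logistic
reference backend is bundled for tests; a gradient-boosted backend
(`xgboost`, if installed) is configured with the conventional published
hyperparameters (max_depth 14, gamma 1, min_child_weight 1, 2000 rounds).
"Feature genes" are those with strictly positive importance, ranked
descending with ID tie-breaks — a declared proxy, since published
workflows rarely state an importance cutoff. DEFGs are the intersection
of feature genes with DEGs, partitioned by layer.

# Crosstalk triplets

Pairwise Pearson correlations on `log2(x + 1)` over tumor samples link
the three DEFG layers; a pair is co-expressed when `|r| >= 0.4` and
`p < 0.05` (inclusive on r, strict on p, as conventionally printed; note
`|r| = 0.4` first crosses `p < 0.05` near n = 25). A miRNA-dependent
lncRNA–mRNA interaction is a co-expressed lncRNA–mRNA pair whose members
are both co-expressed with the same miRNA; enumeration is exhaustive and
deduplicated. No sign constraint is applied — biologically, both signs
occur. Triplets are then validated against a miRNA-target evidence table
with six database flag columns: the miRNA–mRNA edge needs support in at
least 4 of 6, the miRNA–lncRNA edge in at least 1 of the 3 designated
lncRNA-evidence columns; absent rows count as zero support. Correlations
default to tumor samples only (the subtype analysis concerns tumors);
normals can be included explicitly via the `samples` argument.

# Survival and clinical readouts

Expression is dichotomized at the mean (ties to "high" — declared and
configurable), survival compared by Kaplan–Meier curves and the two-group
log-rank test (hypergeometric variance, no stratification), and the
survival rate at a horizon read off the product-limit curve at the last
event time before the horizon. The generator's time unit is months, so
the 5-year rate uses horizon 60; with day-scaled inputs the corresponding
horizon is 1825. Clinical covariates are compared between subtypes by
Pearson's chi-square without continuity correction.

# The synthetic generator

`generate_dataset()` emits the structure the analysis assumes, plus its
ground truth:

* **Expression model.** `value = 2^(mu + effects + N(0, noise_sd))` with
  per-gene baseline `mu ~ U(2, 8)` on the log2 scale — a log-normal
  abundance model. The reference data's distributional form is not
  published; log-normal is this package's modeling choice. Negative
  binomial count noise, batch effects, and library-size artifacts are
  deliberately out of scope, so passing recovery tests demonstrate
  correctness of the algorithms under the stated model, not robustness to
  real RNA-seq artifacts.
* **Subtypes.** 20% of each layer's genes carry a `+subtype_shift` log2
  mean shift in their own subtype (markers are split round-robin across
  subtypes). The default shift 1.5 equals three residual standard
  deviations (`noise_sd = 0.5`) — the separation regime under which the
  recovery properties are stated.
* **Tumor-vs-normal DE.** A `de_fraction` (default 0.1) of genes per
  layer receives `±de_lfc` (default 1.5) in tumors, half up, half down.
* **Triplets.** Each planted triplet's three members (one per layer) load
  on a shared standard-normal latent factor with loading
  `lambda = noise_sd * sqrt(r / (1 - r))` and signs (miRNA -1, lncRNA +1,
  mRNA +1), so every pairwise correlation approaches `triplet_r` (default
  0.7) with the classic pattern of a miRNA anti-correlated with both
  targets. The latent-factor construction controls the sign pattern
  exactly, which correlated-noise draws would not. Triplet members also
  receive the DE effect (direction = loading sign) so the
  feature-gene → DEG → crosstalk funnel carries planted signal
  end-to-end; strict global-null runs therefore set `n_triplets = 0`.
* **Survival.** Exponential event times; subtype 2 has
  `hazard_ratio`-fold (default 3) the reference hazard. Censoring is
  administrative-uniform on `(0, follow_up_max)` (default 60 months),
  with the baseline hazard calibrated by root-finding so the expected
  censored fraction in the reference arm equals `censor_rate`
  (default 0.3). `censor_rate = 0` disables censoring entirely.
* **Clinical covariates.** Two categorical covariates with
  subtype-linked level odds (default odds ratio 3), for chi-square
  testing.
* **Evidence table.** `generate_target_db()` gives every planted
  miRNA–mRNA edge 4–6 of 6 database flags and every planted miRNA–lncRNA
  edge 1–3 of the 3 designated flags; decoy edges stay strictly below
  both thresholds. The table is synthetic and is labelled as such; it
  emulates the *structure* of integrated target resources, not their
  content.

Default sizes (120 tumors, 20 normals; 300/80/150 genes) are a
reduced-scale analogue of a typical cohort with tens of thousands of
mRNAs/lncRNAs and thousands of miRNAs; they keep a full pipeline run
around ten seconds while leaving every planted effect estimable.

# Numerical and design notes

* Determinism: every stochastic stage takes a seed; `run_pipeline()`
  derives fixed per-stage substreams from one master seed and records
  md5 checksums of all artifacts in a manifest, so a repeated run is
  byte-identical.
* Ties: gene rankings break by input order (filters) or
  lexicographically by ID (scores, importances); hierarchical merge ties
  follow `hclust`'s smallest-index convention; mean-split ties go
  "high"; the K vote ties to the smallest K.
* The pipeline's DEFG funnel can drop planted triplet members whose
  baseline expression falls in the filtered bottom quartile — module-level
  recovery of the crosstalk chain is therefore measured on the full
  layers, while the pipeline reports its own (possibly lower) recall.
* Network export writes numbers with 17 significant digits so that
  write → read → write is byte-stable.
* Test problem sizes (10-seed recovery runs at n = 120, 50 null datasets
  at 20 vs 20, 200 permutation sets at 200 permutations, 1000 log-rank
  replicates) are the package's own choice of the smallest sizes at which
  the stated properties are sharp.

# Worked example

```{r example, eval = FALSE}
sim <- sim_config(n_tumor = 50, n_normal = 12,
                  n_genes = c(mrna = 120, mirna = 40, lncrna = 60),
                  n_triplets = 5)
report <- run_pipeline(sim, out_dir = tempfile("run"), seed = 3,
                       reps = 20, n_perm = 100)
report$selected_k     # number of subtypes chosen by the four-metric vote
report$subtype_ari    # agreement with the planted labels
report$n_validated    # database-validated crosstalk triplets
report$logrank_p      # subtype survival separation
```

# Known limitations

* The generator's noise model is Gaussian on the log scale; count-level
  overdispersion, zero inflation, and batch structure are not emulated.
* Gene-set permutation (as opposed to phenotype permutation) understates
  inter-gene correlation under the null; its p-values are anticonservative
  on correlated data. The choice mirrors the workflow this package
  implements and is flagged rather than silently corrected.
* The evaluation protocol treats classifier internals as exchangeable;
  conclusions about any particular learner require plugging in that
  learner as a backend.
* Cox regression, covariate-adjusted differential expression, and
  sequence-based target prediction are out of scope.
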
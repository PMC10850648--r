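---
title: "Methods: immunophenotype stratification of AIRD cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immunophenotype stratification of AIRD cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airdstrat)
```

## The analysis

`airdstrat` analyses cohort-wide flow-cytometry immunophenotypes — per-sample
counts of 46 immune-cell subsets in peripheral blood mononuclear cells
(PBMCs) — across eleven autoimmune rheumatic diseases (AIRDs) and healthy
controls. The pipeline asks three nested questions: which cell types co-vary
(cell-type resolution), which diseases share an immunophenotype profile
(disease resolution), and which patients — regardless of diagnosis — share an
immune state (patient resolution). Downstream stages attach clinical and
genetic meaning to the patient clusters: per-disease heterogeneity of cluster
membership, cluster-versus-clinical association within one disease, and
polygenic-risk-score (PRS) associations with clinical features and cell-type
abundances.

Because cohort data of this kind cannot be redistributed, the package ships a
synthetic cohort generator whose defaults emulate the structure such a study
exhibits; every claim the test suite makes is a claim about recovery of
structure that the generator planted.

## Normalisation

Counts are converted to log fractions of the *total viable PBMC count*, the
per-sample sum of the five major lineage totals (CD4 T cells, B cells, NK
cells, dendritic cells, monocytes):

$$ x_{st} = \log\frac{c_{st} + \delta}{\sum_{l \in L} c_{sl}} $$

with pseudocount $\delta = 0.5$ by default. The pseudocount only matters for
rare subsets near zero; with $\delta = 0$ zero counts are treated as missing
rather than mapped to $-\infty$. The transform is invariant to per-sample
scaling of the counts and monotone in each count. Natural log is used; the
base is configurable and affects only a global scale.

Two consequences of dividing by a shared denominator matter later:

* the five lineage log-fractions are nearly linearly dependent
  (compositional closure), and
* per-sample denominator variation adds a *common mode* — a shift applied to
  every cell type of a sample at once — which concentrates in the leading
  principal component of the normalised matrix.

## Confounder residualisation

`residualize()` replaces each cell-type column by ordinary-least-squares
residuals on age, sex and the top `n_pcs` principal components of the
normalised matrix. The PCs act as a surrogate for assay batch structure; with
`n_pcs = 10` (the default intended for real data with batch effects) the ten
largest directions of variation are removed wholesale. This is a blunt but
standard instrument, and it cuts both ways: any biological cluster signal
living in the top PCs is removed together with the batch signal. For
synthetic cohorts that plant no batch structure the package therefore
residualises only age, sex and the single leading PC — the compositional
common mode described above — since removing further PCs would only delete
signal. This choice (`n_pcs_residual = 1` in `simulate_and_validate()`) is a
property of the data-generating process, not a tuning knob: when noise is
negligible the common mode is negligible too and `n_pcs_residual = 0` is the
appropriate setting.

Residualisation stores its covariate design in the returned object and reuses
it when called on an already-residualised matrix, which makes the operation
idempotent. Recomputing PCs of the residual matrix on a second pass would
instead strip the *next* `n_pcs` components — a silent way to destroy data.

## Clustering at three resolutions

All three resolutions use agglomerative hierarchical clustering
(`stats::hclust`); entities are ordered lexicographically before distances
are computed so equal-height merges resolve identically regardless of input
order.

* **Cell types** — distance $1 - r$ with $r$ the Pearson correlation across
  samples; average linkage (the standard pairing for correlation distance).
* **Diseases** — samples are embedded in the top 10 PCs of the normalised
  matrix, each disease is represented by its centroid, and centroids are
  clustered on Euclidean distance with Ward linkage.
* **Patients** — Euclidean distance on the top-10-PC embedding of the
  residualised matrix, Ward linkage.

### Choosing the number of clusters

`select_k()` sweeps cuts of the merge tree and applies a per-resolution
admissibility rule:

1. *Cell types*: no cluster may mix the major lineage classes T, B and
   innate (a shipped lineage map assigns each of the 46 subsets;
   plasmablasts are assigned to B by ontogeny even though their abundance
   often tracks activated T cells).
2. *Diseases*: every cluster must contain at least two diseases.
3. *Patients*: at least two clusters must each hold fewer than 20 % of the
   patients.

Because hierarchical cuts are nested, these rules have opposite
monotonicities. Lineage purity and the presence of small patient clusters
can only improve as `k` grows, so rules 1 and 3 select the **smallest**
admissible `k` ≥ 2. A singleton-disease cluster, once split off, persists at
every finer cut, so rule 2 is satisfied on a down-set of `k` values and
selects the **largest** admissible `k` — the resolution just before a disease
is isolated. When no cut is admissible the fallback `k` is returned with an
explicit `forced` flag and a warning, never silently.

## Stability by stratified subsampling

`stability_run()` repeats the entire clustering — including the selection of
`k` — on stratified subsamples (default: 95 % of each disease group, drawn
without replacement) and scores each repeat against the full-data solution
restricted to the subsample. The score is *concordance*: candidate clusters
are matched to reference clusters by maximum-agreement assignment on the
contingency table (solved exactly by dynamic programming over label
subsets), and the fraction of samples whose matched labels agree is
reported. When the subsample selects a different `k`, the rectangular
assignment leaves clusters unmatched and their members count as
disagreements, so instability of the cluster number is penalised rather than
hidden. Since no single summary is canonical, the report carries the mean,
median and pooled concordance along with the per-iteration adjusted Rand
index.

## Network layers

* **Cell-type correlation network**: an undirected edge for every pair with
  $|r| > 0.4$ (strict), signed by the correlation sign and weighted by
  $|r|$; correlation-test p-values are mapped to significance tiers with the
  Bonferroni denominator equal to the number of cell-type pairs.
* **Disease inverse-distance network**: weights $w = 1/d$ on the PC-centroid
  distances, retaining edges with $w$ strictly above one third of the
  maximum weight.
* **Disease-by-cell-type network**: per disease, a logistic regression of
  disease-versus-control on all cell-type abundances with sex forced into
  the model (age optionally), followed by backward-forward stepwise
  selection starting from the full model. Retained coefficients become
  directed edges; their Wald p-values form a single multiple-testing family
  across the whole network and are mapped to tiers — Bonferroni, BH-FDR
  < 5 %, < 10 %, nominal p < 0.05.

### Why BIC is the default stepwise criterion

With ~46 correlated predictors and a few hundred samples per disease model,
AIC's constant penalty of 2 per parameter retains a substantial share of
null cell types per fit. The compositional near-collinearity of the lineage
fractions makes this worse: near-collinear null predictors acquire large,
mutually cancelling coefficients whose conditional Wald statistics look
significant, so AIC selection floods the null network with tiered edges.
BIC's $\log n$ penalty restores type-I control while keeping the planted
moderate effect (log-odds 2 per unit log-abundance) detectable — the
acceptance checks compute both the null edge rate and the power under the
BIC default. BIC is therefore the default; `criterion = "AIC"` remains
available. All reported p-values are
post-selection and flagged as such in the graph metadata — they describe the
selected model, not an unconditional test.

## Association tests

* **Per-disease heterogeneity**: Pearson chi-square on the 2 × k table of
  one disease versus the rest across patient clusters; when any expected
  cell falls below 5 (small groups violate the asymptotics) the p-value is
  computed by Monte-Carlo permutation (10 000 draws, seeded). The Bonferroni
  threshold divides by the number of disease groups tested (0.05/12 in the
  reference design).
* **Cluster versus clinical** (one disease): one-versus-rest per feature and
  cluster; Wilcoxon rank-sum for continuous features (robust to skewed
  activity scores), Fisher's exact test for binary ones, effects as mean
  differences or Haldane-corrected log odds ratios; BH-FDR across the whole
  feature × cluster family. Treatment response is encoded as
  Δ = baseline − week 24, so positive Δ means improvement.
* **PRS associations**: per score, linear (continuous) or logistic (binary)
  regression of each target on the score adjusted for genetic principal
  components; BH-FDR per score family, flags at FDR < 0.10 and p < 0.05.

FDR families follow the analysis unit (one family per network, one per
score, one per cluster–clinical run) rather than pooling across unrelated
analyses.

## The synthetic cohort generator

`generate_cohort()` draws from a multiplicative log-normal abundance model:
per sample, the log-abundance of each cell type is a baseline log-fraction
plus a disease archetype, an optional planted patient-cluster archetype,
confounder terms (age per decade, sex, additive batch shifts) and Gaussian
log-scale noise (optionally block-correlated through a latent factor model).
Counts are rounded exponentials scaled to a per-sample total PBMC count
drawn log-normal with mean $10^5$ — totals are not published for such
cohorts, and this value exercises the normalisation without creating
small-count artefacts. Group sizes default to the reference cohort design:
947 samples over 11 AIRDs (285 RA, 170 SLE, …) and 54 controls. All
randomness flows through one seed; generation is bit-reproducible.

Three structured builders define the validation conditions:

* `scenario_patient_clusters()` plants six patient archetypes at proportions
  11/11/23/23/24/8 % (identical in every disease group, allocated exactly by
  largest remainder). Each archetype shifts a signature set of subsets by
  ±2 × `noise_sd` per feature, with equal numbers of up- and down-shifted
  features. The balance is deliberate: fraction data cannot expand one
  compartment without contracting another, and balanced shifts keep the
  planted signal orthogonal to the common mode so that removing the leading
  PC costs no signal. The two 11 % archetypes differ in only six features
  (the closest pair), the 8 % archetype opposes the first; this geometry
  makes the patient admissibility rule first hold at exactly six clusters,
  while cuts at 2–5 clusters leave at most one small cluster.
* `scenario_disease_supergroups()` groups the twelve diseases into four
  archetype super-groups; within each, one designated member carries a
  larger disease-specific offset so that refining the four-cluster partition
  always isolates a single disease first, making four the largest admissible
  cut.
* `scenario_celltype_blocks()` partitions the 46 subsets into six
  biologically motivated correlation blocks (within-block r ≈ 0.8) and
  couples the B-cell block factor to the activated-T factor (cross r ≈
  0.44), mimicking plasmablast/activated-T covariation; cuts below six
  clusters therefore mix B with T and the lineage rule first holds at six.

Optional layers plant clinical effects (per-cluster shifts on baseline or
Δ features), autoantibody positivity, and PRS effects (slopes on clinical
features or cell-type abundances, with simulated genetic PCs).

What the generator does **not** emulate: gating and acquisition noise of
real flow cytometry, longitudinal within-patient correlation, missingness
mechanisms beyond simple QC defects, treatment effects on immunophenotypes,
and linkage-disequilibrium structure behind the PRS (scores are drawn
standard normal). Passing tests therefore demonstrate that the pipeline
recovers the statistical structure it assumes — not that real cohorts
possess that structure.

## Numerical and degenerate-input choices

* Zero counts: pseudocount 0.5 by default; `pseudocount = 0` switches to
  treat-as-missing.
* Constant cell-type columns are excluded from correlation clustering and
  left isolated in the correlation network, each with a warning.
* Zero distances in the inverse-distance network are capped at a configured
  maximum weight with a warning.
* Perfectly separating predictors are dropped before stepwise selection
  (their likelihood is unbounded), with a warning naming the cell type.
* Equal-height merges are resolved by lexicographic entity order.
* The assignment matching in `concordance()` is exact for up to 20 clusters
  per side, far above any resolution used here.
* Monte-Carlo chi-square p-values use the caller's seeded RNG stream;
  `stability_run()` derives one sub-seed per iteration so reports are
  bit-reproducible.

## Problem sizes in the test suite

The suite validates at the reference cohort scale where the claim depends on
it (947 samples for patient clustering and stability; 150 + 54 for the
stepwise network; 123 for PRS power, with 100–200 simulation replicates and
2000 calibration replicates for the chi-square test), and at toy scale
(5–10 entities) wherever a brute-force oracle provides the expected answer.
Stability uses 100 subsampling iterations in the tests; the function default
is 1000.

## Known limitations

* The patient-resolution rule ("at least two clusters under 20 %") is
  scale-sensitive: in small cohorts merged pairs of planted clusters can
  fall under the threshold and stop the sweep early. The per-k report
  returned by `select_k()` makes such decisions auditable.
* Stepwise p-values are post-selection; tiers order evidence but are not
  unconditional error rates.
* PC-based residualisation cannot distinguish batch variation from biology
  that happens to dominate the same components; with vanishing noise the
  leading PC *is* biology and should not be removed.
* The disease resolution clusters centroids; diseases with very few samples
  contribute noisy centroids and groups with fewer than two samples are
  excluded.
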
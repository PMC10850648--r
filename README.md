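# airdstrat

Immunophenotype-based stratification of autoimmune rheumatic disease (AIRD)
cohorts.

Cohort-wide flow cytometry yields, for every patient, the abundance of ~46
immune-cell subsets in peripheral blood mononuclear cells (PBMCs). Across a
spectrum of AIRDs — rheumatoid arthritis (RA), systemic lupus erythematosus
(SLE), systemic sclerosis, vasculitis and others — such matrices carry three
layers of structure: cell types that co-vary, diseases with similar immune
profiles, and patients who share an immune state regardless of their
diagnosis. `airdstrat` implements the full analysis path for researchers in
clinical immunology and biostatistics who want to extract and validate those
layers: normalisation, confounder adjustment, multi-resolution clustering
with principled selection of the cluster number, a subsampling stability
check, network construction, and downstream clinical/genetic association
testing — plus a synthetic cohort generator so that every stage is testable
without patient-level data.

## The method in brief

Counts are normalised per sample by the **total viable PBMC count** (the sum
of the five major lineage totals) and log-transformed:
`x[s,t] = log((c[s,t] + 0.5) / sum_l c[s,l])`. Age, sex and (as a batch
surrogate) top principal components are regressed out column-wise before
patient-level clustering.

Hierarchical clustering is run at three resolutions, each with an
admissibility rule that fixes the number of clusters *k*:

| resolution | distance | linkage | rule for k |
|---|---|---|---|
| cell types | 1 − Pearson r | average | smallest k whose clusters do not mix the T / B / innate lineages |
| diseases | Euclidean, PC-space centroids | Ward | largest k in which every cluster keeps ≥ 2 diseases |
| patients | Euclidean, top-10-PC embedding | Ward | smallest k with ≥ 2 clusters each under 20 % of patients |

Robustness is quantified by stratified subsampling (95 % of each disease
group, re-clustering de novo including the choice of *k*) and scored by
maximum-agreement **concordance** between the subsample solution and the
full-data solution restricted to the subsample.

Three network layers summarise the structure: the cell-type correlation
network (edges at |r| > 0.4), the disease inverse-distance network (weights
1/d, edges above one third of the maximum weight), and a disease-by-cell-type
association network from backward-forward stepwise logistic regression of
disease-versus-control on all cell abundances (sex-adjusted), with edges
tiered by Bonferroni / BH-FDR 5 % / 10 % / nominal significance.

Association stages test per-disease heterogeneity of patient-cluster
membership (chi-square, Bonferroni 0.05/12), one-vs-rest cluster–clinical
associations (rank-sum / Fisher, BH-FDR), and polygenic-risk-score (PRS)
associations with clinical features and cell abundances (regression adjusted
for genetic PCs, BH-FDR < 0.10).

## Worked example

Generate the reference synthetic cohort (947 samples, 12 groups, six planted
patient archetypes), run the patient-resolution pipeline and compare with the
planted truth:

```r
library(airdstrat)

scen    <- scenario_patient_clusters(seed = 1)
cohort  <- generate_cohort(scen)
norm    <- normalize_log(qc_filter(cohort$counts)$counts)
resid   <- residualize(norm, cohort$metadata, n_pcs = 1)
patients <- cluster_patients(resid)
patients
#> Cluster solution (patient): 947 entities in k = 6 clusters
#>
#>   1   2   3   4   5   6
#> 219  75 220 227 103 103

truth <- planted_truth(cohort)$patient_cluster
mclust::adjustedRandIndex(truth[patients$entity_ids], patients$labels)
#> [1] 0.995
```

The admissibility rule settles on six clusters — the planted resolution —
and the partition agrees with the truth at ARI 0.995. The cluster sizes
(8–24 % of the cohort) mirror the planted proportions. In this scenario the
archetypes were planted independently of diagnosis, so the per-disease
heterogeneity test is correctly null:

```r
het <- cluster_heterogeneity(cohort$metadata, patients)
head(het[order(het$p), c("feature", "effect", "p", "tier")], 2)
#>   feature     effect         p tier
#> 5     IIM 0.01834248 0.9972783 none
#> 10    SjS 0.01827791 0.9976002 none
```

Stability of the solution under 95 % stratified subsampling:

```r
fn  <- function(n, m) cluster_patients(n)
rep <- stability_run(resid, cohort$metadata, fn, fraction = 0.95,
                     n_iter = 100, seed = 1)
rep$mean_concordance
#> [1] 0.9963
```

`run_full_pipeline(run_config(scenario = ..., out_dir = "run"))` executes
all six stages (preprocess, three-resolution clustering, stability,
networks, associations) and writes TSV/JSON/GraphML artifacts plus a
deterministic manifest; `inst/scripts/airdstrat-run.R` wraps this for shell
use with a YAML config.

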
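# boolgate

Detects genes whose nutrient/light regulation depends on a
transcription-factor genotype, and summarizes how the regulation changes as
Boolean logic.

The package targets a common design in plant systems biology: a balanced
2×2×2 factorial crossing nitrogen treatment (−N / +N), light (dark / light)
and genotype (knockout mutant vs. wild-type sibling), with biological
replicates in every cell and expression measured on arrays or any platform
producing a genes × samples signal matrix with per-sample detection calls.
It is written for the analyst who has such a matrix and wants the full
chain from per-gene statistics to interpretable per-cluster regulatory
models.

## The method

1. **Detection filter** — drop genes called Absent on every array.
2. **Per-gene 3-way factorial ANOVA** — for each gene,
   `y ~ N + L + G + L:N + L:G + N:G + N:L:G` on log2 signals, fitted by the
   closed-form balanced-design decomposition (exact match with `aov`,
   vectorized over all genes). Genes with p ≤ 0.01 on any
   genotype-containing term (`G`, `N:G`, `L:G`, `N:L:G`) form the
   *genotype union*: the genes whose environmental regulation the mutation
   alters. A plug-in FDR estimate (α·m / #discoveries) is reported per term
   and pooled.
3. **Clustering** — union genes are clustered on replicate-averaged
   8-condition profiles (Pearson distance, average linkage); the number of
   clusters comes from the leave-one-condition-out Figure of Merit with a
   segmented-fit elbow.
4. **Boolean gate inference** — per cluster and genotype, a stacked 2-way
   ANOVA plus a binarized centroid select one of the 16 two-input Boolean
   functions of (N, L), rendered as AND/OR/XOR gates with negated inputs
   and an activation/repression sign.
5. **De-regulation typing** — the wild-type/mutant gate pair is classified
   as **attenuation** (same logic, weaker in the mutant), **inversion**
   (sign-flipped logic), **hidden** (regulation only in the mutant) or
   **complex** (anything else).

A synthetic-data generator (`generate_dataset`, `study_cluster_roster`)
plants clusters with known Boolean logic and class, so every stage can be
validated against ground truth; `binomial_overrepresentation` tests
functional-term enrichment of gene lists; `linkage_scan` screens the
mutated locus' chromosome for genotype fold changes that would betray a
linked second insertion.

## Worked example

Simulate the 20-cluster benchmark study (240 genes, 2×2×2 × 3 replicates)
and run the pipeline stages:

```r
library(boolgate)

sim  <- generate_dataset(simulation_config(clusters = study_cluster_roster(),
                                           seed = 1))
ds   <- filter_by_detection_calls(sim$dataset)
lists <- select_genes(fit_all(ds), alpha = 0.01)
lists
#> significant genes at p <= 0.01 (plug-in FDR pooled: 0.033)
#>   N         70 genes (term FDR 0.034)
#>   L         61 genes (term FDR 0.039)
#>   G        134 genes (term FDR 0.018)
#>   L:N       88 genes (term FDR 0.027)
#>   L:G       55 genes (term FDR 0.044)
#>   N:G       39 genes (term FDR 0.062)
#>   N:L:G     56 genes (term FDR 0.043)

union <- genotype_union(lists)          # 173 genotype-dependent genes
pm    <- condition_profiles(ds, union)
fom   <- figure_of_merit(pm)            # selects k = 19
dend  <- hierarchical_cluster(correlation_distance(pm))
models <- infer_cluster_models(ds, cut_clusters(dend, fom$selected_k, pm))
models
#> cluster_01  n=11  attenuation  WT: N XOR L -> activation        mut: N XOR L -> activation
#> cluster_02  n=6   attenuation  WT: L -> repression              mut: L -> repression
#> ...
#> cluster_12  n=8   hidden       WT: <unregulated>                mut: L -> repression
#> ...
#> cluster_18  n=14  complex      WT: NOT N AND NOT L -> activation mut: N -> repression
```

Each line is one co-expressed cluster: its size, its de-regulation class,
and the inferred Boolean regulation per genotype (`NOT` marks a negated
input, the sign tells whether the gate output activates or represses the
cluster). Here the pipeline recovers 19 of the 20 planted clusters — two
attenuation clusters with correlated profiles merge — and 18/20 planted
gates and 20/20 classes are recovered exactly
(`score_recovery(sim$truth, cluster_membership(...), models)`).

`run_pipeline(pipeline_config(...))` performs the same chain end to end and
writes all intermediates (ANOVA table, per-term gene lists, FOM curve,
cluster memberships, per-cluster Boolean models as JSON, summary) into an
output directory, every file carrying the configuration in its header.

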
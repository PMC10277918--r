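# imcohort

`imcohort` is an R package for analysing multiplexed imaging mass cytometry
(IMC) cohorts at single-cell resolution, built around the question of
whether the cellular composition of a tumor — in particular the abundance of
a vimentin-high, hormone-receptor-positive epithelial phenotype — separates
patients who recur from patients who do not. It targets studies of the
common design: a tissue-microarray cohort imaged in several acquisition
batches, segmented into per-cell label masks, with per-patient
recurrence-free follow-up.

The package covers the full chain from pixels to survival curves:

1. **Quantification** — per-cell mean intensities, centroids and areas from
   a multi-channel image plus integer label mask (`quantify_image()`,
   `merge_images()`).
2. **Preprocessing** — quantile-anchored ("range") batch correction that
   maps each batch's trimmed intensity range onto a reference, followed by
   the arcsinh transform with cofactor 5
   (`range_batch_correct()`, `arcsinh_transform()`).
3. **Gating** — rule-based population calls with per-image thresholds
   (epithelial = E-cadherin⁺ cytokeratin⁺ αSMA⁻, CD8 T = CD8a⁺ CD3⁺, …)
   and the compartment subtraction arithmetic
   (`apply_gates()`, `compartment_counts()`).
4. **Phenotyping** — PhenoGraph-style clustering (k-nearest-neighbor graph,
   Jaccard edge weights, Louvain modularity optimisation), marker
   enrichment modeling (MEM) scores in \[−10, 10\], hierarchical
   meta-clustering, and patient-level tumor grouping
   (`cluster_cells()`, `mem_scores()`, `meta_cluster()`,
   `cluster_tumors()`).
5. **Spatial neighborhoods** — mask-contact neighbor graphs and clustering
   of the cells directly adjacent to a query population
   (`build_neighbor_graph()`, `neighborhood_enrichment()`).
6. **Statistics and survival** — Mann-Whitney differential abundance,
   Fisher/Spearman helpers, Kaplan-Meier curves with the Mantel-Cox
   log-rank test, median/quartile/zero dichotomisation, the IHC staining
   index SI = intensity(0–3) × area(1–3), and purity-based sample selection
   (`compare_abundance()`, `km_logrank()`, `staining_index()`,
   `select_high_purity()`).

Because raw IMC cohorts of this kind are rarely public, the package ships a
first-class synthetic cohort generator (`cohort_config()`,
`simulate_cohort()`) that emits multi-channel images, label masks, panel,
clinical and ground-truth tables with planted phenotype shifts, batch
factors and survival contrasts, so that every downstream stage can be
validated against known truth.

All user-facing functions take and return tibbles and chain with the pipe;
fitted objects have `tidy()`, `glance()` and `autoplot()` methods.

## Core model

Cells are clustered on a z-scaled 21-marker profile by building the k = 30
nearest-neighbor graph (Euclidean), reweighting each edge by the Jaccard
similarity of the two cells' neighbor sets, and maximising weighted
modularity with Louvain. Each cluster c is annotated per marker m by the
MEM enrichment

    MEM(c, m) = sign(Md_c − Md_ref) · ( |Md_c − Md_ref| + IQR_ref/IQR_c − 1 )

against all cells outside c, scaled so the largest |MEM| is 10. Clusters
are merged into meta clusters by average-linkage hierarchical clustering of
their profiles. Per-patient meta-cluster fractions are compared between
recurrence groups with two-sided Mann-Whitney U tests, and patient-level
summaries (e.g. median epithelial vimentin) are dichotomised and compared
by Kaplan-Meier / log-rank.

## Worked example

```r
library(imcohort)
library(dplyr)

cfg <- cohort_config(n_patients = 16, n_recurrent = 8,
                     images_per_patient = c(2, 2),
                     cells_per_image = c(250, 350),
                     image_size_px = c(300, 300))
cohort <- simulate_cohort(cfg, seed = 1)
cohort
#> Synthetic IMC cohort: 16 patients (8 recurrent), 32 images, 9716 cells
#>   panel: 21 markers; images rendered

cells <- cohort |>
  quantify_cohort() |>
  range_batch_correct() |>
  arcsinh_transform() |>
  apply_gates()

clusters <- cluster_cells(cells, k = 30, seed = 1)
clusters
#> PhenoGraph clustering: 9716 cells, 11 clusters, modularity 0.802

mem  <- mem_scores(cells, clusters)
meta <- meta_cluster(mem, n_meta = 6)

assign_meta <- left_join(clusters$assignments, meta, by = "cluster")
fractions   <- cluster_fractions(assign_meta, cluster_col = "meta_cluster")
ab <- compare_abundance(fractions, cohort$clinical)
tidy(ab) |> arrange(p_value)
#> # A tibble: 6 × 6
#>   cluster median_nonrecurrent median_recurrent     u  p_value significant
#>     <int>               <dbl>            <dbl> <dbl>    <dbl> <lgl>
#> 1       1              0.299            0.153     64 0.000778 TRUE
#> 2       2              0.247            0.350      0 0.000778 TRUE
#> 3       3              0.145            0.173      8 0.0117   TRUE
#> 4       5              0.0505           0.0650    19 0.172    FALSE
#> 5       6              0.120            0.131     19 0.172    FALSE
#> 6       4              0.136            0.127     33 0.916    FALSE
```

Meta cluster 1 — the vimentin-high epithelial phenotype planted by the
generator — holds a median 29.9% of cells in non-recurrent patients but
only 15.3% in recurrent ones (U = 64, the maximum for 8 vs 8 patients,
p ≈ 8 × 10⁻⁴): the planted depletion is recovered. Dichotomising patients
by median epithelial vimentin and comparing recurrence-free survival:

```r
vim <- cells |>
  filter(gate_epithelial) |>
  group_by(patient_id) |>
  summarise(vimentin = median(vimentin))
km <- km_logrank(cohort$clinical[match(vim$patient_id,
                                       cohort$clinical$patient_id), ],
                 groups = dichotomize(vim$vimentin, "median"))
km
#> Kaplan-Meier recurrence-free survival comparison
#>   log-rank (Mantel-Cox) chi-square = 15.370, df = 1, p = 8.836e-05
#>   patients (events): low 8 (8), high 8 (0)
autoplot(km)
```

All eight recurrences fall in the vimentin-low half — the survival contrast
the generator ties to vimentin-low status at hazard ratio 4.

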
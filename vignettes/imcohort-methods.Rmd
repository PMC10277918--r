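---
title: "Methods: from label masks to recurrence-free survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from label masks to recurrence-free survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imcohort)
```

`imcohort` implements a single-cell analysis chain for multiplexed imaging
mass cytometry (IMC) cohorts: quantification from segmentation masks, batch
correction, gating, graph-based phenotyping with meta-clustering, spatial
neighborhood enrichment, differential abundance and survival analysis. This
vignette explains each stage's model, its assumptions, the parameters that
matter, and the numerical choices made where the design was genuinely open.
It also describes exactly what the synthetic cohort generator does and does
not emulate, because every empirical claim in the test suite is made
against that generator, not against real tissue.

## The synthetic cohort generator

The generator is the package's study-design document in executable form.
Its defaults describe a two-batch TMA study of 36 stage IB endometrial
tumors, 17 of them recurrent, each patient contributing 1–3 ablated cores
of 2,000–3,300 cells (roughly 2,000–10,000 cells per patient), imaged with
a 21-marker panel.

**Cells.** Each image is populated by `place_cells()`: disk-shaped cells
with radii drawn uniformly from 2–4 px are placed by random sequential
adsorption on an 800 × 800 px frame (a ~1 mm core at ~1 µm resolution),
using a spatial hash grid so placement stays near-linear. A configurable
fraction (default 0.3) of cells is placed deliberately in contact
(boundary gap ≤ 1 px) with an earlier cell so that contact-based neighbor
graphs are non-trivial; all other pairs keep a minimum boundary gap
(default 2 px). Disks never overlap, so each label is a connected,
pairwise-disjoint pixel set. When a contact placement is geometrically
blocked (every candidate partner already sits in a tight pair), the cell
falls back to random placement after half the attempt budget — the contact
fraction is a target, not a guarantee. Configurations whose requested
density exceeds what sequential packing can achieve are rejected up front
("infeasible geometry").

**Intensities.** Each phenotype is a log-normal intensity profile: "on"
markers at log-mean 3 (≈ 20 counts), intermediate at 1.5, background at
−0.7 (≈ 0.5 counts), log-SD 0.4 throughout. No canonical per-marker intensity distribution
exists for data of this kind; log-normal is an explicit modelling
assumption recorded in the configuration, not a claim about real
tissue. Within a cell, pixels are
uniform by default (`pixel_noise_cv = 0`), which makes quantification
round-trip exactly; a positive coefficient of variation adds Gaussian
pixel noise, and the truth table then records the realized per-cell pixel
mean so the round-trip contract stays well-defined.

**Batches.** Images cycle through acquisition batches (core 1 → batch 1,
core 2 → batch 2), and each batch multiplies all raw intensities by a
per-marker factor — by default 1.0 and 1.5. A multiplicative effect is
exactly the kind of distortion a quantile-anchored affine correction can
remove, which makes the batch-correction invariant testable rather than
merely plausible.

**Composition and outcome.** Six default phenotypes span the compartments
of an endometrial tumor core: vimentin-high ER⁺/PR⁺ epithelium (30%),
vimentin-low epithelium (25%), αSMA⁺ stroma (25%), CD8 T cells (8%),
macrophages (6%) and endothelium (6%). In recurrent patients the
vimentin-high epithelial fraction shifts by −0.15 (compensated by the
other compartments and renormalised); patient-to-patient composition
varies around the group mean as a Dirichlet draw with precision 200,
i.e. a fraction of 0.3 has an SD of ≈ 0.03 — enough noise that group
comparisons are honest rank tests, not foregone conclusions.

**Survival.** Recurrent patients draw exponential event times;
non-recurrent patients draw uniform censoring times on 12–72 months — the
simplest model under which log-rank recovery is testable. The event rate
is log(2)/36 per month (median ≈ 36 months), multiplied by a hazard ratio
(default 4) for patients whose planted vimentin-high epithelial fraction
lies below the cohort median. Times are reported in months from primary
treatment, with `event = 1` only for recurrence.

**Determinism.** All table-level draws happen before any rasterisation, so
`simulate_cohort(cfg, seed)` produces identical clinical/truth tables
whether or not images are rendered, and identical everything for identical
config + seed. `render_images = FALSE` is the fast path used by the
50-seed recovery studies, which only need compositions and survival times.

What the generator does **not** emulate: realistic tissue texture and
marker spillover, nuclear/membrane sub-compartments, segmentation errors,
spatially organised micro-environments (phenotypes are placed independently
of position), and storage- or staining-related drift. Passing tests
therefore demonstrate that the pipeline recovers known structure of this
statistical form at these sample sizes — not that it is robust to every
artefact of real IMC data.

## Quantification

`quantify_image()` computes, per mask label, the mean of each channel over
the cell's pixels, the unweighted pixel centroid and the pixel area. Mean
(not summed) intensity is used because it is standard IMC practice and
invariant to cell area. Pixel coordinates are 0-based with x = column and
y = row, a convention stated once and used everywhere, including the
neighbor analysis. Labels need not be consecutive; every positive label
yields exactly one row, and quantification is invariant to label
renumbering. `merge_images()` concatenates per-image tables (the two cores
of one tumor) and enforces a globally unique (image, cell) key.

## Batch correction and transformation

`range_batch_correct()` realises range-style unanchored batch correction as
a quantile-anchored affine map: per marker and batch, the batch's
(q_low, q_high) = (0.01, 0.99) intensity quantiles are sent onto the
reference quantiles, pooled over all cells by default (no reference batch
is privileged). Trimming at the 1st/99th percentile keeps single extreme
pixels from defining the map; the exact anchors are configurable.
Corrected intensities are clipped at zero; a batch whose anchors coincide
(a degenerate, near-constant channel) is left unchanged with a warning.
Correction happens on raw intensities *before* the arcsinh transform,
matching the order in which such corrections are applied to signal
intensities ahead of downstream import.

Two properties are worth separating. The anchor quantiles of all batches
agree after correction to ~1e−6 by construction (an affine map commutes
with the linearly interpolated empirical quantile). The between-batch
*median* gap, in contrast, is a noisy statistic for bimodal markers: when
the pooled median falls in the low-density valley between an "off" and an
"on" mode, tiny composition differences move it a long way. At the
default cohort scale (~95,000 cells per batch in a paired two-core
design) the residual per-marker median gap after correcting the planted
×1.5 factor is typically 2–5%; the dominant term is median sampling noise,
not uncorrected batch effect.

`arcsinh_transform()` applies asinh(x / cofactor) with cofactor 5, the
standard variance-stabilising transform for mass-cytometry counts: linear
near zero, logarithmic for large counts, strictly increasing and
invertible. The transform overwrites the marker columns in place — the
pipeline order (correct raw, then transform) is explicit in user code
rather than tracked by parallel column sets.

## Gating

`apply_gates()` assigns population labels by marker-threshold rules:
epithelial (E-cadherin⁺ cytokeratin⁺ αSMA⁻), non-epithelial (αSMA⁺
E-cadherin⁻), CD8 T (CD8a⁺ CD3⁺) and proliferative (Ki-67⁺) by default.
Thresholds are resolved independently per image; the default policy is
Otsu's method on the transformed values — the reproducible analogue of
setting cut-offs "by eye" for each image — with per-image quantile and
fixed-value policies as overrides, and a quantile fallback (with warning)
when Otsu is unresolvable on a constant channel. Labels from distinct
rules may overlap; epithelial and non-epithelial are mutually exclusive by
rule construction. Cells matching neither compartment remain unassigned
rather than being forced, and the unassigned fraction is reported by
`compartment_counts()`.

`compartment_counts()` implements the subtraction arithmetic: for each
immune population, cells inside the epithelial compartment are estimated
as total − in-non-epithelial; stromal cells are the non-epithelial cells
left after subtracting immune populations. Derived counts that go negative
under threshold noise are floored at zero with a warning — the arithmetic
itself offers no other principled repair.

## Phenotyping

`build_knn_graph()` uses k = 30 Euclidean nearest neighbors on per-marker
z-scaled values (scaling prevents high-dynamic-range markers from
dominating; a flag disables it), symmetrises the edge set, and weights
each edge by the Jaccard similarity of the two cells' neighbor sets. The
neighbor set includes the cell itself, so any kNN edge has weight in
(0, 1] — three mutually equidistant points at k = 2 form a complete graph
of weight 1. k = 30, Euclidean distance, Jaccard weighting and Louvain at
resolution 1.0 are the canonical PhenoGraph defaults; none is dictated by
the data, all are exposed. The exact kNN search is delegated to
BiocNeighbors.

`louvain_communities()` maximises weighted modularity at the requested
resolution (igraph's Louvain), with the random seed fixed for
reproducibility; cluster ids are contiguous and ordered by decreasing
size. The reported modularity is verified in the test suite against the
direct Newman formula evaluated on the returned partition, and on small
graphs against exhaustive maximisation over all partitions.

`mem_scores()` quantifies each cluster against all remaining cells:
sign(Δmedian) · (|Δmedian| + IQR_ref/IQR_pop − 1), scaled per run so the
largest absolute score is 10. A zero IQR (a constant marker within a
cluster) is replaced by the smallest positive IQR observed in the run,
with a message. When the medians tie, the score is zero — the sign
convention zeroes the IQR term as well, which keeps "identical
distributions score 0" exact at the cost of ignoring pure-dispersion
enrichment; this trade-off is deliberate and documented here.

`meta_cluster()` agglomerates cluster profiles (MEM scores or median
profiles) with average linkage on Euclidean distance and cuts at a
user-chosen number of meta clusters. The published meta-cluster counts for
cohorts of this design (11, 7, 7, …) are data-driven outcomes, not
parameters, so `n_meta` is always explicit. `cluster_tumors()` builds one
feature vector per patient — per-marker medians, meta-cluster fractions,
or both (which variant a given study used is often underdetermined, so
both are implemented) — z-scales features, clusters with average linkage
and labels groups in dendrogram order; patients under 100 cells (default)
are excluded with a warning.

`compare_abundance()` runs a two-sided Mann-Whitney U test per cluster on
per-patient fractions between outcome groups and reports raw p-values —
the reporting convention for this kind of per-cluster screen — with an
optional Benjamini-Hochberg column that is off by default.

## Spatial neighborhoods

`build_neighbor_graph()` declares two cells neighbors when dilating one
cell's pixel set by `expansion_px` (default 4, a conventional
pixel-expansion radius; no radius is canonical) reaches the other —
equivalently, when the minimum Euclidean distance between their pixel
centers is at most `expansion_px`. Only boundary pixels are searched,
since the minimum inter-cell distance is always attained at boundaries;
the fixed-radius search is again delegated to BiocNeighbors, and the edge
set is validated in tests against an O(n²) all-pairs pixel-distance
oracle. Neighbors are computed within an image only, and query cells are
excluded from their own neighbor set by default (the object of interest is
the cells *adjacent to* the query population), with a flag to include
them. `neighborhood_enrichment()` then reuses the phenotyping stack on the
neighbor subset and tests per-patient neighbor-cluster fractions between
recurrence groups.

## Statistics and survival

`mann_whitney_u()` is two-sided throughout, exact (via the null
distribution of U) when the pooled sample size is ≤ 12 and tie-free, and
a tie-corrected normal approximation without continuity correction
otherwise — so identical samples give p = 1 exactly, and an all-tied
comparison (zero variance) is defined as p = 1. `spearman_cor()` uses
average ranks and rejects constant input. `fisher_exact()` sums
hypergeometric probabilities no larger than the observed table's.
`km_logrank()` wraps the product-limit estimator and the Mantel-Cox
log-rank chi-square (survival package), reporting per-group
"patients (events)" labels as used in survival figure legends; time zero
is primary treatment and `event = 0` covers both end of follow-up and
death from other causes.

`dichotomize()` supports three rules: median (values at the median go to
the *low* group — the tie side is not universally standardised, so the
choice is documented and fixed), lowest quartile, and zero-vs-positive
(for staining-index data, loss = SI 0). `staining_index()` is the product
of an intensity score {0, 1, 2, 3} and an area score {1, 2, 3}, giving the
codomain {0, 1, 2, 3, 4, 6, 9} with maximum 9. `select_high_purity()`
keeps the floor(fraction · n) lowest purity scores (lower = purer), with
deterministic ties broken by sample id; the floor convention makes
0.33 × 254 select 83 samples.

## Problem sizes in the test suite

The suite validates statistical recovery at the design's patient-level
dimensions (36 patients, 17 recurrent, −0.15 fraction shift, hazard ratio
4, 50 seeds) while keeping per-patient cell counts and image frames
compact — a few hundred cells per patient on 200–300 px frames for the
rendered fixtures, and the table-only fast path for the 50-seed loops.
Patient-level power depends on the number of patients and the
between-patient composition noise, both of which are kept at design scale;
cell counts only sharpen the per-patient fraction estimates, and a few
hundred cells already estimate a 0.15–0.30 fraction to within ~0.02. The
batch-correction invariant is the exception: it is checked at full cell
counts (~190,000 cells) because the residual median gap is dominated by
median sampling noise, which is only small at that scale.

## Known limitations

* The generator plants composition, batch and survival structure but not
  spatial micro-architecture; neighborhood enrichment is exercised through
  composition differences among neighbors, not through planted
  phenotype-to-phenotype adjacency preferences.
* Louvain determinism is per seed and igraph version; partitions may
  legitimately differ across igraph releases even at the same seed.
* Otsu-per-image gating assumes each gated marker is roughly bimodal
  within each image; on markers without a clear positive population the
  threshold is arbitrary (the quantile fallback warns only for exactly
  constant channels).
* The epithelial/non-epithelial gate pair is not exhaustive, and all
  compartment percentages are reported against explicitly named
  denominators for that reason.
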
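# dcspatial

Spatial analysis of dendritic-cell (DC) organization in lymph-node
cell-coordinate maps.

Quantitative imaging of immunostained lymph-node sections produces tables
of classified cells — pixel coordinates plus a phenotype (CD1a+/CD83−
immature DC, CD83+ mature DC, CD3+ T cell, CD20+ B cell,
pan-cytokeratin+ tumor, hematoxylin-only other). `dcspatial` turns such
tables into the statistics that distinguish healthy from tumor-draining
nodes: how many DCs a node holds, how mature they are, how strongly they
aggregate into parafollicular clusters, how many T cells sit within reach
of clustered versus isolated DCs, and whether those metrics stratify
patient disease-free survival. It is aimed at researchers analyzing
multiplexed-IHC or digital-pathology cell maps of lymphoid tissue.

## The model

**Density-based clustering (DBC).** For the DC subset `S` and parameters
`R` (radius, pixels) and `D` (density): every DC `p` with
`n(p) = |{q ∈ S : d(p,q) ≤ R}| ≥ D` (the center counts) makes all DCs in
its circle provisionally one cluster; provisional clusters sharing any
member merge transitively; uncovered DCs are noise. Unlike DBSCAN, border
points are not singly assigned — overlapping clusters merge wholesale.
Defaults `R = 250`, `D = 5` (calibrated against biologist-annotated
aggregates; re-derivable with `grid_search()`). `dbc_cluster()` is the
fast grid-indexed implementation; `dbc_oracle()` the quadratic reference
it is tested against.

**Node metrics.** `%DCs` and `%T cells` of the node total
(T + DC + other), `%mature DCs` (CD83+ of all DCs), `%clustered DCs`,
clusters per DC, mean cluster size, `%mature of clustered` — with missing
(not zero) values when a denominator is empty.

**Co-localization.** A T cell within 100 px of its nearest DC is
associated with that DC; per-DC T counts are compared between clustered
and noise DCs (`associate_t_cells()`, `coloc_summary()`).

**Cohort statistics.** Mann–Whitney and Wilcoxon signed-rank comparisons,
an eligibility filter (≥5 years follow-up unless relapsed earlier, no
concurrent cancer, DC percentage strictly inside the central 90%),
median-split stratification, Kaplan–Meier curves with the log-rank test,
and OLS for metric associations.

**Synthetic data.** `generate_node()` / `generate_cohort()` plant
hard-separated Gaussian DC aggregates with known ground truth, maturity
differing inside versus outside clusters, T-cell enrichment in the 100-px
disc of planted DCs, and exponential survival whose hazard decreases with
the node's true clustered fraction — the substrate for all recovery and
power testing.

## Worked example

```r
library(dcspatial)

g <- generate_node(synth_config(seed = 42))   # one synthetic node
a <- dbc_cluster(g$map)                       # R = 250 px, D = 5
a
#> dbc_assignment: 580 DCs, 10 clusters, 41 noise (R=250, D=5)

round(compute_node_metrics(g$map, a)[, 2:8], 3)
#>   pct_dcs pct_mature_dcs pct_clustered_dcs rel_cluster_count
#> 1  11.406         55.517            92.931             0.017
#>   mean_cluster_size pct_mature_clustered pct_t_cells
#> 1              53.9               56.957      49.735

clustered_label_f1(a, truth_annotation(g$truth))
#> [1] 0.9972093

unlist(coloc_summary(associate_t_cells(g$map), a))
#>   mean_t_clustered mean_t_unclustered   n_clustered_dcs n_unclustered_dcs
#>          1.0816327          0.6829268        539.0000000         41.0000000
```

539 of 580 DCs (92.9%) fall into 10 recovered clusters (F1 = 0.997
against the planted truth), and clustered DCs average ~1.08 associated
T cells against ~0.68 for isolated DCs — the planted enrichment.

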
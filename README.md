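# satkit — saturation analysis for single-cell RNA-seq atlas sampling

How many cells does an atlas experiment actually need? Droplet scRNA-seq
makes it cheap to profile hundreds of thousands of cells, but cluster
discovery saturates: past a certain point, additional cells reproduce the
same cell types instead of revealing new ones. `satkit` implements a
downsampling framework that measures where that point lies for a given
dataset, so study designers can trade "cellular coverage" of one sample
against profiling more individuals, organs, or time points.

It is aimed at computational biologists analyzing UMI count matrices
(10x-style MTX or HDF5 input) and works equally on simulated data — a
built-in negative-binomial simulator with planted hierarchical cluster
structure makes every step testable without external downloads.

## The method

Starting from a QC-filtered genes × cells count matrix, `satkit` draws
nested random subsets (repeated halving, or an explicit fraction series),
re-clusters every subset independently (Louvain community detection on a
k-nearest-neighbor graph whose edges are weighted by the Jaccard similarity
of the endpoints' neighbor sets, built in significant-PC space), and scores
each subset against the full analysis. Because subsets keep their barcodes,
two clusterings are compared cell-by-cell through an overlap (contingency)
table N over their common cells, with reference clusters *i* and subset
clusters *j*:

- **Preservation** of reference cluster *i*: max_j N_ij / N_i· — the
  largest fraction of the cluster's cells found together in any single
  subset cluster (top-down stability).
- **Conservation** of subset cluster *j*: max_i N_ij / N_·j — the
  reciprocal, bottom-up score.
- **Split** of cluster *i*: #{ j : N_ij ≥ 1 } — how many clusters of the
  opposite analysis its cells land in. Preservation 0.5 with split 2 is an
  even two-way split; preservation 0.5 with split 10 is scattering.
- **Complexity index**: the total branch length of an average-linkage
  dendrogram over cluster centroids computed in one fixed reference PC
  space — a relative, unitless measure of how heterogeneous a cell set is,
  comparable across subsets of the same dataset.
- **Saturation verdict**: regress mean preservation on subset size (and on
  complexity) by OLS, then re-fit while truncating the largest x values one
  at a time. When the full-data fit has R² < 0.6 *and* R² does not increase
  as larger subsets are admitted, the curve has bent into a plateau:
  sampling is saturated.

Rand / adjusted-Rand indices, per-cluster Wilcoxon marker detection with
Benjamini–Hochberg correction, unique-marker accounting, and marker
retention through downsampling round out the toolkit.

## Worked example

```r
library(satkit)

x  <- simulate_counts(sim_config(n_cells = 2000, n_genes = 200, seed = 101))
qc <- qc_filter(x, qc_params(min_genes = 100))
pars <- function(s) clustering_params(louvain_seed = s, resolution = 0.1)

full  <- cluster_pipeline(qc$matrix, pars(7))
truth <- cluster_assignment(barcodes(qc$matrix), qc$matrix$truth_labels, "truth")
compare_analyses(truth, full$assignment)
#> ClusterComparison ('truth' vs 'full[k=10,pcs=6/50,res=0.1,seed=7]'): 1844 common cells
#>   mean preservation 1.000 | mean conservation 1.000 | Rand 1.000 | ARI 1.000

series <- nested_halving(barcodes(qc$matrix), 4, seed = 202)
subs <- lapply(1:4, function(l) {
  r <- cluster_pipeline(qc$matrix[, series$subsets[[l]]], pars(7 + l))
  r$assignment$analysis_id <- paste0("half^", l)
  r$assignment
})
rep <- saturation_report(subs, full$assignment, full$space)
rep$curve
#>   subset n_cells complexity n_clusters mean_preservation mean_conservation
#> 1 half^1     922   62.41422          5                 1                 1
#> 2 half^2     461   62.18148          5                 1                 1
#> 3 half^3     230   61.84476          5                 1                 1
#> 4 half^4     115   61.78027          5                 1                 1
rep
#> SaturationReport over 4 subsets
#>   vs cell number: SaturationCurve: 4 points, full-data R^2 = 0.000 (threshold 0.60) -> saturated
#>   vs complexity:  SaturationCurve: 4 points, full-data R^2 = 0.000 (threshold 0.60) -> saturated
```

Five well-separated simulated cell types are recovered exactly (ARI 1
against truth); every halving level reproduces all five clusters with mean
preservation 1 and near-constant complexity, so the preservation curve is
flat and both scans call the dataset saturated — 115 cells already tell the
same story as 1,844. A rare (<1 %) planted population behaves differently:
see `plant_rare_population()` and the methods vignette.

`run_saturation_pipeline()` wires all stages together (QC → full clustering
→ downsampling replicates → per-subset re-clustering → comparison →
complexity → verdict), writes label TSVs, overlap CSVs, curves and a
reproducibility manifest, and `inst/cli/satkit.R` exposes each stage as a
shell subcommand (`simulate`, `qc`, `cluster`, `recluster`, `downsample`,
`compare`, `markers`, `saturate`, `run`).

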
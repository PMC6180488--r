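#' Clustering parameters
#'
#' @param n_pcs_total Principal components computed by the pipeline.
#' @param n_neighbors `k` for the k-nearest-neighbor graph (Euclidean
#'   distance in PC space).
#' @param use_significant_pcs Restrict distances to the significant PCs
#'   (Marchenko-Pastur rule) rather than all `n_pcs_total`.
#' @param louvain_seed Seed for the Louvain community detection.
#' @param resolution Louvain resolution (1 = classic modularity).
#' @param min_genes_variable Optional number of most-variable genes to keep
#'   before PCA; `NULL` uses all genes.
#' @return A `ClusteringParams` list.
#' @export
clustering_params <- function(n_pcs_total = 50, n_neighbors = 10,
                              use_significant_pcs = TRUE,
                              louvain_seed = 1L, resolution = 1.0,
                              min_genes_variable = NULL) {
  stopifnot(n_neighbors >= 2, n_pcs_total >= 1, resolution > 0)
  structure(list(n_pcs_total = as.integer(n_pcs_total),
                 n_neighbors = as.integer(n_neighbors),
                 use_significant_pcs = isTRUE(use_significant_pcs),
                 louvain_seed = as.integer(louvain_seed),
                 resolution = resolution,
                 min_genes_variable = min_genes_variable),
            class = "ClusteringParams")
}

# k nearest neighbors (excluding self) by Euclidean distance; ties broken by
# cell index so downstream clustering is exactly reproducible. The compiled
# kernel and the plain-R fallback implement identical semantics; the R
# version doubles as the oracle in the test suite.
knn_indices <- function(scores, k) {
  n <- nrow(scores)
  if (n < k + 1L) {
    stop(sprintf("need at least k+1 = %d cells for a %d-NN graph, got %d",
                 k + 1L, k, n))
  }
  .knn_indices_cpp(scores, as.integer(k))
}

knn_indices_r <- function(scores, k, block = 1024L) {
  n <- nrow(scores)
  if (n < k + 1L) stop("too few cells")
  sq <- rowSums(scores^2)
  nn <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(scores[idx, , drop = FALSE], scores)
    for (r in seq_along(idx)) {
      d <- d2[r, ]
      d[idx[r]] <- Inf                      # exclude self
      nn[idx[r], ] <- order(d)[seq_len(k)]  # order() breaks ties by index
    }
  }
  nn
}

#' k-nearest-neighbor graph with Jaccard edge weights
#'
#' Builds the graph used for community detection: cells are connected when
#' one is among the other's `k` nearest neighbors in (significant) PC space,
#' and each edge is weighted by the Jaccard similarity of the two endpoint
#' cells' neighbor sets (`|N(a) intersect N(b)| / |N(a) union N(b)|`, the
#' sets excluding the cells themselves). Zero-weight edges are dropped.
#'
#' @param space An `EmbeddingSpace`.
#' @param params A [clustering_params()] object.
#' @return An `igraph` graph with vertex names set to barcodes and a
#'   `weight` edge attribute in `(0, 1]`; also classed `NeighborGraph`.
#' @export
knn_jaccard_graph <- function(space, params = clustering_params()) {
  d <- if (params$use_significant_pcs) {
    min(space$n_significant, ncol(space$pc_scores))
  } else {
    min(params$n_pcs_total, ncol(space$pc_scores))
  }
  scores <- space$pc_scores[, seq_len(d), drop = FALSE]
  k <- params$n_neighbors
  nn <- knn_indices(scores, k)
  edges <- .jaccard_edges_cpp(nn)
  g <- igraph::graph_from_data_frame(
    data.frame(from = rownames(scores)[edges$from],
               to = rownames(scores)[edges$to],
               weight = edges$weight),
    directed = FALSE,
    vertices = data.frame(name = rownames(scores)))
  class(g) <- c("NeighborGraph", class(g))
  g
}

#' Louvain community detection on a neighbor graph
#'
#' Runs weighted Louvain modularity optimization. Disconnected components
#' are handled natively (each is partitioned independently). The result is
#' deterministic for a fixed `louvain_seed`.
#'
#' @param graph A [knn_jaccard_graph()] result (any weighted `igraph` works).
#' @param params A [clustering_params()] object.
#' @param analysis_id Name recorded in the returned assignment.
#' @return A `ClusterAssignment` whose labels are cluster numbers as strings.
#' @export
louvain_cluster <- function(graph, params = clustering_params(),
                            analysis_id = "louvain") {
  if (igraph::vcount(graph) == 0L) stop("louvain_cluster: empty graph")
  set.seed(params$louvain_seed)
  comm <- igraph::cluster_louvain(graph, resolution = params$resolution)
  cluster_assignment(igraph::V(graph)$name,
                     as.character(igraph::membership(comm)),
                     analysis_id = analysis_id)
}

#' Full clustering pipeline
#'
#' Composes the standard chain on a QC-filtered count matrix:
#' depth normalization (counts-per-10K, log1p) -> per-gene centering and
#' scaling -> PCA (`n_pcs_total` components) -> significant-PC selection ->
#' kNN-Jaccard graph -> Louvain. All parameters are recorded in the
#' assignment's `analysis_id`.
#'
#' @param x A `CountMatrix` (already QC-filtered).
#' @param params A [clustering_params()] object.
#' @param analysis_id Base name for the analysis.
#' @return List with `assignment` (a `ClusterAssignment`) and `space` (the
#'   `EmbeddingSpace` the clustering was computed in).
#' @export
cluster_pipeline <- function(x, params = clustering_params(),
                             analysis_id = "full") {
  expr <- normalize_counts(x)
  if (!is.null(params$min_genes_variable) &&
      params$min_genes_variable < nrow(expr)) {
    v <- apply(as.matrix(expr), 1, stats::var)
    expr <- expr[order(v, decreasing = TRUE)[seq_len(params$min_genes_variable)], ,
                 drop = FALSE]
  }
  space <- run_pca(expr, n_components = params$n_pcs_total,
                   reference_id = analysis_id)
  graph <- knn_jaccard_graph(space, params)
  id <- sprintf("%s[k=%d,pcs=%d/%d,res=%g,seed=%d]", analysis_id,
                params$n_neighbors, space$n_significant,
                ncol(space$pc_scores), params$resolution, params$louvain_seed)
  assignment <- louvain_cluster(graph, params, analysis_id = id)
  list(assignment = assignment, space = space)
}

#' Iterative reclustering of a cluster group
#'
#' Re-runs the full pipeline -- including a fresh PCA, so new axes of
#' variation can surface -- on only the cells belonging to a set of clusters,
#' e.g. all clusters annotated as one broad type. Returned labels are
#' namespaced under the parent group (`"<group>.<sub>"`).
#'
#' @param x The `CountMatrix` the original assignment was computed from.
#' @param assignment The parent `ClusterAssignment`.
#' @param group Character vector of parent cluster labels to recluster.
#' @param params A [clustering_params()] object.
#' @return List with `assignment` and `space` for the subgroup analysis.
#' @export
iterative_recluster <- function(x, assignment, group,
                                params = clustering_params()) {
  group <- as.character(group)
  if (length(group) == 0L) stop("iterative_recluster: empty group")
  missing <- setdiff(group, unique(assignment$labels))
  if (length(missing)) {
    stop("iterative_recluster: unknown cluster label(s): ",
         paste(missing, collapse = ", "))
  }
  cells <- assignment$cells[assignment$labels %in% group]
  if (length(cells) < params$n_neighbors + 1L) {
    stop(sprintf("iterative_recluster: group has %d cells, need > %d",
                 length(cells), params$n_neighbors))
  }
  sub <- x[, cells]
  parent <- paste(sort(group), collapse = "+")
  res <- cluster_pipeline(sub, params, analysis_id = parent)
  res$assignment$labels <- paste(parent, res$assignment$labels, sep = ".")
  res
}

#' Correlation of gene loadings between two PC spaces
#'
#' Measures how well axes of variation are conserved between two analyses:
#' entry `(i, j)` is the absolute Pearson correlation of PC `i`'s gene
#' loadings in `space_a` with PC `j`'s loadings in `space_b`, computed over
#' the shared gene set.
#'
#' @param space_a,space_b `EmbeddingSpace` objects.
#' @return Matrix of absolute correlations in `[0, 1]`.
#' @export
pc_correlation <- function(space_a, space_b) {
  shared <- intersect(rownames(space_a$pc_loadings), rownames(space_b$pc_loadings))
  if (length(shared) == 0L) stop("pc_correlation: no shared genes")
  abs(stats::cor(space_a$pc_loadings[shared, , drop = FALSE],
                 space_b$pc_loadings[shared, , drop = FALSE]))
}
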
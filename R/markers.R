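#' One-vs-rest marker genes per cluster
#'
#' For every cluster and gene, tests the cells of the cluster against all
#' other cells with a two-sided Wilcoxon rank-sum test on the normalized
#' expression, adjusts p-values by Benjamini-Hochberg within each cluster,
#' and calls a gene a marker when it is significantly *up*: adjusted p below
#' `max_padj` and log2 fold-change of at least `min_lfc`. Fold-change is
#' computed on back-transformed means (`log2((mean(expm1(in)) + 1) /
#' (mean(expm1(rest)) + 1))`), the convention used by mainstream single-cell
#' toolkits.
#'
#' @param expr Normalized log1p genes x cells matrix (see
#'   [normalize_counts()]).
#' @param assignment `ClusterAssignment` over (a subset of) the columns.
#' @param min_lfc Minimum log2 fold-change.
#' @param max_padj Maximum BH-adjusted p-value.
#' @return A `MarkerTable` data frame with one row per (cluster, gene):
#'   `cluster`, `gene`, `avg_log2FC`, `p_value`, `p_adj`, `pct_in`,
#'   `pct_rest`, `is_marker`, `unique_marker` (marker of exactly one
#'   cluster).
#' @export
find_markers <- function(expr, assignment, min_lfc = 0.25, max_padj = 0.05) {
  cells <- intersect(colnames(expr), assignment$cells)
  if (length(cells) == 0L) stop("find_markers: no assignment cells in expr")
  x <- as.matrix(expr[, cells, drop = FALSE])
  labs <- assignment$labels[match(cells, assignment$cells)]
  clusters <- sort(unique(labs))
  if (length(clusters) < 2L) stop("find_markers: need at least 2 clusters")

  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    in_cl <- labs == cl
    if (sum(in_cl) < 2L) {
      warning(sprintf("find_markers: skipping cluster '%s' (size %d)", cl, sum(in_cl)))
      next
    }
    xi <- x[, in_cl, drop = FALSE]
    xr <- x[, !in_cl, drop = FALSE]
    pvals <- vapply(seq_len(nrow(x)), function(g) {
      a <- xi[g, ]; b <- xr[g, ]
      if (stats::var(c(a, b)) == 0) return(1)
      stats::wilcox.test(a, b, exact = FALSE)$p.value
    }, numeric(1))
    mean_in <- rowMeans(expm1(xi))
    mean_rest <- rowMeans(expm1(xr))
    lfc <- log2((mean_in + 1) / (mean_rest + 1))
    padj <- stats::p.adjust(pvals, method = "BH")
    out[[ci]] <- data.frame(cluster = cl, gene = rownames(x),
                            avg_log2FC = lfc, p_value = pvals, p_adj = padj,
                            pct_in = rowMeans(xi > 0),
                            pct_rest = rowMeans(xr > 0),
                            is_marker = padj <= max_padj & lfc >= min_lfc,
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  if (is.null(tab)) stop("find_markers: no cluster large enough to test")
  marker_genes <- tab$gene[tab$is_marker]
  n_clusters_marking <- table(marker_genes)
  tab$unique_marker <- tab$is_marker &
    tab$gene %in% names(n_clusters_marking)[n_clusters_marking == 1L]
  class(tab) <- c("MarkerTable", class(tab))
  tab
}

#' Per-cluster marker and unique-marker counts
#'
#' A gene counts as *unique* when it is a marker of exactly one cluster;
#' clusters with no unique marker have "no unique identifiers" -- they are
#' distinguished only by combinations of marker-level differences.
#'
#' @param table A `MarkerTable` from [find_markers()].
#' @return Data frame per cluster: `n_markers`, `n_unique`, and
#'   `no_unique_identifiers` flag.
#' @export
unique_marker_counts <- function(table) {
  agg <- stats::aggregate(cbind(n_markers = table$is_marker,
                                n_unique = table$unique_marker),
                          by = list(cluster = table$cluster), FUN = sum)
  agg$no_unique_identifiers <- agg$n_unique == 0L
  agg
}

#' Marker retention through downsampling
#'
#' What fraction of each reference cluster's markers is still called in the
#' matched subset cluster. Markers tend to be lost as cell number shrinks
#' and tests lose power.
#'
#' @param full_table `MarkerTable` of the reference analysis.
#' @param subset_table `MarkerTable` of the downsampled analysis.
#' @param cluster_map Named character vector mapping reference cluster ->
#'   best-matching subset cluster (e.g. from
#'   `compare_analyses(...)$preservation`, columns `cluster`/`best_match`).
#' @return Data frame per reference cluster: `n_full_markers`, `n_retained`,
#'   `retention` (`NA` for unmatched clusters).
#' @export
marker_retention <- function(full_table, subset_table, cluster_map) {
  full_clusters <- unique(full_table$cluster)
  res <- lapply(full_clusters, function(cl) {
    full_m <- full_table$gene[full_table$cluster == cl & full_table$is_marker]
    target <- cluster_map[[cl]]
    if (is.null(target) || is.na(target)) {
      return(data.frame(cluster = cl, matched = NA_character_,
                        n_full_markers = length(full_m),
                        n_retained = NA_integer_, retention = NA_real_))
    }
    sub_m <- subset_table$gene[subset_table$cluster == target & subset_table$is_marker]
    kept <- length(intersect(full_m, sub_m))
    data.frame(cluster = cl, matched = target,
               n_full_markers = length(full_m), n_retained = kept,
               retention = if (length(full_m)) kept / length(full_m) else NA_real_)
  })
  do.call(rbind, res)
}
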
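#' Cluster centroids in a reference PC space
#'
#' Every downsampled analysis is summarized in the *same* embedding (the PC
#' space of the largest reference set) so complexity indices are comparable
#' across subsets: a cluster's centroid is the arithmetic mean of its cells'
#' significant-PC scores in that space.
#'
#' @param space The reference `EmbeddingSpace`.
#' @param assignment A `ClusterAssignment` whose cells are present in
#'   `space` (downsampled subsets of the reference cells always are).
#' @param use_significant Restrict to the significant PCs (default) rather
#'   than all computed components.
#' @return Numeric matrix, one row per cluster (rownames = cluster labels).
#' @export
cluster_centroids <- function(space, assignment, use_significant = TRUE) {
  d <- if (use_significant) min(space$n_significant, ncol(space$pc_scores))
       else ncol(space$pc_scores)
  idx <- match(assignment$cells, rownames(space$pc_scores))
  labs <- sort(unique(assignment$labels))
  present <- !is.na(idx)
  missing_cluster <- setdiff(labs, unique(assignment$labels[present]))
  if (length(missing_cluster)) {
    stop("cluster_centroids: cluster(s) with no cells in the embedding: ",
         paste(missing_cluster, collapse = ", "))
  }
  scores <- space$pc_scores[idx[present], seq_len(d), drop = FALSE]
  g <- factor(assignment$labels[present], levels = labs)
  cent <- rowsum(scores, g) / as.vector(table(g))
  rownames(cent) <- labs
  cent
}

#' Complexity index of a set of cluster centroids
#'
#' Builds a hierarchical tree over the centroids (average linkage on
#' Euclidean distance by default) with leaves at height 0, and sums the
#' lengths of all branches (each edge's length is the parent merge height
#' minus the child's height). The sum is the complexity index: 0 for a
#' single cluster or identical centroids, and it scales linearly with the
#' centroid coordinates, so it is a relative, unitless measure of how spread
#' out -- how heterogeneous -- the cluster structure is.
#'
#' @param centroids Matrix from [cluster_centroids()] (clusters x PCs).
#' @param linkage `"average"` (default) or `"complete"`.
#' @return A `ComplexityTree`: list with `tree` (an `hclust`, or `NULL` for a
#'   single cluster), `leaves`, `branch_lengths`, and the scalar `index`.
#' @export
complexity_index <- function(centroids, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  if (k < 1L) stop("complexity_index: need at least one centroid")
  if (k == 1L) {
    return(structure(list(tree = NULL, leaves = rownames(centroids),
                          branch_lengths = numeric(0), index = 0),
                     class = "ComplexityTree"))
  }
  hc <- stats::hclust(stats::dist(centroids), method = linkage)
  # node height of each merge; children referenced as negative (leaf, height
  # 0) or positive (earlier merge)
  child_height <- function(ref, heights) if (ref < 0) 0 else heights[ref]
  bl <- numeric(0)
  for (m in seq_along(hc$height)) {
    for (ref in hc$merge[m, ]) {
      bl <- c(bl, hc$height[m] - child_height(ref, hc$height))
    }
  }
  structure(list(tree = hc, leaves = hc$labels, branch_lengths = bl,
                 index = sum(bl)),
            class = "ComplexityTree")
}

#' @export
print.ComplexityTree <- function(x, ...) {
  cat(sprintf("ComplexityTree: %d clusters, complexity index %.4g\n",
              max(1L, length(x$leaves)), x$index))
  invisible(x)
}

#' Complexity-targeted downsampling
#'
#' Selects the cells of a chosen set of clusters (e.g. one branch of the
#' complexity tree, to construct an intentionally low- or high-complexity
#' subset) and recomputes the complexity index on just those clusters'
#' centroids in the same reference space.
#'
#' @param space The reference `EmbeddingSpace`.
#' @param assignment The reference `ClusterAssignment`.
#' @param branch Character vector of cluster labels to keep.
#' @param use_significant Passed to [cluster_centroids()].
#' @return List with `cells` (barcodes of the selected clusters) and
#'   `complexity` (the sub-tree's `ComplexityTree`).
#' @export
complexity_downsample <- function(space, assignment, branch,
                                  use_significant = TRUE) {
  branch <- as.character(branch)
  if (length(branch) == 0L) stop("complexity_downsample: empty branch")
  missing <- setdiff(branch, unique(assignment$labels))
  if (length(missing)) {
    stop("complexity_downsample: unknown cluster(s): ",
         paste(missing, collapse = ", "))
  }
  keep <- assignment$labels %in% branch
  sub <- cluster_assignment(assignment$cells[keep], assignment$labels[keep],
                            analysis_id = paste0(assignment$analysis_id, ":branch"))
  cent <- cluster_centroids(space, sub, use_significant = use_significant)
  list(cells = sub$cells, complexity = complexity_index(cent))
}

r_squared <- function(x, y) {
  if (stats::var(y) == 0) return(0)   # degenerate plateau: no linear signal
  fit <- stats::lm.fit(cbind(1, x), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' R-squared truncation scan and saturation verdict
#'
#' The saturation framework: regress the preservation score on the x
#' variable (cell count or complexity index) by ordinary least squares, then
#' repeat the fit after removing the largest distinct x values one at a
#' time. Saturation is called when the full-data fit explains little
#' variance (R-squared below `threshold`) *and* R-squared does not increase
#' as ever-larger x values are admitted over the last `window` truncations
#' -- i.e. the curve bends into a plateau at the large-x end. A zero-variance
#' (perfectly flat) response has R-squared defined as 0 and is saturated.
#'
#' @param x,y Numeric vectors: subset size (or complexity) and mean
#'   preservation. `x` must be positive.
#' @param threshold Verdict threshold on the full-data R-squared.
#' @param min_points Smallest number of points (and distinct x values kept)
#'   for any fit.
#' @param window Number of final truncations over which R-squared must be
#'   non-increasing.
#' @return A `SaturationCurve`: list with `points` (data frame), `r2_scan`
#'   (data frame `max_x`, `n_points`, `r2`, ordered by increasing `max_x`),
#'   `full_r2`, `threshold`, `verdict` (`"saturated"` / `"not_saturated"`).
#' @export
saturation_scan <- function(x, y, threshold = 0.6, min_points = 3L,
                            window = 3L) {
  stopifnot(length(x) == length(y))
  if (length(x) < min_points) {
    stop(sprintf("saturation_scan: need at least %d points, got %d",
                 min_points, length(x)))
  }
  if (any(x <= 0)) stop("saturation_scan: x values must be positive")
  ux <- sort(unique(x), decreasing = TRUE)
  scan <- data.frame(max_x = numeric(0), n_points = integer(0), r2 = numeric(0))
  for (drop in 0:length(ux)) {
    keep_x <- ux[seq(drop + 1, length.out = length(ux) - drop)]
    if (length(keep_x) < 2L) break
    sel <- x %in% keep_x
    if (sum(sel) < min_points) break
    scan <- rbind(scan, data.frame(max_x = max(keep_x),
                                   n_points = sum(sel),
                                   r2 = r_squared(x[sel], y[sel])))
  }
  if (nrow(scan) == 0L) stop("saturation_scan: not enough distinct x values")
  scan <- scan[order(scan$max_x), , drop = FALSE]
  rownames(scan) <- NULL
  full_r2 <- scan$r2[nrow(scan)]
  tail_r2 <- utils::tail(scan$r2, window)
  non_increasing <- all(diff(tail_r2) <= 1e-9)
  verdict <- if (full_r2 < threshold && non_increasing) "saturated" else "not_saturated"
  structure(list(points = data.frame(x = x, y = y), r2_scan = scan,
                 full_r2 = full_r2, threshold = threshold, verdict = verdict),
            class = "SaturationCurve")
}

#' @export
print.SaturationCurve <- function(x, ...) {
  cat(sprintf("SaturationCurve: %d points, full-data R^2 = %.3f (threshold %.2f) -> %s\n",
              nrow(x$points), x$full_r2, x$threshold, x$verdict))
  invisible(x)
}

#' Assemble saturation curves from a downsampling experiment
#'
#' Given the reference clustering, its embedding, and one clustering per
#' downsampled subset, builds the three diagnostic curves of the framework:
#' mean cluster preservation vs subset size, mean preservation vs subset
#' complexity index (centroids in the reference space), and number of
#' clusters vs complexity. The two preservation curves are each run through
#' [saturation_scan()].
#'
#' @param subset_assignments List of `ClusterAssignment` objects, one per
#'   downsampled subset (any sizes, replicates welcome).
#' @param full_assignment The reference `ClusterAssignment`.
#' @param space The reference `EmbeddingSpace`.
#' @param threshold,min_points,window Passed to [saturation_scan()].
#' @return A `SaturationReport`: list with `curve` (data frame per subset:
#'   `subset`, `n_cells`, `complexity`, `n_clusters`, `mean_preservation`,
#'   `mean_conservation`), `vs_cells` and `vs_complexity`
#'   (`SaturationCurve`s), and `comparisons` (per-subset
#'   `ClusterComparison`s).
#' @export
saturation_report <- function(subset_assignments, full_assignment, space,
                              threshold = 0.6, min_points = 3L, window = 3L) {
  if (length(subset_assignments) < min_points) {
    stop(sprintf("saturation_report: need at least %d clustered subsets",
                 min_points))
  }
  rows <- vector("list", length(subset_assignments))
  comps <- vector("list", length(subset_assignments))
  for (i in seq_along(subset_assignments)) {
    sub <- subset_assignments[[i]]
    comp <- compare_analyses(full_assignment, sub)
    cent <- cluster_centroids(space, sub)
    cx <- complexity_index(cent)
    rows[[i]] <- data.frame(subset = sub$analysis_id,
                            n_cells = length(sub$cells),
                            complexity = cx$index,
                            n_clusters = length(unique(sub$labels)),
                            mean_preservation = comp$mean_preservation,
                            mean_conservation = comp$mean_conservation,
                            stringsAsFactors = FALSE)
    comps[[i]] <- comp
  }
  curve <- do.call(rbind, rows)
  structure(list(curve = curve,
                 vs_cells = saturation_scan(curve$n_cells,
                                            curve$mean_preservation,
                                            threshold, min_points, window),
                 vs_complexity = saturation_scan(curve$complexity,
                                                 curve$mean_preservation,
                                                 threshold, min_points, window),
                 comparisons = comps),
            class = "SaturationReport")
}

#' @export
print.SaturationReport <- function(x, ...) {
  cat("SaturationReport over", nrow(x$curve), "subsets\n")
  cat("  vs cell number: "); print(x$vs_cells)
  cat("  vs complexity:  "); print(x$vs_complexity)
  invisible(x)
}
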
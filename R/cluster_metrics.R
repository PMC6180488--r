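#' Pairwise cluster-overlap matrix between two analyses
#'
#' Because downsampled subsets keep their original barcodes, two clusterings
#' can be compared cell-by-cell: the overlap matrix counts, for every pair of
#' one reference ("original") cluster and one subset cluster, how many common
#' cells they share. All per-cluster scores in this package are read off this
#' table. The comparison is restricted to the barcodes present in both
#' analyses; reference clusters with no common cells appear as all-zero rows.
#'
#' @param a Reference `ClusterAssignment` (rows).
#' @param b Subset `ClusterAssignment` (columns).
#' @return An `OverlapMatrix`: list with `counts` (rows x cols), `row_sizes`,
#'   `col_sizes` (totals over common cells), `n_common`, and the two
#'   analysis ids.
#' @export
overlap_matrix <- function(a, b) {
  common <- intersect(a$cells, b$cells)
  if (length(common) == 0L) {
    stop("overlap_matrix: the two analyses share no barcodes")
  }
  la <- factor(a$labels[match(common, a$cells)], levels = sort(unique(a$labels)))
  lb <- factor(b$labels[match(common, b$cells)], levels = sort(unique(b$labels)))
  counts <- unclass(table(la, lb))
  dimnames(counts) <- list(levels(la), levels(lb))
  structure(list(counts = counts,
                 row_sizes = rowSums(counts),
                 col_sizes = colSums(counts),
                 n_common = length(common),
                 row_id = a$analysis_id, col_id = b$analysis_id),
            class = "OverlapMatrix")
}

#' @export
print.OverlapMatrix <- function(x, ...) {
  cat(sprintf("OverlapMatrix: %d x %d clusters ('%s' vs '%s'), %d common cells\n",
              nrow(x$counts), ncol(x$counts), x$row_id, x$col_id, x$n_common))
  invisible(x)
}

#' Row- and column-normalized overlap fractions
#'
#' @param overlap An `OverlapMatrix`.
#' @return List of two matrices the shape of `counts`: `row_frac` divides
#'   each count by its row cluster's size, `col_frac` by its column
#'   cluster's size.
#' @export
overlap_fractions <- function(overlap) {
  list(row_frac = overlap$counts / overlap$row_sizes,
       col_frac = sweep(overlap$counts, 2, overlap$col_sizes, "/"))
}

score_axis <- function(overlap, direction) {
  if (direction == "preservation") {
    frac <- overlap$counts / overlap$row_sizes
    sizes <- overlap$row_sizes
    other <- colnames(overlap$counts)
  } else {
    frac <- t(sweep(overlap$counts, 2, overlap$col_sizes, "/"))
    sizes <- overlap$col_sizes
    other <- rownames(overlap$counts)
  }
  empty <- sizes == 0
  if (any(empty)) {
    warning(sprintf("%s undefined for cluster(s) with no common cells: %s",
                    direction, paste(names(sizes)[empty], collapse = ", ")))
    frac[empty, ] <- -Inf
  }
  score <- ifelse(empty, NA_real_, apply(frac, 1, max))
  best <- ifelse(empty, NA_character_, other[apply(frac, 1, which.max)])
  res <- data.frame(cluster = names(sizes), size = as.integer(sizes),
                    score = as.numeric(score), best_match = best,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "direction") <- direction
  class(res) <- c("PreservationResult", class(res))
  res
}

#' Cluster preservation scores
#'
#' The top-down stability score: for each reference cluster, the largest
#' fraction of its common cells found together in any single subset cluster.
#' A cluster whose cells are split 50/50 between two subset clusters scores
#' 0.5; a perfectly recovered cluster scores 1.
#'
#' @param overlap An `OverlapMatrix` (reference clusters in rows).
#' @return A `PreservationResult` data frame: `cluster`, `size` (common
#'   cells), `score`, `best_match`.
#' @export
preservation <- function(overlap) score_axis(overlap, "preservation")

#' Cluster conservation scores
#'
#' The reciprocal, bottom-up score: for each *subset* cluster, the largest
#' fraction of its cells that originates from any single reference cluster.
#' Conservation can be high while preservation is low, e.g. when one
#' reference cluster is split into several pure subset clusters.
#'
#' @param overlap An `OverlapMatrix`.
#' @return A `PreservationResult` data frame over the column clusters.
#' @export
conservation <- function(overlap) score_axis(overlap, "conservation")

#' Cluster split counts
#'
#' How many clusters of the opposite analysis contain at least one cell of
#' the cluster of interest. Together with preservation this distinguishes an
#' even two-way split (preservation 0.5, split 2) from scattering across
#' many clusters (preservation 0.5, split 10).
#'
#' @param overlap An `OverlapMatrix`.
#' @param cluster A single cluster label.
#' @param direction `"rows"` if `cluster` is a reference (row) cluster,
#'   `"cols"` for a subset (column) cluster.
#' @return Integer number of opposite-axis clusters sharing >= 1 cell.
#' @export
split_count <- function(overlap, cluster, direction = c("rows", "cols")) {
  direction <- match.arg(direction)
  cluster <- as.character(cluster)
  labs <- if (direction == "rows") rownames(overlap$counts) else colnames(overlap$counts)
  if (!cluster %in% labs) {
    stop(sprintf("split_count: unknown %s cluster '%s'", direction, cluster))
  }
  v <- if (direction == "rows") overlap$counts[cluster, ] else overlap$counts[, cluster]
  sum(v >= 1)
}

#' All split counts along one axis
#' @rdname split_count
#' @export
split_counts <- function(overlap, direction = c("rows", "cols")) {
  direction <- match.arg(direction)
  m <- if (direction == "rows") overlap$counts else t(overlap$counts)
  stats::setNames(as.integer(rowSums(m >= 1)), rownames(m))
}

#' Rand index and adjusted Rand index
#'
#' Agreement between two clusterings over their common cells: the fraction
#' of cell pairs on which the analyses agree (both together or both apart),
#' optionally corrected for chance (Hubert-Arabie adjustment).
#'
#' @param a,b `ClusterAssignment` objects sharing at least two barcodes.
#' @param adjusted Return the adjusted index.
#' @return A number; raw Rand is in `[0, 1]`, adjusted Rand is `<= 1` and
#'   approximately 0 for independent labelings.
#' @export
rand_index <- function(a, b, adjusted = FALSE) {
  ov <- overlap_matrix(a, b)
  n <- ov$n_common
  if (n < 2L) stop("rand_index: need at least 2 common cells")
  nij <- ov$counts
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(nij))
  sum_a <- sum(ch2(ov$row_sizes))
  sum_b <- sum(ch2(ov$col_sizes))
  total <- ch2(n)
  if (!adjusted) {
    # agreements = pairs together in both + pairs apart in both
    (total + 2 * sum_ij - sum_a - sum_b) / total
  } else {
    expected <- sum_a * sum_b / total
    max_idx <- (sum_a + sum_b) / 2
    if (max_idx == expected) return(1)      # both trivial partitions
    (sum_ij - expected) / (max_idx - expected)
  }
}

#' Compare two clustering analyses
#'
#' One-stop comparison: builds the overlap matrix and bundles per-cluster
#' preservation, conservation and split counts with their means and the
#' (adjusted) Rand index.
#'
#' @param a Reference `ClusterAssignment`.
#' @param b Subset `ClusterAssignment`.
#' @param weighted Also report cell-weighted mean scores (weights = cluster
#'   common-cell sizes); the headline means are unweighted so rare clusters
#'   count equally.
#' @return A `ClusterComparison` list: `overlap`, `preservation` and
#'   `conservation` frames (each with a `split` column), `mean_preservation`,
#'   `mean_conservation`, optional weighted means, `rand`, `ari`, `n_common`.
#' @export
compare_analyses <- function(a, b, weighted = FALSE) {
  ov <- overlap_matrix(a, b)
  pres <- preservation(ov)
  pres$split <- split_counts(ov, "rows")[pres$cluster]
  cons <- conservation(ov)
  cons$split <- split_counts(ov, "cols")[cons$cluster]
  res <- list(overlap = ov, preservation = pres, conservation = cons,
              mean_preservation = mean(pres$score, na.rm = TRUE),
              mean_conservation = mean(cons$score, na.rm = TRUE),
              rand = rand_index(a, b, adjusted = FALSE),
              ari = rand_index(a, b, adjusted = TRUE),
              n_common = ov$n_common)
  if (weighted) {
    wmean <- function(df) stats::weighted.mean(df$score, df$size, na.rm = TRUE)
    res$weighted_mean_preservation <- wmean(pres)
    res$weighted_mean_conservation <- wmean(cons)
  }
  class(res) <- "ClusterComparison"
  res
}

#' @export
print.ClusterComparison <- function(x, ...) {
  cat(sprintf(paste0("ClusterComparison ('%s' vs '%s'): %d common cells\n",
                     "  mean preservation %.3f | mean conservation %.3f | ",
                     "Rand %.3f | ARI %.3f\n"),
              x$overlap$row_id, x$overlap$col_id, x$n_common,
              x$mean_preservation, x$mean_conservation, x$rand, x$ari))
  invisible(x)
}
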
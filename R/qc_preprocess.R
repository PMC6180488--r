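#' Quality-control parameters
#'
#' Thresholds for per-cell filtering. The defaults follow common mouse-brain
#' droplet practice: drop a cell when more than 10% of its UMIs map to
#' mitochondrial genes, or more than 10% to ribosomal-protein genes, or when
#' it has fewer than 1000 detected genes. Gene families are recognized by
#' symbol prefix (mouse conventions by default).
#'
#' @param max_mito_frac Maximum tolerated mitochondrial UMI fraction
#'   (removal is strict `>`), in `[0, 1]`.
#' @param max_ribo_frac Maximum tolerated ribosomal UMI fraction, in `[0, 1]`.
#' @param min_genes Minimum number of detected genes per cell.
#' @param mito_prefixes Gene-symbol prefixes counted as mitochondrial.
#' @param ribo_prefixes Prefixes counted as ribosomal.
#' @param combined Apply the fraction threshold to the mitochondrial +
#'   ribosomal sum instead of to each family separately.
#' @return A `QCParams` list.
#' @export
qc_params <- function(max_mito_frac = 0.10, max_ribo_frac = 0.10,
                      min_genes = 1000L,
                      mito_prefixes = "mt-",
                      ribo_prefixes = c("Rps", "Rpl"),
                      combined = FALSE) {
  stopifnot(max_mito_frac >= 0, max_mito_frac <= 1,
            max_ribo_frac >= 0, max_ribo_frac <= 1,
            min_genes >= 1)
  structure(list(max_mito_frac = max_mito_frac, max_ribo_frac = max_ribo_frac,
                 min_genes = as.integer(min_genes),
                 mito_prefixes = mito_prefixes, ribo_prefixes = ribo_prefixes,
                 combined = isTRUE(combined)),
            class = "QCParams")
}

prefix_match <- function(names, prefixes) {
  hit <- rep(FALSE, length(names))
  for (p in prefixes) hit <- hit | startsWith(names, p)
  hit
}

#' Per-cell QC metrics
#'
#' @param x A `CountMatrix`.
#' @param params A [qc_params()] object (used for the gene-family prefixes).
#' @return Data frame with one row per cell: `barcode`, `n_genes` (genes with
#'   at least one count), `total_counts`, `mito_frac`, `ribo_frac`.
#' @export
qc_metrics <- function(x, params = qc_params()) {
  counts <- x$counts
  tot <- Matrix::colSums(counts)
  mito <- prefix_match(gene_names(x), params$mito_prefixes)
  ribo <- prefix_match(gene_names(x), params$ribo_prefixes)
  mito_frac <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(tot, 1) else numeric(ncol(counts))
  ribo_frac <- if (any(ribo)) Matrix::colSums(counts[ribo, , drop = FALSE]) / pmax(tot, 1) else numeric(ncol(counts))
  data.frame(barcode = barcodes(x),
             n_genes = Matrix::colSums(counts > 0),
             total_counts = as.numeric(tot),
             mito_frac = as.numeric(mito_frac),
             ribo_frac = as.numeric(ribo_frac),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter cells by QC thresholds
#'
#' Removes cells whose mitochondrial fraction exceeds `max_mito_frac`, whose
#' ribosomal fraction exceeds `max_ribo_frac` (strict `>`; or whose combined
#' fraction exceeds `max_mito_frac` when `combined`), or that detect fewer
#' than `min_genes` genes. The gene set is left untouched, so filtering is
#' idempotent.
#'
#' @param x A `CountMatrix`.
#' @param params A [qc_params()] object.
#' @return List with `matrix` (the filtered `CountMatrix`) and `report` (the
#'   [qc_metrics()] frame plus a logical `kept` column; summary counts in
#'   `attr(report, "summary")`).
#' @export
qc_filter <- function(x, params = qc_params()) {
  rep <- qc_metrics(x, params)
  if (params$combined) {
    frac_ok <- (rep$mito_frac + rep$ribo_frac) <= params$max_mito_frac
  } else {
    frac_ok <- rep$mito_frac <= params$max_mito_frac &
      rep$ribo_frac <= params$max_ribo_frac
  }
  keep <- frac_ok & rep$n_genes >= params$min_genes
  if (!any(keep)) stop("qc_filter: no cells pass the QC thresholds")
  rep$kept <- keep
  attr(rep, "summary") <- c(n_input = nrow(rep), n_kept = sum(keep),
                            n_removed = sum(!keep))
  list(matrix = x[, which(keep)], report = rep)
}

#' Depth-normalize a count matrix
#'
#' Scales every cell to the same total count (10,000 by default, i.e.
#' counts-per-10K) and then, by default, applies `log1p`.
#'
#' @param x A `CountMatrix` or a sparse/dense genes x cells matrix.
#' @param target_sum Per-cell total after scaling.
#' @param log1p Apply the `log(1 + x)` transform after scaling.
#' @return A sparse genes x cells matrix of normalized expression.
#' @export
normalize_counts <- function(x, target_sum = 1e4, log1p = TRUE) {
  counts <- if (inherits(x, "CountMatrix")) x$counts else x
  stopifnot(target_sum > 0)
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) {
    stop("normalize_counts: zero-count cell(s): ",
         paste(utils::head(colnames(counts)[tot == 0], 5), collapse = ", "))
  }
  norm <- methods::as(counts %*% Matrix::Diagonal(x = target_sum / tot),
                      "CsparseMatrix")
  dimnames(norm) <- dimnames(counts)
  if (log1p) norm@x <- log1p(norm@x)
  norm
}

#' Principal-component embedding of an expression matrix
#'
#' Centers and scales every gene to unit variance (dropping zero-variance
#' genes), then computes the first `n_components` principal components of the
#' cells. The number of significant components is estimated immediately via
#' [n_significant_pcs()] so downstream steps can restrict to them.
#'
#' @param expr Normalized genes x cells matrix (see [normalize_counts()]).
#' @param n_components Number of components to keep (clamped, with a warning,
#'   when the matrix is smaller).
#' @param reference_id Name recorded for the analysis that defined this space.
#' @return An `EmbeddingSpace`: list with `pc_scores` (cells x k, barcodes as
#'   rownames), `pc_loadings` (genes x k), `eigenvalues` (non-increasing),
#'   `n_significant`, `n_cells`, `n_genes`, `reference_id`.
#' @export
run_pca <- function(expr, n_components = 50, reference_id = "analysis") {
  x <- t(as.matrix(expr))                       # cells x genes
  sds <- apply(x, 2, stats::sd)
  zero_var <- sds == 0
  if (any(zero_var)) {
    message(sprintf("run_pca: dropping %d zero-variance gene(s)", sum(zero_var)))
    x <- x[, !zero_var, drop = FALSE]
  }
  max_k <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_k) {
    warning(sprintf("run_pca: clamping n_components from %d to %d", n_components, max_k))
    n_components <- max_k
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE, rank. = n_components)
  ev <- p$sdev[seq_len(n_components)]^2
  space <- structure(list(pc_scores = p$x,
                          pc_loadings = p$rotation,
                          eigenvalues = ev,
                          n_significant = NA_integer_,
                          n_cells = nrow(x), n_genes = ncol(x),
                          reference_id = reference_id),
                     class = "EmbeddingSpace")
  space$n_significant <- n_significant_pcs(space)
  space
}

#' @export
print.EmbeddingSpace <- function(x, ...) {
  cat(sprintf("EmbeddingSpace '%s': %d cells x %d PCs (%d significant; %d genes)\n",
              x$reference_id, nrow(x$pc_scores), ncol(x$pc_scores),
              x$n_significant, x$n_genes))
  invisible(x)
}

#' Number of significant principal components
#'
#' Counts the eigenvalues of the scaled data that exceed the
#' Marchenko-Pastur upper edge `(1 + sqrt(n_genes / n_cells))^2`, the largest
#' eigenvalue expected from an i.i.d. random matrix of the same shape with
#' unit-variance columns. Alternatively (`method = "permutation"`) the edge
#' is replaced by the largest eigenvalue observed after independently
#' permuting every gene's values. The result is clamped to at least 1.
#'
#' @param space An `EmbeddingSpace` from [run_pca()].
#' @param n_cells,n_genes Shape of the matrix the eigenvalues came from;
#'   defaults to the shape recorded in `space`.
#' @param method `"mp"` (Marchenko-Pastur edge, default) or `"permutation"`.
#' @param expr Scaled data matrix, required for `method = "permutation"`.
#' @param n_perm,seed Permutation count and seed for the permutation method.
#' @return Integer number of significant components (>= 1).
#' @export
n_significant_pcs <- function(space, n_cells = space$n_cells,
                              n_genes = space$n_genes,
                              method = c("mp", "permutation"),
                              expr = NULL, n_perm = 10, seed = 1L) {
  method <- match.arg(method)
  ev <- space$eigenvalues
  if (method == "mp") {
    edge <- (1 + sqrt(n_genes / n_cells))^2
  } else {
    if (is.null(expr)) stop("permutation method needs the expression matrix")
    x <- t(as.matrix(expr))
    x <- scale(x[, apply(x, 2, stats::sd) > 0, drop = FALSE])
    set.seed(seed)
    edge <- max(vapply(seq_len(n_perm), function(i) {
      xp <- apply(x, 2, sample)
      (svd(xp, nu = 0, nv = 0)$d[1]^2) / (nrow(x) - 1)
    }, numeric(1)))
  }
  max(1L, sum(ev > edge))
}

#' Per-cluster QC summary
#'
#' Summarizes QC metrics by cluster: iteratively derived clusters enriched
#' for extreme mitochondrial content are often quality artifacts rather than
#' cell types, so cluster tables carry the mean mito/ribo fraction alongside
#' size.
#'
#' @param x A `CountMatrix`.
#' @param assignment A `ClusterAssignment` over (a subset of) its cells.
#' @param params [qc_params()] supplying the gene-family prefixes.
#' @return Data frame per cluster: `n_cells`, `mean_genes`, `mean_mito_frac`,
#'   `mean_ribo_frac`.
#' @export
cluster_qc_summary <- function(x, assignment, params = qc_params()) {
  met <- qc_metrics(x, params)
  idx <- match(assignment$cells, met$barcode)
  if (anyNA(idx)) stop("assignment cells missing from the matrix")
  met <- met[idx, ]
  agg <- stats::aggregate(
    cbind(mean_genes = met$n_genes, mean_mito_frac = met$mito_frac,
          mean_ribo_frac = met$ribo_frac),
    by = list(cluster = assignment$labels), FUN = mean)
  sizes <- cluster_sizes(assignment)
  agg <- cbind(agg[, "cluster", drop = FALSE],
               n_cells = as.integer(sizes[agg$cluster]),
               agg[, c("mean_genes", "mean_mito_frac", "mean_ribo_frac")])
  agg[order(agg$cluster), ]
}
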
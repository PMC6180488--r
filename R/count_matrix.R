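#' Construct a CountMatrix
#'
#' The package's primary container: a sparse genes x cells matrix of UMI
#' counts with gene names, unique cell barcodes, a per-cell library (batch)
#' label, and, for simulated data, ground-truth cluster labels.
#'
#' @param counts A matrix or sparse Matrix of non-negative integer counts,
#'   genes in rows and cells in columns.
#' @param gene_names Character vector of gene symbols (one per row). Defaults
#'   to `rownames(counts)`.
#' @param barcodes Character vector of unique cell barcodes (one per column).
#'   Defaults to `colnames(counts)`.
#' @param library_labels Per-cell library of origin. A single string is
#'   recycled to all cells.
#' @param truth_labels Optional per-cell ground-truth cluster label
#'   (simulated data only).
#' @param truth_broad Optional per-cell broad-type label (simulated data with
#'   a two-level hierarchy).
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, gene_names = rownames(counts),
                         barcodes = colnames(counts),
                         library_labels = "library1",
                         truth_labels = NULL, truth_broad = NULL) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_names) || is.null(barcodes)) {
    stop("gene_names and barcodes are required (set dimnames or pass explicitly)")
  }
  gene_names <- as.character(gene_names)
  barcodes <- as.character(barcodes)
  if (length(gene_names) != nrow(counts)) {
    stop(sprintf("integrity error: %d gene names for %d matrix rows",
                 length(gene_names), nrow(counts)))
  }
  if (length(barcodes) != ncol(counts)) {
    stop(sprintf("integrity error: %d barcodes for %d matrix columns",
                 length(barcodes), ncol(counts)))
  }
  if (anyDuplicated(barcodes)) {
    stop("integrity error: duplicate barcodes: ",
         paste(utils::head(unique(barcodes[duplicated(barcodes)]), 3), collapse = ", "))
  }
  v <- counts@x
  if (any(v < 0)) stop("integrity error: negative counts")
  if (any(v != round(v))) stop("integrity error: non-integral counts")
  if (length(library_labels) == 1L) library_labels <- rep(library_labels, ncol(counts))
  stopifnot(length(library_labels) == ncol(counts))
  if (!is.null(truth_labels)) {
    truth_labels <- as.character(truth_labels)
    stopifnot(length(truth_labels) == ncol(counts))
  }
  if (!is.null(truth_broad)) {
    truth_broad <- as.character(truth_broad)
    stopifnot(length(truth_broad) == ncol(counts))
  }
  dimnames(counts) <- list(gene_names, barcodes)
  structure(list(counts = counts,
                 library_labels = as.character(library_labels),
                 truth_labels = truth_labels,
                 truth_broad = truth_broad),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells (%.1f%% non-zero), %d library(ies)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts)),
              length(unique(x$library_labels))))
  if (!is.null(x$truth_labels)) {
    cat(sprintf("  truth labels: %d classes\n", length(unique(x$truth_labels))))
  }
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Number of cells / genes in a CountMatrix
#' @param x A `CountMatrix`.
#' @return Integer count.
#' @export
n_cells <- function(x) ncol(x$counts)

#' @rdname n_cells
#' @export
n_genes <- function(x) nrow(x$counts)

#' Gene names and barcodes of a CountMatrix
#' @param x A `CountMatrix`.
#' @return Character vector.
#' @export
gene_names <- function(x) rownames(x$counts)

#' @rdname gene_names
#' @export
barcodes <- function(x) colnames(x$counts)

#' Subset a CountMatrix
#'
#' `x[i, j]` keeps genes `i` and cells `j`; per-cell labels stay aligned.
#'
#' @param x A `CountMatrix`.
#' @param i Gene index (integer, logical or character).
#' @param j Cell index (integer, logical or barcode character).
#' @param ... Ignored.
#' @export
`[.CountMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(j)) j <- match(j, colnames(x$counts))
  if (anyNA(j)) stop("unknown barcode(s) in subset")
  count_matrix(x$counts[i, j, drop = FALSE],
               library_labels = x$library_labels[j],
               truth_labels = if (!is.null(x$truth_labels)) x$truth_labels[j],
               truth_broad = if (!is.null(x$truth_broad)) x$truth_broad[j])
}

#' Construct a ClusterAssignment
#'
#' Maps each cell barcode of one clustering analysis to its cluster label.
#' Labels are always stored as character strings so labels produced by
#' iterative reclustering (e.g. `"CR_3"`) survive round trips unchanged.
#'
#' @param cells Character vector of unique barcodes.
#' @param labels Per-cell cluster label (coerced to character).
#' @param analysis_id String naming the analysis (e.g. `"full"`,
#'   `"subset_1/2"`).
#' @return An object of class `ClusterAssignment`.
#' @export
cluster_assignment <- function(cells, labels, analysis_id = "analysis") {
  cells <- as.character(cells)
  labels <- as.character(labels)
  if (length(cells) == 0L) stop("integrity error: empty assignment")
  if (length(cells) != length(labels)) {
    stop("integrity error: one label per cell required")
  }
  if (anyDuplicated(cells)) {
    stop("integrity error: duplicate barcodes in assignment")
  }
  if (anyNA(labels) || any(labels == "")) {
    stop("integrity error: missing cluster label")
  }
  structure(list(cells = cells, labels = labels,
                 analysis_id = as.character(analysis_id)[1]),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment '%s': %d cells in %d clusters\n",
              x$analysis_id, length(x$cells), length(unique(x$labels))))
  invisible(x)
}

#' @export
as.data.frame.ClusterAssignment <- function(x, ...) {
  data.frame(barcode = x$cells, cluster = x$labels, stringsAsFactors = FALSE)
}

#' Cluster sizes of an assignment
#' @param assignment A `ClusterAssignment`.
#' @return Named integer vector of cells per cluster.
#' @export
cluster_sizes <- function(assignment) {
  tab <- table(assignment$labels)
  stats::setNames(as.integer(tab), names(tab))
}
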
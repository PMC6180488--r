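#' Read a 10x Genomics Matrix Market directory
#'
#' Assembles a [count_matrix()] from the CellRanger triplet layout: a Matrix
#' Market coordinate file plus gene and barcode name files. Both the "v2"
#' dialect (`matrix.mtx`, 2-column `genes.tsv`, `barcodes.tsv`) and the "v3"
#' dialect (3-column `features.tsv`, optionally gzipped) are auto-detected by
#' filename. Gene symbols are taken from the second column when present.
#'
#' @param path Directory containing the three files.
#' @param library_label Library label applied to every cell; defaults to the
#'   directory name.
#' @return A `CountMatrix` (genes x cells).
#' @export
read_mtx_dir <- function(path, library_label = basename(normalizePath(path))) {
  if (!dir.exists(path)) stop("format error: no such directory: ", path)
  find1 <- function(cands, what) {
    for (f in cands) {
      full <- file.path(path, f)
      if (file.exists(full)) return(full)
    }
    stop(sprintf("format error: missing %s file in %s (looked for %s)",
                 what, path, paste(cands, collapse = ", ")))
  }
  mtx_f <- find1(c("matrix.mtx", "matrix.mtx.gz"), "matrix")
  gene_f <- find1(c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"),
                  "gene/feature")
  bc_f <- find1(c("barcodes.tsv", "barcodes.tsv.gz"), "barcode")

  m <- Matrix::readMM(mtx_f)
  genes <- utils::read.table(gene_f, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
  bcs <- readLines(bc_f)
  bcs <- bcs[nzchar(bcs)]
  if (nrow(genes) != nrow(m)) {
    stop(sprintf("integrity error: %s lists %d genes but matrix header has %d rows",
                 basename(gene_f), nrow(genes), nrow(m)))
  }
  if (length(bcs) != ncol(m)) {
    stop(sprintf("integrity error: %s lists %d barcodes but matrix header has %d columns",
                 basename(bc_f), length(bcs), ncol(m)))
  }
  sym <- if (ncol(genes) >= 2) genes[[2]] else genes[[1]]
  count_matrix(m, gene_names = sym, barcodes = bcs,
               library_labels = library_label)
}

#' Write a CountMatrix as a 10x-style Matrix Market directory
#'
#' Inverse of [read_mtx_dir()]. The coordinate file carries the
#' `%%MatrixMarket matrix coordinate integer general` banner with 1-based
#' indices.
#'
#' @param x A `CountMatrix`.
#' @param path Output directory (created if needed).
#' @param version `"v2"` writes `genes.tsv` (id, symbol); `"v3"` writes a
#'   3-column `features.tsv` (id, symbol, type).
#' @param gzip Gzip the three files (v3-style).
#' @return `path`, invisibly.
#' @export
write_mtx_dir <- function(x, path, version = c("v2", "v3"), gzip = FALSE) {
  version <- match.arg(version)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  open_out <- function(f) if (gzip) gzfile(f, "w") else file(f, "w")

  m <- methods::as(x$counts, "TsparseMatrix")
  con <- open_out(file.path(path, paste0("matrix.mtx", ext)))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  if (length(m@x)) {
    writeLines(sprintf("%d %d %d", m@i + 1L, m@j + 1L, as.integer(m@x)), con)
  }
  close(con)

  ids <- sprintf("ENSG%08d", seq_len(n_genes(x)))
  if (version == "v2") {
    con <- open_out(file.path(path, paste0("genes.tsv", ext)))
    writeLines(paste(ids, gene_names(x), sep = "\t"), con)
  } else {
    con <- open_out(file.path(path, paste0("features.tsv", ext)))
    writeLines(paste(ids, gene_names(x), "Gene Expression", sep = "\t"), con)
  }
  close(con)

  con <- open_out(file.path(path, paste0("barcodes.tsv", ext)))
  writeLines(barcodes(x), con)
  close(con)
  invisible(path)
}

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("read_10x_h5/write_10x_h5 require a python interpreter ",
                       "with h5py on the PATH")
  p
}

run_h5_tool <- function(args) {
  script <- system.file("python", "h5_tool.py", package = "satkit")
  if (!nzchar(script)) stop("h5_tool.py not found in installed package")
  out <- suppressWarnings(system2(python_bin(), c(shQuote(script), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("format error: ", paste(out, collapse = "\n"))
  }
  invisible(out)
}

#' Read a 10x HDF5 gene-barcode matrix
#'
#' Reads both HDF5 layouts emitted by CellRanger: the legacy per-genome group
#' (`<genome>/{data,indices,indptr,shape,genes,gene_names,barcodes}`) and the
#' modern `matrix/` group with a `features` subgroup. Conversion is delegated
#' to a bundled python helper (requires `python` with `h5py` and `scipy` on
#' the PATH); the decoded arrays are handed back through a temporary Matrix
#' Market directory so the result is bit-identical to [read_mtx_dir()] on the
#' same data.
#'
#' @param path Path to the `.h5` file.
#' @param library_label Library label for all cells; defaults to the file
#'   name without extension.
#' @return A `CountMatrix`.
#' @export
read_10x_h5 <- function(path,
                        library_label = sub("\\.h5$", "", basename(path))) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  tmp <- tempfile("h5mtx")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  run_h5_tool(c("to-mtx", shQuote(path), shQuote(tmp)))
  read_mtx_dir(tmp, library_label = library_label)
}

#' Write a CountMatrix as a 10x-style HDF5 file
#'
#' Writes the modern `matrix/` CSC layout. Mainly used to build round-trip
#' fixtures; requires `python` with `h5py` on the PATH.
#'
#' @param x A `CountMatrix`.
#' @param path Output `.h5` path.
#' @return `path`, invisibly.
#' @export
write_10x_h5 <- function(x, path) {
  tmp <- tempfile("mtxh5")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  write_mtx_dir(x, tmp, version = "v3")
  run_h5_tool(c("from-mtx", shQuote(tmp), shQuote(path)))
  invisible(path)
}

#' Write / read a cluster-assignment TSV
#'
#' The on-disk form is a UTF-8 TSV with header `barcode<TAB>cluster`.
#' `read_labels(write_labels(x))` reproduces `x` exactly (labels are strings).
#'
#' @param assignment A `ClusterAssignment`.
#' @param path File path.
#' @return `write_labels` returns `path` invisibly; `read_labels` returns a
#'   `ClusterAssignment`.
#' @export
write_labels <- function(assignment, path) {
  utils::write.table(as.data.frame(assignment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_labels
#' @param analysis_id Analysis id for the returned assignment; defaults to
#'   the file name.
#' @export
read_labels <- function(path, analysis_id = sub("\\.tsv$", "", basename(path))) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character", comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("integrity error: empty or malformed label file: ", path)
  }
  cluster_assignment(df[[1]], df[[2]], analysis_id = analysis_id)
}

#' Write an overlap matrix as the paired-fraction CSV
#'
#' One row per reference cluster and one column per subset cluster; each cell
#' holds `<frac1>_<frac2>` at 4 decimal places, where `frac1` divides the
#' shared-cell count by the row cluster's size and `frac2` by the column
#' cluster's size.
#'
#' @param overlap An `OverlapMatrix` from [overlap_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_overlap_csv <- function(overlap, path) {
  fr <- overlap_fractions(overlap)
  txt <- matrix(sprintf("%.4f_%.4f", fr$row_frac, fr$col_frac),
                nrow = nrow(fr$row_frac), dimnames = dimnames(fr$row_frac))
  utils::write.csv(txt, path, quote = FALSE)
  invisible(path)
}

#' Read back a paired-fraction overlap CSV
#'
#' @param path CSV written by [write_overlap_csv()].
#' @return List with numeric matrices `row_frac` and `col_frac`.
#' @export
read_overlap_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                        colClasses = "character")
  m <- as.matrix(df)
  split2 <- function(k) {
    matrix(as.numeric(vapply(strsplit(m, "_", fixed = TRUE), `[`, "", k)),
           nrow = nrow(m), dimnames = dimnames(m))
  }
  list(row_frac = split2(1), col_frac = split2(2))
}
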
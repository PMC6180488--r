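#' Default end-to-end pipeline configuration
#'
#' A complete configuration for [run_saturation_pipeline()], by default
#' simulating a five-type matrix and analyzing it. Any part can be
#' overridden by passing a modified copy (or a JSON file with the same
#' structure to the command-line wrapper). `qc$min_genes` defaults to 100
#' here because the simulated matrices carry a few hundred genes; for real
#' 10x data raise it to the conventional 1000.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       input = list(type = "simulate", path = NULL,
                    sim = list(n_cells = 2000L, n_genes = 200L)),
       qc = list(min_genes = 100L, max_mito_frac = 0.10, max_ribo_frac = 0.10),
       clustering = list(n_pcs_total = 50L, n_neighbors = 10L,
                         resolution = 1.0),
       downsample = list(n_levels = 4L, replicates = 2L),
       threshold = 0.6)
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] starting", name))
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  message(sprintf("[%s] done (%.1fs)", name, elapsed))
  attr(res, "elapsed") <- elapsed
  res
}

#' Run the full saturation-analysis pipeline
#'
#' Orchestrates every stage: ingest (or simulate) a count matrix, QC-filter,
#' cluster the full set, draw nested downsampling replicates, re-cluster
#' every subset, compare each subset's clusters to the full clustering,
#' compute complexity indices in the full set's PC space, and issue the
#' saturation verdict. All label tables, comparison matrices, curves, the
#' verdict, and a reproducibility manifest are written under `out_dir`.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or a
#'   path to a JSON file with the same structure.
#' @param out_dir Output directory (created; default a fresh temporary
#'   directory).
#' @return Invisibly, a list with `report` (the [saturation_report()]
#'   result), `full` (assignment + space), `matrix`, and `out_dir`.
#' @export
run_saturation_pipeline <- function(config = default_pipeline_config(),
                                    out_dir = tempfile("satkit_run")) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("configuration error: config file not found: ", config)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  base <- default_pipeline_config()
  for (k in names(base)) {
    if (is.null(config[[k]])) {
      config[[k]] <- base[[k]]
    } else if (is.list(base[[k]])) {
      for (k2 in names(base[[k]])) {
        if (is.null(config[[k]][[k2]])) config[[k]][[k2]] <- base[[k]][[k2]]
      }
    }
  }
  if (identical(config$input$type, "mtx") || identical(config$input$type, "h5")) {
    if (is.null(config$input$path)) {
      stop("configuration error: input$path is required for type '",
           config$input$type, "'")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "labels"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "comparisons"), showWarnings = FALSE)
  seed <- as.integer(config$seed)
  timings <- list()

  x <- stage("input", switch(config$input$type,
    simulate = simulate_counts(do.call(sim_config,
      c(config$input$sim, list(seed = seed)))),
    mtx = read_mtx_dir(config$input$path),
    h5 = read_10x_h5(config$input$path),
    stop("unknown input type: ", config$input$type)))
  timings$input <- attr(x, "elapsed")

  qc <- stage("qc", qc_filter(x, do.call(qc_params, config$qc)))
  timings$qc <- attr(qc, "elapsed")
  utils::write.table(qc$report, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  xf <- qc$matrix

  cp <- do.call(clustering_params,
                c(config$clustering, list(louvain_seed = seed)))
  full <- stage("cluster_full", cluster_pipeline(xf, cp, analysis_id = "full"))
  timings$cluster_full <- attr(full, "elapsed")
  write_labels(full$assignment, file.path(out_dir, "labels", "full.tsv"))

  ds <- config$downsample
  subset_assignments <- list()
  sub_seeds <- list()
  for (r in seq_len(ds$replicates)) {
    series <- nested_halving(barcodes(xf), ds$n_levels,
                             seed = seed + 1000L * r, parent_id = "full")
    sub_seeds[[paste0("replicate_", r)]] <- series$seed
    for (l in seq_len(ds$n_levels)) {
      id <- sprintf("subset_r%d_l%d", r, l)
      cp_sub <- do.call(clustering_params,
                        c(config$clustering,
                          list(louvain_seed = seed + 1000L * r + l)))
      res <- stage(id, cluster_pipeline(xf[, series$subsets[[l]]], cp_sub,
                                        analysis_id = id))
      res$assignment$analysis_id <- id
      subset_assignments[[id]] <- res$assignment
      write_labels(res$assignment,
                   file.path(out_dir, "labels", paste0(id, ".tsv")))
    }
  }

  report <- stage("saturate",
                  saturation_report(subset_assignments, full$assignment,
                                    full$space, threshold = config$threshold))
  utils::write.table(report$curve, file.path(out_dir, "curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$vs_cells$r2_scan,
                     file.path(out_dir, "r2_scan_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$vs_complexity$r2_scan,
                     file.path(out_dir, "r2_scan_complexity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(report$comparisons)) {
    id <- report$curve$subset[i]
    write_overlap_csv(report$comparisons[[i]]$overlap,
                      file.path(out_dir, "comparisons", paste0(id, "_overlap.csv")))
  }
  verdict <- list(vs_cells = report$vs_cells$verdict,
                  vs_cells_r2 = report$vs_cells$full_r2,
                  vs_complexity = report$vs_complexity$verdict,
                  vs_complexity_r2 = report$vs_complexity$full_r2,
                  threshold = config$threshold)
  jsonlite::write_json(verdict, file.path(out_dir, "verdict.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    tool = "satkit",
    version = as.character(utils::packageVersion("satkit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = c(list(master = seed, louvain_full = seed), sub_seeds),
    n_cells_input = n_cells(x), n_cells_kept = n_cells(xf),
    timings_sec = timings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  message(sprintf("[saturate] verdict vs cells: %s (R^2 = %.3f)",
                  verdict$vs_cells, verdict$vs_cells_r2))
  invisible(list(report = report, full = full, matrix = xf,
                 out_dir = out_dir))
}
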
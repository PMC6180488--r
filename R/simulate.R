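#' Describe one simulated broad cell type
#'
#' @param name Type name (becomes the broad truth label).
#' @param frequency Expected fraction of cells of this type; frequencies
#'   must sum to 1 across types.
#' @param shift Magnitude of the type's expression perturbation: each gene's
#'   baseline mean is multiplied by `exp(shift * z_g)` with a fixed
#'   per-type standard-normal `z_g`. 0 means indistinguishable from
#'   baseline; around 1 gives strongly separated types.
#' @param subtypes Optional list of [sim_subtype()] entries (within-type
#'   frequencies must sum to 1).
#' @return A list describing the type.
#' @export
sim_type <- function(name, frequency, shift, subtypes = list()) {
  stopifnot(frequency > 0, frequency <= 1, shift >= 0)
  list(name = as.character(name), frequency = frequency, shift = shift,
       subtypes = subtypes)
}

#' Describe one simulated subtype within a broad type
#'
#' @param name Subtype name (truth label becomes `"<type>_<subtype>"`).
#' @param frequency Fraction of the parent type's cells.
#' @param shift Subtype-level perturbation magnitude (usually smaller than
#'   the broad-type shift).
#' @param n_markers Number of genes given to this subtype as exclusive
#'   markers.
#' @param marker_fc Mean fold-change of those markers in the subtype.
#' @return A list describing the subtype.
#' @export
sim_subtype <- function(name, frequency, shift, n_markers = 0L,
                        marker_fc = 4) {
  stopifnot(frequency > 0, frequency <= 1, shift >= 0, n_markers >= 0,
            marker_fc >= 1)
  list(name = as.character(name), frequency = frequency, shift = shift,
       n_markers = as.integer(n_markers), marker_fc = marker_fc)
}

#' Simulation configuration
#'
#' Defines a sparse UMI count matrix with known (optionally two-level)
#' cluster structure: gene-wise negative-binomial counts around a baseline
#' mean profile perturbed per broad type and per subtype, per-cell depths
#' drawn log-normally, and dedicated mitochondrial ("mt-") and ribosomal
#' ("Rps"/"Rpl") gene blocks whose per-cell UMI shares follow configurable
#' Beta distributions, so QC code paths run on simulated data unmodified.
#'
#' @param n_cells,n_genes Matrix dimensions (`n_genes` includes the
#'   mito/ribo blocks).
#' @param types List of [sim_type()] entries; default: five equally frequent
#'   well-separated types.
#' @param nb_dispersion Negative-binomial dispersion `phi`
#'   (`var = mu + phi * mu^2`).
#' @param depth_meanlog,depth_sdlog Log-normal parameters of per-cell total
#'   UMI depth.
#' @param mito_mean,mito_sd,ribo_mean,ribo_sd Mean and sd of the per-cell
#'   mitochondrial / ribosomal UMI fractions (Beta-distributed).
#' @param n_mito_genes,n_ribo_genes Sizes of the dedicated gene blocks.
#' @param n_libraries Number of libraries; cells are labeled round-robin.
#' @param seed RNG seed; the simulation is fully deterministic given it.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_cells = 2000L, n_genes = 200L,
                       types = NULL,
                       nb_dispersion = 0.5,
                       depth_meanlog = log(2500), depth_sdlog = 0.3,
                       mito_mean = 0.05, mito_sd = 0.02,
                       ribo_mean = 0.05, ribo_sd = 0.02,
                       n_mito_genes = 10L, n_ribo_genes = 20L,
                       n_libraries = 2L, seed = 1L) {
  if (is.null(types)) {
    types <- lapply(1:5, function(i) sim_type(paste0("T", i), 0.2, shift = 1))
  }
  freqs <- vapply(types, `[[`, numeric(1), "frequency")
  if (abs(sum(freqs) - 1) > 1e-8) {
    stop("sim_config: type frequencies must sum to 1")
  }
  for (ty in types) {
    if (length(ty$subtypes)) {
      sf <- vapply(ty$subtypes, `[[`, numeric(1), "frequency")
      if (abs(sum(sf) - 1) > 1e-8) {
        stop(sprintf("sim_config: subtype frequencies of '%s' must sum to 1",
                     ty$name))
      }
    }
  }
  stopifnot(nb_dispersion > 0, n_genes > n_mito_genes + n_ribo_genes,
            n_libraries >= 1)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 types = types, nb_dispersion = nb_dispersion,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 mito_mean = mito_mean, mito_sd = mito_sd,
                 ribo_mean = ribo_mean, ribo_sd = ribo_sd,
                 n_mito_genes = as.integer(n_mito_genes),
                 n_ribo_genes = as.integer(n_ribo_genes),
                 n_libraries = as.integer(n_libraries),
                 seed = as.integer(seed)),
            class = "SimConfig")
}

rbeta_ms <- function(n, m, s) {
  if (s <= 0) return(rep(m, n))
  v <- min(s^2, m * (1 - m) * 0.95)   # keep shape parameters positive
  k <- m * (1 - m) / v - 1
  stats::rbeta(n, m * k, (1 - m) * k)
}

#' Simulate a count matrix with planted cluster structure
#'
#' @param config A [sim_config()] object.
#' @return A `CountMatrix` with `truth_labels` (subtype level, equal to the
#'   broad label for types without subtypes) and `truth_broad`; marker-gene
#'   assignments are attached as `attr(x, "planted_markers")` (a data frame
#'   `gene`, `subtype`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n_bio <- config$n_genes - config$n_mito_genes - config$n_ribo_genes
  bio_names <- sprintf("Gene%04d", seq_len(n_bio))
  mito_names <- sprintf("mt-Sim%d", seq_len(config$n_mito_genes))
  ribo_names <- if (config$n_ribo_genes > 0) {
    half <- ceiling(config$n_ribo_genes / 2)
    c(sprintf("RpsSim%d", seq_len(half)),
      sprintf("RplSim%d", seq_len(config$n_ribo_genes - half)))
  } else character(0)

  baseline <- stats::rlnorm(n_bio, 0, 1)

  # flatten the type/subtype hierarchy into leaf populations
  leaves <- list()
  marker_rows <- list()
  next_marker <- 1L
  for (ty in config$types) {
    subs <- ty$subtypes
    if (length(subs) == 0L) subs <- list(sim_subtype(ty$name, 1, 0))
    type_factor <- exp(ty$shift * stats::rnorm(n_bio))
    for (st in subs) {
      leaf_label <- if (identical(st$name, ty$name)) ty$name else paste(ty$name, st$name, sep = "_")
      mean_g <- baseline * type_factor * exp(st$shift * stats::rnorm(n_bio))
      if (st$n_markers > 0) {
        idx <- seq(next_marker, length.out = st$n_markers)
        if (max(idx) > n_bio) stop("simulate_counts: not enough genes for the requested markers")
        next_marker <- next_marker + st$n_markers
        mean_g[idx] <- mean_g[idx] * st$marker_fc
        marker_rows[[length(marker_rows) + 1L]] <-
          data.frame(gene = bio_names[idx], subtype = leaf_label,
                     stringsAsFactors = FALSE)
      }
      freq <- ty$frequency * st$frequency
      if (freq * config$n_cells < 1) {
        warning(sprintf("simulate_counts: expected size of '%s' is below 1 cell",
                        leaf_label))
      }
      leaves[[length(leaves) + 1L]] <- list(label = leaf_label,
                                            broad = ty$name,
                                            freq = freq, mean = mean_g)
    }
  }

  freqs <- vapply(leaves, `[[`, numeric(1), "freq")
  leaf_idx <- sample.int(length(leaves), config$n_cells, replace = TRUE,
                         prob = freqs)
  depth <- stats::rlnorm(config$n_cells, config$depth_meanlog, config$depth_sdlog)
  fm <- rbeta_ms(config$n_cells, config$mito_mean, config$mito_sd)
  fr <- rbeta_ms(config$n_cells, config$ribo_mean, config$ribo_sd)
  w_mito <- stats::rlnorm(config$n_mito_genes, 0, 0.5)
  w_mito <- w_mito / sum(w_mito)
  w_ribo <- stats::rlnorm(config$n_ribo_genes, 0, 0.5)
  w_ribo <- w_ribo / sum(w_ribo)

  size <- 1 / config$nb_dispersion
  counts <- matrix(0L, config$n_genes, config$n_cells)
  for (li in seq_along(leaves)) {
    cells <- which(leaf_idx == li)
    if (!length(cells)) next
    w_bio <- leaves[[li]]$mean / sum(leaves[[li]]$mean)
    mu <- rbind(w_bio %o% ((1 - fm[cells] - fr[cells]) * depth[cells]),
                w_mito %o% (fm[cells] * depth[cells]),
                w_ribo %o% (fr[cells] * depth[cells]))
    counts[, cells] <- stats::rnbinom(length(mu), mu = mu, size = size)
  }

  x <- count_matrix(counts,
                    gene_names = c(bio_names, mito_names, ribo_names),
                    barcodes = sprintf("cell_%05d", seq_len(config$n_cells)),
                    library_labels = paste0("lib", (seq_len(config$n_cells) - 1L) %%
                                              config$n_libraries + 1L),
                    truth_labels = vapply(leaves, `[[`, "", "label")[leaf_idx],
                    truth_broad = vapply(leaves, `[[`, "", "broad")[leaf_idx])
  attr(x, "planted_markers") <- if (length(marker_rows)) {
    do.call(rbind, marker_rows)
  } else {
    data.frame(gene = character(0), subtype = character(0))
  }
  x
}

#' Plant a rare population into an existing simulated matrix
#'
#' Replaces a random subset of cells with draws from a new, shifted
#' population (negative-binomial around the dataset's own baseline profile
#' perturbed by `exp(shift * z_g)`), relabeling them in the truth. Used to
#' study how rare (< 1%) populations survive downsampling.
#'
#' @param x A `CountMatrix` (with or without truth labels).
#' @param frequency Fraction of cells to convert; `frequency * n_cells`
#'   must be at least 5.
#' @param shift Perturbation magnitude of the rare population.
#' @param seed RNG seed.
#' @param dispersion Negative-binomial dispersion for the new draws.
#' @param label Truth label given to the planted cells.
#' @return The modified `CountMatrix`.
#' @export
plant_rare_population <- function(x, frequency, shift, seed = 1L,
                                  dispersion = 0.5, label = "rare") {
  n <- n_cells(x)
  n_rare <- round(frequency * n)
  if (n_rare < 5) {
    stop(sprintf("plant_rare_population: frequency %.4g of %d cells gives %d < 5 cells",
                 frequency, n, n_rare))
  }
  set.seed(seed)
  pick <- sample.int(n, n_rare)
  counts <- as.matrix(x$counts)
  base <- rowMeans(counts)
  base[base == 0] <- min(base[base > 0])
  mean_g <- base * exp(shift * stats::rnorm(length(base)))
  w <- mean_g / sum(mean_g)
  depth <- pmax(Matrix::colSums(x$counts)[pick], 1)
  for (i in seq_along(pick)) {
    counts[, pick[i]] <- stats::rnbinom(length(w), mu = depth[i] * w,
                                        size = 1 / dispersion)
  }
  truth <- if (is.null(x$truth_labels)) rep("background", n) else x$truth_labels
  broad <- if (is.null(x$truth_broad)) truth else x$truth_broad
  truth[pick] <- label
  broad[pick] <- label
  count_matrix(counts, gene_names = gene_names(x), barcodes = barcodes(x),
               library_labels = x$library_labels,
               truth_labels = truth, truth_broad = broad)
}
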
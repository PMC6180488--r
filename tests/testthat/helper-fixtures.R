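# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures on disk.

# small deterministic CountMatrix with recognizable mito/ribo genes
tiny_matrix <- function(n_genes = 30, n_cells = 12, seed = 1,
                        n_mito = 3, n_ribo = 4) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_cells, lambda = 3), n_genes, n_cells)
  genes <- c(sprintf("mt-G%d", seq_len(n_mito)),
             sprintf("RpsG%d", seq_len(n_ribo)),
             sprintf("Gene%02d", seq_len(n_genes - n_mito - n_ribo)))
  count_matrix(counts, gene_names = genes,
               barcodes = sprintf("bc%03d", seq_len(n_cells)),
               library_labels = rep(c("libA", "libB"), length.out = n_cells))
}

random_assignment <- function(n, k, seed, id = "rand",
                              cells = sprintf("c%04d", seq_len(n))) {
  set.seed(seed)
  cluster_assignment(cells, sample(paste0("k", seq_len(k)), n, replace = TRUE),
                     analysis_id = id)
}

# O(n^2) pair-counting oracle for the (adjusted) Rand index
rand_oracle <- function(la, lb, adjusted = FALSE) {
  n <- length(la)
  agree <- 0; both_together <- 0
  tog_a <- 0; tog_b <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- la[i] == la[j]; sb <- lb[i] == lb[j]
      if (sa == sb) agree <- agree + 1
      if (sa && sb) both_together <- both_together + 1
      if (sa) tog_a <- tog_a + 1
      if (sb) tog_b <- tog_b + 1
    }
  }
  total <- n * (n - 1) / 2
  if (!adjusted) return(agree / total)
  expected <- tog_a * tog_b / total
  max_idx <- (tog_a + tog_b) / 2
  if (max_idx == expected) return(1)
  (both_together - expected) / (max_idx - expected)
}

# brute-force per-cluster maxima over an explicit contingency table
preservation_oracle <- function(la, lb) {
  out <- c()
  for (cl in sort(unique(la))) {
    members <- which(la == cl)
    best <- 0
    for (s in unique(lb)) {
      best <- max(best, sum(lb[members] == s) / length(members))
    }
    out[cl] <- best
  }
  out
}

# all set partitions of 1..n as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, next_max) {
    if (length(labels) == n) { out[[length(out) + 1]] <<- labels; return() }
    for (v in seq_len(next_max + 1)) {
      rec(c(labels, v), max(next_max, v))
    }
  }
  rec(integer(0), 0L)
  out
}

# exhaustive best-modularity partition of a small weighted igraph
best_modularity_oracle <- function(g) {
  parts <- all_partitions(igraph::vcount(g))
  best <- -Inf; best_part <- NULL
  for (p in parts) {
    m <- igraph::modularity(g, p, weights = igraph::E(g)$weight)
    if (m > best) { best <- m; best_part <- p }
  }
  list(modularity = best, membership = best_part)
}

# simulated two-subtype dataset used by recluster/marker tests
hierarchical_sim <- function(n_cells = 800, seed = 11) {
  cfg <- sim_config(
    n_cells = n_cells, n_genes = 150, seed = seed,
    types = list(
      sim_type("A", 0.5, shift = 1, subtypes = list(
        sim_subtype("a1", 0.5, shift = 0.4, n_markers = 8, marker_fc = 4),
        sim_subtype("a2", 0.5, shift = 0.4, n_markers = 8, marker_fc = 4))),
      sim_type("B", 0.5, shift = 1)))
  simulate_counts(cfg)
}

expect_same_assignment <- function(a, b) {
  expect_identical(a$cells, b$cells)
  expect_identical(a$labels, b$labels)
}
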
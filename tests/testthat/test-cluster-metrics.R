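test_that("overlap matrix is the contingency table over common cells", {
  # identical assignments -> diagonal of cluster sizes
  a <- random_assignment(60, 3, seed = 1, id = "a")
  ov <- overlap_matrix(a, a)
  expect_equal(diag(ov$counts), cluster_sizes(a)[rownames(ov$counts)],
               ignore_attr = TRUE)
  expect_equal(sum(ov$counts) - sum(diag(ov$counts)), 0)
  expect_equal(rowSums(ov$counts), ov$row_sizes)
  expect_equal(colSums(ov$counts), ov$col_sizes)

  # hand enumeration: one cluster {1..4} vs {1,2}->X {3,4}->Y
  a2 <- cluster_assignment(paste0("c", 1:4), rep("A", 4), "a")
  b2 <- cluster_assignment(paste0("c", 1:4), c("X", "X", "Y", "Y"), "b")
  ov2 <- overlap_matrix(a2, b2)
  expect_equal(as.vector(ov2$counts), c(2, 2))

  # b covering only half the cells of a: row sizes reflect common cells only
  a3 <- cluster_assignment(paste0("c", 1:6), rep(c("A", "B"), each = 3), "a")
  b3 <- cluster_assignment(paste0("c", c(1, 2, 4)), c("X", "X", "Y"), "b")
  ov3 <- overlap_matrix(a3, b3)
  expect_equal(ov3$n_common, 3)
  expect_equal(unname(ov3$row_sizes), c(2, 1))
  expect_equal(unname(ov3$counts["A", ]), c(2, 0))

  expect_error(overlap_matrix(a2, cluster_assignment("zz", "1", "b")),
               "no barcodes")
})

test_that("preservation and split reproduce the worked examples", {
  # 100 common cells split 50/50 into two subset clusters
  ref <- cluster_assignment(sprintf("c%03d", 1:100), rep("orig", 100), "full")
  even <- cluster_assignment(sprintf("c%03d", 1:100),
                             rep(c("s1", "s2"), each = 50), "sub")
  ov <- overlap_matrix(ref, even)
  expect_equal(preservation(ov)$score, 0.5)
  expect_equal(split_count(ov, "orig", "rows"), 2L)

  # 50 cells in one cluster, 50 spread over nine more -> split 10
  scattered <- cluster_assignment(
    sprintf("c%03d", 1:100),
    c(rep("s1", 50), paste0("s", 1 + rep(1:9, length.out = 50))), "sub")
  ov2 <- overlap_matrix(ref, scattered)
  expect_equal(preservation(ov2)$score, 0.5)
  expect_equal(split_count(ov2, "orig", "rows"), 10L)

  # identical clusterings: every score 1, every split 1
  k3 <- random_assignment(90, 3, seed = 4)
  ovk <- overlap_matrix(k3, k3)
  expect_true(all(preservation(ovk)$score == 1))
  expect_true(all(conservation(ovk)$score == 1))
  expect_true(all(split_counts(ovk, "rows") == 1L))

  expect_error(split_count(ov, "missing", "rows"), "unknown")
})

test_that("scores match the brute-force contingency oracle on random pairs", {
  for (seed in 1:25) {
    n <- 40
    a <- random_assignment(n, sample(2:5, 1), seed = seed, id = "a")
    b <- random_assignment(n, sample(2:5, 1), seed = seed + 1000, id = "b")
    ov <- overlap_matrix(a, b)
    pres <- preservation(ov)
    oracle <- preservation_oracle(a$labels, b$labels)
    expect_equal(setNames(pres$score, pres$cluster), oracle)
    cons <- conservation(ov)
    oracle_c <- preservation_oracle(b$labels, a$labels)
    expect_equal(setNames(cons$score, cons$cluster), oracle_c)
  }
})

test_that("conservation is preservation of the transposed comparison", {
  for (seed in 1:50) {
    a <- random_assignment(30, 4, seed = seed, id = "a")
    b <- random_assignment(30, 3, seed = seed + 500, id = "b")
    cons <- conservation(overlap_matrix(a, b))
    pres <- preservation(overlap_matrix(b, a))
    expect_equal(cons$score, pres$score)
    expect_equal(cons$cluster, pres$cluster)
  }
})

test_that("one cluster split into pure halves: conservation 1, preservation 0.5", {
  a <- cluster_assignment(paste0("c", 1:20), rep("A", 20), "a")
  b <- cluster_assignment(paste0("c", 1:20), rep(c("X", "Y"), each = 10), "b")
  ov <- overlap_matrix(a, b)
  expect_equal(preservation(ov)$score, 0.5)
  expect_equal(conservation(ov)$score, c(1, 1))
})

test_that("rand index equals exhaustive pair counting", {
  # exhaustive over all set-partition pairs of 5 cells
  parts <- all_partitions(5)
  cells <- paste0("c", 1:5)
  for (i in seq(1, length(parts), by = 7)) {
    for (j in seq(1, length(parts), by = 7)) {
      a <- cluster_assignment(cells, parts[[i]], "a")
      b <- cluster_assignment(cells, parts[[j]], "b")
      expect_equal(rand_index(a, b), rand_oracle(parts[[i]], parts[[j]]))
      expect_equal(rand_index(a, b, adjusted = TRUE),
                   rand_oracle(parts[[i]], parts[[j]], adjusted = TRUE))
    }
  }
  # random labelings of 8 cells
  for (seed in 1:40) {
    a <- random_assignment(8, 3, seed = seed, id = "a")
    b <- random_assignment(8, 4, seed = seed + 99, id = "b")
    expect_equal(rand_index(a, b), rand_oracle(a$labels, b$labels))
    expect_equal(rand_index(a, b, adjusted = TRUE),
                 rand_oracle(a$labels, b$labels, adjusted = TRUE))
  }
  expect_error(rand_index(cluster_assignment("c1", "1", "a"),
                          cluster_assignment("c1", "2", "b")), "2 common")
})

test_that("adjusted rand agrees with mclust and is null-centered", {
  for (seed in 1:10) {
    a <- random_assignment(200, 5, seed = seed, id = "a")
    b <- random_assignment(200, 4, seed = seed + 77, id = "b")
    expect_equal(rand_index(a, b, adjusted = TRUE),
                 mclust::adjustedRandIndex(a$labels, b$labels),
                 tolerance = 1e-12)
  }
  aris <- vapply(1:100, function(seed) {
    a <- random_assignment(1000, 5, seed = seed, id = "a")
    b <- random_assignment(1000, 5, seed = seed + 5000, id = "b")
    rand_index(a, b, adjusted = TRUE)
  }, numeric(1))
  expect_lt(max(abs(aris)), 0.05)
})

test_that("preservation >= 1/split and degradation is monotone in expectation", {
  for (seed in 1:20) {
    a <- random_assignment(60, 4, seed = seed, id = "a")
    b <- random_assignment(60, 5, seed = seed + 3, id = "b")
    ov <- overlap_matrix(a, b)
    pres <- preservation(ov)
    spl <- split_counts(ov, "rows")
    expect_true(all(pres$score >= 1 / spl[pres$cluster] - 1e-12))
  }

  # relabeling a growing fraction of cells degrades mean preservation
  set.seed(42)
  base <- random_assignment(400, 4, seed = 10, id = "a")
  mean_pres <- sapply(c(0, 0.2, 0.4, 0.8), function(p) {
    mean(sapply(1:15, function(r) {
      labs <- base$labels
      flip <- sample(400, round(p * 400))
      labs[flip] <- sample(paste0("k", 1:4), length(flip), replace = TRUE)
      b <- cluster_assignment(base$cells, labs, "b")
      mean(preservation(overlap_matrix(base, b))$score)
    }))
  })
  expect_true(all(diff(mean_pres) < 0))
})

test_that("compare_analyses bundles the metrics coherently", {
  a <- random_assignment(80, 4, seed = 2, id = "a")
  same <- compare_analyses(a, a)
  expect_equal(same$mean_preservation, 1)
  expect_equal(same$mean_conservation, 1)
  expect_equal(same$ari, 1)
  expect_true(all(same$preservation$split == 1))

  # one of two equal clusters merged in b
  m_a <- cluster_assignment(paste0("c", 1:40), rep(c("A", "B"), each = 20), "a")
  m_b <- cluster_assignment(paste0("c", 1:40), rep("X", 40), "b")
  cmp <- compare_analyses(m_a, m_b, weighted = TRUE)
  expect_equal(cmp$mean_preservation, 1.0)
  expect_equal(cmp$mean_conservation, 0.5)
  expect_equal(cmp$weighted_mean_conservation, 0.5)

  # round trip through the overlap CSV
  f <- tempfile(fileext = ".csv")
  write_overlap_csv(cmp$overlap, f)
  rt <- read_overlap_csv(f)
  fr <- overlap_fractions(cmp$overlap)
  expect_equal(rt$row_frac, fr$row_frac, tolerance = 1e-4)
  unlink(f)
})
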
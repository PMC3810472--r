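# Binary graph machinery: ROI extraction, connectivity, thresholding,
# degree, clustering, path length, rewired references, participation.

test_that("ROI time courses are in-mask voxel means", {
  d <- array(0, c(3, 1, 1, 4))
  d[1, 1, 1, ] <- c(1, 2, 3, 4)
  d[2, 1, 1, ] <- c(3, 4, 5, 6)
  d[3, 1, 1, ] <- -d[1, 1, 1, ]
  ds <- bold_dataset(d, tr_seconds = 2)
  labels <- array(c(1L, 1L, 2L), c(3, 1, 1))
  ts <- extract_roi_timeseries(ds, labels)
  expect_equal(ts["1", ], c(2, 3, 4, 5))
  expect_equal(ts["2", ], c(-1, -2, -3, -4))

  # two voxels x and -x average to zero
  d2 <- array(0, c(2, 1, 1, 4))
  d2[1, 1, 1, ] <- c(1, -1, 2, -2)
  d2[2, 1, 1, ] <- -d2[1, 1, 1, ]
  ts2 <- extract_roi_timeseries(bold_dataset(d2), array(1L, c(2, 1, 1)))
  expect_true(all(ts2 == 0))
})

test_that("connectivity matrices are capped Fisher z with zero diagonal", {
  set.seed(9)
  n <- rnorm(168)
  a <- n + rnorm(168, sd = sqrt(3))  # corr(a, n) ~ 0.5
  z <- connectivity_matrix(rbind(x = n, y = a))
  expect_equal(diag(z), c(0, 0), ignore_attr = TRUE)
  expect_equal(z[1, 2], atanh(cor(n, a)))

  dup <- connectivity_matrix(rbind(n, n))
  expect_equal(dup[1, 2], atanh(1 - 1e-7))

  null_ts <- matrix(rnorm(40 * 168), 40, 168)
  zn <- connectivity_matrix(null_ts)
  off <- zn[upper.tri(zn)]
  expect_lt(abs(mean(off)), 3 / sqrt(165) / sqrt(length(off)) * 10)

  expect_error(connectivity_matrix(rbind(rep(1, 10), rnorm(10))),
               "zero-variance")
})

test_that("proportional thresholding keeps exactly round(S*m) edges deterministically", {
  set.seed(10)
  w <- matrix(rnorm(25), 5, 5); w <- (w + t(w)) / 2; diag(w) <- 0
  g <- threshold_proportional(w, 0.2)
  expect_equal(sum(g) / 2, 2)  # round(0.2 * 10)
  # the two largest off-diagonal weights are kept
  ut <- which(upper.tri(w))
  top2 <- ut[order(-w[ut])][1:2]
  expect_true(all(g[top2] == 1))

  expect_equal(sum(threshold_proportional(w, 1)) / 2, 10)

  ties <- matrix(1, 6, 6); diag(ties) <- 0
  g1 <- threshold_proportional(ties, 0.5)
  g2 <- threshold_proportional(ties, 0.5)
  expect_identical(unclass(g1), unclass(g2))
  expect_equal(sum(g1) / 2, round(0.5 * 15))

  # monotone nesting of edge sets along the sparsity grid
  for (s1 in c(0.1, 0.2)) {
    ga <- threshold_proportional(w, s1)
    gb <- threshold_proportional(w, s1 + 0.15)
    expect_true(all(gb[ga == 1] == 1))
  }
  expect_error(threshold_proportional(w, 0), "sparsity")
})

test_that("degree and z-degree match hand computation", {
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  dz <- degree_and_z(binary_graph(star))
  expect_equal(dz$degree, c(3L, 1L, 1L, 1L))

  path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  z <- degree_and_z(binary_graph(path3))$z_degree
  # degrees (1, 2, 1): population z of (1,2,3) pattern applies to sorted variants
  d <- c(1, 2, 3)
  expect_equal(sort(unique(round((d - mean(d)) / sqrt(2 / 3), 4))),
               c(-1.2247, 0, 1.2247))

  ring <- ring_lattice_graph(6, 2)
  expect_error(degree_and_z(ring), "z-degree undefined")
})

test_that("clustering matches the brute-force oracle", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(clustering_coefficients(binary_graph(tri))$c_i, rep(1, 3))

  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(clustering_coefficients(binary_graph(star))$mean_c, 0)

  # 4-cycle plus a chord
  cyc <- rbind(c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 0, 1, 0))
  cyc[1, 3] <- cyc[3, 1] <- 1
  got <- clustering_coefficients(binary_graph(cyc))$c_i
  expect_equal(got, oracle_clustering(cyc))
})

test_that("path length matches analytic values and the Floyd-Warshall oracle", {
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(characteristic_path_length(binary_graph(k5)), 1)

  p3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(characteristic_path_length(binary_graph(p3)), 4 / 3)

  two <- matrix(0, 4, 4); two[1, 2] <- two[2, 1] <- two[3, 4] <- two[4, 3] <- 1
  expect_error(characteristic_path_length(binary_graph(two)), "disconnected")

  set.seed(11)
  for (i in 1:10) {
    a <- random_adjacency(sample(5:30, 1), 0.3, connected = TRUE)
    expect_equal(characteristic_path_length(binary_graph(a)),
                 oracle_path_length(a))
  }
})

test_that("rewiring conserves the degree sequence and edge count exactly", {
  set.seed(12)
  g <- planted_partition_graph(3, 10, 0.7, 0.1, seed = 4)
  r <- random_reference(g, n_swaps_per_edge = 10, seed = 6)
  expect_identical(rowSums(unclass(r)), rowSums(unclass(g)))
  expect_identical(sum(r), sum(g))
  # seeded: reproducible, and different seeds differ
  r2 <- random_reference(g, n_swaps_per_edge = 10, seed = 6)
  expect_identical(unclass(r), unclass(r2))
  expect_false(identical(unclass(r),
                         unclass(random_reference(g, 10, seed = 7))))

  tri <- binary_graph(matrix(1, 3, 3) - diag(3))
  expect_warning(rtri <- random_reference(tri, 10, seed = 1), "no valid")
  expect_identical(unclass(rtri), unclass(tri))
})

test_that("rewired ring lattices lose clustering but keep short paths", {
  rl <- ring_lattice_graph(100, 6)
  c0 <- clustering_coefficients(rl)$mean_c
  r <- random_reference(rl, n_swaps_per_edge = 10, seed = 8)
  c1 <- clustering_coefficients(r)$mean_c
  expect_equal(c0, 0.6)
  expect_lt(c1, 0.2)          # toward the density ~ 0.06
  expect_lt(characteristic_path_length(binary_graph(unclass(r))), 4)
})

test_that("a dense random graph is its own null: gamma ~ lambda ~ 1", {
  set.seed(13)
  a <- random_adjacency(50, 0.3, connected = TRUE)
  gm <- normalized_global_metrics(binary_graph(a), n_random = 20, seed = 9)
  expect_equal(gm$gamma, 1, tolerance = 0.15)
  expect_equal(gm$lambda, 1, tolerance = 0.1)
  expect_error(normalized_global_metrics(binary_graph(a), n_random = 0),
               "n_random")
})

test_that("participation matches hand values and the oracle", {
  # all edges within the own module
  two_k3 <- matrix(0, 6, 6)
  two_k3[1:3, 1:3] <- 1; two_k3[4:6, 4:6] <- 1; diag(two_k3) <- 0
  member <- rep(1:2, each = 3)
  expect_equal(participation_coefficients(binary_graph(two_k3), member),
               rep(0, 6))

  # degree 2, one edge into each of two modules -> 0.5
  a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- a[1, 3] <- a[3, 1] <- 1
  p <- participation_coefficients(binary_graph(a), c(1, 1, 2))
  expect_equal(p[1], 0.5)

  # degree 4 spread evenly over 4 modules -> 0.75
  st <- matrix(0, 5, 5); st[1, 2:5] <- 1; st <- st + t(st)
  p4 <- participation_coefficients(binary_graph(st), c(1, 1, 2, 3, 4))
  expect_equal(p4[1], 0.75)

  set.seed(14)
  a <- random_adjacency(20, 0.3)
  mem <- sample(1:3, 20, replace = TRUE)
  expect_equal(participation_coefficients(binary_graph(a), mem),
               oracle_participation(a, mem))
})

test_that("metrics agree with igraph as an independent cross-check", {
  set.seed(30)
  for (i in 1:5) {
    a <- random_adjacency(25, 0.3, connected = TRUE)
    ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(characteristic_path_length(binary_graph(a)),
                 igraph::mean_distance(ig), tolerance = 1e-12)
    expect_equal(clustering_coefficients(binary_graph(a))$c_i,
                 igraph::transitivity(ig, type = "localundirected",
                                      isolates = "zero"),
                 tolerance = 1e-12)
    mem <- sample(1:3, 25, replace = TRUE)
    expect_equal(modularity_q(binary_graph(a), mem),
                 igraph::modularity(ig, mem), tolerance = 1e-12)
  }
  # detected partitions score the same Q under igraph's implementation
  g <- planted_partition_graph(4, 15, 0.7, 0.05, seed = 31)
  p <- detect_communities(g)
  ig <- igraph::graph_from_adjacency_matrix(unclass(g), mode = "undirected")
  expect_equal(p$q, igraph::modularity(ig, p$assignment), tolerance = 1e-12)
})

test_that("module summaries are plain arithmetic means", {
  nm <- list(z_degree = rep(0, 6), participation = c(1, 1, 1, 0, 0, 0),
             c_i = seq(0, 1, length.out = 6))
  ms <- module_summaries(nm, rep(1:2, each = 3))
  expect_equal(ms$mean_z_degree, c(0, 0))
  expect_equal(ms$mean_participation, c(1, 0))
  expect_equal(ms$mean_clustering, c(0.2, 0.8))
})
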
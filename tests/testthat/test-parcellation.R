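# Atlas refinement: region voxel matrices, subdivision, homogeneity.

# small cohort with planted sub-structure inside every region
mini_cohort <- function(n_sub = 4, seed = 100, modules_per_region = 2,
                        grid = c(6, 6, 6), n_regions = 8) {
  cfg <- synth_config(grid_shape = grid, n_regions = n_regions,
                      modules_per_region = modules_per_region,
                      n_frames = 120, n_subjects_per_group = n_sub,
                      module_assignment = split(seq_len(n_regions),
                                                rep(c("a", "b"),
                                                    each = n_regions / 2)),
                      seed = seed)
  co <- generate_cohort(cfg)
  list(config = cfg, cohort = co,
       controls = co$subjects[co$manifest$group == "control"])
}

test_that("region mean matrices are averaged capped Fisher z", {
  # one subject, two perfectly correlated voxels -> cap
  d <- array(0, c(2, 1, 1, 30))
  s <- sin(seq_len(30))
  d[1, 1, 1, ] <- s; d[2, 1, 1, ] <- 2 * s + 1
  ds <- bold_dataset(d)
  z <- region_mean_voxel_matrix(list(ds), array(1L, c(2, 1, 1)), 1)
  expect_equal(z[1, 2], atanh(1 - 1e-7))
  expect_equal(diag(z), rep(0, 2), ignore_attr = TRUE)

  # r = 0.5 -> atanh(0.5)
  set.seed(18)
  x <- rnorm(5000); y <- x + rnorm(5000, sd = sqrt(3))
  d2 <- array(0, c(2, 1, 1, 5000))
  d2[1, 1, 1, ] <- x; d2[2, 1, 1, ] <- y
  z2 <- region_mean_voxel_matrix(list(bold_dataset(d2)),
                                 array(1L, c(2, 1, 1)), 1)
  expect_equal(z2[1, 2], atanh(0.5), tolerance = 0.06)

  expect_error(region_mean_voxel_matrix(list(ds), array(1L, c(2, 1, 1)), 9),
               "empty")
})

test_that("zero-variance voxels are excluded with a warning", {
  d <- array(rnorm(3 * 30), c(3, 1, 1, 30))
  d[2, 1, 1, ] <- 7
  ds <- bold_dataset(d)
  expect_warning(
    z <- region_mean_voxel_matrix(list(ds), array(1L, c(3, 1, 1)), 1),
    "zero-variance")
  expect_equal(nrow(z), 2)
  expect_equal(attr(z, "excluded"), 2L)
})

test_that("subdivision recovers planted blocks and respects homogeneity", {
  z <- matrix(0, 20, 20)
  z[1:10, 1:10] <- 1; z[11:20, 11:20] <- 1
  diag(z) <- 0
  lab <- subdivide_region(z, 0.3)
  expect_equal(partition_nmi(lab, rep(1:2, each = 10)), 1)

  # homogeneous matrix: no positive-Q split, single sub-label
  homog <- matrix(0.5, 12, 12); diag(homog) <- 0
  expect_equal(unique(subdivide_region(homog, 0.3)), 1L)
})

test_that("sub-parcellation nests inside parents and raises homogeneity", {
  mc <- mini_cohort()
  sp <- build_subparcellation(mc$controls, mc$cohort$atlas)
  atlas <- mc$cohort$atlas

  # nesting: every sub-region inside exactly one parent; union = parent
  for (s in seq_len(sp$n_nodes)) {
    vox <- which(sp$labels == s)
    expect_true(length(vox) > 0)
    expect_equal(unique(as.vector(atlas)[vox]), sp$parent[s])
  }
  for (r in sort(unique(as.vector(atlas)))) {
    subs <- which(sp$parent == r)
    expect_equal(sort(which(sp$labels %in% subs)),
                 sort(which(atlas == r)))
  }

  # planted 2 blocks per region recovered
  expect_equal(sp$n_nodes, 16)
  expect_true(all(sp$homogeneity$parent$n_subregions == 2))

  # refined homogeneity strictly exceeds parent homogeneity per region
  hr <- sp$homogeneity$refined
  hp <- sp$homogeneity$parent
  mean_ref <- tapply(hr$homogeneity, hr$parent, mean)
  expect_true(all(mean_ref > hp$homogeneity[match(names(mean_ref),
                                                  hp$region)]))

  # planted sub-regions recovered almost perfectly (the strict
  # NMI = 1 rate over many seeds is asserted in the acceptance suite)
  planted <- attr(mc$cohort$atlas, "subregions")
  expect_gte(partition_nmi(sp$labels[atlas > 0], planted[atlas > 0]), 0.95)
})

test_that("a single indivisible region yields a one-node parcellation", {
  # two identical voxels: the thresholded 2-voxel graph keeps
  # round(0.3 * 1) = 0 edges, no split has positive Q
  s <- sin(seq_len(50))
  d <- array(0, c(2, 1, 1, 50))
  d[1, 1, 1, ] <- s; d[2, 1, 1, ] <- s + 0.001 * cos(seq_len(50))
  sp <- build_subparcellation(list(bold_dataset(d)), array(1L, c(2, 1, 1)))
  expect_equal(sp$n_nodes, 1)
  expect_equal(unique(as.vector(sp$labels)), 1L)
})
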
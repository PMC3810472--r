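# Synthetic cohort generator: atlas blocks, latent-factor correlation
# structure, motion traces, planted-partition graphs.

test_that("toy atlas partitions the grid into equal contiguous blocks", {
  cfg <- synth_config(grid_shape = c(6, 6, 6), n_regions = 8,
                      module_assignment = list(a = 1:4, b = 5:8))
  atlas <- generate_toy_atlas(cfg)
  expect_setequal(unique(as.vector(atlas)), 1:8)
  expect_true(all(table(atlas) == 27))
  # each region is a contiguous 3x3x3 block
  for (r in 1:8) {
    ijk <- arrayInd(which(atlas == r), dim(atlas))
    expect_true(all(apply(ijk, 2, function(v) diff(range(v)) == 2)))
  }

  cfg1 <- synth_config(grid_shape = c(6, 6, 6), n_regions = 1,
                       module_assignment = list(a = 1))
  expect_true(all(generate_toy_atlas(cfg1) == 1L))

  cfg7 <- synth_config(grid_shape = c(6, 6, 6), n_regions = 7,
                       module_assignment = list(a = 1:7))
  expect_error(generate_toy_atlas(cfg7), "axis")
})

test_that("config validation rejects bad couplings and assignments", {
  expect_error(synth_config(noise_sd = 0), "noise_sd")
  expect_error(synth_config(n_regions = 4,
                            module_assignment = list(a = 1:3)),
               "exactly once")
  w <- matrix(1.0, 4, 2)
  expect_error(synth_config(within_module_coupling = w), "0, 1")
})

test_that("modular time series are deterministic and group-labelled", {
  cfg <- synth_config(grid_shape = c(6, 6, 6), n_regions = 8,
                      n_frames = 40, n_subjects_per_group = 2,
                      module_assignment = list(sensorimotor = 1:4,
                                               visual = 5:8))
  a <- generate_modular_timeseries(cfg, "control", subject_seed = 7)
  b <- generate_modular_timeseries(cfg, "control", subject_seed = 7)
  expect_identical(a$data, b$data)
  c2 <- generate_modular_timeseries(cfg, "control", subject_seed = 8)
  expect_false(identical(a$data, c2$data))
  expect_error(generate_modular_timeseries(cfg, "nope", 1), "unknown group")
})

test_that("zero coupling yields near-zero voxel correlations", {
  mods <- list(a = 1:4, b = 5:8)
  cfg <- synth_config(grid_shape = c(6, 6, 6), n_regions = 8,
                      n_frames = 168, module_assignment = mods,
                      within_module_coupling =
                        matrix(0, 2, 2, dimnames = list(names(mods), NULL)),
                      between_module_coupling = local({
                        b <- diag(2); dimnames(b) <- list(names(mods), names(mods))
                        list(control = b, patient = b)
                      }),
                      subregion_coupling = 0, noise_sd = 1)
  ds <- generate_modular_timeseries(cfg, "control", 11)
  x <- t(matrix(ds$data, 216, 168))
  r <- cor(x[, sample.int(216, 40)])
  off <- r[upper.tri(r)]
  # null correlation SE at n = 168 is ~1/sqrt(167) ~ 0.077
  expect_lt(abs(mean(off)), 3 * 0.077 / sqrt(length(off)) + 0.01)
  expect_lt(max(abs(off)), 5 * 0.077)
})

test_that("correlation hierarchy: sub-region > module > between-module", {
  set.seed(1)
  cfg <- synth_config(grid_shape = c(6, 6, 6), n_regions = 8,
                      module_assignment = list(a = 1:4, b = 5:8))
  ds <- generate_modular_timeseries(cfg, "control", 3)
  pl <- attr(ds, "planted")
  x <- t(matrix(ds$data, 216, cfg$n_frames))
  r <- cor(x)
  sub <- as.vector(pl$subregions)
  mod <- pl$module_of_region[as.vector(pl$atlas)]
  ut <- upper.tri(r)
  same_sub <- outer(sub, sub, "==") & ut
  same_mod <- outer(mod, mod, "==") & !outer(sub, sub, "==") & ut
  diff_mod <- outer(mod, mod, "!=") & ut
  m1 <- mean(r[same_sub]); m2 <- mean(r[same_mod]); m3 <- mean(r[diff_mod])
  se <- function(v) sd(v) / sqrt(length(v))
  expect_gt(m1 - m2, 3 * sqrt(se(r[same_sub])^2 + se(r[same_mod])^2))
  expect_gt(m2 - m3, 3 * sqrt(se(r[same_mod])^2 + se(r[diff_mod])^2))
})

test_that("motion traces honour step SD, spikes and seeds", {
  z <- generate_motion_trace(20, step_sd = rep(0, 6), seed = 1)
  expect_true(all(z == 0))
  sp <- generate_motion_trace(60, step_sd = rep(0, 6),
                              spike = list(frame = 50,
                                           magnitudes = c(3.5, 0, 0, 0, 0, 0)),
                              seed = 1)
  expect_gte(max(abs(sp[, "tx"])), 3.5)
  a <- generate_motion_trace(100, seed = 5)
  b <- generate_motion_trace(100, seed = 5)
  expect_identical(unclass(a), unclass(b))
  expect_error(generate_motion_trace(10, spike = list(frame = 11,
                                                      magnitudes = rep(1, 6))),
               "out of range")
  expect_error(generate_motion_trace(1), "n_frames")
})

test_that("planted-partition graphs match their edge probabilities", {
  g0 <- planted_partition_graph(3, 4, p_in = 1, p_out = 0, seed = 1)
  member <- attr(g0, "membership")
  expect_true(all(g0[outer(member, member, "==") & upper.tri(g0)] == 1))
  expect_true(all(g0[outer(member, member, "!=")] == 0))

  g1 <- planted_partition_graph(3, 4, p_in = 1, p_out = 0.999999, seed = 1)
  # p_out ~ 1: essentially complete
  expect_gte(sum(g1) / 2, choose(12, 2) - 3)

  g <- planted_partition_graph(4, 20, p_in = 0.8, p_out = 0.05, seed = 2)
  member <- attr(g, "membership")
  same <- outer(member, member, "==") & upper.tri(g)
  diff <- outer(member, member, "!=") & upper.tri(g)
  n_in <- sum(same); n_out <- sum(diff)
  expect_lt(abs(sum(g[same]) - 0.8 * n_in), 3 * sqrt(n_in * 0.8 * 0.2) + 1)
  expect_lt(abs(sum(g[diff]) - 0.05 * n_out), 3 * sqrt(n_out * 0.05 * 0.95) + 1)
  expect_error(planted_partition_graph(2, 5, 0.3, 0.5), "smaller")
})

test_that("cohort generation is deterministic and saveable", {
  cfg <- synth_config(grid_shape = c(4, 4, 4), n_regions = 8,
                      n_frames = 20, n_subjects_per_group = 2,
                      module_assignment = list(a = 1:4, b = 5:8))
  co <- generate_cohort(cfg)
  expect_length(co$subjects, 4)
  expect_identical(co$subjects[[1]]$data,
                   generate_cohort(cfg)$subjects[[1]]$data)
  dir <- file.path(tempdir(), "cohort_test")
  man <- save_cohort(co, dir)
  expect_true(all(file.exists(man$bold_path)))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  unlink(dir, recursive = TRUE)
})
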
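# Framewise displacement, motion summaries, exclusion rules, confound audit.

mk_trace <- function(...) {
  rows <- list(...)
  motion_trace(do.call(rbind, c(list(rep(0, 6)), rows)))
}

test_that("framewise displacement follows the absolute-difference-sum formula", {
  const <- motion_trace(matrix(0, 10, 6))
  expect_equal(framewise_displacement(const), rep(0, 9))

  step <- mk_trace(c(1, 0, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0))
  expect_equal(framewise_displacement(step), c(1, 0))

  rot <- mk_trace(c(0, 0, 0, 1, 0, 0))
  expect_equal(framewise_displacement(rot), pi / 180 * 50)
  expect_equal(framewise_displacement(rot, sphere_radius = 100), pi / 180 * 100)
})

test_that("FD depends only on parameter differences and is additive", {
  set.seed(42)
  p <- apply(matrix(rnorm(60), 10, 6), 2, cumsum)
  p <- sweep(p, 2, p[1, ])
  tr <- motion_trace(p)
  fd <- framewise_displacement(tr)
  # invariance: adding a constant to one parameter's whole trace changes
  # nothing once re-referenced (differences are unchanged)
  p2 <- p; p2[, 3] <- p2[, 3] + 5; p2 <- sweep(p2, 2, p2[1, ])
  expect_equal(framewise_displacement(motion_trace(p2)), fd)
  # additivity across parameters
  fd_single <- sapply(1:6, function(j) {
    pj <- matrix(0, 10, 6); pj[, j] <- p[, j]
    framewise_displacement(motion_trace(pj))
  })
  expect_equal(rowSums(fd_single), fd)
})

test_that("motion summaries match hand computations", {
  z <- motion_summaries(motion_trace(matrix(0, 5, 6)))
  expect_equal(c(z$d_max, z$d_rms, z$fd_max, z$fd_rms), rep(0, 4))

  spike <- mk_trace(c(2, 0, 0, 0, 0, 0), rep(0, 6))
  expect_equal(motion_summaries(spike)$d_max, 2)

  two <- mk_trace(c(1, 0, 0, 0, 0, 0))
  s <- motion_summaries(two)
  # pooled RMS over 2 frames: sqrt((0 + 1^2) / 2)
  expect_equal(s$d_rms, sqrt(1 / 2))
  expect_equal(s$fd_max, 1)
  expect_equal(s$fd_rms, 1)
  # rotations are radius-converted before entering d_max
  rot <- mk_trace(c(0, 0, 0, 0, 2, 0))
  expect_equal(motion_summaries(rot)$d_max, 2 * pi / 180 * 50)
})

test_that("exclusion triggers exactly at the documented cutoffs", {
  # translation range 3.5 mm
  tr <- mk_trace(c(3.5, 0, 0, 0, 0, 0))
  dec <- apply_exclusion(tr)
  expect_false(dec$include)
  expect_match(dec$reasons, "translation", all = FALSE)

  # all ranges at 1.0, fd fine -> include
  ok <- mk_trace(c(1, 0, 0, 0, 0, 0), c(1, 1, 0, 1, 0, 0))
  expect_true(apply_exclusion(ok)$include)

  # rotation range above 3 degrees
  rot <- mk_trace(c(0, 0, 0, 0, 3.2, 0))
  expect_match(apply_exclusion(rot)$reasons, "rotation", all = FALSE)

  # fd_max 2.6 with ranges fine: 2.6 mm single-frame translation excursion
  # split over two parameters so no single range exceeds 3.0
  fdtr <- mk_trace(c(1.5, 1.1, 0, 0, 0, 0), rep(0, 6))
  dec2 <- apply_exclusion(fdtr)
  expect_false(dec2$include)
  expect_match(dec2$reasons, "framewise", all = FALSE)

  # boundary: a slow drift up to just below the range cutoffs is included
  # (per-frame FD stays tiny even though the total range is near 3)
  drift <- matrix(0, 100, 6)
  drift[, 1] <- seq(0, 2.997, length.out = 100)
  drift[, 4] <- seq(0, 2.997, length.out = 100)
  expect_true(apply_exclusion(motion_trace(drift))$include)
  # the same drift slightly past 3.0 is excluded
  expect_false(apply_exclusion(motion_trace(drift * 1.01))$include)
})

test_that("enlarging cutoffs never turns include into exclude", {
  set.seed(7)
  n_included <- 0
  for (i in 1:20) {
    p <- apply(matrix(rnorm(120, sd = 0.25), 20, 6), 2, cumsum)
    tr <- motion_trace(sweep(p, 2, p[1, ]))
    base <- apply_exclusion(tr, exclusion_rule())
    wide <- apply_exclusion(tr, exclusion_rule(max_translation = 6,
                                               max_rotation = 6, max_fd = 5))
    if (base$include) {
      n_included <- n_included + 1
      expect_true(wide$include)
    }
  }
  expect_gt(n_included, 0)
})

test_that("motion audit flags true motion coupling and excludes constants", {
  set.seed(3)
  n <- 20
  sums <- data.frame(d_max = runif(n), d_rms = runif(n),
                     fd_max = runif(n), fd_rms = runif(n))
  edges <- cbind(motion_copy = sums$fd_rms,
                 constant = rep(1, n),
                 noise = rnorm(n))
  aud <- motion_confound_audit(edges, sums, alpha = 0.01)
  expect_equal(aud$correlation["fd_rms", "motion_copy"], 1, tolerance = 1e-12)
  expect_lt(aud$p["fd_rms", "motion_copy"], 0.01)
  # constant edge: undefined, excluded from the test count
  expect_true(all(is.na(aud$p[, "constant"])))
  expect_equal(aud$n_tests, 8)
  expect_error(motion_confound_audit(edges[1:3, ], sums[1:3, ]), "4 subjects")
})

test_that("motion file round trip preserves the trace; SPM dialect converts", {
  tr <- generate_motion_trace(30, seed = 2)
  f <- tempfile(fileext = ".txt")
  write.table(format(unclass(tr), digits = 12), f, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  back <- read_motion_file(f)
  expect_equal(unclass(back), unclass(tr), tolerance = 1e-9,
               ignore_attr = TRUE)
  # SPM dialect: rotations in radians
  spm <- unclass(tr); spm[, 4:6] <- spm[, 4:6] * pi / 180
  write.table(format(spm, digits = 12), f, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  back2 <- read_motion_file(f, dialect = "spm")
  expect_equal(unclass(back2), unclass(tr), tolerance = 1e-9,
               ignore_attr = TRUE)
  unlink(f)
})
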
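# Synthetic cohort generator: seeded BOLD-like volumes with planted modular
# correlation structure, toy atlases, motion traces, and planted-partition
# graphs. Stands in for an (undeposited) patient/control resting-state cohort
# so every downstream stage of the pipeline is testable offline.

#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' voxel time series with a three-level latent-factor correlation hierarchy
#' (sub-region > anatomical region's network module > between modules),
#' nested inside a block atlas, with two groups that differ in coupling.
#'
#' Each voxel series is
#' \deqn{x_v(t) = \sqrt{w_m}\,M_m(t) + \sqrt{u}\,S_s(t) + g\,G(t) + \sigma\,\epsilon_v(t)}
#' where `M_m` is the latent signal of network module `m` (module latents are
#' correlated across modules with the group's between-module coupling),
#' `S_s` the latent of the voxel's planted sub-region, `G` an optional global
#' signal and `\epsilon` i.i.d. Gaussian noise. All latents are i.i.d. unit
#' Gaussian across frames, so the implied covariance is positive
#' semi-definite by construction. Expected correlations are
#' within sub-region `(w + u)/V`, within module `w/V`, and between modules
#' `sqrt(w_m w_{m'}) rho_{mm'}/sqrt(V_m V_{m'})` with `V` the voxel variance.
#'
#' Defaults describe the demo study: a 16^3 grid, 64 block regions in 4
#' network modules, 2 planted sub-regions per region, 168 frames at TR 2 s,
#' 12 subjects per group. The patient group has raised within-module
#' coupling in the "sensorimotor" module (0.30 to 0.45) and lowered
#' between-module coupling of the "visual" module (0.30 to 0.10), planting
#' the module-degree-up / module-participation-down effect pattern.
#'
#' @param grid_shape integer(3), voxels per axis.
#' @param n_frames number of frames per run.
#' @param tr_seconds repetition time in seconds.
#' @param n_regions number of atlas regions (block partition of the grid).
#' @param modules_per_region planted sub-regions per atlas region.
#' @param module_assignment named list: network module -> integer region IDs.
#'   Every region must belong to exactly one module.
#' @param within_module_coupling matrix (module x group) of within-module
#'   coupling weights `w` in \[0, 1).
#' @param between_module_coupling list (one symmetric module x module matrix
#'   per group) of between-module latent correlations in \[0, 1).
#' @param subregion_coupling extra variance share `u` of the sub-region
#'   latent, in \[0, 1).
#' @param noise_sd standard deviation of the voxel noise, > 0.
#' @param global_coupling coefficient of a shared global signal (0 = off;
#'   the analysis performs no global-signal regression, so default off).
#' @param n_subjects_per_group subjects per group.
#' @param groups character(2), group labels; the second is the "patient"
#'   analog carrying the planted effects.
#' @param motion_step_sd per-frame random-walk step SD for the six motion
#'   parameters (mm for translations, degrees for rotations).
#' @param seed root seed for the cohort.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(16L, 16L, 16L),
                         n_frames = 168L,
                         tr_seconds = 2,
                         n_regions = 64L,
                         modules_per_region = 2L,
                         module_assignment = NULL,
                         within_module_coupling = NULL,
                         between_module_coupling = NULL,
                         subregion_coupling = 0.3,
                         noise_sd = sqrt(0.4),
                         global_coupling = 0,
                         n_subjects_per_group = 12L,
                         groups = c("control", "patient"),
                         motion_step_sd = rep(0.03, 6L),
                         seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 1))
    stopf("grid_shape must be 3 positive integers")
  if (n_frames < 2) stopf("n_frames must be >= 2")
  if (tr_seconds <= 0) stopf("tr_seconds must be positive")
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  if (length(groups) != 2L) stopf("exactly two groups are required")
  if (is.null(module_assignment)) {
    # four canonical resting-state-network analogs, equal share of regions
    nm <- c("subcortical", "default_mode", "visual", "sensorimotor")
    if (n_regions %% 4L == 0L) {
      per <- n_regions / 4L
      module_assignment <- split(seq_len(n_regions),
                                 rep(nm, each = per))[nm]
    } else {
      module_assignment <- split(seq_len(n_regions),
                                 rep_len(nm, n_regions))
    }
  }
  regions <- sort(unlist(module_assignment, use.names = FALSE))
  if (!identical(as.integer(regions), seq_len(n_regions)))
    stopf("module_assignment must cover every region exactly once")
  mods <- names(module_assignment)
  n_mod <- length(mods)
  if (is.null(within_module_coupling)) {
    within_module_coupling <- matrix(0.30, n_mod, 2L,
                                     dimnames = list(mods, groups))
    if ("sensorimotor" %in% mods)
      within_module_coupling["sensorimotor", 2L] <- 0.45
  }
  if (is.null(between_module_coupling)) {
    base <- matrix(0.30, n_mod, n_mod, dimnames = list(mods, mods))
    diag(base) <- 1
    between_module_coupling <- list(base, base)
    names(between_module_coupling) <- groups
    if ("visual" %in% mods) {
      b <- between_module_coupling[[2L]]
      b["visual", ] <- b[, "visual"] <- 0.10
      b["visual", "visual"] <- 1
      between_module_coupling[[2L]] <- b
    }
  }
  w <- within_module_coupling
  if (any(w < 0 | w >= 1)) stopf("within_module_coupling must lie in [0, 1)")
  for (b in between_module_coupling)
    if (any(b[upper.tri(b)] < 0 | b[upper.tri(b)] >= 1))
      stopf("between_module_coupling must lie in [0, 1)")
  if (subregion_coupling < 0 || subregion_coupling >= 1)
    stopf("subregion_coupling must lie in [0, 1)")
  structure(list(
    grid_shape = as.integer(grid_shape), n_frames = as.integer(n_frames),
    tr_seconds = tr_seconds, n_regions = as.integer(n_regions),
    modules_per_region = as.integer(modules_per_region),
    module_assignment = module_assignment,
    within_module_coupling = w,
    between_module_coupling = between_module_coupling,
    subregion_coupling = subregion_coupling, noise_sd = noise_sd,
    global_coupling = global_coupling,
    n_subjects_per_group = as.integer(n_subjects_per_group),
    groups = groups, motion_step_sd = motion_step_sd,
    seed = as.integer(seed)), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic cohort config:",
      paste(x$grid_shape, collapse = "x"), "grid,",
      x$n_regions, "regions in", length(x$module_assignment),
      "network modules,", x$modules_per_region, "sub-regions/region\n")
  cat(" ", x$n_frames, "frames @ TR", x$tr_seconds, "s;",
      x$n_subjects_per_group, "subjects per group (",
      paste(x$groups, collapse = ", "), "); seed", x$seed, "\n")
  invisible(x)
}

# Most balanced factorization of n into 3 factors (k1, k2, k3), each
# required to divide the corresponding grid axis.
block_factors <- function(n_regions, grid_shape) {
  best <- NULL; best_ok <- NULL
  for (k1 in 1:n_regions) {
    if (n_regions %% k1 != 0) next
    rest <- n_regions / k1
    for (k2 in 1:rest) {
      if (rest %% k2 != 0) next
      k3 <- rest / k2
      triple <- c(k1, k2, k3)
      score <- max(triple) / min(triple)
      ok <- all(grid_shape %% triple == 0)
      if (ok && (is.null(best_ok) || score < best_ok$score))
        best_ok <- list(triple = triple, score = score)
      if (is.null(best) || score < best$score)
        best <- list(triple = triple, score = score)
    }
  }
  if (!is.null(best_ok)) return(best_ok$triple)
  bad <- which(grid_shape %% best$triple != 0)[1L]
  stopf("cannot split a %s grid into %d equal blocks: axis %d (size %d) is not divisible by %d",
        paste(grid_shape, collapse = "x"), n_regions, bad,
        grid_shape[bad], best$triple[bad])
}

#' Generate a toy block atlas
#'
#' Partitions the grid into `n_regions` contiguous rectangular blocks,
#' labelled 1..n_regions; a stand-in for an anatomical template. All voxels
#' are in-mask (background 0 never occurs for divisible grids).
#'
#' @param config a [synth_config()].
#' @return integer 3D array of region labels with attribute `subregions`,
#'   an integer 3D array of the planted sub-region labels (dense IDs
#'   1..n_regions*modules_per_region) used by recovery tests.
#' @export
generate_toy_atlas <- function(config) {
  gs <- config$grid_shape
  k <- block_factors(config$n_regions, gs)
  bs <- gs %/% k
  idx <- arrayInd(seq_len(prod(gs)), gs)
  bx <- (idx[, 1] - 1L) %/% bs[1]
  by <- (idx[, 2] - 1L) %/% bs[2]
  bz <- (idx[, 3] - 1L) %/% bs[3]
  labels <- 1L + bx + k[1] * (by + k[2] * bz)
  atlas <- array(as.integer(labels), gs)
  # planted sub-regions: split each block into contiguous slabs along its
  # longest axis (ties broken toward x); near-equal voxel counts
  mpr <- config$modules_per_region
  sub <- array(0L, gs)
  ax <- which.max(bs)
  for (r in seq_len(config$n_regions)) {
    vox <- which(atlas == r)
    pos <- arrayInd(vox, gs)[, ax]
    o <- order(pos, vox)
    slab <- as.integer(cut(seq_along(vox), breaks = mpr, labels = FALSE))
    sub[vox[o]] <- (r - 1L) * mpr + slab
  }
  attr(atlas, "subregions") <- sub
  atlas
}

#' Construct a BOLD dataset container
#'
#' @param data 4D numeric array (x, y, z, frame).
#' @param mask logical 3D array congruent with `data`; default all TRUE.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id subject identifier.
#' @param group group label.
#' @return object of class `bold_dataset`.
#' @export
bold_dataset <- function(data, mask = NULL, tr_seconds = 2,
                         subject_id = "subject", group = NA_character_) {
  d <- dim(data)
  if (length(d) != 4L) stopf("data must be a 4D array")
  if (d[4] < 2L) stopf("need at least 2 frames")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3])) stopf("mask and data are not congruent")
  if (any(!is.finite(data[rep(as.vector(mask), d[4])])))
    stopf("non-finite values inside mask")
  structure(list(data = data, mask = mask, tr_seconds = tr_seconds,
                 subject_id = subject_id, group = group),
            class = "bold_dataset")
}

#' @export
print.bold_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat("bold_dataset", x$subject_id,
      if (!is.na(x$group)) paste0("(", x$group, ")"), ":",
      paste(d[1:3], collapse = "x"), "grid,", d[4], "frames, TR",
      x$tr_seconds, "s,", sum(x$mask), "in-mask voxels\n")
  invisible(x)
}

# frames x in-mask-voxels matrix view of a dataset
bold_matrix <- function(dataset) {
  d <- dim(dataset$data)
  m <- matrix(dataset$data, prod(d[1:3]), d[4])
  t(m[as.vector(dataset$mask), , drop = FALSE])
}

# write a frames x voxels matrix back into the dataset's 4D array
bold_from_matrix <- function(dataset, x) {
  d <- dim(dataset$data)
  m <- matrix(0, prod(d[1:3]), d[4])
  m[as.vector(dataset$mask), ] <- t(x)
  dataset$data <- array(m, d)
  dataset
}

#' Generate one subject's modular BOLD-like time series
#'
#' Latent-factor construction (see [synth_config()]): module latents are
#' drawn correlated according to the group's between-module coupling,
#' sub-region latents and noise i.i.d. Deterministic given `subject_seed`.
#'
#' @param config a [synth_config()].
#' @param group one of `config$groups`.
#' @param subject_seed integer seed for this subject.
#' @param subject_id identifier stored in the result.
#' @return a [bold_dataset()]; the planted voxel->sub-region and
#'   region->module maps are attached as attribute `planted`.
#' @export
generate_modular_timeseries <- function(config, group, subject_seed,
                                        subject_id = paste0("sub_", subject_seed)) {
  if (!group %in% config$groups) stopf("unknown group '%s'", group)
  if (config$noise_sd <= 0) stopf("noise_sd must be positive")
  gi <- match(group, config$groups)
  atlas <- generate_toy_atlas(config)
  sub <- attr(atlas, "subregions")
  gs <- config$grid_shape
  nt <- config$n_frames
  mods <- names(config$module_assignment)
  n_mod <- length(mods)
  module_of_region <- integer(config$n_regions)
  for (m in seq_len(n_mod))
    module_of_region[config$module_assignment[[m]]] <- m
  n_sub <- config$n_regions * config$modules_per_region
  x <- with_seed(subject_seed, {
    cmat <- config$between_module_coupling[[gi]]
    ch <- chol(cmat)  # errors if the implied structure is not PSD
    lat_mod <- matrix(stats::rnorm(nt * n_mod), nt, n_mod) %*% ch
    lat_sub <- matrix(stats::rnorm(nt * n_sub), nt, n_sub)
    glob <- stats::rnorm(nt)
    vox_region <- as.vector(atlas)
    vox_sub <- as.vector(sub)
    vox_mod <- module_of_region[vox_region]
    w <- sqrt(config$within_module_coupling[vox_mod, gi])
    u <- sqrt(config$subregion_coupling)
    n_vox <- prod(gs)
    noise <- matrix(stats::rnorm(nt * n_vox, sd = config$noise_sd), nt, n_vox)
    lat_mod[, vox_mod, drop = FALSE] * rep(w, each = nt) +
      u * lat_sub[, vox_sub, drop = FALSE] +
      config$global_coupling * glob + noise
  })
  ds <- bold_dataset(array(t(x), c(gs, nt)), mask = array(TRUE, gs),
                     tr_seconds = config$tr_seconds,
                     subject_id = subject_id, group = group)
  attr(ds, "planted") <- list(atlas = atlas, subregions = sub,
                              module_of_region = module_of_region,
                              module_names = mods)
  ds
}

#' Generate a random-walk head-motion trace
#'
#' Six rigid-body parameters (3 translations in mm, 3 rotations in degrees)
#' relative to the first frame, simulated as a Gaussian random walk starting
#' at zero, with an optional transient spike at a stated frame.
#'
#' @param n_frames number of frames (>= 2).
#' @param step_sd numeric(6) per-parameter step standard deviations.
#' @param spike optional `list(frame =, magnitudes =)` adding `magnitudes`
#'   (numeric(6)) to that single frame.
#' @param seed integer seed.
#' @return a [motion_trace()].
#' @export
generate_motion_trace <- function(n_frames, step_sd = rep(0.03, 6L),
                                  spike = NULL, seed = 1L) {
  if (n_frames < 2) stopf("n_frames must be >= 2")
  step_sd <- rep_len(step_sd, 6L)
  if (any(step_sd < 0)) stopf("step_sd must be non-negative")
  p <- with_seed(seed, {
    steps <- matrix(stats::rnorm((n_frames - 1L) * 6L,
                                 sd = rep(step_sd, each = n_frames - 1L)),
                    n_frames - 1L, 6L)
    rbind(0, apply(steps, 2L, cumsum))
  })
  if (!is.null(spike)) {
    f <- spike$frame
    if (is.null(f) || f < 1L || f > n_frames)
      stopf("spike frame %s out of range 1..%d", format(f), n_frames)
    p[f, ] <- p[f, ] + rep_len(spike$magnitudes, 6L)
    if (f == 1L) p <- sweep(p, 2L, p[1L, ], "-")  # frame 1 stays reference
  }
  motion_trace(p)
}

#' Generate a planted-partition random graph
#'
#' Undirected simple graph on `n_modules * nodes_per_module` nodes: each
#' within-module pair is connected with probability `p_in`, each
#' between-module pair with `p_out` (`p_out < p_in`).
#'
#' @param n_modules,nodes_per_module partition shape.
#' @param p_in,p_out edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed integer seed.
#' @return a [binary_graph()] adjacency matrix with attribute `membership`
#'   (the planted node -> module vector).
#' @export
planted_partition_graph <- function(n_modules, nodes_per_module,
                                    p_in, p_out, seed = 1L) {
  if (p_out >= p_in) stopf("p_out must be strictly smaller than p_in")
  if (p_in > 1 || p_out < 0) stopf("p_in, p_out must lie in [0, 1]")
  n <- n_modules * nodes_per_module
  member <- rep(seq_len(n_modules), each = nodes_per_module)
  a <- with_seed(seed, {
    same <- outer(member, member, "==")
    pmat <- ifelse(same, p_in, p_out)
    u <- matrix(0, n, n)
    ut <- upper.tri(u)
    u[ut] <- stats::runif(sum(ut)) < pmat[ut]
    u + t(u)
  })
  g <- binary_graph(a)
  attr(g, "membership") <- member
  g
}

#' Ring-lattice / Watts-Strogatz graph
#'
#' Each node is connected to its `k` nearest neighbours on a ring (`k`
#' even); with `p_rewire > 0` each edge is rewired to a uniformly chosen
#' non-duplicate endpoint with that probability (the Watts-Strogatz
#' construction). At `p_rewire = 0` this is the canonical high-clustering,
#' long-path substrate; a small rewiring probability adds the shortcuts
#' that collapse the characteristic path length while clustering stays
#' high — the small-world regime.
#'
#' @param n number of nodes.
#' @param k even neighbourhood size.
#' @param p_rewire per-edge rewiring probability.
#' @param seed integer seed (used when `p_rewire > 0`).
#' @return a [binary_graph()].
#' @export
ring_lattice_graph <- function(n, k, p_rewire = 0, seed = 1L) {
  if (k %% 2 != 0 || k < 2 || k >= n) stopf("k must be even, 2 <= k < n")
  a <- matrix(0, n, n)
  for (d in seq_len(k / 2)) {
    i <- seq_len(n)
    j <- ((i - 1L + d) %% n) + 1L
    a[cbind(i, j)] <- 1
    a[cbind(j, i)] <- 1
  }
  if (p_rewire > 0) {
    a <- with_seed(seed, {
      for (d in seq_len(k / 2)) {
        for (i in seq_len(n)) {
          if (stats::runif(1) >= p_rewire) next
          j <- ((i - 1L + d) %% n) + 1L
          if (a[i, j] == 0) next  # already rewired away
          cand <- which(a[i, ] == 0)
          cand <- setdiff(cand, i)
          if (!length(cand)) next
          jj <- cand[sample.int(length(cand), 1L)]
          a[i, j] <- a[j, i] <- 0
          a[i, jj] <- a[jj, i] <- 1
        }
      }
      a
    })
  }
  binary_graph(a)
}

#' Generate a full synthetic cohort
#'
#' Draws `n_subjects_per_group` subjects for each group plus per-subject
#' motion traces; all seeds are forked deterministically from the config
#' seed.
#'
#' @param config a [synth_config()].
#' @return list with elements `subjects` (list of [bold_dataset()]),
#'   `motion` (list of [motion_trace()]), `manifest` (data.frame:
#'   subject_id, group), `atlas` and `config`.
#' @export
generate_cohort <- function(config) {
  atlas <- generate_toy_atlas(config)
  subjects <- list(); motion <- list(); rows <- list()
  for (g in config$groups) {
    for (i in seq_len(config$n_subjects_per_group)) {
      sid <- sprintf("%s_%02d", g, i)
      sseed <- fork_seed(config$seed, "bold", g, i)
      subjects[[sid]] <- generate_modular_timeseries(config, g, sseed, sid)
      motion[[sid]] <- generate_motion_trace(
        config$n_frames, step_sd = config$motion_step_sd,
        seed = fork_seed(config$seed, "motion", g, i))
      rows[[sid]] <- data.frame(subject_id = sid, group = g,
                                stringsAsFactors = FALSE)
    }
  }
  list(subjects = subjects, motion = motion,
       manifest = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       atlas = atlas, config = config)
}

#' Write a synthetic cohort to disk
#'
#' BOLD volumes and the atlas as NIfTI-1, motion traces as whitespace-
#' delimited six-column text (translations mm, rotations degrees), the
#' cohort manifest as TSV and the config as YAML.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest with file paths added.
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$bold_path <- NA_character_; man$motion_path <- NA_character_
  for (i in seq_len(nrow(man))) {
    sid <- man$subject_id[i]
    bp <- file.path(dir, paste0(sid, "_bold.nii"))
    mp <- file.path(dir, paste0(sid, "_motion.txt"))
    ds <- cohort$subjects[[sid]]
    img <- RNifti::asNifti(ds$data, pixdim = c(rep(1, 3), ds$tr_seconds))
    RNifti::writeNifti(img, bp)
    utils::write.table(format(cohort$motion[[sid]], digits = 10), mp,
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    man$bold_path[i] <- bp; man$motion_path[i] <- mp
  }
  atlas_path <- file.path(dir, "atlas.nii")
  RNifti::writeNifti(RNifti::asNifti(cohort$atlas), atlas_path)
  write_tsv(man, file.path(dir, "manifest.tsv"))
  cfg <- cohort$config
  cfg_list <- lapply(unclass(cfg), function(x)
    if (is.matrix(x)) as.data.frame(x) else x)
  yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  invisible(man)
}
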
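# Refinement of an anatomical atlas into functionally homogeneous
# sub-regions: per-region voxel correlation matrices averaged over a
# reference cohort, proportional thresholding, and spectral community
# detection within each region.

#' Mean voxel-level Fisher-z matrix for one region
#'
#' Per subject, the Pearson correlation matrix of all voxel time series in
#' the region, Fisher z-transformed (capped, see [fisher_z()]), then
#' averaged element-wise over the cohort. The diagonal is set to 0.
#' Voxels with zero variance in any subject are excluded (with a warning)
#' and recorded in the `excluded` attribute.
#'
#' @param cohort list of [bold_dataset()]s (the reference group).
#' @param atlas integer label volume.
#' @param region region ID.
#' @return symmetric Fisher-z matrix over the region's voxels, with
#'   attributes `voxels` (linear voxel indices) and `excluded`.
#' @export
region_mean_voxel_matrix <- function(cohort, atlas, region) {
  if (length(cohort) < 1L) stopf("need at least one subject")
  vox <- which(as.vector(atlas) == region)
  if (length(vox) == 0L) stopf("region %s is empty", format(region))
  d4 <- dim(cohort[[1L]]$data)
  excluded <- integer()
  series <- lapply(cohort, function(ds) {
    flat <- matrix(ds$data, prod(d4[1:3]), d4[4])
    x <- t(flat[vox, , drop = FALSE])
    zv <- which(apply(x, 2L, stats::sd) == 0)
    excluded <<- union(excluded, zv)
    x
  })
  keep <- setdiff(seq_along(vox), excluded)
  if (length(excluded))
    warning(sprintf("region %s: %d zero-variance voxel(s) excluded",
                    format(region), length(excluded)))
  if (length(keep) < 1L) stopf("region %s has no usable voxels", format(region))
  zsum <- 0
  for (x in series)
    zsum <- zsum + fisher_z(stats::cor(x[, keep, drop = FALSE]))
  z <- zsum / length(series)
  diag(z) <- 0
  attr(z, "voxels") <- vox[keep]
  attr(z, "excluded") <- vox[excluded]
  z
}

#' Subdivide one region by community detection
#'
#' Thresholds the region's Fisher-z voxel matrix to a binary graph keeping
#' the strongest 30% of weights (proportional threshold), then runs Newman
#' spectral community detection on it. A single sub-region is a valid
#' outcome when no split increases modularity.
#'
#' @param matrix symmetric Fisher-z voxel matrix (from
#'   [region_mean_voxel_matrix()]).
#' @param proportional_threshold fraction of strongest weights kept.
#' @param fine_tune passed to [detect_communities()].
#' @return integer vector: voxel -> sub-label assignment (dense 1..k).
#' @export
subdivide_region <- function(matrix, proportional_threshold = 0.3,
                             fine_tune = TRUE) {
  if (nrow(matrix) < 2L) return(rep(1L, nrow(matrix)))
  g <- threshold_proportional(matrix, proportional_threshold)
  detect_communities(g, fine_tune = fine_tune)$assignment
}

# mean off-diagonal of a symmetric matrix (0-diagonal convention)
mean_offdiag <- function(z) {
  n <- nrow(z)
  if (n < 2L) return(NA_real_)
  sum(z) / (n * (n - 1))
}

#' Build a refined sub-parcellation of the whole atlas
#'
#' Applies [subdivide_region()] to every region of the atlas using the
#' reference cohort (by design the control group only, so node definitions
#' are never influenced by the patient group), relabels sub-regions
#' densely, and reports per-region homogeneity (mean pairwise voxel
#' Fisher z) for both the parent and the refined parcellation, plus a
#' post-hoc 6-connectivity fragmentation count per sub-region (spatial
#' contiguity is not enforced).
#'
#' @param cohort list of [bold_dataset()]s (reference group).
#' @param atlas integer label volume.
#' @param proportional_threshold passed to [subdivide_region()].
#' @param region_names optional character names of the parent regions.
#' @return object of class `subparcellation`: list with `labels` (integer
#'   volume), `parent` (sub-region -> parent region ID), `names`
#'   (sub-region names, `"<Region> <k>"`), `n_nodes`, and `homogeneity`
#'   (list of data.frames `parent` and `refined`).
#' @export
build_subparcellation <- function(cohort, atlas, proportional_threshold = 0.3,
                                  region_names = NULL) {
  regions <- sort(unique(as.vector(atlas[atlas > 0])))
  if (is.null(region_names))
    region_names <- paste0("R", regions)
  labels <- array(0L, dim(atlas))
  parent <- integer(); names_out <- character()
  hom_parent <- data.frame(region = regions, n_voxels = NA_integer_,
                           homogeneity = NA_real_, n_subregions = NA_integer_)
  hom_sub <- list()
  next_id <- 0L
  for (ri in seq_along(regions)) {
    r <- regions[ri]
    z <- region_mean_voxel_matrix(cohort, atlas, r)
    vox <- attr(z, "voxels")
    assign_r <- subdivide_region(z, proportional_threshold)
    k <- max(assign_r)
    hom_parent$n_voxels[ri] <- length(vox)
    hom_parent$homogeneity[ri] <- mean_offdiag(z)
    hom_parent$n_subregions[ri] <- k
    for (s in seq_len(k)) {
      next_id <- next_id + 1L
      sel <- assign_r == s
      labels[vox[sel]] <- next_id
      parent[next_id] <- r
      names_out[next_id] <- paste(region_names[ri], s)
      hom_sub[[next_id]] <- data.frame(
        sub_id = next_id, parent = r,
        name = names_out[next_id], n_voxels = sum(sel),
        homogeneity = mean_offdiag(z[sel, sel, drop = FALSE]))
    }
  }
  refined <- do.call(rbind, hom_sub)
  # fragmentation report: connected components per sub-region (faces)
  refined$n_components <- vapply(seq_len(next_id), function(s) {
    cl <- label_clusters(labels == s, connectivity = 6L)
    max(cl$labels, 0L)
  }, 0L)
  structure(list(labels = labels, parent = parent, names = names_out,
                 n_nodes = next_id,
                 homogeneity = list(parent = hom_parent, refined = refined),
                 proportional_threshold = proportional_threshold),
            class = "subparcellation")
}

#' @export
print.subparcellation <- function(x, ...) {
  hp <- x$homogeneity$parent; hr <- x$homogeneity$refined
  cat("subparcellation:", x$n_nodes, "sub-regions from", nrow(hp),
      "parent regions (threshold S =", x$proportional_threshold, ")\n")
  cat(sprintf("  mean homogeneity (Fisher z): parent %.3f, refined %.3f\n",
              mean(hp$homogeneity, na.rm = TRUE),
              mean(hr$homogeneity, na.rm = TRUE)))
  invisible(x)
}
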
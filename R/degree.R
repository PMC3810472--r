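# Voxel-level degree centrality: correlate every in-mask voxel with every
# other voxel, count supra-threshold connections, z-transform, and build
# group hub maps.

#' Voxel degree centrality map
#'
#' For each in-mask voxel, counts the other in-mask voxels whose time
#' series correlate above `r_threshold` (one-sided on signed r: `r >
#' r_threshold`; anti-correlations do not count). The correlation matrix is
#' processed in column blocks so peak memory stays bounded by
#' `n_voxels * block_size`; the result is independent of the block size.
#'
#' @param dataset a [bold_dataset()].
#' @param r_threshold correlation threshold (default 0.25).
#' @param block_size number of voxels per correlation block.
#' @param on_zero_variance `"error"` (default) or `"mask"`: zero-variance
#'   in-mask voxels either abort with the voxel named, or are removed from
#'   the mask before computing.
#' @return object of class `degree_map`: list with `degree` (integer 3D
#'   array, NA outside mask), `z_degree` (NULL until [z_transform_map()]),
#'   `mask`, `r_threshold`, `n_mask_voxels`.
#' @export
voxel_degree_map <- function(dataset, r_threshold = 0.25, block_size = 1024L,
                             on_zero_variance = c("error", "mask")) {
  on_zero_variance <- match.arg(on_zero_variance)
  if (abs(r_threshold) >= 1) stopf("r_threshold must lie in (-1, 1)")
  mask <- dataset$mask
  x <- bold_matrix(dataset)
  nv <- ncol(x)
  if (nv < 2L) stopf("need at least 2 in-mask voxels")
  xs <- standardize_cols(x)
  zv <- attr(xs, "zero_var")
  if (!is.null(zv)) {
    if (on_zero_variance == "error") {
      vox <- which(as.vector(mask))[zv[1L]]
      ijk <- arrayInd(vox, dim(mask))
      stopf("zero-variance in-mask voxel at (%d, %d, %d)",
            ijk[1], ijk[2], ijk[3])
    }
    keep <- setdiff(seq_len(nv), zv)
    mask[which(as.vector(mask))[zv]] <- FALSE
    xs <- standardize_cols(x[, keep, drop = FALSE])
    nv <- length(keep)
  }
  nt <- nrow(xs)
  deg <- integer(nv)
  blocks <- split(seq_len(nv), ceiling(seq_len(nv) / block_size))
  for (b in blocks) {
    r <- crossprod(xs, xs[, b, drop = FALSE]) / (nt - 1)
    deg[b] <- colSums(r > r_threshold) - 1L  # self-correlation r = 1 always counts
  }
  vol <- array(NA_integer_, dim(mask))
  vol[mask] <- deg
  structure(list(degree = vol, z_degree = NULL, mask = mask,
                 r_threshold = r_threshold, n_mask_voxels = nv),
            class = "degree_map")
}

#' @export
print.degree_map <- function(x, ...) {
  cat("degree_map:", x$n_mask_voxels, "in-mask voxels, r >",
      x$r_threshold, "| mean degree",
      sprintf("%.1f", mean(x$degree[x$mask])),
      if (!is.null(x$z_degree)) "(z-transformed)", "\n")
  invisible(x)
}

#' z-transform a degree map
#'
#' `z = (degree - mean) / SD` over in-mask voxels, with the population SD
#' convention. Out-of-mask voxels stay NA.
#'
#' @param map a [degree_map()].
#' @return the map with `z_degree` filled.
#' @export
z_transform_map <- function(map) {
  d <- map$degree[map$mask]
  s <- pop_sd(d)
  if (s == 0) stopf("all in-mask degrees are equal; z-transform undefined")
  z <- array(NA_real_, dim(map$degree))
  z[map$mask] <- (d - mean(d)) / s
  map$z_degree <- z
  map
}

#' Group hub map from z-degree maps
#'
#' Voxelwise one-sample t statistic of the subjects' z-degrees against 0;
#' the hub volume marks voxels with t above `t_cutoff`.
#'
#' @param z_maps list of z-transformed [degree_map()]s with congruent
#'   masks.
#' @param t_cutoff hub threshold on the t statistic.
#' @return list with `t_map` (3D array), `hubs` (logical 3D array),
#'   `t_cutoff`, `n_subjects`.
#' @export
hub_map <- function(z_maps, t_cutoff = 6) {
  if (length(z_maps) < 2L) stopf("need at least 2 subjects")
  mask <- z_maps[[1L]]$mask
  for (m in z_maps) {
    if (!identical(dim(m$mask), dim(mask)) || !identical(m$mask, mask))
      stopf("subject masks do not match")
    if (is.null(m$z_degree)) stopf("z_degree missing; run z_transform_map() first")
  }
  z <- vapply(z_maps, function(m) m$z_degree[mask],
              numeric(sum(mask)))
  n <- ncol(z)
  mu <- rowMeans(z)
  se <- apply(z, 1L, stats::sd) / sqrt(n)
  t_in <- ifelse(se > 0, mu / se, 0)
  t_map <- array(NA_real_, dim(mask))
  t_map[mask] <- t_in
  hubs <- array(FALSE, dim(mask))
  hubs[mask] <- t_in > t_cutoff
  list(t_map = t_map, hubs = hubs, t_cutoff = t_cutoff, n_subjects = n)
}
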
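# Voxelwise group t-maps with cluster-extent inference: supra-threshold
# connected components, a permutation null of maximum cluster sizes, and
# BH-FDR over cluster p-values.

# neighbour offsets for 6/18/26-connectivity in 3D
connectivity_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(off != 0)
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1,
                 stopf("connectivity must be 6, 18 or 26"))
  off[keep, , drop = FALSE]
}

#' Label connected clusters in a binary volume
#'
#' Maximal face-connected components (6-connectivity by default; 18/26
#' configurable) of the TRUE voxels of a 3D logical array.
#'
#' @param volume logical 3D array.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full cube).
#' @return list with `labels` (integer 3D array, 0 = background) and
#'   `sizes` (voxels per cluster, cluster IDs 1..k).
#' @export
label_clusters <- function(volume, connectivity = 6L) {
  dm <- dim(volume)
  if (length(dm) != 3L) stopf("volume must be a 3D array")
  off <- connectivity_offsets(connectivity)
  labels <- array(0L, dm)
  vox <- which(volume)
  if (length(vox) == 0L)
    return(list(labels = labels, sizes = integer()))
  coords <- arrayInd(vox, dm)
  in_set <- array(FALSE, dm)
  in_set[vox] <- TRUE
  cur <- 0L
  stack <- integer(length(vox))
  for (v in vox) {
    if (labels[v] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- v
    labels[v] <- cur
    while (top > 0L) {
      u <- stack[top]; top <- top - 1L
      uc <- arrayInd(u, dm)
      for (o in seq_len(nrow(off))) {
        w <- uc + off[o, ]
        if (any(w < 1L) || any(w > dm)) next
        wl <- w[1L] + dm[1L] * (w[2L] - 1L + dm[2L] * (w[3L] - 1L))
        if (in_set[wl] && labels[wl] == 0L) {
          labels[wl] <- cur
          top <- top + 1L
          stack[top] <- wl
        }
      }
    }
  }
  list(labels = labels, sizes = as.integer(tabulate(labels[labels > 0L], cur)))
}

# clusters of t > threshold (direction = +1) or t < -threshold (-1)
supra_clusters <- function(t_map, threshold, direction, connectivity) {
  supra <- array(FALSE, dim(t_map))
  ok <- !is.na(t_map)
  supra[ok] <- if (direction > 0) t_map[ok] > threshold else t_map[ok] < -threshold
  label_clusters(supra, connectivity)
}

#' Voxelwise group comparison of z-degree maps with cluster inference
#'
#' Voxelwise two-sample t-test (pooled variance) between the groups'
#' z-degree maps; the two one-sided supra-threshold maps at the t-value of
#' `cluster_forming_p` are decomposed into face-connected clusters. Cluster
#' p-values come from a permutation null of the maximum cluster size
#' (group labels permuted, both directions pooled into one maximum-style
#' null), and are BH-FDR adjusted across all observed clusters. The
#' smallest surviving cluster size is reported as the critical size.
#' Voxels with degenerate (zero pooled) variance are masked out and
#' counted.
#'
#' @param zmaps_a,zmaps_b lists of z-transformed [degree_map()]s with
#'   congruent masks.
#' @param cluster_forming_p one-sided cluster-defining p (default 0.005).
#' @param cluster_alpha FDR level for cluster significance.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @param connectivity cluster connectivity (6, 18 or 26).
#' @return object of class `cluster_result`: list with `t_map`, `clusters`
#'   (data.frame: direction, size k, peak_t, peak coordinates, p,
#'   p_adjusted, significant), `critical_size`, `t_threshold`,
#'   `n_degenerate_voxels`, `null_max_sizes`.
#' @export
voxel_degree_group_test <- function(zmaps_a, zmaps_b,
                                    cluster_forming_p = 0.005,
                                    cluster_alpha = 0.05,
                                    n_perm = 1000L, seed = 1L,
                                    connectivity = 6L) {
  if (length(zmaps_a) < 2L || length(zmaps_b) < 2L)
    stopf("need at least 2 subjects per group")
  mask <- zmaps_a[[1L]]$mask
  for (m in c(zmaps_a, zmaps_b))
    if (!identical(m$mask, mask)) stopf("subject masks do not match")
  get_z <- function(m) {
    if (is.null(m$z_degree)) stopf("z_degree missing; run z_transform_map()")
    m$z_degree[mask]
  }
  xa <- t(vapply(zmaps_a, get_z, numeric(sum(mask))))
  xb <- t(vapply(zmaps_b, get_z, numeric(sum(mask))))
  na <- nrow(xa); nb <- nrow(xb)
  df <- na + nb - 2
  t_threshold <- stats::qt(1 - cluster_forming_p, df)
  tt <- column_t_test(xa, xb)
  degenerate <- is.na(tt$t)
  t_map <- array(NA_real_, dim(mask))
  t_map[mask] <- ifelse(degenerate, NA_real_, tt$t)
  obs <- list()
  for (dir in c(1, -1)) {
    cl <- supra_clusters(t_map, t_threshold, dir, connectivity)
    if (length(cl$sizes) == 0L) next
    for (ci in seq_along(cl$sizes)) {
      vox <- which(cl$labels == ci)
      tv <- t_map[vox]
      pk <- vox[which.max(abs(tv))]
      obs[[length(obs) + 1L]] <- data.frame(
        direction = if (dir > 0) "A>B" else "B>A",
        k = cl$sizes[ci],
        peak_t = tv[which.max(abs(tv))],
        peak_x = arrayInd(pk, dim(mask))[1L],
        peak_y = arrayInd(pk, dim(mask))[2L],
        peak_z = arrayInd(pk, dim(mask))[3L],
        stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(obs)) do.call(rbind, obs) else
    data.frame(direction = character(), k = integer(), peak_t = numeric(),
               peak_x = integer(), peak_y = integer(), peak_z = integer())
  # permutation null of the maximum cluster size (both directions)
  pooled <- rbind(xa, xb)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ia <- sample.int(na + nb, na)
      pt <- column_t_test(pooled[ia, , drop = FALSE],
                          pooled[-ia, , drop = FALSE])
      pm <- array(NA_real_, dim(mask))
      pm[mask] <- pt$t
      mx <- 0L
      for (dir in c(1, -1)) {
        cl <- supra_clusters(pm, t_threshold, dir, connectivity)
        if (length(cl$sizes)) mx <- max(mx, max(cl$sizes))
      }
      mx
    }, integer(1))
  })
  if (nrow(clusters)) {
    clusters$p <- vapply(clusters$k, function(k)
      (1 + sum(null_max >= k)) / (n_perm + 1), 0)
    adj <- fdr_adjust(clusters$p, q = cluster_alpha)
    clusters$p_adjusted <- adj$p_adjusted
    clusters$significant <- adj$rejected
    clusters <- clusters[order(clusters$p, -clusters$k), ]
    rownames(clusters) <- NULL
  } else {
    clusters$p <- numeric(); clusters$p_adjusted <- numeric()
    clusters$significant <- logical()
  }
  critical_size <- if (any(clusters$significant))
    min(clusters$k[clusters$significant]) else NA_integer_
  structure(list(t_map = t_map, clusters = clusters,
                 critical_size = critical_size,
                 t_threshold = t_threshold,
                 cluster_forming_p = cluster_forming_p,
                 cluster_alpha = cluster_alpha,
                 n_degenerate_voxels = sum(degenerate),
                 null_max_sizes = null_max),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "cluster result: %d clusters (t threshold %.2f, forming p %.3g); %d significant at FDR %.2f",
    nrow(x$clusters), x$t_threshold, x$cluster_forming_p,
    sum(x$clusters$significant), x$cluster_alpha))
  if (!is.na(x$critical_size))
    cat("; critical size k =", x$critical_size)
  cat("\n")
  invisible(x)
}
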
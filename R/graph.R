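# Node-level graph construction and binary graph metrics: proportional
# thresholding, degree/z-degree, clustering, characteristic path length,
# degree-preserving rewired null networks and normalized (small-world)
# metrics, participation coefficients and module summaries.

#' Construct a binary graph
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param sparsity optional realized sparsity stored as an attribute.
#' @return the adjacency matrix, classed `binary_graph`.
#' @export
binary_graph <- function(adjacency, sparsity = NULL) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stopf("adjacency must be square")
  if (any(a != 0 & a != 1)) stopf("adjacency must be binary")
  if (any(diag(a) != 0)) stopf("self-loops are not allowed")
  if (any(a != t(a))) stopf("adjacency must be symmetric")
  storage.mode(a) <- "double"
  n <- nrow(a)
  if (is.null(sparsity))
    sparsity <- if (n > 1L) sum(a) / (n * (n - 1)) else 0
  structure(a, sparsity = sparsity,
            class = c("binary_graph", class(matrix())))
}

#' @export
print.binary_graph <- function(x, ...) {
  n <- nrow(x)
  cat("binary_graph:", n, "nodes,", sum(x) / 2, "edges, sparsity",
      sprintf("%.3f\n", attr(x, "sparsity")))
  invisible(x)
}

#' Mean time course per sub-region
#'
#' @param dataset a [bold_dataset()].
#' @param parcellation a [subparcellation()] or an integer label volume.
#' @return nodes x frames matrix of regional mean time courses; row names
#'   are node names when available.
#' @export
extract_roi_timeseries <- function(dataset, parcellation) {
  labels <- if (inherits(parcellation, "subparcellation"))
    parcellation$labels else parcellation
  if (!identical(dim(labels), dim(dataset$mask)))
    stopf("parcellation and dataset are not congruent")
  d <- dim(dataset$data)
  flat <- matrix(dataset$data, prod(d[1:3]), d[4])
  lab <- as.vector(labels)
  lab[!as.vector(dataset$mask)] <- 0L
  ids <- sort(unique(lab[lab > 0L]))
  if (inherits(parcellation, "subparcellation")) {
    want <- seq_len(parcellation$n_nodes)
    missing <- setdiff(want, ids)
    if (length(missing))
      stopf("node %d has no in-mask voxels", missing[1L])
    ids <- want
  }
  ts <- matrix(0, length(ids), d[4])
  for (i in seq_along(ids))
    ts[i, ] <- colMeans(flat[lab == ids[i], , drop = FALSE])
  rownames(ts) <- if (inherits(parcellation, "subparcellation"))
    parcellation$names else as.character(ids)
  ts
}

#' Node-by-node connectivity matrix
#'
#' Zero-lag Pearson correlation of regional time courses, Fisher
#' z-transformed (capped, see [fisher_z()]); diagonal set to 0.
#'
#' @param ts nodes x frames matrix.
#' @return symmetric Fisher-z matrix, classed `connectivity_matrix`.
#' @export
connectivity_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3L) stopf("need at least 3 frames")
  v <- apply(ts, 1L, stats::sd)
  if (any(v == 0))
    stopf("zero-variance time course at node %s",
          paste(utils::head(rownames(ts)[v == 0] %||% which(v == 0)), collapse = ", "))
  z <- fisher_z(stats::cor(t(ts)))
  diag(z) <- 0
  structure(z, class = c("connectivity_matrix", class(matrix())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Proportional threshold to a binary graph
#'
#' Keeps the `round(S * n(n-1)/2)` largest off-diagonal weights (upper
#' triangle); ties are broken deterministically by (row, column)
#' lexicographic order so results are identical across runs and platforms.
#'
#' @param matrix symmetric weight matrix (e.g. a [connectivity_matrix()]).
#' @param sparsity target sparsity S in (0, 1\].
#' @return a [binary_graph()].
#' @export
threshold_proportional <- function(matrix, sparsity) {
  if (sparsity <= 0 || sparsity > 1) stopf("sparsity must lie in (0, 1]")
  w <- as.matrix(matrix)
  n <- nrow(w)
  ut <- which(upper.tri(w))
  m_keep <- round(sparsity * n * (n - 1) / 2)
  idx <- arrayInd(ut, dim(w))
  o <- order(-w[ut], idx[, 1L], idx[, 2L])
  keep <- ut[o[seq_len(m_keep)]]
  a <- base::matrix(0, n, n)
  a[keep] <- 1
  a <- a + t(a)
  dimnames(a) <- dimnames(w)
  binary_graph(a, sparsity = sparsity)
}

#' Node degree and z-degree
#'
#' Degree is the number of edges incident to each node; the z-degree
#' standardizes it across nodes with the population mean and SD.
#'
#' @param graph a [binary_graph()].
#' @return list with `degree` (integer) and `z_degree` (numeric).
#' @export
degree_and_z <- function(graph) {
  if (nrow(graph) < 2L) stopf("need at least 2 nodes")
  d <- rowSums(unclass(graph))
  s <- pop_sd(d)
  if (s == 0) stopf("degree SD is zero; z-degree undefined (regular graph)")
  list(degree = as.integer(d), z_degree = (d - mean(d)) / s)
}

#' Clustering coefficients (binary, Watts-Strogatz convention)
#'
#' `C_i` is the fraction of a node's neighbour pairs that are themselves
#' connected: `2 t_i / (D_i (D_i - 1))` with `t_i` the number of triangles
#' through node i. Nodes of degree < 2 get `C_i = 0` and are included in
#' the mean.
#'
#' @param graph a [binary_graph()].
#' @return list with per-node `c_i` and `mean_c`.
#' @export
clustering_coefficients <- function(graph) {
  a <- unclass(graph)
  d <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  ci <- ifelse(d >= 2, 2 * tri / (d * (d - 1)), 0)
  list(c_i = ci, mean_c = mean(ci))
}

# hop-count distance matrix (BFS, unit edges); -1 where unreachable
graph_distances <- function(graph) {
  bfs_distances_cpp(unclass(graph) != 0)
}

#' Is the graph connected?
#'
#' @param graph a [binary_graph()].
#' @return logical.
#' @export
is_connected <- function(graph) {
  if (nrow(graph) <= 1L) return(TRUE)
  all(graph_distances(graph)[1L, ] >= 0)
}

#' Characteristic path length
#'
#' Mean shortest hop-count path over all ordered node pairs i != j.
#' Requires a connected graph; a disconnected graph is an error (no
#' silent infinite or harmonic-mean substitution).
#'
#' @param graph a [binary_graph()].
#' @return the characteristic path length L.
#' @export
characteristic_path_length <- function(graph) {
  n <- nrow(graph)
  if (n < 2L) stopf("need at least 2 nodes")
  d <- graph_distances(graph)
  if (any(d < 0)) stopf("graph is disconnected; path length undefined")
  sum(d) / (n * (n - 1))
}

#' Degree-preserving rewired reference network
#'
#' Maslov-Sneppen double-edge swaps: repeatedly picks two edges (a,b),
#' (c,d) and rewires them to (a,d), (c,b), rejecting swaps that would
#' create self-loops or multi-edges. The degree sequence (and hence the
#' edge count) is conserved exactly. Seeded and deterministic.
#'
#' @param graph a [binary_graph()].
#' @param n_swaps_per_edge target number of successful swaps per edge.
#' @param seed integer seed.
#' @return a rewired [binary_graph()]. If no valid swap exists (e.g. a
#'   triangle), the input is returned with a warning.
#' @export
random_reference <- function(graph, n_swaps_per_edge = 10, seed = 1L) {
  a <- unclass(graph)
  idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  m <- nrow(idx)
  if (m < 2L) {
    warning("fewer than 2 edges; returning the input graph")
    return(graph)
  }
  res <- with_seed(seed, {
    rewire_cpp(idx, nrow(a), as.integer(round(n_swaps_per_edge * m)))
  })
  if (res$n_success == 0L) {
    warning("no valid degree-preserving swap exists; returning the input graph")
    return(graph)
  }
  out <- base::matrix(0, nrow(a), ncol(a))
  out[res$edges] <- 1
  out <- out + t(out)
  dimnames(out) <- dimnames(a)
  binary_graph(out, sparsity = attr(graph, "sparsity"))
}

#' Normalized global metrics (small-world indices)
#'
#' Computes the mean clustering coefficient C and characteristic path
#' length L of the graph and normalizes them by their averages over
#' `n_random` degree-preserving rewired reference networks:
#' gamma = C / mean(C_random), lambda = L / mean(L_random), and
#' sigma = gamma / lambda. gamma >> 1 with lambda ~ 1 indicates
#' small-world topology. Disconnected references are skipped (their count
#' is reported); if all references are disconnected this is an error.
#'
#' @param graph a connected [binary_graph()].
#' @param n_random number of reference networks.
#' @param n_swaps_per_edge rewiring budget per reference.
#' @param seed integer seed (forked per reference).
#' @return object of class `global_metrics`: list with `mean_c`, `l`,
#'   `gamma`, `lambda`, `sigma`, `c_random`, `l_random`,
#'   `n_disconnected_refs`.
#' @export
normalized_global_metrics <- function(graph, n_random = 20,
                                      n_swaps_per_edge = 10, seed = 1L) {
  if (n_random < 1) stopf("n_random must be >= 1")
  n <- nrow(graph)
  mean_dist <- function(g) {
    d <- graph_distances(g)
    if (any(d < 0)) return(NA_real_)   # disconnected
    sum(d) / (n * (n - 1))
  }
  l <- mean_dist(graph)
  if (is.na(l)) stopf("graph is disconnected")
  cc <- clustering_coefficients(graph)$mean_c
  c_r <- l_r <- rep(NA_real_, n_random)
  for (i in seq_len(n_random)) {
    ref <- random_reference(graph, n_swaps_per_edge,
                            seed = fork_seed(seed, "ref", i))
    l_ref <- mean_dist(ref)
    if (is.na(l_ref)) next
    c_r[i] <- clustering_coefficients(ref)$mean_c
    l_r[i] <- l_ref
  }
  ok <- !is.na(c_r)
  if (!any(ok)) stopf("all %d rewired references were disconnected", n_random)
  gamma <- cc / mean(c_r[ok])
  lambda <- l / mean(l_r[ok])
  structure(list(mean_c = cc, l = l, gamma = gamma, lambda = lambda,
                 sigma = gamma / lambda, c_random = c_r[ok],
                 l_random = l_r[ok], n_disconnected_refs = sum(!ok)),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, ...) {
  cat(sprintf("global metrics: C %.3f, L %.3f, gamma %.3f, lambda %.3f, sigma %.3f (%d refs, %d disconnected skipped)\n",
              x$mean_c, x$l, x$gamma, x$lambda, x$sigma,
              length(x$c_random), x$n_disconnected_refs))
  invisible(x)
}

#' Participation coefficients
#'
#' `P_i = 1 - sum_m (k_im / D_i)^2`, with `k_im` the number of edges from
#' node i into module m. 0 when all of a node's edges stay in one module
#' (and for isolated nodes), approaching 1 for edges spread evenly across
#' modules.
#'
#' @param graph a [binary_graph()].
#' @param partition a [partition()] or a membership vector covering all
#'   nodes.
#' @return numeric vector of per-node participation coefficients.
#' @export
participation_coefficients <- function(graph, partition) {
  member <- if (inherits(partition, "partition")) partition$assignment
            else as.integer(partition)
  a <- unclass(graph)
  n <- nrow(a)
  if (length(member) != n) stopf("partition does not cover all nodes")
  d <- rowSums(a)
  mods <- sort(unique(member))
  kim2 <- base::matrix(0, n, length(mods))
  for (j in seq_along(mods))
    kim2[, j] <- rowSums(a[, member == mods[j], drop = FALSE])^2
  p <- ifelse(d > 0, 1 - rowSums(kim2) / d^2, 0)
  as.numeric(p)
}

#' Per-module summaries of node metrics
#'
#' Arithmetic means of z-degree, participation and clustering over the
#' nodes of each module of a reference partition (derived from the control
#' group and applied unchanged to every subject).
#'
#' @param node_metrics data.frame/list with per-node `z_degree`,
#'   `participation` and optionally `c_i`.
#' @param partition a [partition()] or membership vector.
#' @return data.frame: module, n_nodes, mean_z_degree,
#'   mean_participation (and mean_clustering when supplied).
#' @export
module_summaries <- function(node_metrics, partition) {
  member <- if (inherits(partition, "partition")) partition$assignment
            else as.integer(partition)
  mods <- sort(unique(member))
  if (any(tabulate(match(member, mods)) == 0L)) stopf("empty module")
  get_mean <- function(v) vapply(mods, function(m) mean(v[member == m]), 0)
  out <- data.frame(module = mods,
                    n_nodes = as.integer(table(factor(member, levels = mods))),
                    mean_z_degree = get_mean(node_metrics$z_degree),
                    mean_participation = get_mean(node_metrics$participation))
  if (!is.null(node_metrics$c_i))
    out$mean_clustering <- get_mean(node_metrics$c_i)
  out
}
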
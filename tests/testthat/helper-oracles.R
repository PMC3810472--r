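# Brute-force reference implementations and graph generators used to
# cross-check the package's graph metrics. Deliberately naive (loops,
# Floyd-Warshall, direct formula sums) and independent of the package's
# code paths.

oracle_degree <- function(a) as.integer(rowSums(a))

# triangle-counting by explicit neighbour-pair enumeration
oracle_clustering <- function(a) {
  n <- nrow(a)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (u in seq_along(nb)) for (v in seq_len(u - 1))
      if (a[nb[u], nb[v]] != 0) links <- links + 1
    ci[i] <- 2 * links / (k * (k - 1))
  }
  ci
}

# all-pairs shortest hop counts via Floyd-Warshall (relaxation over
# intermediate nodes k; vectorized across the (i, j) plane)
oracle_distances_fw <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a != 0] <- 1
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

oracle_path_length <- function(a) {
  d <- oracle_distances_fw(a)
  if (any(!is.finite(d))) return(NA_real_)
  n <- nrow(a)
  sum(d) / (n * (n - 1))
}

# direct evaluation of Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(ci, cj)
oracle_modularity <- function(a, member) {
  k <- rowSums(a)
  m2 <- sum(k)
  if (m2 == 0) return(0)
  q <- 0
  n <- nrow(a)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (member[i] == member[j])
      q <- q + a[i, j] - k[i] * k[j] / m2
  q / m2
}

oracle_participation <- function(a, member) {
  n <- nrow(a)
  p <- numeric(n)
  for (i in seq_len(n)) {
    d <- sum(a[i, ])
    if (d == 0) next
    s <- 0
    for (m in unique(member)) s <- s + (sum(a[i, member == m]) / d)^2
    p[i] <- 1 - s
  }
  p
}

# Erdos-Renyi adjacency matrix (plain matrix, not classed)
random_adjacency <- function(n, p, connected = FALSE) {
  repeat {
    a <- matrix(0, n, n)
    ut <- upper.tri(a)
    a[ut] <- as.numeric(stats::runif(sum(ut)) < p)
    a <- a + t(a)
    if (!connected) return(a)
    if (n == 1 || all(is.finite(oracle_distances_fw(a)))) return(a)
  }
}

# enumerate every labelled graph on n nodes (2^(n(n-1)/2) of them)
all_graphs <- function(n) {
  ne <- n * (n - 1) / 2
  ut <- which(upper.tri(matrix(0, n, n)))
  lapply(seq_len(2^ne) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(ne)]
    a <- matrix(0, n, n)
    a[ut] <- bits
    a + t(a)
  })
}
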
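# Group inference: nonparametric permutation tests, Benjamini-Hochberg FDR,
# per-edge two-sample t-tests and ranked edge reports.

#' Two-sample permutation test on the difference of means
#'
#' The statistic is `mean(a) - mean(b)`. The p-value follows the add-one
#' Monte-Carlo convention `p = (1 + #{permuted stat at least as extreme}) /
#' (n_perm + 1)`. When the total number of distinct group assignments
#' `choose(na + nb, na)` does not exceed `n_perm`, the test switches to
#' exact enumeration and `p` is the exact proportion over all assignments.
#'
#' @param values_a,values_b numeric group samples (each of length >= 2... 1
#'   is rejected).
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed integer seed for the Monte-Carlo draw.
#' @param alternative `"two_sided"`, `"greater"` (a > b) or `"less"`.
#' @return list with `statistic`, `p`, `exact` (logical), `n_perm_used`.
#' @export
permutation_test <- function(values_a, values_b, n_perm = 5000L, seed = 1L,
                             alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stopf("both groups need at least 2 values")
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  na <- length(values_a); nb <- length(values_b)
  pool <- c(values_a, values_b)
  n <- na + nb
  obs <- mean(values_a) - mean(values_b)
  stat_from_idx <- function(ia) {
    sa <- sum(pool[ia])
    sa / na - (sum(pool) - sa) / nb
  }
  extreme <- function(s) switch(alternative,
    two_sided = abs(s) >= abs(obs) - 1e-12,
    greater = s >= obs - 1e-12,
    less = s <= obs + 1e-12)
  n_total <- choose(n, na)
  if (n_total <= n_perm) {
    combos <- utils::combn(n, na)
    stats_all <- apply(combos, 2L, stat_from_idx)
    p <- mean(extreme(stats_all))
    return(list(statistic = obs, p = p, exact = TRUE,
                n_perm_used = ncol(combos)))
  }
  hits <- with_seed(seed, {
    idx <- vapply(seq_len(n_perm), function(i) sample.int(n, na),
                  integer(na))
    sa <- colSums(matrix(pool[idx], nrow = na))
    sum(extreme(sa / na - (sum(pool) - sa) / nb))
  })
  list(statistic = obs, p = (1 + hits) / (n_perm + 1), exact = FALSE,
       n_perm_used = n_perm)
}

#' Benjamini-Hochberg FDR adjustment with rejection mask
#'
#' Step-up adjusted p-values (`min` over `j >= rank` of `m * p_(j) / j`,
#' clipped at 1; computed via [stats::p.adjust()]) and the set rejected at
#' level `q`.
#'
#' @param p_values numeric p-values in \[0, 1\].
#' @param q FDR level.
#' @return list with `p_adjusted` and logical `rejected`.
#' @export
fdr_adjust <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, rejected = adj <= q)
}

# vectorized two-sample t over the columns of two matrices
# (subjects x features); pooled variance by default, Welch optional
column_t_test <- function(xa, xb, var_equal = TRUE) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- colSums(sweep(xa, 2L, ma)^2) / (na - 1)
  vb <- colSums(sweep(xb, 2L, mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- ifelse(se > 0, (ma - mb) / se, NA_real_)
  list(t = t, df = df, mean_a = ma, mean_b = mb, se = se)
}

#' Edge-level two-sample t-tests
#'
#' Tests every edge (upper-triangle node pair) of the Fisher-z
#' connectivity matrices for a group difference with a two-sample t-test
#' (pooled variance by default, Welch via `var_equal = FALSE`). Edges that
#' are constant within both groups have an undefined statistic and are
#' flagged and excluded from significance counts. The scope can be
#' restricted to edges incident to a node set (e.g. one module's nodes).
#'
#' @param matrices_a,matrices_b lists of [connectivity_matrix()] (or plain
#'   symmetric matrices) per subject; node order must agree.
#' @param alpha significance level used for the significant-edge count.
#' @param scope optional integer vector of node indices; only edges with at
#'   least one end in `scope` are tested. With `cross_scope_only = TRUE`
#'   only edges from `scope` to nodes outside it are kept.
#' @param cross_scope_only see `scope`.
#' @param alternative `"two_sided"`, `"greater"` (A > B) or `"less"`.
#' @param var_equal pooled (TRUE) or Welch (FALSE) statistic.
#' @return data.frame of class `edge_test` with node indices and names,
#'   group means (Fisher z), t, df, p, and `defined`; the significant
#'   count at `alpha` is attached as attribute `n_significant`.
#' @export
edge_group_test <- function(matrices_a, matrices_b, alpha = 0.05,
                            scope = NULL, cross_scope_only = FALSE,
                            alternative = c("two_sided", "greater", "less"),
                            var_equal = TRUE) {
  alternative <- match.arg(alternative)
  if (length(matrices_a) < 2L || length(matrices_b) < 2L)
    stopf("need at least 2 subjects per group")
  z1 <- matrices_a[[1L]]
  n <- nrow(z1)
  node_names <- rownames(z1) %||% paste0("node", seq_len(n))
  check <- function(m) {
    if (nrow(m) != n) stopf("node order/count mismatch between subjects")
    if (!is.null(rownames(m)) && !identical(rownames(m), node_names))
      stopf("node order mismatch between subjects")
  }
  lapply(c(matrices_a, matrices_b), check)
  ut <- which(upper.tri(z1))
  ij <- arrayInd(ut, c(n, n))
  if (!is.null(scope)) {
    in_scope_i <- ij[, 1L] %in% scope
    in_scope_j <- ij[, 2L] %in% scope
    keep <- if (cross_scope_only) xor(in_scope_i, in_scope_j)
            else in_scope_i | in_scope_j
    ut <- ut[keep]; ij <- ij[keep, , drop = FALSE]
  }
  xa <- t(vapply(matrices_a, function(m) as.matrix(m)[ut], numeric(length(ut))))
  xb <- t(vapply(matrices_b, function(m) as.matrix(m)[ut], numeric(length(ut))))
  tt <- column_t_test(xa, xb, var_equal = var_equal)
  p <- switch(alternative,
    two_sided = 2 * stats::pt(-abs(tt$t), tt$df),
    greater = stats::pt(tt$t, tt$df, lower.tail = FALSE),
    less = stats::pt(tt$t, tt$df))
  out <- data.frame(
    node_i = ij[, 1L], node_j = ij[, 2L],
    name_i = node_names[ij[, 1L]], name_j = node_names[ij[, 2L]],
    mean_a = tt$mean_a, mean_b = tt$mean_b,
    t = tt$t, df = tt$df, p = p,
    direction = ifelse(tt$mean_a >= tt$mean_b, "A>B", "B>A"),
    defined = !is.na(tt$t), stringsAsFactors = FALSE)
  attr(out, "n_significant") <- sum(out$p[out$defined] < alpha)
  attr(out, "alpha") <- alpha
  class(out) <- c("edge_test", class(out))
  out
}

#' Top differing edges
#'
#' The `k` edges with the smallest p-values, the report shape used for
#' edge-level results: both node names, group means and p. Ties in p are
#' broken by lexicographic node pair. If fewer than `k` edges have a
#' defined statistic, all of them are returned with a warning.
#'
#' @param comparisons an [edge_group_test()] result.
#' @param k number of edges to report.
#' @return data.frame of the `k` top-ranked edges.
#' @export
top_edges <- function(comparisons, k = 10L) {
  valid <- comparisons[comparisons$defined & is.finite(comparisons$p), ]
  if (nrow(valid) < k) {
    warning(sprintf("only %d edges with defined statistics (requested %d)",
                    nrow(valid), k))
    k <- nrow(valid)
  }
  o <- order(valid$p, valid$node_i, valid$node_j)
  out <- valid[o[seq_len(k)], ]
  rownames(out) <- NULL
  out
}
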
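# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically fork a root seed into per-stage / per-subject seeds,
# keeping results within 32-bit integer range.
fork_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  # FNV-1a style string hash folded to a positive 31-bit integer
  h <- 2166136261 %% 2147483647
  for (ch in utf8ToInt(key)) {
    h <- bitwXor(h, ch)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483562L + 1L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Fisher z-transform with a cap on |r|
#'
#' `atanh(1)` is infinite; correlations of duplicated series hit r = 1 on
#' degenerate or synthetic data. Values of |r| above `1 - 1e-7` are capped
#' before the transform so every z value is finite.
#'
#' @param r numeric vector or matrix of correlations in \[-1, 1\].
#' @param cap largest absolute correlation passed to `atanh()`.
#' @return transformed values, same shape as `r`.
#' @export
fisher_z <- function(r, cap = 1 - 1e-7) {
  r <- pmax(pmin(r, cap), -cap)
  atanh(r)
}

#' Normalized mutual information between two partitions
#'
#' Used to score recovery of planted community structure. Returns 1 for
#' identical partitions (up to label permutation) and 0 for independent ones.
#' The normalization is by the arithmetic mean of the two entropies; if both
#' partitions are single-cluster the NMI is defined as 1.
#'
#' @param a,b integer/character membership vectors of equal length.
#' @return NMI in \[0, 1\].
#' @export
partition_nmi <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions have different lengths")
  n <- length(a)
  tab <- table(a, b)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi / ((ha + hb) / 2)
}

# population standard deviation (divide by n, not n - 1)
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# standardize columns of a frames x voxels matrix to mean 0, sd 1
# (sample sd), so crossprod(x)/ (nrow - 1) is the Pearson matrix
standardize_cols <- function(x) {
  x <- sweep(x, 2L, colMeans(x), "-")
  s <- sqrt(colSums(x^2) / (nrow(x) - 1L))
  if (any(s == 0)) return(structure(x, zero_var = which(s == 0)))
  sweep(x, 2L, s, "/")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
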
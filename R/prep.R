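# Temporal preprocessing of voxel time series: nuisance regression followed
# by zero-phase temporal bandpass filtering (0.01-0.08 Hz).

#' Build a nuisance regressor set
#'
#' Columns are centred to zero mean. Typical content: the six motion
#' parameters plus white-matter and ventricle mean signals.
#'
#' @param ... named numeric vectors or matrices (frames in rows), or a
#'   single data.frame/matrix.
#' @return object of class `nuisance_set` (a numeric matrix).
#' @export
nuisance_set <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && (is.matrix(parts[[1L]]) || is.data.frame(parts[[1L]])))
    x <- as.matrix(parts[[1L]])
  else x <- do.call(cbind, parts)
  x <- as.matrix(x)
  if (ncol(x) < 1L) stopf("nuisance set needs at least one column")
  if (is.null(colnames(x))) colnames(x) <- paste0("reg", seq_len(ncol(x)))
  x <- sweep(x, 2L, colMeans(x), "-")
  structure(x, class = c("nuisance_set", class(matrix())))
}

#' Nuisance regression of voxel time series
#'
#' Per-voxel ordinary least squares of the series on an intercept plus the
#' nuisance regressors; the residual series replaces the data. Residual
#' voxel means are ~0 by construction. With an empty/`NULL` nuisance set
#' the result is the demeaned input.
#'
#' @param dataset a [bold_dataset()] (or a frames x voxels matrix).
#' @param nuisance a [nuisance_set()] or `NULL` (intercept only).
#' @return object of the same type as `dataset`, holding residuals.
#' @export
nuisance_regression <- function(dataset, nuisance = NULL) {
  is_ds <- inherits(dataset, "bold_dataset")
  y <- if (is_ds) bold_matrix(dataset) else as.matrix(dataset)
  nt <- nrow(y)
  design <- cbind(intercept = rep(1, nt))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nt)
      stopf("nuisance rows (%d) do not match frames (%d)", nrow(nuisance), nt)
    design <- cbind(design, nuisance)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stopf("nuisance design is rank deficient; collinear columns: %s",
          paste(dropped, collapse = ", "))
  }
  res <- y - design %*% qr.coef(qrd, y)
  if (is_ds) bold_from_matrix(dataset, res) else res
}

# cache of zero-phase bandpass filter matrices keyed by
# (n_frames, tr, low, high, order)
.filter_cache <- new.env(parent = emptyenv())

bandpass_matrix <- function(n_frames, tr_seconds, low_hz, high_hz, order) {
  key <- paste(n_frames, tr_seconds, low_hz, high_hz, order, sep = "_")
  got <- get0(key, envir = .filter_cache)
  if (!is.null(got)) return(got)
  fs <- 1 / tr_seconds
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  # forward-backward filtering is linear in the input, so the whole
  # operation is one n x n matrix: filter the identity basis once
  f <- apply(diag(n_frames), 2L, function(e) signal::filtfilt(bf, e))
  assign(key, f, envir = .filter_cache)
  f
}

#' Temporal bandpass filter
#'
#' Zero-phase (forward-backward) Butterworth bandpass, default passband
#' 0.01-0.08 Hz, order 2 per pass. Zero-phase filtering preserves the
#' zero-lag correlation structure the connectivity analysis relies on.
#' Each series is demeaned before filtering (the passband excludes DC, and
#' removing the offset first avoids start-up transients on the mean level),
#' so a constant series maps exactly to zero.
#'
#' @param dataset a [bold_dataset()] (or a frames x voxels matrix; then
#'   `tr_seconds` must be supplied).
#' @param low_hz,high_hz passband edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1 / (2 * tr_seconds)`.
#' @param order Butterworth order per pass.
#' @param tr_seconds repetition time, required for matrix input.
#' @return filtered object of the same type as `dataset`.
#' @export
bandpass_filter <- function(dataset, low_hz = 0.01, high_hz = 0.08,
                            order = 2L, tr_seconds = NULL) {
  is_ds <- inherits(dataset, "bold_dataset")
  if (is_ds) tr_seconds <- dataset$tr_seconds
  if (is.null(tr_seconds)) stopf("tr_seconds is required for matrix input")
  nyq <- 1 / (2 * tr_seconds)
  if (high_hz >= nyq)
    stopf("high_hz (%g) must be below the Nyquist frequency (%g Hz)", high_hz, nyq)
  if (low_hz <= 0 || low_hz >= high_hz)
    stopf("need 0 < low_hz < high_hz")
  y <- if (is_ds) bold_matrix(dataset) else as.matrix(dataset)
  y <- sweep(y, 2L, colMeans(y), "-")
  f <- bandpass_matrix(nrow(y), tr_seconds, low_hz, high_hz, order)
  out <- f %*% y
  if (is_ds) bold_from_matrix(dataset, out) else out
}

#' Standard preprocessing of one subject
#'
#' Nuisance regression first, then bandpass filtering, in that order.
#'
#' @inheritParams nuisance_regression
#' @inheritParams bandpass_filter
#' @return preprocessed [bold_dataset()].
#' @export
preprocess_dataset <- function(dataset, nuisance = NULL,
                               low_hz = 0.01, high_hz = 0.08, order = 2L) {
  bandpass_filter(nuisance_regression(dataset, nuisance),
                  low_hz = low_hz, high_hz = high_hz, order = order)
}
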
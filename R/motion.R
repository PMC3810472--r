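# Head-motion quality control: framewise displacement (Power convention),
# four per-subject motion summaries, exclusion rules, and an audit that
# checks connectivity results for motion confounds.

#' Construct a motion trace
#'
#' Six rigid-body realignment parameters per frame, relative to the first
#' frame: columns `tx, ty, tz` (mm) and `rx, ry, rz` (degrees).
#'
#' @param params numeric matrix, frames x 6. The first row must be all
#'   zeros (the reference frame).
#' @return object of class `motion_trace` (a matrix).
#' @export
motion_trace <- function(params) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stopf("a motion trace has 6 columns, got %d", ncol(params))
  if (nrow(params) < 2L) stopf("a motion trace needs at least 2 frames")
  if (any(abs(params[1L, ]) > 1e-12))
    stopf("first frame must be all zeros (reference frame)")
  colnames(params) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  structure(params, class = c("motion_trace", class(matrix())))
}

#' @export
print.motion_trace <- function(x, ...) {
  cat("motion_trace:", nrow(x), "frames; max |translation|",
      sprintf("%.3f mm;", max(abs(x[, 1:3]))), "max |rotation|",
      sprintf("%.3f deg\n", max(abs(x[, 4:6]))))
  invisible(x)
}

#' Read a six-column motion parameter file
#'
#' Whitespace-delimited text, one row per frame. The `"standard"` dialect
#' is translations (mm) then rotations (degrees); the `"spm"` dialect has
#' rotations in radians (SPM's `rp_*.txt`), which are converted to degrees.
#'
#' @param path file path.
#' @param dialect `"standard"` or `"spm"`.
#' @return a [motion_trace()].
#' @export
read_motion_file <- function(path, dialect = c("standard", "spm")) {
  dialect <- match.arg(dialect)
  p <- as.matrix(utils::read.table(path, header = FALSE))
  if (dialect == "spm") p[, 4:6] <- p[, 4:6] * 180 / pi
  p <- sweep(p, 2L, p[1L, ], "-")  # re-reference to the first frame
  motion_trace(p)
}

# convert the rotation columns to mm of arc on a sphere of given radius
radius_convert <- function(params, sphere_radius) {
  params[, 4:6] <- params[, 4:6] * pi / 180 * sphere_radius
  params
}

#' Framewise displacement
#'
#' Power's instantaneous-motion index: for frame i > 1,
#' `FD(i) = sum_j |d_j(i) - d_j(i-1)|` over the six parameters, with each
#' rotation difference converted from degrees to the arc length it evokes
#' on the surface of a sphere of radius `sphere_radius` (default 50 mm,
#' approximately the mean cortex-to-head-centre distance).
#'
#' @param trace a [motion_trace()].
#' @param sphere_radius rotation conversion radius in mm.
#' @return numeric vector of length `n_frames - 1`, in mm.
#' @export
framewise_displacement <- function(trace, sphere_radius = 50) {
  if (nrow(trace) < 2L) stopf("framewise displacement needs >= 2 frames")
  d <- radius_convert(unclass(trace), sphere_radius)
  rowSums(abs(diff(d)))
}

#' Per-subject motion summaries
#'
#' Computes the four head-motion summaries used for reporting and the
#' confound audit: maximum head displacement `d_max` (largest |parameter|
#' across frames, rotations radius-converted to mm), root-mean-square
#' motion `d_rms`, and the maximum and RMS of the framewise displacement
#' series.
#'
#' `d_rms` variants: `"pooled"` (default) is
#' `sqrt(mean_i sum_j d_j(i)^2)` over all frames and radius-converted
#' parameters; `"per_frame_euclidean"` takes the RMS of the per-frame
#' Euclidean norms of the translation part only plus the rotation arcs,
#' i.e. the same quantity — both are monotone summaries of overall
#' displacement; the pooled form is the documented default.
#'
#' @param trace a [motion_trace()].
#' @param sphere_radius rotation conversion radius in mm.
#' @param rms_variant `"pooled"` or `"per_frame_euclidean"`.
#' @return object of class `motion_summary`: list with `d_max`, `d_rms`,
#'   `fd_max`, `fd_rms` (all mm) and the per-frame `fd_series`.
#' @export
motion_summaries <- function(trace, sphere_radius = 50,
                             rms_variant = c("pooled", "per_frame_euclidean")) {
  rms_variant <- match.arg(rms_variant)
  d <- radius_convert(unclass(trace), sphere_radius)
  fd <- framewise_displacement(trace, sphere_radius)
  d_rms <- switch(rms_variant,
    pooled = sqrt(mean(rowSums(d^2))),
    per_frame_euclidean = sqrt(mean(sqrt(rowSums(d^2))^2)))
  structure(list(d_max = max(abs(d)), d_rms = d_rms,
                 fd_max = max(fd), fd_rms = sqrt(mean(fd^2)),
                 fd_series = fd, sphere_radius = sphere_radius),
            class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf("motion summary: d_max %.3f mm, d_rms %.3f mm, fd_max %.3f mm, fd_rms %.3f mm\n",
              x$d_max, x$d_rms, x$fd_max, x$fd_rms))
  invisible(x)
}

#' Subject exclusion rule for head motion
#'
#' Defaults are the study cutoffs: any per-parameter translation range
#' (minimum to maximum) above 3.0 mm, any rotation range above 3.0 degrees,
#' or a maximum framewise displacement above 2.5 mm excludes the subject.
#'
#' @param max_translation mm, per-parameter min-to-max range cutoff.
#' @param max_rotation degrees, per-parameter min-to-max range cutoff.
#' @param max_fd mm, cutoff on the maximum framewise displacement.
#' @param sphere_radius mm, rotation conversion radius for FD.
#' @return object of class `exclusion_rule`.
#' @export
exclusion_rule <- function(max_translation = 3.0, max_rotation = 3.0,
                           max_fd = 2.5, sphere_radius = 50) {
  if (any(c(max_translation, max_rotation, max_fd, sphere_radius) <= 0))
    stopf("all exclusion cutoffs must be strictly positive")
  structure(list(max_translation = max_translation,
                 max_rotation = max_rotation, max_fd = max_fd,
                 sphere_radius = sphere_radius), class = "exclusion_rule")
}

#' Apply the motion exclusion rule to a subject
#'
#' A subject is excluded iff any translation parameter's min-to-max range
#' exceeds `max_translation`, any rotation parameter's range exceeds
#' `max_rotation`, or the maximum framewise displacement exceeds `max_fd`.
#' Every violated criterion is reported.
#'
#' @param trace a [motion_trace()].
#' @param rule an [exclusion_rule()].
#' @param summary optional precomputed [motion_summaries()] (must have been
#'   computed with `rule$sphere_radius`).
#' @return list with `include` (logical) and `reasons` (character vector,
#'   empty when included).
#' @export
apply_exclusion <- function(trace, rule = exclusion_rule(), summary = NULL) {
  if (is.null(summary))
    summary <- motion_summaries(trace, rule$sphere_radius)
  p <- unclass(trace)
  t_range <- apply(p[, 1:3, drop = FALSE], 2L, function(v) diff(range(v)))
  r_range <- apply(p[, 4:6, drop = FALSE], 2L, function(v) diff(range(v)))
  reasons <- character()
  if (any(t_range > rule$max_translation))
    reasons <- c(reasons, sprintf(
      "translation: %s range %.2f mm > %.2f mm",
      names(which(t_range > rule$max_translation))[1L],
      max(t_range), rule$max_translation))
  if (any(r_range > rule$max_rotation))
    reasons <- c(reasons, sprintf(
      "rotation: %s range %.2f deg > %.2f deg",
      names(which(r_range > rule$max_rotation))[1L],
      max(r_range), rule$max_rotation))
  if (summary$fd_max > rule$max_fd)
    reasons <- c(reasons, sprintf(
      "framewise displacement: fd_max %.2f mm > %.2f mm",
      summary$fd_max, rule$max_fd))
  list(include = length(reasons) == 0L, reasons = reasons)
}

#' Motion confound audit of edge-level connectivity
#'
#' Correlates each of the four head-motion summaries with the connectivity
#' strength of candidate edges across subjects and counts significant
#' correlations, next to the count expected under the null
#' (`alpha * n_tests`). A result compatible with the null count is
#' evidence that group differences in connectivity are not motion-driven.
#'
#' @param edge_values numeric matrix, subjects x edges (Fisher-z values);
#'   column names identify edges.
#' @param summaries list of [motion_summaries()] (or a data.frame with
#'   columns d_max, d_rms, fd_max, fd_rms), aligned with the rows of
#'   `edge_values`.
#' @param alpha per-test significance level.
#' @return object of class `motion_audit`: list with the correlation and
#'   p-value matrices (parameter x edge), `n_significant`,
#'   `n_expected_null`, `n_tests`, and indices of excluded zero-variance
#'   pairs.
#' @export
motion_confound_audit <- function(edge_values, summaries, alpha = 0.01) {
  edge_values <- as.matrix(edge_values)
  n <- nrow(edge_values)
  if (n < 4L) stopf("motion audit needs at least 4 subjects")
  if (is.data.frame(summaries)) {
    sm <- as.matrix(summaries[, c("d_max", "d_rms", "fd_max", "fd_rms")])
  } else {
    sm <- t(vapply(summaries, function(s)
      c(d_max = s$d_max, d_rms = s$d_rms, fd_max = s$fd_max,
        fd_rms = s$fd_rms), numeric(4)))
  }
  if (nrow(sm) != n) stopf("summaries and edge_values are misaligned")
  params <- colnames(sm)
  r <- matrix(NA_real_, 4L, ncol(edge_values),
              dimnames = list(params, colnames(edge_values)))
  pv <- r
  edge_sd <- apply(edge_values, 2L, stats::sd)
  par_sd <- apply(sm, 2L, stats::sd)
  for (j in seq_len(ncol(edge_values))) {
    if (edge_sd[j] == 0) next
    for (k in seq_len(4L)) {
      if (par_sd[k] == 0) next
      ct <- stats::cor.test(sm[, k], edge_values[, j])
      r[k, j] <- ct$estimate
      pv[k, j] <- ct$p.value
    }
  }
  defined <- !is.na(pv)
  structure(list(correlation = r, p = pv,
                 n_significant = sum(pv[defined] < alpha),
                 n_tests = sum(defined),
                 n_expected_null = alpha * sum(defined),
                 alpha = alpha,
                 excluded = which(!defined, arr.ind = TRUE)),
            class = "motion_audit")
}

#' @export
print.motion_audit <- function(x, ...) {
  cat(sprintf(
    "motion audit: %d of %d parameter-edge correlations significant at alpha = %g (%.1f expected under the null)\n",
    x$n_significant, x$n_tests, x$alpha, x$n_expected_null))
  invisible(x)
}
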
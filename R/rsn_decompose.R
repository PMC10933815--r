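#' Decompose a cohort's network amplitudes into synchrony and BOLD amplitude
#'
#' The central estimator of the package. For every subject it extracts the
#' stage-1 dual-regression network timeseries and computes the three
#' per-network measures:
#' \itemize{
#'   \item network amplitude \eqn{a_k = \mathrm{sd}(d_k)}, with
#'     \eqn{D = (G^TG)^{-1}G^TX};
#'   \item temporal synchrony \eqn{\hat a_k = \mathrm{sd}(\hat d_k)}, the same
#'     statistic after z-scoring every voxel's timeseries, so it reflects only
#'     phase alignment among within-network voxels;
#'   \item BOLD amplitude \eqn{\dot a_k}, a summary of per-voxel fluctuation
#'     SDs over the strongly weighted (|Z| > z) voxels.
#' }
#'
#' @param runs a list of N x T matrices, or a single N x T matrix (one
#'   subject).
#' @param maps N x K matrix of signed group map weights.
#' @param z_threshold mask threshold for the BOLD amplitude (default 3.29,
#'   two-sided p = 1e-3).
#' @param bold_method BOLD amplitude variant, see \code{\link{bold_amplitude}}.
#' @param keep_timeseries keep the raw stage-1 timeseries (needed by the
#'   netmats stage).
#' @param subject_ids optional character vector of subject identifiers.
#' @return an object of class \code{"rsn_decomp"}: list with S x K matrices
#'   \code{amplitude}, \code{synchrony}, \code{bold}, the call metadata, and
#'   (optionally) \code{timeseries}, a list of K x T matrices.
#' @seealso \code{\link{triplet_correlations}}, \code{\link{cohort_netmats}},
#'   \code{\link{amplitude_covariation}}
#' @export
rsn_decompose <- function(runs, maps,
                          z_threshold = 3.29,
                          bold_method = c("binary_mean", "weighted_sum", "root_sum_var"),
                          keep_timeseries = TRUE,
                          subject_ids = NULL) {
  bold_method <- match.arg(bold_method)
  if (is.matrix(runs)) runs <- list(runs)
  if (!is.list(runs) || !length(runs)) stop("'runs' must be a non-empty list of matrices")
  maps <- as_matrix_numeric(maps, "maps")
  K <- ncol(maps); S <- length(runs)
  ids <- subject_ids %||% sprintf("subj%03d", seq_len(S))
  labs <- colnames(maps) %||% sprintf("net%02d", seq_len(K))

  amp <- syn <- bold <- matrix(NA_real_, S, K, dimnames = list(ids, labs))
  ts_list <- if (keep_timeseries) vector("list", S) else NULL
  for (s in seq_len(S)) {
    D <- spatial_regress(runs[[s]], maps)
    amp[s, ] <- network_amplitude(D)
    syn[s, ] <- temporal_synchrony(runs[[s]], maps)
    bold[s, ] <- bold_amplitude(runs[[s]], maps, method = bold_method, z = z_threshold)
    if (keep_timeseries) ts_list[[s]] <- D
  }
  structure(list(amplitude = amp, synchrony = syn, bold = bold,
                 timeseries = ts_list,
                 z_threshold = z_threshold, bold_method = bold_method,
                 n_voxels = nrow(maps), n_networks = K,
                 n_timepoints = ncol(runs[[1L]]), n_subjects = S,
                 network_labels = labs, subject_ids = ids,
                 call = match.call()),
            class = "rsn_decomp")
}

#' @export
print.rsn_decomp <- function(x, ...) {
  cat("Resting-state network amplitude decomposition\n")
  cat(sprintf("  %d subjects, %d networks, %d voxels, %d timepoints\n",
              x$n_subjects, x$n_networks, x$n_voxels, x$n_timepoints))
  cat(sprintf("  BOLD amplitude: %s at |Z| > %g\n", x$bold_method, x$z_threshold))
  cat("  measures: amplitude, synchrony, bold (use coef() to extract)\n")
  invisible(x)
}

#' Extract a measure table from a decomposition
#'
#' @param object an \code{rsn_decomp} object.
#' @param measure which S x K measure matrix to return.
#' @param ... unused.
#' @export
coef.rsn_decomp <- function(object, measure = c("amplitude", "synchrony", "bold"), ...) {
  object[[match.arg(measure)]]
}

#' Summarize an amplitude decomposition
#'
#' Per-network means and SDs of the three measures, plus the across-subject
#' correlations of network amplitude with temporal synchrony and with BOLD
#' amplitude (the headline contrast of the decomposition).
#'
#' @param object an \code{rsn_decomp} object.
#' @param ... unused.
#' @export
summary.rsn_decomp <- function(object, ...) {
  trip <- triplet_correlations(object)
  out <- list(
    means = rbind(amplitude = colMeans(object$amplitude),
                  synchrony = colMeans(object$synchrony),
                  bold = colMeans(object$bold)),
    triplet = trip,
    n_subjects = object$n_subjects)
  class(out) <- "summary.rsn_decomp"
  out
}

#' @export
print.summary.rsn_decomp <- function(x, ...) {
  cat("Per-network measure means:\n")
  print(round(x$means, 4))
  cat(sprintf("\nAcross-subject correlations with network amplitude (n = %d):\n", x$n_subjects))
  tab <- x$triplet$full
  cat(sprintf("  amplitude ~ synchrony: mean r = %.3f (range %.3f..%.3f)\n",
              mean(tab[, "r_amp_syn"]), min(tab[, "r_amp_syn"]), max(tab[, "r_amp_syn"])))
  cat(sprintf("  amplitude ~ BOLD amp : mean r = %.3f (range %.3f..%.3f)\n",
              mean(tab[, "r_amp_bold"]), min(tab[, "r_amp_bold"]), max(tab[, "r_amp_bold"])))
  invisible(x)
}

#' Scatter of network amplitude against synchrony and BOLD amplitude
#'
#' @param x an \code{rsn_decomp} object.
#' @param networks which networks to pool (default all).
#' @param ... passed to \code{plot}.
#' @export
plot.rsn_decomp <- function(x, networks = seq_len(x$n_networks), ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  a <- x$amplitude[, networks, drop = FALSE]
  s <- x$synchrony[, networks, drop = FALSE]
  b <- x$bold[, networks, drop = FALSE]
  graphics::plot(as.numeric(s), as.numeric(a), xlab = "temporal synchrony",
                 ylab = "network amplitude", main = "amplitude ~ synchrony", ...)
  graphics::plot(as.numeric(b), as.numeric(a), xlab = "BOLD amplitude",
                 ylab = "network amplitude", main = "amplitude ~ BOLD amplitude", ...)
  invisible(x)
}
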
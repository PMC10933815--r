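#' Dual-regression stage 1: spatial regression of a run onto group maps
#'
#' Computes the exact least-squares solution \eqn{D = (G^T G)^{-1} G^T X},
#' regressing every timepoint's voxel vector onto the K group spatial maps to
#' obtain one timeseries per network. Solved through a QR factorization of G
#' rather than an explicit inverse.
#'
#' @param run N x T matrix of voxel timeseries (one subject's BOLD run).
#' @param maps N x K matrix of signed group map weights.
#' @param keep_residual_variance if TRUE, attach per-voxel residual variances
#'   as attribute \code{"residual_variance"}.
#' @return K x T matrix of network timeseries (rows named after the map
#'   columns when present).
#' @export
spatial_regress <- function(run, maps, keep_residual_variance = FALSE) {
  run <- as_matrix_numeric(run, "run")
  maps <- as_matrix_numeric(maps, "maps")
  if (nrow(run) != nrow(maps)) stop("run and maps must have the same number of voxels")
  if (ncol(run) <= ncol(maps)) stop("need T > K timepoints")
  if (any(colSums(abs(maps)) == 0)) stop("maps contain an all-zero column")
  kap <- kappa(crossprod(maps), exact = FALSE)
  if (!is.finite(kap) || kap > 1e12)
    stop(sprintf("G'G is (near-)singular: condition number %.3g", kap))
  qrG <- qr(maps)
  D <- qr.coef(qrG, run)
  rownames(D) <- colnames(maps)
  if (keep_residual_variance) {
    E <- run - maps %*% D
    attr(D, "residual_variance") <- apply(E, 1L, stats::var)
  }
  D
}

#' Network amplitude: per-network SD of the stage-1 timeseries
#'
#' @param ts K x T matrix of network timeseries (from
#'   \code{\link{spatial_regress}} on the raw run).
#' @return named non-negative vector of length K (sample SD, denominator
#'   T - 1).
#' @export
network_amplitude <- function(ts) {
  ts <- as_matrix_numeric(ts, "ts")
  out <- apply(ts, 1L, stats::sd)
  names(out) <- rownames(ts)
  out
}

#' Temporally normalize a BOLD run
#'
#' Z-scores every voxel's timeseries: \eqn{\hat x_i = (x_i - \mu_i)/\sigma_i},
#' so that every voxel carries unit fluctuation amplitude. Errors on
#' zero-variance voxels (no silent dropping).
#'
#' @param run N x T matrix.
#' @return N x T matrix with every row mean 0 and sample SD 1.
#' @export
temporal_normalize <- function(run) {
  run <- as_matrix_numeric(run, "run")
  if (ncol(run) < 2L) stop("need at least 2 timepoints")
  row_standardize(run, what = "voxel timeseries")
}

#' Temporal synchrony: network amplitude of the normalized run
#'
#' The SD of the stage-1 timeseries computed from the temporally normalized
#' data \eqn{\hat D = (G^T G)^{-1} G^T \hat X}; large when the voxels
#' weighted strongly in a map fluctuate in phase, and invariant to per-voxel
#' positive affine rescaling of the input.
#'
#' @inheritParams spatial_regress
#' @return named non-negative vector of length K.
#' @export
temporal_synchrony <- function(run, maps) {
  network_amplitude(spatial_regress(temporal_normalize(run), maps))
}

#' Binary network masks from thresholded group maps
#'
#' \code{m_k(i) = 1} iff \code{|g_k(i)| > z} (strict inequality).
#'
#' @param maps N x K weight matrix.
#' @param z positive Z threshold (default 3.29, i.e. two-sided p = 1e-3).
#' @return N x K binary (0/1) matrix; errors if any mask selects fewer than 2
#'   voxels, since a one-voxel network timeseries has no synchrony content.
#' @export
threshold_mask <- function(maps, z = 3.29) {
  maps <- as_matrix_numeric(maps, "maps")
  if (!is.numeric(z) || length(z) != 1L || z < 0) stop("z must be a non-negative scalar")
  M <- (abs(maps) > z) * 1L
  n_sel <- colSums(M)
  if (any(n_sel < 2L)) {
    bad <- which(n_sel < 2L)
    stop(sprintf("mask at |Z| > %g selects < 2 voxels for network(s): %s",
                 z, paste(colnames(maps)[bad] %||% bad, collapse = ", ")))
  }
  dimnames(M) <- dimnames(maps)
  M
}

#' Two-sided normal quantile from a tail probability
#'
#' Returns z with \eqn{P(|Z| > z) = p} under the standard normal, e.g.
#' z = 3.29 for p = 1e-3.
#'
#' @param p two-sided tail probability in (0, 1).
#' @return positive real.
#' @export
z_from_two_sided_p <- function(p) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1)) stop("p must lie in (0, 1)")
  stats::qnorm(p / 2, lower.tail = FALSE)
}

#' BOLD amplitude: per-network summary of voxelwise fluctuation amplitudes
#'
#' Summarizes the vector v of per-voxel timeseries standard deviations over
#' the voxels weighted strongly in each map:
#' \itemize{
#'   \item \code{binary_mean}: mean of v over the |Z| > z mask
#'     (\eqn{\dot a_k = m_k^T v / \sum_i m_k(i)});
#'   \item \code{weighted_sum}: \eqn{g_k^T v / N} (signed weights, may be
#'     negative);
#'   \item \code{root_sum_var}: \eqn{\sqrt{(g_k \circ g_k)^T (v \circ v)}}.
#' }
#' All variants are homogeneous of degree 1 in the data.
#'
#' @inheritParams spatial_regress
#' @param method one of \code{"binary_mean"}, \code{"weighted_sum"},
#'   \code{"root_sum_var"}.
#' @param z mask threshold used by \code{binary_mean}.
#' @return named vector of length K.
#' @export
bold_amplitude <- function(run, maps, method = c("binary_mean", "weighted_sum", "root_sum_var"),
                           z = 3.29) {
  method <- match.arg(method)
  run <- as_matrix_numeric(run, "run")
  maps <- as_matrix_numeric(maps, "maps")
  if (nrow(run) != nrow(maps)) stop("run and maps must have the same number of voxels")
  v <- apply(run, 1L, stats::sd)
  out <- switch(method,
    binary_mean = {
      M <- threshold_mask(maps, z)
      as.numeric(crossprod(M, v)) / colSums(M)
    },
    weighted_sum = as.numeric(crossprod(maps, v)) / nrow(maps),
    root_sum_var = sqrt(as.numeric(crossprod(maps^2, v^2)))
  )
  names(out) <- colnames(maps)
  out
}

#' Consistency of amplitude and synchrony under equal voxel SDs
#'
#' For a run whose rows are zero-mean with a common SD sigma, the network
#' amplitude equals sigma times the temporal synchrony. Verifies this
#' identity and reports the deviation.
#'
#' @inheritParams spatial_regress
#' @param tol relative tolerance for both the precondition and the identity.
#' @return list with \code{sigma}, \code{max_rel_dev}, \code{ok}.
#' @export
sigma_identity_check <- function(run, maps, tol = 1e-8) {
  run <- as_matrix_numeric(run, "run")
  sds <- apply(run, 1L, stats::sd)
  mus <- rowMeans(run)
  sigma <- mean(sds)
  if (max(abs(sds - sigma)) > tol * sigma || max(abs(mus)) > tol * sigma)
    stop("precondition violated: rows must be zero-mean with a common SD")
  a <- network_amplitude(spatial_regress(run, maps))
  ahat <- temporal_synchrony(run, maps)
  dev <- max(abs(a - sigma * ahat) / pmax(abs(a), .Machine$double.eps))
  list(sigma = sigma, max_rel_dev = dev, ok = dev <= tol)
}

#' Map-threshold sweep of synchrony computation
#'
#' For each threshold z, restricts each network's map column and the
#' normalized data to the voxels with |g_k| > z and recomputes the stage-1
#' timeseries per network independently (single-column restricted
#' regression). Reports, per threshold: (1) the mean per-subject temporal
#' correlation between the full and thresholded network timeseries; (2) the
#' per-network across-subject correlation between full and thresholded
#' synchrony; (3) the per-network across-subject correlation between the full
#' network amplitude and the thresholded synchrony.
#'
#' @param runs list of N x T runs (one per subject).
#' @param maps N x K weight matrix.
#' @param z_list ascending numeric vector of thresholds.
#' @return object of class \code{"rsn_sweep"}: list with per-threshold
#'   entries each holding \code{timeseries_r} (mean over subjects and
#'   networks), \code{synchrony_r} and \code{amplitude_synchrony_r}
#'   (length-K vectors).
#' @export
sweep_thresholds <- function(runs, maps, z_list = c(3.29, 4.42, 5.33)) {
  maps <- as_matrix_numeric(maps, "maps")
  if (is.unsorted(z_list)) stop("z_list must be ascending")
  K <- ncol(maps); S <- length(runs)
  norm_runs <- lapply(runs, temporal_normalize)
  D_full <- lapply(norm_runs, spatial_regress, maps = maps)
  a_full <- t(vapply(lapply(runs, spatial_regress, maps = maps),
                     network_amplitude, numeric(K)))
  ahat_full <- t(vapply(D_full, network_amplitude, numeric(K)))

  out <- lapply(z_list, function(z) {
    M <- threshold_mask(maps, z)
    ts_r <- matrix(NA_real_, S, K)
    ahat_z <- matrix(NA_real_, S, K)
    for (s in seq_len(S)) {
      for (k in seq_len(K)) {
        sel <- M[, k] == 1L
        g <- maps[sel, k, drop = FALSE]
        if (sum(g^2) == 0) stop(sprintf("singular restricted design for network %d", k))
        d <- as.numeric(crossprod(g, norm_runs[[s]][sel, , drop = FALSE])) / sum(g^2)
        ts_r[s, k] <- stats::cor(d, D_full[[s]][k, ])
        ahat_z[s, k] <- stats::sd(d)
      }
    }
    list(z = z,
         timeseries_r = mean(ts_r),
         synchrony_r = vapply(seq_len(K), function(k) stats::cor(ahat_full[, k], ahat_z[, k]), 0),
         amplitude_synchrony_r = vapply(seq_len(K), function(k) stats::cor(a_full[, k], ahat_z[, k]), 0))
  })
  names(out) <- sprintf("z=%g", z_list)
  structure(list(thresholds = z_list, results = out), class = "rsn_sweep")
}

#' @export
print.rsn_sweep <- function(x, ...) {
  cat("Map-threshold sweep over z =", paste(x$thresholds, collapse = ", "), "\n")
  for (r in x$results) {
    cat(sprintf("  z > %-5g  mean ts r = %.3f  mean synchrony r = %.3f  mean amp~synchrony r = %.3f\n",
                r$z, r$timeseries_r, mean(r$synchrony_r), mean(r$amplitude_synchrony_r)))
  }
  invisible(x)
}
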
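#' Partial-correlation network matrix
#'
#' Between-network functional connectivity as partial correlations: with P
#' the (optionally ridge-regularized) inverse covariance of the K network
#' timeseries, \eqn{C_{ij} = -P_{ij}/\sqrt{P_{ii}P_{jj}}}, diagonal set to 1.
#'
#' @param ts K x T matrix of network timeseries.
#' @param ridge non-negative ridge added to the covariance diagonal, as a
#'   fraction of the mean variance (default 0; with T well above K no
#'   regularization is needed).
#' @param method \code{"partial"} (default) or \code{"full"} for a plain
#'   Pearson correlation netmat.
#' @return K x K symmetric matrix with unit diagonal.
#' @export
partial_correlation <- function(ts, ridge = 0, method = c("partial", "full")) {
  method <- match.arg(method)
  ts <- as_matrix_numeric(ts, "ts")
  K <- nrow(ts)
  if (ncol(ts) <= K) stop("need T > K timepoints")
  if (method == "full") {
    C <- stats::cor(t(ts))
  } else {
    S <- stats::cov(t(ts))
    if (ridge > 0) S <- S + diag(ridge * mean(diag(S)), K)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop("covariance is not positive definite; supply a positive 'ridge'")
    P <- chol2inv(ch)
    C <- -P / sqrt(diag(P) %o% diag(P))
    diag(C) <- 1
    C <- (C + t(C)) / 2
  }
  if (!is.null(rownames(ts))) dimnames(C) <- list(rownames(ts), rownames(ts))
  C
}

#' Per-network summary connectivity strengths
#'
#' For each network k, over the off-diagonal entries of row k of the netmat:
#' the mean absolute value, the mean of the positive entries, and the mean of
#' the negative entries (NA when a sign class is empty).
#'
#' @param nm K x K netmat from \code{\link{partial_correlation}}.
#' @return list with length-K vectors \code{absolute}, \code{positive},
#'   \code{negative}.
#' @export
summary_fc <- function(nm) {
  nm <- as_matrix_numeric(nm, "nm")
  K <- nrow(nm)
  if (K < 2L) stop("summary FC undefined for K = 1 (no off-diagonal entries)")
  absolute <- positive <- negative <- numeric(K)
  for (k in seq_len(K)) {
    ck <- nm[k, -k]
    absolute[k] <- mean(abs(ck))
    positive[k] <- if (any(ck > 0)) mean(ck[ck > 0]) else NA_real_
    negative[k] <- if (any(ck < 0)) mean(ck[ck < 0]) else NA_real_
  }
  nms <- rownames(nm)
  list(absolute = stats::setNames(absolute, nms),
       positive = stats::setNames(positive, nms),
       negative = stats::setNames(negative, nms))
}

#' Netmats and FC summaries for a whole cohort
#'
#' @param decomp an \code{\link{rsn_decompose}} fit with retained timeseries,
#'   or a list of K x T timeseries matrices.
#' @inheritParams partial_correlation
#' @return list with \code{netmats} (list of K x K matrices) and
#'   \code{absolute}, \code{positive}, \code{negative} (S x K matrices).
#' @export
cohort_netmats <- function(decomp, ridge = 0, method = c("partial", "full")) {
  method <- match.arg(method)
  ts_list <- if (inherits(decomp, "rsn_decomp")) {
    if (is.null(decomp$timeseries))
      stop("decomposition was fitted with keep_timeseries = FALSE")
    decomp$timeseries
  } else decomp
  nms <- lapply(ts_list, partial_correlation, ridge = ridge, method = method)
  sfc <- lapply(nms, summary_fc)
  pack <- function(type) t(vapply(sfc, `[[`, numeric(nrow(nms[[1L]])), type))
  list(netmats = nms,
       absolute = pack("absolute"),
       positive = pack("positive"),
       negative = pack("negative"))
}

#' Within-subject correlation between a measure and summary FC
#'
#' For one subject, the Pearson correlation over the K networks between the
#' subject's per-network measure values and each of the absolute, positive
#' and negative summary FC; missing FC entries are dropped pairwise.
#'
#' @param measure_row length-K vector (e.g. one row of an amplitude table).
#' @param sfc summary FC list from \code{\link{summary_fc}}.
#' @return named vector c(absolute =, positive =, negative =); NA when fewer
#'   than 3 complete pairs remain or the measure is constant.
#' @export
within_subject_amp_fc <- function(measure_row, sfc) {
  one <- function(fc) {
    ok <- is.finite(fc) & is.finite(measure_row)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::sd(measure_row[ok]) == 0 || stats::sd(fc[ok]) == 0) return(NA_real_)
    stats::cor(measure_row[ok], fc[ok])
  }
  c(absolute = one(sfc$absolute), positive = one(sfc$positive),
    negative = one(sfc$negative))
}

#' Across-subject correlations between a measure and summary FC
#'
#' For every network and FC type, the Pearson correlation (and p-value)
#' across subjects between the measure column and the FC column, with
#' Bonferroni correction across the K x 3 tests.
#'
#' @param measure S x K measure table.
#' @param fc list with S x K matrices \code{absolute}, \code{positive},
#'   \code{negative} (as from \code{\link{cohort_netmats}}).
#' @return data.frame(network, fc_type, r, p, p_bonf).
#' @export
across_subject_amp_fc <- function(measure, fc) {
  measure <- as_matrix_numeric(measure, "measure")
  if (nrow(measure) < 10L) stop("need at least 10 subjects")
  K <- ncol(measure)
  types <- c("absolute", "positive", "negative")
  rows <- list()
  for (type in types) {
    mat <- fc[[type]]
    for (k in seq_len(K)) {
      x <- measure[, k]; y <- mat[, k]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 4L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warning(sprintf("constant or empty column for network %d (%s)", k, type))
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x[ok], y[ok])
        r <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        network = colnames(measure)[k] %||% as.character(k),
        fc_type = type, r = r, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(1, out$p * nrow(out))
  out
}
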
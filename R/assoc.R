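#' Regression-based deconfounding
#'
#' Residualizes every column of Y on the confound matrix (plus an intercept).
#' Missing entries in a Y column are handled by fitting on that column's
#' complete rows and leaving its NAs in place; the confound matrix itself
#' must be complete.
#'
#' @param Y S x m numeric matrix or data.frame (may contain NAs).
#' @param confounds S x Q numeric matrix, no missing values.
#' @return matrix of residuals with the shape (and NA pattern) of Y; each
#'   column is orthogonal to every confound column and to the intercept over
#'   its complete rows.
#' @export
deconfound <- function(Y, confounds) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  if (is.data.frame(Y)) Y <- as.matrix(Y)
  confounds <- as_matrix_numeric(cbind(intercept = 1, confounds), "confounds")
  if (nrow(Y) != nrow(confounds)) stop("Y and confounds must have the same number of rows")
  q <- qr(confounds)
  if (q$rank < ncol(confounds)) {
    keep <- q$pivot[seq_len(q$rank)]
    bad <- setdiff(seq_len(ncol(confounds)), keep)
    stop(sprintf("confound matrix is rank deficient; collinear column(s): %s",
                 paste(colnames(confounds)[bad] %||% bad, collapse = ", ")))
  }
  out <- Y
  for (j in seq_len(ncol(Y))) {
    ok <- is.finite(Y[, j])
    if (sum(ok) <= ncol(confounds)) stop(sprintf("too few complete rows in column %d", j))
    fit <- stats::lm.fit(confounds[ok, , drop = FALSE], Y[ok, j])
    out[ok, j] <- fit$residuals
    out[!ok, j] <- NA_real_
  }
  out
}

#' Soft-shrinkage SVD imputation of missing entries
#'
#' Iterative low-rank matrix completion: columns are standardized internally,
#' missing cells initialized at zero (the column mean), and the matrix is
#' repeatedly reconstructed from its SVD with soft-thresholded singular
#' values, refreshing only the missing cells, until the relative change of
#' the imputed values falls below \code{tol}. Observed entries are returned
#' bit-identical.
#'
#' @param x S x V numeric matrix or data.frame with NAs marking missing
#'   entries.
#' @param shrinkage soft threshold on the singular values, as a fraction of
#'   the leading singular value of the mean-filled standardized matrix
#'   (default 0.1).
#' @param max_iter,tol stopping rule.
#' @return matrix of the same shape with missing entries imputed.
#' @export
impute_missing <- function(x, shrinkage = 0.1, max_iter = 200L, tol = 1e-6) {
  was_df <- is.data.frame(x)
  if (was_df) x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric")
  miss <- !is.finite(x)
  if (!any(miss)) return(if (was_df) as.data.frame(x) else x)
  if (any(colSums(!miss) == 0L)) stop("column(s) with no observed values cannot be imputed")
  mu <- apply(x, 2L, function(c) mean(c[is.finite(c)]))
  sdv <- apply(x, 2L, function(c) stats::sd(c[is.finite(c)]))
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  z <- sweep(sweep(x, 2L, mu), 2L, sdv, `/`)
  z[miss] <- 0
  d1 <- svd(z, nu = 0L, nv = 0L)$d[1L]
  lambda_target <- shrinkage * d1
  # warm-started threshold path: geometric annealing from half the leading
  # singular value down to the target, so that small targets still make
  # progress past the mean-filled start
  path <- if (lambda_target >= 0.5 * d1) lambda_target else
    exp(seq(log(0.5 * d1), log(max(lambda_target, 1e-12 * d1)), length.out = 20L))
  for (lambda in path) {
    for (it in seq_len(max_iter)) {
      sv <- svd(z)
      d <- pmax(sv$d - lambda, 0)
      recon <- sv$u %*% (d * t(sv$v))
      new_vals <- recon[miss]
      delta <- sqrt(sum((new_vals - z[miss])^2)) / max(sqrt(sum(new_vals^2)), .Machine$double.eps)
      z[miss] <- new_vals
      if (delta < tol) break
    }
  }
  out <- x
  filled <- sweep(sweep(z, 2L, sdv, `*`), 2L, mu, `+`)
  out[miss] <- filled[miss]
  if (was_df) as.data.frame(out) else out
}

#' Pearson correlation with p-value under pairwise deletion
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @return list(r, p, n) with the two-sided p from the t distribution with
#'   n - 2 degrees of freedom.
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) stop("zero variance input")
  ct <- stats::cor.test(x[ok], y[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha familywise significance level.
#' @param m_tests number of tests in the family.
#' @return alpha / m_tests.
#' @export
bonferroni_threshold <- function(alpha, m_tests) {
  if (m_tests < 1L) stop("m_tests must be >= 1")
  alpha / m_tests
}

#' Smallest |r| reaching a p-value threshold at sample size n
#'
#' Inverts the t test of a Pearson correlation: the magnitude of r whose
#' two-sided p equals \code{p} with \code{n} complete pairs.
#'
#' @param p two-sided p-value.
#' @param n sample size (n > 2).
#' @return positive real below 1.
#' @export
critical_r <- function(p, n) {
  if (n <= 2) stop("n must exceed 2")
  tq <- stats::qt(p / 2, df = n - 2, lower.tail = FALSE)
  tq / sqrt(n - 2 + tq^2)
}

#' Mass univariate correlation of measures against phenotypes
#'
#' Correlates each measure column (e.g. sensory and cognitive cluster
#' amplitudes) with every phenotype column under pairwise deletion,
#' reporting r, p, -log10 p and significance flags at the Bonferroni and at a
#' stringent threshold. With exactly two measures the signed difference of
#' the -log10 p profiles is added. Optionally both sides are residualized on
#' age first.
#'
#' @param measures S x m matrix (m measures) or vector.
#' @param phenotypes S x V data.frame/matrix with NAs for missing.
#' @param stringent_p stringent significance threshold (default 1e-20).
#' @param alpha familywise level for the Bonferroni flag (default 0.05).
#' @param age optional length-S vector; when supplied, age is regressed out
#'   of the measures and each phenotype before correlating.
#' @param min_pairs variables with fewer complete pairs are dropped (with a
#'   message).
#' @return data.frame(variable, measure, r, p, neglog10p, sig_bonferroni,
#'   sig_stringent) plus, for two measures, attribute
#'   \code{"neglog10p_diff"}: a data.frame of signed differences.
#' @export
mass_correlate <- function(measures, phenotypes, stringent_p = 1e-20,
                           alpha = 0.05, age = NULL, min_pairs = 4L) {
  if (is.null(dim(measures))) measures <- cbind(measure = measures)
  if (is.data.frame(measures)) measures <- as.matrix(measures)
  ph <- as.matrix(as.data.frame(phenotypes))
  storage.mode(ph) <- "double"
  if (!is.null(age)) {
    measures <- deconfound(measures, cbind(age = age))
    ph <- deconfound(ph, cbind(age = age))
  }
  V <- ncol(ph)
  thr <- bonferroni_threshold(alpha, V)
  mnames <- colnames(measures) %||% sprintf("measure%d", seq_len(ncol(measures)))
  rows <- list()
  dropped <- character()
  for (j in seq_len(V)) {
    vn <- colnames(ph)[j] %||% as.character(j)
    for (i in seq_len(ncol(measures))) {
      ok <- is.finite(measures[, i]) & is.finite(ph[, j])
      if (sum(ok) < min_pairs) { dropped <- union(dropped, vn); next }
      res <- pearson_with_p(measures[, i], ph[, j])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = vn, measure = mnames[i], r = res$r, p = res$p,
        neglog10p = -log10(max(res$p, .Machine$double.xmin)),
        sig_bonferroni = res$p < thr, sig_stringent = res$p < stringent_p,
        n = res$n, stringsAsFactors = FALSE)
    }
  }
  if (length(dropped))
    message("dropped (too few complete pairs): ", paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (ncol(measures) == 2L) {
    wide <- stats::reshape(out[, c("variable", "measure", "neglog10p")],
                           idvar = "variable", timevar = "measure", direction = "wide")
    diffs <- data.frame(variable = wide$variable,
                        neglog10p_diff = wide[[2L]] - wide[[3L]])
    attr(out, "neglog10p_diff") <- diffs
  }
  out
}

#' Compare two overlapping dependent correlations
#'
#' Tests H0: cor(x1, y) = cor(x2, y) on the same sample, where the two
#' correlations share y and are themselves dependent through cor(x1, x2).
#' Uses Dunn and Clark's z with the backtransformed-average modification of
#' Hittner, May and Silver: the Fisher-z difference is scaled by a variance
#' term evaluated at the backtransformed average of the two correlations.
#'
#' @param x1,x2,y paired numeric vectors; incomplete triples are dropped.
#' @param variant \code{"hittner2003"} (default) or \code{"dunn_clark"}
#'   (pooled-average r instead of the backtransformed average).
#' @return object of class \code{"corr_comparison"}: list(r1, r2, r12, n,
#'   p1, p2, statistic, p_diff).
#' @export
compare_dependent_correlations <- function(x1, x2, y, variant = c("hittner2003", "dunn_clark")) {
  variant <- match.arg(variant)
  ok <- is.finite(x1) & is.finite(x2) & is.finite(y)
  n <- sum(ok)
  if (n < 10L) stop("need at least 10 complete triples")
  x1 <- x1[ok]; x2 <- x2[ok]; y <- y[ok]
  r1 <- stats::cor(x1, y); r2 <- stats::cor(x2, y); r12 <- stats::cor(x1, x2)
  if (any(abs(c(r1, r2)) >= 1)) stop("|r| = 1: Fisher z undefined")
  z1 <- atanh(r1); z2 <- atanh(r2)
  rm_ <- switch(variant,
                hittner2003 = tanh((z1 + z2) / 2),
                dunn_clark = (r1 + r2) / 2)
  cov_term <- (r12 * (1 - 2 * rm_^2) - 0.5 * rm_^2 * (1 - 2 * rm_^2 - r12^2)) /
    (1 - rm_^2)^2
  stat <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cov_term))
  p_of <- function(r) {
    tv <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tv), df = n - 2, lower.tail = FALSE)
  }
  structure(list(r1 = r1, r2 = r2, r12 = r12, n = n,
                 p1 = p_of(r1), p2 = p_of(r2),
                 statistic = stat, p_diff = 2 * stats::pnorm(-abs(stat)),
                 variant = variant),
            class = "corr_comparison")
}

#' @export
print.corr_comparison <- function(x, ...) {
  cat(sprintf("Comparison of dependent overlapping correlations (%s), n = %d\n",
              x$variant, x$n))
  cat(sprintf("  r1 = %.3f (p = %.3g), r2 = %.3f (p = %.3g), r12 = %.3f\n",
              x$r1, x$p1, x$r2, x$p2, x$r12))
  cat(sprintf("  z = %.3f, two-sided p(r1 = r2) = %.3g\n", x$statistic, x$p_diff))
  invisible(x)
}

#' Full and partial correlations among the three amplitude measures
#'
#' Per network, the across-subject correlations among network amplitude (a),
#' temporal synchrony (s) and BOLD amplitude (b), plus the partial
#' correlations of amplitude with each of the other two controlling for the
#' third, and the corresponding r-squared variance-explained values.
#'
#' @param amplitude,synchrony,bold S x K measure tables with aligned
#'   subjects; alternatively pass a single \code{\link{rsn_decompose}} fit as
#'   \code{amplitude}.
#' @return list with K x 5 matrix \code{full}/partial columns
#'   (r_amp_syn, r_amp_bold, r_syn_bold, pr_amp_syn, pr_amp_bold) exposed as
#'   \code{full} (first three) and \code{partial} (last two), plus
#'   \code{r_squared} for the two full amplitude correlations.
#' @export
triplet_correlations <- function(amplitude, synchrony = NULL, bold = NULL) {
  if (inherits(amplitude, "rsn_decomp")) {
    synchrony <- amplitude$synchrony
    bold <- amplitude$bold
    amplitude <- amplitude$amplitude
  }
  a <- as_matrix_numeric(amplitude, "amplitude")
  s <- as_matrix_numeric(synchrony, "synchrony")
  b <- as_matrix_numeric(bold, "bold")
  stopifnot(all(dim(a) == dim(s)), all(dim(a) == dim(b)))
  K <- ncol(a)
  partial_r <- function(r12, r13, r23) (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
  full <- matrix(NA_real_, K, 3, dimnames = list(colnames(a), c("r_amp_syn", "r_amp_bold", "r_syn_bold")))
  part <- matrix(NA_real_, K, 2, dimnames = list(colnames(a), c("pr_amp_syn", "pr_amp_bold")))
  for (k in seq_len(K)) {
    if (stats::sd(a[, k]) == 0 || stats::sd(s[, k]) == 0 || stats::sd(b[, k]) == 0)
      stop(sprintf("constant measure column for network %d", k))
    ras <- stats::cor(a[, k], s[, k]); rab <- stats::cor(a[, k], b[, k])
    rsb <- stats::cor(s[, k], b[, k])
    full[k, ] <- c(ras, rab, rsb)
    part[k, ] <- c(partial_r(ras, rab, rsb), partial_r(rab, ras, rsb))
  }
  list(full = full, partial = part,
       r_squared = full[, c("r_amp_syn", "r_amp_bold"), drop = FALSE]^2)
}

#' Multiple linear regression of one measure column on phenotypes
#'
#' Fits the design {systolic BP-like, body-fat-like, haemoglobin-like,
#' sleep-like (any named phenotype columns), age, sex, age x sex, age^2,
#' age^2 x sex} to one measure column by ordinary least squares. All
#' dependent and independent variables except sex are z-scored before the
#' interaction/polynomial terms are built from the z-scored age; sex is kept
#' on its original 0/1 coding.
#'
#' @param y length-S response (one measure column).
#' @param phenos S x p matrix/data.frame of phenotype predictors (complete;
#'   impute first).
#' @param age,sex length-S vectors; sex coded 0/1.
#' @return object of class \code{"rsn_regression"}: data.frame with
#'   coefficients, standard errors and two-sided p-values per predictor.
#' @export
fit_regression <- function(y, phenos, age, sex) {
  phenos <- as.matrix(as.data.frame(phenos))
  storage.mode(phenos) <- "double"
  if (any(!is.finite(phenos)) || any(!is.finite(y)) || any(!is.finite(age)) || any(!is.finite(sex)))
    stop("inputs must be complete; impute missing phenotypes first")
  zs <- function(v) as.numeric(scale(v))
  age_z <- zs(age)
  X <- cbind(apply(phenos, 2L, zs),
             age = age_z, sex = sex,
             age_sex = age_z * sex, age2 = age_z^2, age2_sex = age_z^2 * sex)
  df <- data.frame(y = zs(y), X)
  fit <- stats::lm(y ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) stop("collinear design")
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = out, fit = fit), class = "rsn_regression")
}

#' @export
print.rsn_regression <- function(x, ...) {
  cat("Multiple linear regression (z-scored variables, sex on 0/1 coding)\n")
  print(transform(x$table, estimate = round(estimate, 4), se = round(se, 4),
                  p = signif(p, 3)))
  invisible(x)
}

#' Regression suite across all networks of a measure table
#'
#' Runs \code{\link{fit_regression}} on every network column and applies
#' Bonferroni correction per predictor across the K networks (the correction
#' family is measure x predictor).
#'
#' @param measure S x K measure table.
#' @inheritParams fit_regression
#' @return data.frame(network, term, estimate, se, p, p_bonf).
#' @export
fit_regression_suite <- function(measure, phenos, age, sex) {
  measure <- as_matrix_numeric(measure, "measure")
  K <- ncol(measure)
  tabs <- lapply(seq_len(K), function(k) {
    tab <- fit_regression(measure[, k], phenos, age, sex)$table
    tab$network <- colnames(measure)[k] %||% as.character(k)
    tab
  })
  out <- do.call(rbind, tabs)
  out$p_bonf <- NA_real_
  for (term in unique(out$term)) {
    sel <- out$term == term
    out$p_bonf[sel] <- pmin(1, out$p[sel] * K)
  }
  out[, c("network", "term", "estimate", "se", "p", "p_bonf")]
}
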
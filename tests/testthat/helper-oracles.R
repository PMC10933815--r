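# Independent oracles used to cross-check the implementation.

# Per-timepoint least-squares oracle for stage-1 spatial regression:
# regress each timepoint's voxel vector on the maps with lm.fit.
ols_oracle <- function(run, maps) {
  out <- matrix(NA_real_, ncol(maps), ncol(run))
  for (t in seq_len(ncol(run))) {
    out[, t] <- stats::lm.fit(maps, run[, t])$coefficients
  }
  out
}

# Residualize-and-correlate oracle for partial correlations.
partial_cor_oracle <- function(ts) {
  K <- nrow(ts)
  C <- diag(1, K)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      others <- setdiff(seq_len(K), c(i, j))
      if (length(others) == 0L) {
        r <- stats::cor(ts[i, ], ts[j, ])
      } else {
        Z <- cbind(1, t(ts[others, , drop = FALSE]))
        ri <- stats::lm.fit(Z, ts[i, ])$residuals
        rj <- stats::lm.fit(Z, ts[j, ])$residuals
        r <- stats::cor(ri, rj)
      }
      C[i, j] <- C[j, i] <- r
    }
  }
  C
}

# Permutation oracle for comparing two overlapping dependent correlations:
# under H0 the (standardized) x1/x2 labels are exchangeable per subject.
perm_test_depcorr <- function(x1, x2, y, nperm = 199L) {
  z1 <- as.numeric(scale(x1)); z2 <- as.numeric(scale(x2))
  stat <- function(a, b) abs(atanh(stats::cor(a, y)) - atanh(stats::cor(b, y)))
  obs <- stat(z1, z2)
  n <- length(y)
  exceed <- 0L
  for (p in seq_len(nperm)) {
    swap <- stats::runif(n) < 0.5
    a <- ifelse(swap, z2, z1)
    b <- ifelse(swap, z1, z2)
    if (stat(a, b) >= obs) exceed <- exceed + 1L
  }
  (1 + exceed) / (nperm + 1)
}

# Correlated Gaussian samples from a Cholesky factor.
rmvnorm_chol <- function(n, sigma) {
  matrix(stats::rnorm(n * nrow(sigma)), n) %*% chol(sigma)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
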
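# Internal helpers: seeding, standardization, band-limited noise.

# Deterministic child seed from a root seed and an integer offset; kept
# strictly below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((abs(as.double(seed)) * 48271 + as.double(offset) * 10007) %% 2147483629)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv) else if (exists(".Random.seed", envir = genv, inherits = FALSE)) rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Standardize each row to mean 0, sample SD 1.
row_standardize <- function(x, what = "series") {
  x <- x - rowMeans(x)
  s <- sqrt(rowSums(x^2) / (ncol(x) - 1))
  bad <- which(!is.finite(s) | s == 0)
  if (length(bad)) {
    stop(sprintf("cannot standardize %s with zero variance (rows: %s)",
                 what, paste(utils::head(bad, 10L), collapse = ", ")))
  }
  x / s
}

# n rows of length `tp`: Gaussian noise low-pass filtered in the frequency
# domain at `cutoff_hz` (sampling interval `tr` seconds), each row
# standardized to zero mean and unit sample SD. cutoff_hz = Inf gives
# white noise.
bandlimited_series <- function(n, tp, cutoff_hz = 0.1, tr = 0.735) {
  x <- matrix(stats::rnorm(n * tp), tp, n)
  if (is.finite(cutoff_hz)) {
    freq <- pmin(0:(tp - 1), tp - (0:(tp - 1))) / (tp * tr)
    keep <- freq <= cutoff_hz
    if (sum(keep[-1]) < 4L) {
      # too few passband bins to carry a signal; fall back to white noise
      keep[] <- TRUE
    }
    xf <- stats::mvfft(x)
    xf[!keep, ] <- 0 + 0i
    x <- Re(stats::mvfft(xf, inverse = TRUE)) / tp
  }
  row_standardize(t(x), what = "latent series")
}

as_matrix_numeric <- function(x, arg) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop(sprintf("'%s' must be a numeric matrix", arg))
  if (any(!is.finite(x))) stop(sprintf("'%s' contains non-finite values", arg))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
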
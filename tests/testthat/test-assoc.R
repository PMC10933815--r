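test_that("deconfounding residualizes exactly and idempotently", {
  set.seed(30)
  S <- 500
  conf <- cbind(c1 = rnorm(S), c2 = rnorm(S))
  Y <- cbind(a = 2 * conf[, 1] + rnorm(S), b = rnorm(S))
  R <- deconfound(Y, conf)
  # orthogonality to confounds and the intercept
  expect_lt(max(abs(cor(R, conf))), 1e-10)
  expect_lt(max(abs(colMeans(R))), 1e-10)
  # idempotence
  expect_equal(deconfound(R, conf), R, tolerance = 1e-10)
  # intercept-only confound = demeaning
  expect_equal(deconfound(Y, matrix(0, S, 0)), sweep(Y, 2, colMeans(Y)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # independent Y barely changes
  Y2 <- matrix(rnorm(2000), 2000)
  conf2 <- matrix(rnorm(2000), 2000)
  expect_gt(cor(deconfound(Y2, conf2)[, 1], Y2[, 1]), 0.99)
  # NA pattern preserved, complete rows residualized
  Yna <- Y; Yna[c(3, 9), 1] <- NA
  Rna <- deconfound(Yna, conf)
  expect_true(all(is.na(Rna[c(3, 9), 1])))
  ok <- is.finite(Yna[, 1])
  expect_lt(abs(cor(Rna[ok, 1], conf[ok, 1])), 1e-10)
  # collinear confounds rejected
  expect_error(deconfound(Y, cbind(conf, conf[, 1])), "rank deficient")
})

test_that("soft-SVD imputation completes low-rank structure without touching observed cells", {
  set.seed(31)
  # exact rank-1 matrix, 5% removed, near-zero shrinkage
  u <- rnorm(60); v <- rnorm(12)
  X <- u %o% v
  miss <- matrix(runif(length(X)) < 0.05, 60)
  Xm <- X; Xm[miss] <- NA
  Xi <- impute_missing(Xm, shrinkage = 1e-9, max_iter = 500L, tol = 1e-12)
  expect_lt(max(abs(Xi[miss] - X[miss])), 1e-6)
  # observed cells bit-exact
  expect_identical(Xi[!miss], X[!miss])

  # no missing entries: returned unchanged
  expect_identical(impute_missing(X), X)

  # single missing cell in an otherwise constant column -> that constant
  Z <- cbind(rep(5, 30), rnorm(30), rnorm(30))
  Z[7, 1] <- NA
  Zi <- impute_missing(Z)
  expect_equal(Zi[7, 1], 5, tolerance = 1e-8)

  Z[, 1] <- NA
  expect_error(impute_missing(Z), "no observed values")
})

test_that("correlation machinery reproduces the printed threshold arithmetic", {
  x <- rnorm(50)
  expect_equal(pearson_with_p(x, x)$r, 1)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  y <- rnorm(50); y[1:5] <- NA
  expect_equal(pearson_with_p(x, y)$n, 45)
  expect_error(pearson_with_p(x[1:3], y[1:3]), "4 complete")
  expect_error(pearson_with_p(x, rep(1, 50)), "zero variance")

  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 4897), 3), 1.02e-5)
  expect_equal(round(-log10(bonferroni_threshold(10^-7.5, 21)), 2), 8.82)

  # |r| at p = 1e-20 with n = 37842 rounds to 0.05
  expect_equal(round(critical_r(1e-20, 37842), 2), 0.05)
  # consistency: the returned r attains the requested p
  r <- critical_r(1e-6, 200)
  tv <- r * sqrt((200 - 2) / (1 - r^2))
  expect_equal(2 * pt(tv, 198, lower.tail = FALSE), 1e-6, tolerance = 1e-10)
})

test_that("mass correlation flags planted effects and respects the null", {
  set.seed(32)
  S <- 2000
  latent <- rnorm(S)
  measures <- cbind(sensory = latent + 0.5 * rnorm(S),
                    cognitive = rnorm(S))
  ph <- data.frame(planted = 0.5 * latent + rnorm(S),
                   null1 = rnorm(S), null2 = rnorm(S), null3 = rnorm(S))
  out <- mass_correlate(measures, ph, stringent_p = 1e-6)
  planted_row <- out[out$variable == "planted" & out$measure == "sensory", ]
  expect_true(planted_row$sig_bonferroni && planted_row$sig_stringent)
  null_rows <- out[grepl("null", out$variable), ]
  expect_true(all(!null_rows$sig_stringent))

  # identical measure on both sides: -log10 p differences all zero
  out2 <- mass_correlate(cbind(a = latent, b = latent), ph)
  diffs <- attr(out2, "neglog10p_diff")
  expect_equal(diffs$neglog10p_diff, rep(0, nrow(diffs)))

  # age-deconfounded variant equals explicit residualization of both sides
  age <- rnorm(S)
  ph_age <- data.frame(v = 0.3 * age + rnorm(S))
  m_age <- cbind(m = latent + 0.4 * age)
  out_a <- mass_correlate(m_age, ph_age, age = age)
  r_expl <- cor(deconfound(m_age, cbind(age))[, 1], deconfound(as.matrix(ph_age), cbind(age))[, 1])
  expect_equal(out_a$r, r_expl, tolerance = 1e-12)

  # variables with too few complete pairs are dropped with a message
  ph_bad <- data.frame(ok = rnorm(S), sparse = c(rnorm(3), rep(NA, S - 3)))
  expect_message(out_b <- mass_correlate(measures[, 1], ph_bad), "sparse")
  expect_false("sparse" %in% out_b$variable)
})

test_that("dependent-correlation comparison is symmetric and matches a permutation oracle", {
  set.seed(33)
  sigma <- matrix(c(1, 0.6, 0.5, 0.6, 1, 0.1, 0.5, 0.1, 1), 3)
  d <- rmvnorm_chol(300, sigma)
  cc <- compare_dependent_correlations(d[, 1], d[, 2], d[, 3])
  expect_s3_class(cc, "corr_comparison")
  expect_true(abs(cc$r1) <= 1 && abs(cc$r2) <= 1)
  # symmetry: swapping x1/x2 swaps r1/r2 and preserves p_diff
  cc_swap <- compare_dependent_correlations(d[, 2], d[, 1], d[, 3])
  expect_equal(cc_swap$p_diff, cc$p_diff, tolerance = 1e-12)
  expect_equal(cc_swap$r1, cc$r2)
  # identical measures: r1 = r2, p_diff = 1
  cc_same <- compare_dependent_correlations(d[, 1], d[, 1], d[, 3])
  expect_equal(cc_same$r1, cc_same$r2)
  expect_equal(cc_same$p_diff, 1)

  # strong alternative: decisive and agreeing with the permutation oracle
  n <- 500
  alt <- matrix(c(1, 0.6, 0.5, 0.6, 1, 0.1, 0.5, 0.1, 1), 3)
  p_alt <- replicate(20, {
    d <- rmvnorm_chol(n, alt)
    compare_dependent_correlations(d[, 1], d[, 2], d[, 3])$p_diff
  })
  expect_gt(mean(p_alt < 1e-6), 0.5)

  agree <- replicate(60, {
    null_case <- runif(1) < 0.5
    s <- if (null_case) matrix(c(1, 0.6, 0.3, 0.6, 1, 0.3, 0.3, 0.3, 1), 3)
         else matrix(c(1, 0.6, 0.45, 0.6, 1, 0.1, 0.45, 0.1, 1), 3)
    d <- rmvnorm_chol(150, s)
    p_a <- compare_dependent_correlations(d[, 1], d[, 2], d[, 3])$p_diff
    p_b <- perm_test_depcorr(d[, 1], d[, 2], d[, 3], nperm = 199L)
    (p_a < 0.05) == (p_b < 0.05)
  })
  expect_gt(mean(agree), 0.85)

  expect_error(compare_dependent_correlations(d[1:5, 1], d[1:5, 2], d[1:5, 3]),
               "at least 10")
  lin <- as.numeric(1:20)
  expect_error(compare_dependent_correlations(lin, rnorm(20), lin), "Fisher z")
})

test_that("triplet correlations isolate the driving factor and match the partial oracle", {
  # only synchrony varies: amplitude tracks synchrony, not BOLD amplitude
  cfg_s <- sim_config(n_voxels = 120L, n_networks = 3L, n_timepoints = 300L,
                      n_subjects = 60L, voxel_sd_range = c(1, 1),
                      synchrony_range = c(0.2, 0.9), noise_sd = 0.3, seed = 61L)
  co_s <- make_cohort(cfg_s)
  d_s <- rsn_decompose(co_s$runs, co_s$maps)
  tr_s <- triplet_correlations(d_s)
  expect_gt(min(tr_s$full[, "r_amp_syn"]), 0.9)
  expect_lt(mean(abs(tr_s$full[, "r_amp_bold"])), 0.5)

  # only voxel SDs vary: amplitude tracks BOLD amplitude
  cfg_v <- sim_config(n_voxels = 120L, n_networks = 3L, n_timepoints = 300L,
                      n_subjects = 60L, voxel_sd_range = c(0.5, 1.5),
                      synchrony_range = c(0.6, 0.6), noise_sd = 0.3, seed = 62L)
  co_v <- make_cohort(cfg_v)
  d_v <- rsn_decompose(co_v$runs, co_v$maps)
  tr_v <- triplet_correlations(d_v)
  expect_gt(min(tr_v$full[, "r_amp_bold"]), 0.9)

  # partial correlations equal the residualization oracle
  sc <- small_cohort()
  tr <- triplet_correlations(sc$decomp)
  for (k in seq_len(sc$cfg$n_networks)) {
    a <- sc$decomp$amplitude[, k]; s <- sc$decomp$synchrony[, k]; b <- sc$decomp$bold[, k]
    res_a <- lm.fit(cbind(1, b), a)$residuals
    res_s <- lm.fit(cbind(1, b), s)$residuals
    expect_equal(tr$partial[k, "pr_amp_syn"], cor(res_a, res_s), tolerance = 1e-10,
                 ignore_attr = TRUE)
    res_a2 <- lm.fit(cbind(1, s), a)$residuals
    res_b2 <- lm.fit(cbind(1, s), b)$residuals
    expect_equal(tr$partial[k, "pr_amp_bold"], cor(res_a2, res_b2), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_equal(tr$r_squared, tr$full[, 1:2]^2, ignore_attr = TRUE)
})

test_that("the age/sex regression recovers planted coefficients and honours its coding", {
  set.seed(34)
  S <- 2000
  phenos <- cbind(bp = rnorm(S), fat = rnorm(S), hgb = rnorm(S), sleep = rnorm(S))
  age <- rnorm(S, 60, 7)
  sex <- rbinom(S, 1, 0.5)
  age_z <- as.numeric(scale(age))
  beta <- c(bp = -0.2, fat = 0.1, hgb = 0.15, sleep = -0.05,
            age = -0.3, sex = 0.25, age_sex = 0.1, age2 = -0.05, age2_sex = 0.08)
  lin <- phenos %*% beta[1:4] + beta["age"] * age_z + beta["sex"] * sex +
    beta["age_sex"] * age_z * sex + beta["age2"] * age_z^2 +
    beta["age2_sex"] * age_z^2 * sex
  y <- as.numeric(lin) + rnorm(S) * sd(lin)  # roughly 50% explained variance
  fit <- fit_regression(y, phenos, age, sex)
  tab <- fit$table[fit$table$term != "(Intercept)", ]
  # estimates on the z-scored response: rescale the truth by the actual
  # column and response SDs
  col_sd <- c(apply(phenos, 2, sd), rep(1, 5))
  truth_scaled <- beta * col_sd / sd(y)
  for (tm in names(beta)) {
    row <- tab[tab$term == tm, ]
    expect_lt(abs(row$estimate - truth_scaled[tm]), 3 * row$se)
  }

  # flipping the sex coding flips the sex and interaction coefficients
  fit2 <- fit_regression(y, phenos, age, 1 - sex)
  get <- function(f, tm) f$table$estimate[f$table$term == tm]
  expect_equal(get(fit2, "sex"), -get(fit, "sex"), tolerance = 1e-10)
  expect_equal(get(fit2, "age_sex"), -get(fit, "age_sex"), tolerance = 1e-10)
  expect_equal(get(fit2, "age"), get(fit, "age") + get(fit, "age_sex"), tolerance = 1e-10)

  # z-scoring makes t/p invariant to the original units
  fit3 <- fit_regression(y * 3 + 1, phenos %*% diag(c(10, 0.1, 2, 5)), age / 365, sex)
  expect_equal(fit3$table$p, fit$table$p, tolerance = 1e-8)

  expect_error(fit_regression(y, cbind(phenos, phenos[, 1]), age, sex), "collinear")

  # suite: per-predictor Bonferroni across networks
  sc <- small_cohort()
  ph_small <- matrix(rnorm(sc$cfg$n_subjects * 2), ncol = 2,
                     dimnames = list(NULL, c("v1", "v2")))
  suite <- fit_regression_suite(sc$decomp$synchrony, ph_small,
                                age = rnorm(sc$cfg$n_subjects),
                                sex = rep(0:1, length.out = sc$cfg$n_subjects))
  expect_equal(suite$p_bonf, pmin(1, suite$p * sc$cfg$n_networks))
})
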
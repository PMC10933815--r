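test_that("spatial regression is the exact least-squares solution", {
  # two-voxel hand cases
  s <- sin(seq(0, 4 * pi, length.out = 50))
  expect_equal(as.numeric(spatial_regress(rbind(s, s), cbind(c(1, 1)))), s)
  expect_equal(as.numeric(spatial_regress(rbind(s, -s), cbind(c(1, -1)))), s)

  # random instances against the per-timepoint lm.fit oracle
  set.seed(1)
  for (dims in list(c(50, 3, 200), c(200, 5, 300), c(30, 2, 40))) {
    G <- matrix(rnorm(dims[1] * dims[2]), dims[1])
    X <- matrix(rnorm(dims[1] * dims[3]), dims[1])
    expect_lt(max(abs(spatial_regress(X, G) - ols_oracle(X, G))), 1e-10)
  }

  # singular design rejected with its condition number
  Gs <- cbind(1:10, 2 * (1:10))
  expect_error(spatial_regress(matrix(rnorm(100), 10), Gs), "condition number")
  expect_error(spatial_regress(matrix(rnorm(100), 10), cbind(rep(0, 10), 1:10)),
               "all-zero")
})

test_that("network amplitude matches closed forms and scales linearly", {
  expect_equal(unname(network_amplitude(rbind(rep(2, 100)))), 0)

  # whole-period sine: SD = A/sqrt(2) up to the sample-SD factor
  tt <- 2 * pi * 5 * (0:199) / 200
  for (A in c(1, 3.7)) {
    a <- unname(network_amplitude(rbind(A * sin(tt))))
    expect_equal(a, A / sqrt(2) * sqrt(200 / 199), tolerance = 1e-6)
  }

  # homogeneity of degree 1 (the halving behaviour)
  set.seed(2)
  X <- matrix(rnorm(60 * 100), 60)
  G <- matrix(rnorm(60 * 3), 60)
  a1 <- network_amplitude(spatial_regress(X, G))
  a2 <- network_amplitude(spatial_regress(0.5 * X, G))
  expect_equal(a2, 0.5 * a1, tolerance = 1e-12)
})

test_that("temporal normalization z-scores rows and rejects degenerate voxels", {
  z <- temporal_normalize(rbind(c(1, 2, 3)))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)

  set.seed(3)
  X <- matrix(rnorm(5 * 50), 5)
  X2 <- X * 7 + 3
  expect_equal(temporal_normalize(X2), temporal_normalize(X), tolerance = 1e-12)

  Xc <- X; Xc[2, ] <- 4
  expect_error(temporal_normalize(Xc), "zero variance")
})

test_that("temporal synchrony reflects phase alignment only", {
  # identical voxels, all-ones map: synchrony = 1
  set.seed(4)
  s <- rnorm(300)
  run <- matrix(rep(s, 20), 20, byrow = TRUE) + 0  # identical rows
  expect_equal(unname(temporal_synchrony(run, cbind(rep(1, 20)))), 1,
               tolerance = 1e-10)

  # independent voxels: synchrony ~ 1/sqrt(N)
  run2 <- matrix(rnorm(100 * 5000), 100)
  syn <- unname(temporal_synchrony(run2, cbind(rep(1, 100))))
  expect_equal(syn, 1 / sqrt(100), tolerance = 0.1 / sqrt(100) * 10)

  # invariance to per-voxel positive affine maps; homogeneity of degree 0
  sc <- small_cohort()
  run3 <- sc$cohort$runs[[1L]]
  scales <- runif(nrow(run3), 0.2, 5)
  shifts <- rnorm(nrow(run3))
  syn_a <- temporal_synchrony(run3, sc$cohort$maps)
  syn_b <- temporal_synchrony(run3 * scales + shifts, sc$cohort$maps)
  expect_equal(syn_a, syn_b, tolerance = 1e-10)

  # bound: mean of unit-SD series has SD <= 1
  expect_lte(max(temporal_synchrony(run2, cbind(rep(1, 100)))), 1 + 1e-10)
})

test_that("threshold masks follow the strict |Z| rule", {
  g <- cbind(c(4, -4, 1, 5))
  expect_equal(as.numeric(threshold_mask(g, 3.29)), c(1, 1, 0, 1))
  expect_equal(as.numeric(threshold_mask(g, 0)), c(1, 1, 1, 1))
  # boundary is strict
  gb <- cbind(c(3.29, 3.3, 4, 0))
  expect_equal(as.numeric(threshold_mask(gb, 3.29)), c(0, 1, 1, 0))
  expect_error(threshold_mask(g, 10), "< 2 voxels")
})

test_that("two-sided normal quantiles reproduce the conventional thresholds", {
  expect_equal(round(z_from_two_sided_p(1e-3), 2), 3.29)
  expect_equal(round(z_from_two_sided_p(1e-5), 2), 4.42)
  expect_equal(round(z_from_two_sided_p(1e-7), 2), 5.33)
  expect_equal(z_from_two_sided_p(1 - 1e-12), 0, tolerance = 1e-5)
  expect_error(z_from_two_sided_p(0), "0, 1")
  expect_error(z_from_two_sided_p(1), "0, 1")
  # round trip
  for (p in c(0.5, 0.01, 1e-6)) {
    z <- z_from_two_sided_p(p)
    expect_equal(2 * pnorm(z, lower.tail = FALSE), p, tolerance = 1e-12)
  }
})

test_that("BOLD amplitude variants summarize voxel SDs as specified", {
  # mask picks two voxels with SDs 2 and 4 -> binary mean 3
  tt <- seq_len(400)
  base <- sin(2 * pi * 5 * tt / 400) * sqrt(2) * sqrt(399 / 400)  # unit sample SD
  run <- rbind(2 * base, 4 * base, 0.1 * rnorm(400))
  maps <- cbind(c(5, 5, 0.5))
  expect_equal(unname(bold_amplitude(run, maps, "binary_mean")), 3, tolerance = 1e-10)

  # closed forms of the weighted variants
  v <- apply(run, 1, sd)
  expect_equal(unname(bold_amplitude(run, maps, "weighted_sum")),
               sum(maps[, 1] * v) / 3, tolerance = 1e-12)
  expect_equal(unname(bold_amplitude(run, maps, "root_sum_var")),
               sqrt(sum(maps[, 1]^2 * v^2)), tolerance = 1e-12)

  # halving the data halves every variant
  for (m in c("binary_mean", "weighted_sum", "root_sum_var")) {
    expect_equal(bold_amplitude(run / 2, maps, m),
                 bold_amplitude(run, maps, m) / 2, tolerance = 1e-12)
  }
})

test_that("amplitude equals sigma times synchrony for equal-SD zero-mean runs", {
  sc <- small_cohort()
  maps <- sc$cohort$maps
  base <- temporal_normalize(sc$cohort$runs[[2L]])
  for (sigma in c(1, 2.5, 0.3)) {
    chk <- sigma_identity_check(base * sigma, maps)
    expect_true(chk$ok)
    expect_equal(chk$sigma, sigma, tolerance = 1e-8)
    expect_lt(chk$max_rel_dev, 1e-8)
  }
  expect_error(sigma_identity_check(sc$cohort$runs[[2L]], maps), "precondition")
})

test_that("the two-voxel phase toy attenuates amplitude by |cos(theta/2)|", {
  maps <- cbind(c(1, 1))
  thetas <- seq(0, pi, length.out = 9)
  a0 <- unname(network_amplitude(spatial_regress(two_voxel_phase_run(0), maps)))
  ratios <- vapply(thetas, function(th)
    unname(network_amplitude(spatial_regress(two_voxel_phase_run(th), maps))) / a0, 0)
  expect_equal(ratios, abs(cos(thetas / 2)), tolerance = 1e-6)
  expect_true(all(diff(ratios) < 0))
  expect_lt(ratios[length(ratios)], 1e-6)  # zero at theta = pi

  # anticorrelated weights with positively correlated voxels also cancel
  run <- two_voxel_phase_run(0)
  a_anti <- network_amplitude(spatial_regress(run, cbind(c(1, -1))))
  expect_lt(unname(a_anti), 1e-10)
})

test_that("threshold sweep agrees with direct recomputation", {
  cfg <- sim_config(n_voxels = 80L, n_networks = 3L, n_timepoints = 200L,
                    n_subjects = 15L, overlap_fraction = 0, seed = 31L)
  co <- make_cohort(cfg)
  sw <- sweep_thresholds(co$runs, co$maps, c(3.29, 4.42, 5.33))

  # brute-force recomputation of component (2) at the largest threshold
  z <- 5.33
  M <- threshold_mask(co$maps, z)
  ahat_full <- t(vapply(co$runs, temporal_synchrony, numeric(3), maps = co$maps))
  ahat_thr <- t(vapply(co$runs, function(run) {
    xn <- temporal_normalize(run)
    vapply(1:3, function(k) {
      sel <- M[, k] == 1L
      g <- co$maps[sel, k]
      sd(as.numeric(crossprod(g, xn[sel, ])) / sum(g^2))
    }, 0)
  }, numeric(3)))
  oracle_r <- vapply(1:3, function(k) cor(ahat_full[, k], ahat_thr[, k]), 0)
  expect_equal(sw$results[["z=5.33"]]$synchrony_r, oracle_r, tolerance = 1e-10)

  # with zero overlap, restricting to the support reproduces the full
  # regression exactly
  sw0 <- sweep_thresholds(co$runs, co$maps, c(1e-9))
  expect_equal(sw0$results[[1L]]$timeseries_r, 1, tolerance = 1e-10)
  expect_equal(sw0$results[[1L]]$synchrony_r, rep(1, 3), tolerance = 1e-10)

  # timeseries similarity does not increase as the mask tightens
  ts_r <- vapply(sw$results, `[[`, 0, "timeseries_r")
  expect_true(all(diff(ts_r) < 1e-8))

  expect_error(sweep_thresholds(co$runs, co$maps, c(5, 3)), "ascending")
})
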
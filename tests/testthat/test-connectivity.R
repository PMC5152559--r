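test_that("identical parcels correlate perfectly at every scale", {
  set.seed(3)
  x <- rnorm(200)
  d <- modwt(cbind(a = x, b = x), max_scale = 3)
  for (cm in wavelet_correlation(d))
    expect_equal(cm$r["a", "b"], 1, tolerance = 1e-12)
})

test_that("independent white-noise parcels decorrelate at the 3/sqrt(n) scale", {
  hits <- sapply(1:40, function(s) {
    set.seed(s)
    d <- modwt(matrix(rnorm(2000), 1000, 2), max_scale = 1)
    cm <- wavelet_correlation(d)[[1]]
    abs(cm$r[1, 2]) < 3 / sqrt(cm$n_usable)
  })
  expect_gte(mean(hits), 0.9)   # ~99.7% expected; allow sampling slack
})

test_that("block-covariance cohorts show within > between module correlation", {
  at <- default_atlas()
  gt <- make_ground_truth(at, n_modules = 4, within_r = 0.5,
                          between_r = 0.1, seed = 1)
  co <- simulate_cohort(gt, n_subjects = 2, n_volumes = 269, seed = 7)
  cms <- lapply(co$subjects, function(ts)
    wavelet_correlation(modwt(ts, max_scale = 2), scales = 2)[[1]])
  cm <- group_average(cms)
  mods <- gt$module_assignment
  same <- outer(mods, mods, `==`) & upper.tri(cm$r)
  diff_ <- !outer(mods, mods, `==`) & upper.tri(cm$r)
  expect_gt(mean(cm$r[same]), mean(cm$r[diff_]) + 0.05)
})

test_that("zero-variance parcels are reported, not silently zeroed", {
  x <- cbind(a = rnorm(128), b = rep(1, 128))
  d <- modwt(x, max_scale = 2)
  expect_warning(cms <- wavelet_correlation(d, scales = 1),
                 "zero-variance")
  expect_true(is.na(cms[[1]]$r["a", "b"]))
  expect_equal(cms[[1]]$r["b", "b"], 1)
})

test_that("correlation p-values match the t-transform and a permutation null", {
  cm <- correlation_matrix(matrix(c(1, 0.5, 0.5, 1), 2), n_usable = 100)
  p <- correlation_pvalues(cm)
  expect_equal(p$effective_df, 98)
  # permutation oracle: distribution of |r| between permuted unit-norm
  # vectors with true r = 0.5 observed
  set.seed(42)
  x <- rnorm(100)
  y <- 0.5 * scale(x)[, 1] + sqrt(0.75) * rnorm(100)
  r_obs <- cor(x, y)
  perm <- replicate(10000, cor(x, sample(y)))
  p_perm <- mean(abs(perm) >= abs(r_obs))
  cm2 <- correlation_matrix(matrix(c(1, r_obs, r_obs, 1), 2), n_usable = 100)
  p_t <- correlation_pvalues(cm2)$p[1, 2]
  expect_lt(abs(p_t - p_perm), 3 * sqrt(p_t * (1 - p_t) / 10000) + 2e-4)
})

test_that("p-values decrease monotonically in |r| and hit the exact endpoints", {
  rs <- seq(0, 0.99, by = 0.01)
  ps <- sapply(rs, function(r) {
    cm <- correlation_matrix(matrix(c(1, r, r, 1), 2), n_usable = 50)
    correlation_pvalues(cm)$p[1, 2]
  })
  expect_true(all(diff(ps) < 0))
  expect_equal(ps[1], 1)
  cm1 <- correlation_matrix(matrix(c(1, 1, 1, 1), 2), n_usable = 50)
  expect_equal(correlation_pvalues(cm1)$p[1, 2], 0)
})

test_that("group averaging is the entrywise mean and rejects mixed scales", {
  r1 <- matrix(c(1, 0.2, 0.2, 1), 2)
  r2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  cm1 <- correlation_matrix(r1, scale = 2, n_usable = 100)
  cm2 <- correlation_matrix(r2, scale = 2, n_usable = 120)
  avg <- group_average(list(cm1, cm2))
  expect_equal(avg$r[1, 2], 0.3)
  expect_equal(avg$n_usable, 100L)           # conservative minimum
  expect_identical(group_average(list(cm1))$r, cm1$r)
  cm3 <- correlation_matrix(r2, scale = 3, n_usable = 100)
  expect_error(group_average(list(cm1, cm3)), "scale")
})

test_that("averaging subjects shrinks off-diagonal sampling variance", {
  at <- toy_atlas(3)   # 12 parcels keeps this cheap
  gt <- make_ground_truth(at, n_modules = 2, within_r = 0.4,
                          between_r = 0.1, seed = 2)
  spread <- sapply(1:20, function(s) {
    co <- simulate_cohort(gt, n_subjects = 5, n_volumes = 150,
                          noise_sd = 1, seed = s)
    cms <- lapply(co$subjects, function(ts)
      wavelet_correlation(modwt(ts, max_scale = 1), scales = 1)[[1]])
    grp <- group_average(cms)
    err_single <- cms[[1]]$r - gt$covariance
    err_group <- grp$r - gt$covariance
    c(single = stats::var(err_single[upper.tri(err_single)]),
      group = stats::var(err_group[upper.tri(err_group)]))
  })
  expect_lt(mean(spread["group", ]), mean(spread["single", ]))
})
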
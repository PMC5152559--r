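test_that("one module with zero correlation gives the identity covariance", {
  at <- toy_atlas(2)
  gt <- make_ground_truth(at, n_modules = 1, within_r = 0, between_r = 0,
                          seed = 1)
  expect_equal(unname(gt$covariance), diag(nrow(at)))
})

test_that("equal within/between correlation is module-label invariant", {
  at <- toy_atlas(2)
  g1 <- make_ground_truth(at, n_modules = 2, within_r = 0.3,
                          between_r = 0.3, seed = 1)
  g2 <- make_ground_truth(at, n_modules = 4, within_r = 0.3,
                          between_r = 0.3, seed = 1)
  expect_equal(g1$covariance, g2$covariance)
})

test_that("block ground truth has unit diagonal, PSD spectrum and block values", {
  at <- default_atlas()
  gt <- make_ground_truth(at, n_modules = 4, within_r = 0.5,
                          between_r = 0.1, seed = 1)
  s <- gt$covariance
  expect_equal(unname(diag(s)), rep(1, 116))
  expect_equal(s, t(s))
  expect_gte(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  mods <- gt$module_assignment
  same <- outer(mods, mods, `==`) & upper.tri(s)
  expect_equal(unique(round(s[same], 10)), 0.5)
  expect_equal(unique(round(s[!outer(mods, mods, `==`) & upper.tri(s)], 10)),
               0.1)
})

test_that("thresholded ground-truth covariance is more clustered than its rewired null", {
  at <- default_atlas()
  gt <- make_ground_truth(at, n_modules = 4, within_r = 0.5,
                          between_r = 0.1, seed = 1)
  cm <- correlation_matrix(gt$covariance, scale = 1, n_usable = 1000)
  net <- threshold_network(cm)
  expect_true(is_admissible(net))
  sw <- small_world_summary(net, n_nulls = 10, seed = 4)
  expect_gt(sw$gamma, 1)
})

test_that("cohort simulation is seed-deterministic and shape-faithful", {
  at <- toy_atlas(2)
  gt <- make_ground_truth(at, 2, 0.4, 0.1, seed = 1)
  c1 <- simulate_cohort(gt, n_subjects = 3, n_volumes = 100, seed = 9)
  c2 <- simulate_cohort(gt, n_subjects = 3, n_volumes = 100, seed = 9)
  expect_identical(lapply(c1$subjects, unclass),
                   lapply(c2$subjects, unclass))
  c3 <- simulate_cohort(gt, n_subjects = 3, n_volumes = 100, seed = 10)
  expect_false(identical(unclass(c1$subjects[[1]]),
                         unclass(c3$subjects[[1]])))
  # study-sized cohort
  c4 <- simulate_cohort(gt, n_subjects = 5, n_volumes = 269,
                        tr_seconds = 2.42, seed = 1)
  expect_length(c4$subjects, 5)
  expect_equal(dim(c4$subjects[[1]]), c(269, nrow(at)))
  expect_equal(attr(c4$subjects[[1]], "tr_seconds"), 2.42)
  expect_error(simulate_cohort(gt, n_volumes = 30, seed = 1), "scale 3")
})

test_that("noise-free sample correlations converge to the ground truth", {
  at <- toy_atlas(2)
  gt <- make_ground_truth(at, 2, within_r = 0.5, between_r = 0.1, seed = 1)
  co <- simulate_cohort(gt, n_subjects = 1, n_volumes = 4000, noise_sd = 0,
                        ar_coef = 0, seed = 21)
  r <- cor(unclass(co$subjects[[1]]))
  se <- (1 - 0.5^2) / sqrt(4000)
  same <- outer(gt$module_assignment, gt$module_assignment, `==`) &
    upper.tri(r)
  expect_lt(max(abs(r[same] - 0.5)), 3 * se + 0.02)
  # Frobenius distance decreases with series length
  co_short <- simulate_cohort(gt, 1, n_volumes = 269, noise_sd = 0,
                              ar_coef = 0, seed = 22)
  co_long <- simulate_cohort(gt, 1, n_volumes = 2690, noise_sd = 0,
                             ar_coef = 0, seed = 22)
  fro <- function(c_) norm(cor(unclass(c_$subjects[[1]])) - gt$covariance,
                           "F")
  expect_lt(fro(co_long), fro(co_short))
})

test_that("lesion attenuation scales covariance rows and preserves PSD", {
  at <- toy_atlas(2)
  gt <- make_ground_truth(at, 2, 0.5, 0.1, seed = 1)
  same <- apply_lesion(gt, parcels = c(2, 4), attenuation = 1)
  expect_equal(same$covariance, gt$covariance)
  dead <- apply_lesion(gt, parcels = c(2, 4), attenuation = 0)
  expect_equal(unname(dead$covariance[2, -2]), rep(0, nrow(at) - 1))
  expect_equal(dead$covariance[2, 2], 1)
  part <- apply_lesion(gt, parcels = 2, attenuation = 0.3)
  expect_equal(part$covariance[2, 3], 0.3 * gt$covariance[2, 3])
  expect_gte(min(eigen(part$covariance, TRUE, TRUE)$values), -1e-10)
  expect_error(apply_lesion(gt, parcels = 999), "999")
})

test_that("lesioned parcels lose thresholded degree against their homologs", {
  at <- default_atlas()
  gt <- make_ground_truth(at, 4, 0.5, 0.1, seed = 1)
  lesion <- at$id[at$hemisphere == "r" & at$lobe == "parietal"]
  homologs <- at$homolog_id[match(lesion, at$id)]
  gt_l <- apply_lesion(gt, lesion, attenuation = 0.3)
  co <- simulate_cohort(gt_l, n_subjects = 2, n_volumes = 269, seed = 3)
  cms <- lapply(co$subjects, function(ts)
    wavelet_correlation(modwt(ts, max_scale = 2), scales = 2)[[1]])
  net <- threshold_network(group_average(cms), parcel_ids = at$id)
  deg <- node_degree(net)
  expect_lt(mean(deg[match(lesion, at$id)]),
            mean(deg[match(homologs, at$id)]))
})

test_that("null graph generators honour exact size and kind", {
  g <- make_null_graph("random", 116, 551, seed = 1)
  expect_equal(g$m, 551L)
  expect_equal(mean(node_degree(g)), 2 * 551 / 116)  # 9.5
  sf <- make_null_graph("scale_free", 116, 551, seed = 2)
  expect_equal(sf$m, 551L)
  expect_gt(max(node_degree(sf)), max(node_degree(g)))  # hubs exist
  tp <- make_null_graph("truncated_power_law", 116, 551, seed = 3)
  expect_equal(tp$m, 551L)
  # saturation: complete graph regardless of kind
  for (kind in c("random", "scale_free", "truncated_power_law")) {
    k <- make_null_graph(kind, 8, 28, seed = 4)
    expect_equal(unname(k$adjacency), 1L - diag(8L))
  }
  # degree-preserving rewiring when a reference sequence is supplied
  ref <- node_degree(sf)
  rw <- make_null_graph("random", 116, 551,
                        params = list(degree_sequence = ref), seed = 5)
  expect_equal(sort(node_degree(rw)), sort(ref))
  expect_error(make_null_graph("random", 4, 3,
                               params = list(degree_sequence = c(3, 3, 3, 2)),
                               seed = 1), "degree sequence")
})

test_that("cohort writer round-trips through the timeseries reader", {
  at <- toy_atlas(2)
  gt <- make_ground_truth(at, 2, 0.4, 0.1, seed = 1)
  co <- simulate_cohort(gt, n_subjects = 2, n_volumes = 60, seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  ts <- read_timeseries(file.path(dir, "sub-01.tsv"), tr_seconds = 2.42)
  expect_equal(unname(unclass(ts)), unname(unclass(co$subjects[[1]])),
               tolerance = 1e-12)
  side <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(side$seed, 2)
})
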
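test_that("z-scoring standardizes each trial vector across voxels", {
  x <- rbind(c(1, 2, 3), c(5, 5, 8))
  z <- znorm(x)
  expect_equal(rowMeans(z), c(0, 0))
  expect_equal(apply(z, 1, sd), c(1, 1))
  expect_equal(z[1, ], c(-1, 0, 1))
  expect_equal(znorm(z), z, tolerance = 1e-12)   # idempotent
  expect_error(znorm(rbind(c(2, 2, 2))), "constant")
  expect_error(znorm(matrix(1:3, 3, 1)), "2 voxels")
})

test_that("leave-one-run-out decoding separates noiseless patterns and
           reports analytic chance", {
  ss <- scenes24()
  st <- generate_voxel_patterns(ss, n_subjects = 1, n_runs = 4,
                                reps_per_run = 1, n_voxels = 20,
                                effect_weights = c(scene = 1, category = 0,
                                                   depth = 0),
                                noise_sd = 0, seed = 2, rois = "occluded")
  v <- subset_patterns(st$subjects[[1]], roi = "occluded_V1")
  r <- loro_decode(v, "scene")
  expect_equal(r$mean_accuracy, 1)
  expect_equal(r$chance_level, 1 / 24)
  expect_equal(round(100 * r$chance_level, 2), 4.17)
  expect_length(r$accuracy_per_fold, 4)

  expect_equal(loro_decode(v, "category")$chance_level, 1 / 6)
  expect_equal(loro_decode(v, "depth")$chance_level, 1 / 2)
})

test_that("signal-free patterns decode at chance within the binomial band", {
  ss <- generate_scene_set(6, 3, seed = 51)
  accs <- vapply(1:8, function(k) {
    st <- generate_voxel_patterns(ss, n_subjects = 1, n_runs = 2,
                                  reps_per_run = 2, n_voxels = 20,
                                  effect_weights = c(scene = 0, category = 0,
                                                     depth = 0),
                                  noise_sd = 1, seed = 60 + k,
                                  rois = "occluded")
    loro_decode(subset_patterns(st$subjects[[1]], roi = "occluded_V1"),
                "scene")$mean_accuracy
  }, numeric(1))
  n_trials <- 8 * 24   # trials scored across seeds
  band <- 1.96 * sqrt((1 / 6) * (5 / 6) / n_trials)
  expect_lt(abs(mean(accs) - 1 / 6), band)
})

test_that("run-wise folds never mix train and test trials", {
  v <- signal_patterns()
  runs <- sort(unique(v$run_of_trial))
  for (r in runs) {
    tr <- which(v$run_of_trial != r)
    te <- which(v$run_of_trial == r)
    expect_length(intersect(tr, te), 0)
    expect_setequal(c(tr, te), seq_len(nrow(v$betas)))
  }
  # every class present in every training fold of the fixture
  for (r in runs)
    expect_equal(length(unique(v$scene_of_trial[v$run_of_trial != r])), 24)
})

test_that("permutation nulls center on chance and reach the attainable
           minimum p under strong signal", {
  v <- signal_patterns()
  pt <- permutation_test(v, "depth", n_perm = 39, seed = 11)
  expect_equal(mean(pt$null_accuracies), 0.5,
               tolerance = 3 * sd(pt$null_accuracies) / sqrt(39) + 0.02)
  expect_equal(pt$chance_level, 0.5)

  # strongly separable data: observed beats every shuffle
  ss <- generate_scene_set(6, 3, seed = 52)
  st <- generate_voxel_patterns(ss, n_subjects = 1, n_runs = 2,
                                reps_per_run = 2, n_voxels = 16,
                                effect_weights = c(scene = 3, category = 0,
                                                   depth = 0),
                                noise_sd = 0.1, seed = 3, rois = "occluded")
  v2 <- subset_patterns(st$subjects[[1]], roi = "occluded_V1")
  pt2 <- permutation_test(v2, "scene", n_perm = 19, seed = 4)
  expect_equal(pt2$p_value, 1 / 20)
  expect_error(permutation_test(v2, "scene", n_perm = 0), "at least 1")
})

test_that("cross-classification holds out one scene per group and
           generalizes category signal to unseen scenes", {
  v <- signal_patterns()
  cc <- cross_classify(v, "category", n_iter = 3, seed = 1)
  expect_equal(attr(cc, "n_train_scenes"), 18)
  cd <- cross_classify(v, "depth", n_iter = 3, seed = 1)
  expect_equal(attr(cd, "n_train_scenes"), 22)

  # category-only signal (no shared-exemplar component) still transfers
  ss <- scenes24()
  st <- generate_voxel_patterns(ss, n_subjects = 1, n_runs = 4,
                                reps_per_run = 2, n_voxels = 40,
                                effect_weights = c(scene = 0, category = 2,
                                                   depth = 0),
                                noise_sd = 1, seed = 6, rois = "occluded")
  vc <- subset_patterns(st$subjects[[1]], roi = "occluded_V1")
  ccx <- cross_classify(vc, "category", n_iter = 5, seed = 2)
  expect_gt(ccx$mean_accuracy, 1 / 6 + 0.1)
})

test_that("group-level signed-rank test matches exact enumeration", {
  at_chance <- 1 / 24 + c(-0.02, -0.011, -0.015, 0.005, 0.009, 0.002)
  expect_gte(group_test(at_chance, 1 / 24), 0.5)
  # all five subjects above chance: minimal attainable p = 1 / 2^5
  expect_equal(group_test(c(0.3, 0.31, 0.29, 0.4, 0.35), 0.25), 1 / 32)
  set.seed(9)
  for (n in c(6, 8, 10)) {
    x <- 0.25 + rnorm(n, 0.02, 0.05)
    expect_equal(group_test(x, 0.25), exact_signed_rank_p(x, 0.25))
  }
  expect_error(group_test(c(0.3, 0.3, 0.3, 0.3), 0.25), "at least 5")
  expect_error(group_test(rep(0.25, 6), 0.25), "at chance")
})
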
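test_that("LDC matches hand arithmetic with identity covariance and is
           unbiased under the null", {
  # two voxels, hand-set pattern differences (1,0) and (2,0)
  betas_A <- rbind(c(1, 0), c(0, 0))
  betas_B <- rbind(c(2, 0), c(0, 0))
  r <- ldc_rdm(betas_A, c(1, 2), betas_B, c(1, 2), identity_cov = TRUE)
  expect_equal(as.numeric(r), 1)
  expect_length(r, 1)

  ss <- scenes24()
  st <- generate_voxel_patterns(ss, n_subjects = 1, n_runs = 4,
                                reps_per_run = 2, n_voxels = 30,
                                noise_sd = 2, seed = 5, rois = "occluded")
  v <- subset_patterns(st$subjects[[1]], roi = "occluded_V1")
  full <- scenefeedback:::half_ldc(v, list(c(1, 2), c(3, 4)))
  expect_length(full, 276)

  # null: same generating pattern for both conditions, noise only
  set.seed(8)
  sims <- replicate(500, {
    bA <- matrix(rnorm(8 * 6), 8); bB <- matrix(rnorm(8 * 6), 8)
    as.numeric(ldc_rdm(bA, rep(1:2, 4), bB, rep(1:2, 4)))
  })
  expect_lt(abs(mean(sims)), 2 * sd(sims) / sqrt(500))

  # positivity in expectation when a true difference exists
  sims_sig <- replicate(200, {
    mu <- rep(c(0, 1), 4)
    bA <- matrix(rnorm(8 * 6), 8) + mu; bB <- matrix(rnorm(8 * 6), 8) + mu
    as.numeric(ldc_rdm(bA, rep(1:2, 4), bB, rep(1:2, 4)))
  })
  expect_gt(mean(sims_sig), 0)
  expect_error(ldc_rdm(betas_A, c(1, 1), betas_B, c(1, 2)), "both halves")
})

test_that("split-quarter enumeration yields all ordered half choices", {
  sp8 <- enumerate_splits(8)
  expect_length(sp8, 70)
  expect_length(enumerate_splits(4), 6)
  for (sp in sp8) {
    expect_length(intersect(sp$fit_half, sp$test_half), 0)
    expect_setequal(c(sp$fit_half, sp$test_half), 1:8)
    expect_setequal(unlist(sp$fit_quarters), sp$fit_half)
    expect_equal(lengths(sp$fit_quarters), c(2, 2))
  }
  # ordered: both (H, complement) and (complement, H) occur
  keys <- vapply(sp8, function(sp) paste(sort(sp$fit_half), collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0)
  expect_true(all(vapply(sp8, function(sp)
    paste(sort(sp$test_half), collapse = ",") %in% keys, logical(1))))
  expect_error(enumerate_splits(6), "divisible by 4")
})

test_that("kendall tau-a equals brute-force pair counting including ties", {
  expect_equal(kendall_tau_a(1:5, 1:5), 1)
  expect_equal(kendall_tau_a(1:5, 5:1), -1)
  set.seed(10)
  for (n in c(4, 8, 12)) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(kendall_tau_a(x, y), brute_tau_a(x, y))
    xt <- sample(1:3, n, replace = TRUE)   # heavy ties
    yt <- sample(1:3, n, replace = TRUE)
    expect_equal(kendall_tau_a(xt, yt), brute_tau_a(xt, yt))
  }
  # ties stay in the denominator: constant y gives 0, not NA
  expect_equal(kendall_tau_a(1:4, rep(1, 4)), 0)
  expect_error(kendall_tau_a(1:3, 1:4), "same length")
})

test_that("leave-one-pair-out NNLS recovers synthesis weights and clamps
           anti-correlated channels to zero", {
  set.seed(12)
  ch1 <- new_rdm(runif(276), 24)
  ch2 <- new_rdm(runif(276), 24)
  target <- new_rdm(2 * as.numeric(ch1) + 3 * as.numeric(ch2), 24)
  pred <- nnls_fit_predict(list(ch1, ch2), target)
  W <- attr(pred, "weights")
  expect_lt(max(abs(W[, 1] - 2)), 1e-4)
  expect_lt(max(abs(W[, 2] - 3)), 1e-4)
  expect_lt(max(abs(as.numeric(pred) - as.numeric(target))), 1e-4)

  # perfect single-channel model reproduces itself
  pred1 <- nnls_fit_predict(list(ch1), ch1)
  expect_lt(max(abs(as.numeric(pred1) - as.numeric(ch1))), 1e-6)

  # anti-correlated channel is driven to the non-negativity boundary
  anti <- new_rdm(max(as.numeric(ch1)) - as.numeric(ch1), 24)
  pred_a <- nnls_fit_predict(list(anti), ch1)
  expect_equal(max(attr(pred_a, "weights")), 0)
  # intercept-only predictions: each entry is its fit subset's mean, so the
  # spread collapses relative to the target RDM
  expect_lt(diff(range(as.numeric(pred_a))),
            0.1 * diff(range(as.numeric(ch1))))

  expect_error(nnls_fit_predict(list(new_rdm(1:3, 3)), new_rdm(1:3, 3)),
               "fewer than 2")
})

test_that("model evaluation is cross-validated over split plans and ranks a
           true model above an irrelevant one", {
  set.seed(14)
  feat <- rnorm(8, sd = 2)
  v <- patterns_from_feature(feat, n_runs = 4, noise_sd = 0.2, seed = 3)
  true_ch <- model_channel_rdms(new_feature_matrix(matrix(feat, ncol = 1)))
  rand_ch <- model_channel_rdms(new_feature_matrix(matrix(rnorm(8), ncol = 1)))
  ev_true <- evaluate_model(v, true_ch, identity_cov = TRUE)
  ev_rand <- evaluate_model(v, rand_ch, identity_cov = TRUE)
  expect_length(ev_true$tau_a_per_split, 6)
  expect_gt(ev_true$mean_tau_a, 0.5)
  expect_gt(ev_true$mean_tau_a, ev_rand$mean_tau_a)

  # zero-signal data hovers near zero correlation
  taus <- vapply(1:5, function(k) {
    v0 <- patterns_from_feature(rep(0, 8), n_runs = 4, noise_sd = 1,
                                seed = 100 + k)
    evaluate_model(v0, true_ch, identity_cov = TRUE)$mean_tau_a
  }, numeric(1))
  expect_lt(abs(mean(taus)), 2 * sd(taus) / sqrt(5) + 0.05)
})

test_that("noise ceilings bracket subject self-consistency", {
  same <- replicate(5, new_rdm(1:10, 5), simplify = FALSE)
  nc <- noise_ceiling(same)
  expect_equal(unname(nc), c(1, 1))

  set.seed(15)
  for (k in 1:100) {
    rdms <- replicate(4, rnorm(15), simplify = FALSE)
    nck <- noise_ceiling(rdms)
    expect_lte(nck["lower"], nck["upper"] + 1e-12)
  }
  # independent random RDMs: both bounds near zero
  set.seed(16)
  big <- replicate(18, rnorm(45), simplify = FALSE)
  ncb <- noise_ceiling(big)
  expect_lt(abs(ncb["upper"]), 0.25)
  expect_error(noise_ceiling(list(1:3)), "at least 2")
})

test_that("sliding-bin comparison produces n - k + 1 bins and textbook BY
           correction", {
  # 24 scenes, bin 8 -> 17 bins of C(8,2) = 28 pairs
  set.seed(17)
  feat <- rnorm(24)
  models <- list(
    true = model_channel_rdms(new_feature_matrix(matrix(feat, ncol = 1))),
    rand = model_channel_rdms(new_feature_matrix(matrix(rnorm(24), ncol = 1))))
  patterns <- lapply(1:5, function(s)
    patterns_from_feature(feat, n_runs = 4, noise_sd = 0.4, seed = 20 + s))
  res <- binned_model_comparison(order(rnorm(24)), models, patterns,
                                 bin_size = 8,
                                 splits = enumerate_splits(4)[1:2],
                                 identity_cov = TRUE)
  expect_length(res$bins, 17)
  expect_true(all(lengths(res$bins) == 8))
  expect_equal(dim(res$tau), c(17, 2, 5))
  expect_length(res$p_adj, 17)
  expect_true(all(res$p_adj >= res$p_raw - 1e-12))
  # true model wins on average
  expect_gt(mean(res$tau[, "true", ]), mean(res$tau[, "rand", ]))

  # BY correction equals the hand formula on a printed toy p-vector
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216,
         0.222, 0.251, 0.269, 0.275, 0.34, 0.341, 0.384, 0.569, 0.594, 0.696,
         0.762, 0.94, 0.942, 0.975, 0.986)
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  by_hand <- rev(cummin(rev(pmin(1, cm * m * sort(p) / seq_len(m)))))
  expect_equal(p.adjust(sort(p), method = "BY"), by_hand)
  expect_error(binned_model_comparison(1:6, models, patterns, bin_size = 8),
               "bin_size")
})
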
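test_that("average drawings are scaled jointly across the scene set", {
  ss <- generate_scene_set(4, 2, seed = 61)
  ds <- generate_drawings(ss, 1, 0.8, seed = 1)
  avg <- average_drawings(ds)
  # single observer: a rescaled copy of that drawing
  expect_equal(avg[[1]] > 0, ds$strokes[, , 1, 1] > 0)
  expect_equal(max(vapply(avg, max, numeric(1))), 1)
  expect_equal(min(vapply(avg, min, numeric(1))), 0)

  # overlap darkens: two observers agreeing on a pixel beat one observer
  d2 <- generate_drawings(ss, 2, 1, seed = 2)     # identical pair
  d1 <- d2; d1$strokes[, , , 2] <- 0L             # second observer blank
  a2 <- average_drawings(d2); a1 <- average_drawings(d1)
  drawn <- d2$strokes[, , 1, 1] == 1
  expect_true(all(a2[[1]][drawn] >= a1[[1]][drawn]))
})

test_that("area-average downsampling preserves mean stroke mass", {
  set.seed(62)
  m <- matrix(rbinom(96 * 128, 1, 0.2), 96, 128)
  d <- downsample_raster(m, c(24, 32))
  expect_equal(dim(d), c(24, 32))
  expect_equal(mean(d), mean(m), tolerance = 0.01)
  expect_error(downsample_raster(m, c(25, 32)), "integer multiples")
})

test_that("split-half consistency is capped at identity, near zero for
           independent drawings, and monotone in the generator", {
  ss <- generate_scene_set(4, 2, seed = 63)
  ident <- generate_drawings(ss, 8, 1, seed = 3)
  res <- drawing_consistency(ident, n_resamples = 5, seed = 1)
  expect_equal(res$per_scene_mean_fisher_z, rep(atanh(0.999999), 4))
  expect_equal(res$per_scene_mean_r, rep(1, 4), tolerance = 1e-5)
  # Fisher-mean inverse lies within the per-resample r range by construction
  expect_true(all(res$per_scene_mean_r <= 1 & res$per_scene_mean_r >= -1))

  # fully independent rasters (uniform pixel noise, no shared spatial
  # density profile): split-half correlation centers on zero
  set.seed(4)
  indep <- generate_drawings(ss, 20, 0, seed = 4)
  indep$strokes[] <- rbinom(length(indep$strokes), 1, 0.15)
  res0 <- drawing_consistency(indep, n_resamples = 60, seed = 2)
  se <- sd(res0$per_scene_mean_r) / sqrt(4)
  expect_lt(abs(mean(res0$per_scene_mean_r)), 2 * se + 0.1)

  levels <- c(0.2, 0.6, 0.95)
  est <- vapply(levels, function(cons) {
    ds <- generate_drawings(ss, 12, cons, seed = 5)
    mean(drawing_consistency(ds, n_resamples = 30,
                             seed = 3)$per_scene_mean_r)
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_error(drawing_consistency(generate_drawings(ss, 3, 0.5, seed = 1)),
               "at least 4")
})

test_that("predictability scores are rater-shift invariant and rank by the
           mean z-score", {
  r1 <- rbind(1:6, 1:6 + 0.5)
  p1 <- predictability(r1)
  expect_equal(p1$rank_order, 6:1)
  # adding a constant to one rater changes nothing
  r2 <- r1; r2[2, ] <- r2[2, ] + 3
  expect_equal(predictability(r2)$per_scene_z, p1$per_scene_z)
  expect_error(predictability(rbind(rep(4, 6), 1:6)), "zero-variance")
  expect_error(predictability(matrix(1:6, 1)), "at least 2")
})

test_that("consistency-decodability correlation detects a planted coupling
           and refuses tiny groups", {
  set.seed(64)
  cons <- structure(list(per_scene_mean_fisher_z = seq(0.2, 1.2,
                                                       length.out = 24),
                         per_scene_mean_r = tanh(seq(0.2, 1.2,
                                                     length.out = 24)),
                         n_resamples = 100),
                    class = "consistency_result")
  # decodability proportional to consistency plus subject noise
  ldc <- t(replicate(18, cons$per_scene_mean_fisher_z * 0.5 +
                       rnorm(24, sd = 0.2)))
  res <- consistency_vs_decodability(cons, ldc)
  expect_length(res$per_subject_r, 18)
  expect_lt(res$group_p, 0.05)

  # independent quantities: median p over replicates is not extreme
  ps <- vapply(1:10, function(k) {
    ldc0 <- matrix(rnorm(18 * 24), 18)
    consistency_vs_decodability(cons, ldc0)$group_p
  }, numeric(1))
  expect_gt(median(ps), 0.1)

  expect_warning(consistency_vs_decodability(cons, ldc[1, , drop = FALSE]),
                 "fewer than 5")
  expect_error(consistency_vs_decodability(cons, ldc[, 1:10]), "do not match")
})

test_that("the mixed-effects consistency slope recovers planted effects", {
  set.seed(65)
  n_sub <- 10; n_bin <- 17
  x <- rep(seq(0.2, 0.9, length.out = n_bin), n_sub)
  subj <- rep(seq_len(n_sub), each = n_bin)
  slope_s <- 0.8 + rnorm(n_sub, sd = 0.1)
  y <- slope_s[subj] * x + rnorm(n_sub * n_bin, sd = 0.05)
  fit <- consistency_slope_model(y, x, subj)
  expect_gt(fit$t, 2)
  expect_lt(fit$p, 0.05)
  expect_equal(fit$slope, 0.8, tolerance = 0.15)

  # zero planted slope: |t| typically small
  ts <- vapply(1:10, function(k) {
    y0 <- rnorm(n_sub * n_bin, sd = 0.2)
    abs(suppressWarnings(consistency_slope_model(y0, x, subj))$t)
  }, numeric(1))
  expect_lt(median(ts), 2)

  # single subject falls back to ordinary regression with a warning
  expect_warning(
    f1 <- consistency_slope_model(y[subj == 1], x[subj == 1],
                                  rep(1, n_bin)),
    "single subject")
  expect_true(is.finite(f1$p))
})
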
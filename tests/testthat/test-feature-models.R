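test_that("gist descriptor has the expected dimensionality and degenerate
           behavior", {
  img <- matrix(runif(64 * 64), 64)
  g <- gist_descriptor(img)
  expect_length(g, 512)   # 16 blocks x 8 orientations x 4 scales
  expect_true(all(is.finite(g)))

  # constant image: no bandpass energy relative to a grating
  flat <- gist_descriptor(matrix(0.5, 64, 64))
  x <- matrix(rep(1:64, each = 64), 64)
  grat <- gist_descriptor(0.5 + 0.5 * sin(2 * pi * 0.1 * x))
  expect_lt(max(flat), 1e-6 * max(grat))

  expect_error(gist_descriptor(1:10), "2-D")
})

test_that("a grating at a bank frequency drives its orientation channel in
           every block", {
  f_c <- exp(seq(log(0.02), log(0.3), length.out = 4))
  x <- matrix(rep(1:128, each = 128), 128)
  g <- gist_descriptor(0.5 + 0.5 * sin(2 * pi * f_c[3] * x))
  a <- array(g, dim = c(16, 8, 4))   # block, orientation, scale
  # at the matching scale, channel 1 (variation along x) wins in all blocks
  expect_equal(apply(a[, , 3], 1, which.max), rep(1L, 16))
})

test_that("rotating an image by 90 degrees permutes gist orientation
           channels", {
  set.seed(1)
  img <- matrix(runif(96 * 96), 96)
  rot90 <- function(m) t(m)[nrow(m):1, ]   # counter-clockwise
  g0 <- array(gist_descriptor(img), dim = c(16, 8, 4))      # block, o, scale
  g1 <- array(gist_descriptor(rot90(img)), dim = c(16, 8, 4))
  # orientation o -> o + 4 (mod 8); the block grid rotates with the image,
  # so the multiset of block energies per channel is preserved exactly
  for (o in 1:8) {
    o2 <- (o + 3) %% 8 + 1
    for (s in 1:4)
      expect_equal(sort(g1[, o2, s]), sort(g0[, o, s]), tolerance = 1e-6)
  }
})

test_that("weibull fitting recovers parameters and scales equivariantly", {
  set.seed(1)
  x <- rweibull(1e5, shape = 2, scale = 1)
  img <- matrix(0.5, 20, 20)   # the fit path, not the image path
  fit <- scenefeedback:::fit_weibull_ml(x)
  expect_equal(unname(fit["beta"]), 1, tolerance = 0.02)
  expect_equal(unname(fit["gamma"]), 2, tolerance = 0.02)

  # contrast scaling moves beta proportionally, gamma unchanged
  ss <- scenes24()
  im <- scene_quadrant_images(ss, hidden = TRUE)[[3]]
  masks <- weibull_region_masks(nrow(im), ncol(im), radii_deg = c(1.5, 5),
                                deg_per_px = ss$deg_per_px,
                                fixation = "top_left")
  expect_length(masks, 2)
  s1 <- weibull_stats(im, masks)
  expect_equal(dim(s1), c(2, 2))
  s2 <- weibull_stats(0.5 + 0.5 * (im - 0.5), masks)  # contrast halved
  expect_equal(unname(s2[, "beta"] / s1[, "beta"]), c(0.5, 0.5),
               tolerance = 0.02)
  expect_equal(unname(s2[, "gamma"]), unname(s1[, "gamma"]),
               tolerance = 0.02)

  expect_error(weibull_stats(matrix(0.7, 40, 40),
                             list(all = matrix(TRUE, 40, 40))),
               "degenerate")
})

test_that("hmax C2 responses peak at 1 for contained prototypes and are
           translation invariant", {
  ss <- scenes24()
  bag <- scene_quadrant_images(generate_scene_set(6, 3, seed = 77),
                               hidden = TRUE)
  protos <- learn_prototypes(bag, 12, seed = 1)
  expect_length(protos$patches, 12)
  protos_b <- learn_prototypes(bag, 12, seed = 1)
  expect_identical(protos$patches, protos_b$patches)
  # prototypes come from the held-out bag, not the evaluated scene set
  expect_true(all(protos$meta$source_image %in% seq_along(bag)))

  img <- scene_quadrant_images(ss, hidden = TRUE)[[5]]
  c2_self <- hmax_c2(img, learn_prototypes(list(img), 4, seed = 3))
  expect_equal(c2_self, rep(1, 4))   # zero RBF distance to own patches

  c2 <- hmax_c2(img, protos)
  expect_length(c2, 12)
  expect_true(all(c2 > 0 & c2 <= 1))

  # global max pooling: shifting the image content by one C1 stride leaves
  # responses for interior patches nearly unchanged
  sh <- protos$params$c1_stride_px[1]
  img_shift <- img[, c((sh + 1):ncol(img), 1:sh)]
  c2s <- hmax_c2(img_shift, protos)
  expect_gt(cor(c2, c2s), 0.95)

  expect_error(hmax_c2(img, list()), "non-empty")
})

test_that("category model RDM is binary with the exact within/between
           counts", {
  ss <- scenes24()
  r <- category_model_rdm(ss$category_labels)
  expect_length(r, 276)
  expect_equal(sum(r == 0), 36)    # 6 * choose(4, 2)
  expect_equal(sum(r == 1), 240)
  expect_true(all(as.numeric(category_model_rdm(rep("a", 5))) == 0))
  expect_true(all(as.numeric(category_model_rdm(letters[1:5])) == 1))
})

test_that("depth model reproduces closed-form means and CLT bootstrap
           spread", {
  ratings <- cbind(scene1 = rep(10, 8), scene2 = rep(100, 8))
  dm <- depth_model(ratings, n_boot = 50, seed = 1)
  expect_equal(dm$distribution$mean_log10_m, c(1, 2))
  expect_equal(as.numeric(dm$rdm), 1)
  expect_equal(ncol(dm$feature_matrix), 1)

  set.seed(4)
  r2 <- matrix(10 ^ rnorm(10 * 3, 2, 0.5), 10, 3)
  dm2 <- depth_model(r2, n_boot = 1000, seed = 2)
  expected_se <- apply(log10(r2), 2, sd) / sqrt(10)
  expect_equal(dm2$distribution$sd_log10_m, expected_se, tolerance = 0.15)

  expect_error(depth_model(cbind(c(1, -1), c(2, 2))), "positive")
})

test_that("per-channel squared-Euclidean RDMs match hand arithmetic", {
  fm <- new_feature_matrix(matrix(c(0, 1, 3), ncol = 1), "toy")
  r <- model_channel_rdms(fm)
  expect_length(r, 1)
  expect_equal(as.numeric(r[[1]]), c(1, 9, 4))

  fm2 <- new_feature_matrix(cbind(a = c(0, 1, 3), b = rep(2, 3)))
  r2 <- model_channel_rdms(fm2)
  expect_length(r2, 2)
  expect_equal(as.numeric(r2$b), rep(0, 3))   # constant channel

  m24 <- new_feature_matrix(matrix(rnorm(24 * 5), 24))
  expect_length(model_channel_rdms(m24), 5)
  expect_length(model_channel_rdms(m24)[[1]], 276)

  expect_error(new_feature_matrix(matrix(c(1, NA), 1)), "non-finite")
})

test_that("gist split-half reliability is 1 for identical observers and
           rises with consistency", {
  ss <- generate_scene_set(4, 2, seed = 31)
  ds1 <- generate_drawings(ss, 6, 1, seed = 1)
  rel1 <- gist_split_half_reliability(ds1, n_splits = 3, seed = 1,
                                      n_blocks = 2, n_orientations = 4,
                                      n_scales = 2)
  expect_equal(rel1, rep(1, 4), tolerance = 1e-10)

  rel_lo <- gist_split_half_reliability(
    generate_drawings(ss, 14, 0.2, seed = 2), n_splits = 8, seed = 1,
    n_blocks = 2, n_orientations = 4, n_scales = 2)
  rel_hi <- gist_split_half_reliability(
    generate_drawings(ss, 14, 0.9, seed = 2), n_splits = 8, seed = 1,
    n_blocks = 2, n_orientations = 4, n_scales = 2)
  expect_gt(mean(rel_hi), mean(rel_lo))
})
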
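# shared fixtures, built once per test run

.fixtures <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

scenes24 <- function() fixture("scenes24", function()
  generate_scene_set(24, 6, seed = 42))

# a small signal-bearing study: 1 subject, 4 runs, occluded V1 only
signal_patterns <- function() fixture("signal_patterns", function() {
  st <- generate_voxel_patterns(scenes24(), n_subjects = 1, n_runs = 4,
                                reps_per_run = 2, n_voxels = 60,
                                noise_sd = 2, seed = 7, rois = "occluded")
  subset_patterns(st$subjects[[1]], roi = "occluded_V1")
})

# brute-force exact one-sided signed-rank p-value by sign enumeration
exact_signed_rank_p <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- signs %*% r
  mean(w >= obs)
}

# brute-force tau-a by explicit double loop
brute_tau_a <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
  s / (n * (n - 1) / 2)
}

# patterns whose scene-pair pattern distances realize a target 1-D feature:
# scene i's mean pattern is feature[i] * direction, repeated over runs with
# small noise, so the squared-distance RDM is proportional to the feature's
# channel RDM
patterns_from_feature <- function(feature, n_runs = 4, n_voxels = 30,
                                  noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  ns <- length(feature)
  direction <- rnorm(n_voxels)
  direction <- direction / sqrt(sum(direction^2))
  scene_of_trial <- rep(seq_len(ns), n_runs)
  run_of_trial <- rep(seq_len(n_runs), each = ns)
  betas <- outer(feature[scene_of_trial], direction) +
    matrix(rnorm(length(scene_of_trial) * n_voxels, sd = noise_sd),
           ncol = n_voxels)
  colnames(betas) <- paste0("v", seq_len(n_voxels))
  info <- data.frame(voxel_id = paste0("v", seq_len(n_voxels)),
                     roi = "occluded_V1", position = "occluded", area = "V1",
                     x_deg = 1, y_deg = -1, sigma_deg = 0.1)
  new_voxel_pattern_set(betas, scene_of_trial, run_of_trial, info)
}
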
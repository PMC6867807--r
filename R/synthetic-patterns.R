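#' Generate synthetic voxel beta patterns with planted representational
#' structure
#'
#' For each subject, every voxel carries three latent components drawn once
#' per subject: a scene-specific vector `u_s`, a category vector `c_k` and a
#' depth gain `g`. The beta of a trial showing scene s at voxel v is
#'
#'   `gain_roi * (w_scene * u_s[v] + w_category * c_cat(s)[v]
#'                + w_depth * d(s) * g[v]) + N(0, noise_sd)`
#'
#' where `d(s)` is +1 for Far and -1 for Near scenes and `gain_roi` scales
#' the planted signal per ROI position. Occluded-ROI voxels default to a
#' fraction of the non-occluded signal so that decoding from the occluded
#' ROI is above chance yet clearly weaker than from stimulated cortex, the
#' qualitative ordering the analysis is designed to detect.
#'
#' Every scene appears exactly `reps_per_run` times in every run. Voxel pRFs
#' are sampled uniformly inside their ROI's quadrant with a `2 * sigma`
#' containment margin, so all generated voxels pass the pRF containment
#' filter at `k_sigma = 2`.
#'
#' @param scene_set a `scene_set`.
#' @param n_subjects,n_runs,reps_per_run design sizes (all >= 1).
#' @param n_voxels voxels per ROI.
#' @param effect_weights named numeric `c(scene=, category=, depth=)`.
#' @param noise_sd trial noise SD (>= 0).
#' @param seed integer RNG seed.
#' @param rois character vector of ROI positions to simulate, from
#'   `c("occluded", "nonoccluded_upper", "nonoccluded_lower")`; each is
#'   generated for areas V1 and V2.
#' @param occluded_gain multiplier on planted signal in occluded ROIs.
#' @param sigma_range range of pRF sigma (degrees).
#' @return object of class `pattern_study`: list with `subjects` (list of
#'   `voxel_pattern_set`) and `ground_truth` (per-subject latent components
#'   and the generating weights).
#' @export
generate_voxel_patterns <- function(scene_set, n_subjects = 18, n_runs = 8,
                                    reps_per_run = 2, n_voxels = 200,
                                    effect_weights = c(scene = 1,
                                                       category = 0.5,
                                                       depth = 0.5),
                                    noise_sd = 3, seed = 1,
                                    rois = c("occluded", "nonoccluded_upper",
                                             "nonoccluded_lower"),
                                    occluded_gain = 0.35,
                                    sigma_range = c(0.3, 1)) {
  if (min(n_subjects, n_runs, reps_per_run, n_voxels) < 1)
    stop("all design counts must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  rois <- match.arg(rois, several.ok = TRUE)
  stopifnot(all(c("scene", "category", "depth") %in% names(effect_weights)))
  set.seed(seed)

  ns <- n_scenes(scene_set)
  K <- nlevels(scene_set$category_labels)
  d_scalar <- ifelse(scene_set$depth_labels == "Far", 1, -1)
  occ <- scene_set$occluder_quadrant
  vert <- if (grepl("lower", occ)) sub("lower", "upper", occ)
          else sub("upper", "lower", occ)
  horiz <- if (grepl("right", occ)) sub("right", "left", occ)
           else sub("left", "right", occ)
  # the two non-occluded control ROIs are the vertically and horizontally
  # adjacent quadrants of the occluder
  roi_quadrant <- c(occluded = occ, nonoccluded_upper = vert,
                    nonoccluded_lower = horiz)

  areas <- c("V1", "V2")
  subjects <- vector("list", n_subjects)
  truth <- vector("list", n_subjects)

  for (sub in seq_len(n_subjects)) {
    # voxel metadata across all ROIs
    info <- do.call(rbind, lapply(rois, function(pos) {
      do.call(rbind, lapply(areas, function(a) {
        qb <- quadrant_bounds(roi_quadrant[[pos]], scene_set$field_of_view)
        sig <- stats::runif(n_voxels, sigma_range[1], sigma_range[2])
        data.frame(
          position = pos, area = a, roi = paste(pos, a, sep = "_"),
          sigma_deg = sig,
          x_deg = stats::runif(n_voxels, qb["xmin"] + 2 * sig,
                               qb["xmax"] - 2 * sig),
          y_deg = stats::runif(n_voxels, qb["ymin"] + 2 * sig,
                               qb["ymax"] - 2 * sig)
        )
      }))
    }))
    nv <- nrow(info)
    info$voxel_id <- paste0("v", seq_len(nv))
    gain <- ifelse(info$position == "occluded", occluded_gain, 1)

    u <- matrix(stats::rnorm(ns * nv), ns, nv)    # scene-specific
    cc <- matrix(stats::rnorm(K * nv), K, nv)     # category
    g <- stats::rnorm(nv)                         # depth gain

    # balanced trial order: each run a shuffled concatenation of reps
    scene_of_trial <- unlist(lapply(seq_len(n_runs), function(r)
      sample(rep(seq_len(ns), reps_per_run))), use.names = FALSE)
    run_of_trial <- rep(seq_len(n_runs), each = ns * reps_per_run)
    ntr <- length(scene_of_trial)

    signal <- effect_weights["scene"] * u[scene_of_trial, , drop = FALSE] +
      effect_weights["category"] *
        cc[as.integer(scene_set$category_labels)[scene_of_trial], ,
           drop = FALSE] +
      effect_weights["depth"] *
        outer(d_scalar[scene_of_trial], g)
    betas <- sweep(signal, 2, gain, "*") +
      matrix(stats::rnorm(ntr * nv, sd = noise_sd), ntr, nv)
    colnames(betas) <- info$voxel_id

    subjects[[sub]] <- new_voxel_pattern_set(
      betas = betas, scene_of_trial = scene_of_trial,
      run_of_trial = run_of_trial, voxel_info = info,
      category_of_trial = scene_set$category_labels[scene_of_trial],
      depth_of_trial = scene_set$depth_labels[scene_of_trial],
      subject_id = paste0("sub", sub))
    truth[[sub]] <- list(scene_vectors = u, category_vectors = cc,
                         depth_gain = g)
  }

  structure(list(
    subjects = subjects,
    ground_truth = list(per_subject = truth,
                        effect_weights = effect_weights,
                        noise_sd = noise_sd, occluded_gain = occluded_gain,
                        depth_scalar = d_scalar)
  ), class = "pattern_study")
}

#' Construct a voxel pattern set
#'
#' @param betas trial x voxel numeric matrix.
#' @param scene_of_trial integer scene index per trial.
#' @param run_of_trial integer run index per trial.
#' @param voxel_info data.frame with one row per voxel: `voxel_id`, `roi`,
#'   `position`, `area`, `x_deg`, `y_deg`, `sigma_deg`.
#' @param category_of_trial,depth_of_trial factors per trial (optional but
#'   required for category/depth decoding).
#' @param subject_id identifier.
#' @return object of class `voxel_pattern_set`.
#' @export
new_voxel_pattern_set <- function(betas, scene_of_trial, run_of_trial,
                                  voxel_info, category_of_trial = NULL,
                                  depth_of_trial = NULL,
                                  subject_id = "sub1") {
  stopifnot(nrow(betas) == length(scene_of_trial),
            nrow(betas) == length(run_of_trial),
            ncol(betas) == nrow(voxel_info),
            !anyNA(betas))
  structure(list(betas = betas, scene_of_trial = as.integer(scene_of_trial),
                 run_of_trial = as.integer(run_of_trial),
                 voxel_info = voxel_info,
                 category_of_trial = category_of_trial,
                 depth_of_trial = depth_of_trial,
                 subject_id = subject_id),
            class = "voxel_pattern_set")
}

#' @export
print.voxel_pattern_set <- function(x, ...) {
  cat(sprintf(
    "voxel_pattern_set %s: %d trials x %d voxels, %d runs, ROIs: %s\n",
    x$subject_id, nrow(x$betas), ncol(x$betas), max(x$run_of_trial),
    paste(unique(x$voxel_info$roi), collapse = ", ")))
  invisible(x)
}

#' Restrict a voxel pattern set to selected voxels and/or trials
#'
#' @param vps a `voxel_pattern_set`.
#' @param roi optional ROI label (matched against `voxel_info$roi`).
#' @param voxel_ids optional explicit voxel ids.
#' @param runs optional run subset.
#' @param scenes optional scene subset.
#' @return a `voxel_pattern_set`.
#' @export
subset_patterns <- function(vps, roi = NULL, voxel_ids = NULL, runs = NULL,
                            scenes = NULL) {
  keep_v <- rep(TRUE, ncol(vps$betas))
  if (!is.null(roi)) keep_v <- keep_v & vps$voxel_info$roi %in% roi
  if (!is.null(voxel_ids)) keep_v <- keep_v & vps$voxel_info$voxel_id %in% voxel_ids
  keep_t <- rep(TRUE, nrow(vps$betas))
  if (!is.null(runs)) keep_t <- keep_t & vps$run_of_trial %in% runs
  if (!is.null(scenes)) keep_t <- keep_t & vps$scene_of_trial %in% scenes
  new_voxel_pattern_set(
    betas = vps$betas[keep_t, keep_v, drop = FALSE],
    scene_of_trial = vps$scene_of_trial[keep_t],
    run_of_trial = vps$run_of_trial[keep_t],
    voxel_info = vps$voxel_info[keep_v, , drop = FALSE],
    category_of_trial = vps$category_of_trial[keep_t],
    depth_of_trial = vps$depth_of_trial[keep_t],
    subject_id = vps$subject_id)
}

#' Trial labels for a given decoding target
#' @param vps a `voxel_pattern_set`.
#' @param label_type `"scene"`, `"category"` or `"depth"`.
#' @return factor of per-trial labels.
#' @export
trial_labels <- function(vps, label_type = c("scene", "category", "depth")) {
  label_type <- match.arg(label_type)
  switch(label_type,
    scene = factor(vps$scene_of_trial),
    category = {
      if (is.null(vps$category_of_trial)) stop("no category labels attached")
      factor(vps$category_of_trial)
    },
    depth = {
      if (is.null(vps$depth_of_trial)) stop("no depth labels attached")
      factor(vps$depth_of_trial)
    })
}
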
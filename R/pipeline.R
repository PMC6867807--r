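#' Build a run configuration
#'
#' Collects every knob of an end-to-end run in one serializable list. A run
#' is reproducible from its config alone. The defaults are a single-command
#' demo profile sized for a desk-scale check on one CPU: 6 subjects, 4 runs,
#' 200 voxels per ROI, 50 HMAX prototypes and 200 permutations.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param n_scenes,n_categories,n_subjects,n_runs,reps_per_run,n_voxels
#'   design sizes.
#' @param n_observers,drawing_consistency drawing generator settings
#'   (`drawing_consistency` may be a per-scene vector).
#' @param n_depth_raters,n_predictability_raters rater counts.
#' @param effect_weights,noise_sd,occluded_gain pattern generator settings.
#' @param n_permutations permutation-null shuffles in the decoding stage.
#' @param n_prototypes HMAX prototype count.
#' @param n_consistency_resamples split-half resamples for drawing
#'   consistency.
#' @param analyses character subset of `c("decode", "rsa", "behavior")`.
#' @param models feature models evaluated in the RSA stage.
#' @param roi ROI used for decoding and RSA.
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_scenes = 24, n_categories = 6,
                       n_subjects = 6, n_runs = 4, reps_per_run = 2,
                       n_voxels = 200, n_observers = 47,
                       drawing_consistency = seq(0.95, 0.35,
                                                 length.out = n_scenes),
                       n_depth_raters = 10, n_predictability_raters = 27,
                       effect_weights = c(scene = 1, category = 0.5,
                                          depth = 0.5),
                       noise_sd = 3, occluded_gain = 0.35,
                       n_permutations = 200, n_prototypes = 50,
                       n_consistency_resamples = 200,
                       analyses = c("decode", "rsa", "behavior"),
                       models = c("gist", "category"),
                       roi = "occluded_V1", out_dir = tempfile("sfb_run_")) {
  cfg <- as.list(environment())
  cfg$analyses <- match.arg(analyses, several.ok = TRUE)
  class(cfg) <- "run_config"
  cfg
}

#' Save / load a run configuration as JSON
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$effect_weights <- as.list(cfg$effect_weights)  # keep names in JSON
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$effect_weights <- unlist(raw$effect_weights)
  cfg <- do.call(run_config, raw[setdiff(names(raw), character(0))])
  cfg
}

#' Run the end-to-end synthetic experiment
#'
#' Executes the enabled stages in dependency order: generate scenes,
#' drawings, ratings and voxel patterns; decode scene/category/depth with
#' leave-one-run-out SVMs (plus a permutation null for the scene labels of
#' subject 1); evaluate feature models against LDC RDMs by cross-validated
#' NNLS; and run the behavioral consistency analyses. All tables are written
#' under `config$out_dir` together with a manifest recording the config, its
#' hash and the package version.
#'
#' @param config a `run_config`.
#' @return (invisibly) the report bundle: a list with elements `config`,
#'   `data`, and one element per executed stage.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- list(config = config)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  bundle$data <- stage("generate", {
    scenes <- generate_scene_set(config$n_scenes, config$n_categories,
                                 seed = config$seed)
    drawings <- generate_drawings(scenes, config$n_observers,
                                  config$drawing_consistency,
                                  seed = config$seed + 1)
    depth_ratings <- generate_depth_ratings(scenes, config$n_depth_raters,
                                            seed = config$seed + 2)
    pred_ratings <- generate_predictability_ratings(
      drawings, scenes, config$n_predictability_raters,
      seed = config$seed + 3)
    study <- generate_voxel_patterns(
      scenes, n_subjects = config$n_subjects, n_runs = config$n_runs,
      reps_per_run = config$reps_per_run, n_voxels = config$n_voxels,
      effect_weights = config$effect_weights, noise_sd = config$noise_sd,
      seed = config$seed + 4, occluded_gain = config$occluded_gain)
    write_scene_set(scenes, file.path(config$out_dir, "scenes"))
    list(scenes = scenes, drawings = drawings,
         depth_ratings = depth_ratings, pred_ratings = pred_ratings,
         study = study)
  })
  dat <- bundle$data
  roi_patterns <- lapply(dat$study$subjects, subset_patterns,
                         roi = config$roi)

  if ("decode" %in% config$analyses) {
    bundle$decode <- stage("decode", {
      per_label <- lapply(c(scene = "scene", category = "category",
                            depth = "depth"), function(lt) {
        acc <- vapply(roi_patterns, function(v)
          loro_decode(v, lt)$mean_accuracy, numeric(1))
        chance <- switch(lt, scene = 1 / config$n_scenes,
                         category = 1 / config$n_categories, depth = 0.5)
        list(per_subject = acc,
             group_p = if (length(acc) >= 5) group_test(acc, chance)
                       else NA_real_)
      })
      perm <- permutation_test(roi_patterns[[1]], "scene",
                               n_perm = config$n_permutations,
                               seed = config$seed + 5)
      tab <- data.frame(
        label_type = rep(names(per_label),
                         each = length(roi_patterns)),
        subject = rep(seq_along(roi_patterns), 3),
        accuracy = unlist(lapply(per_label, `[[`, "per_subject")))
      utils::write.table(tab, file.path(config$out_dir, "decoding.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      list(per_label = per_label, permutation = perm, table = tab)
    })
  }

  if ("rsa" %in% config$analyses) {
    bundle$rsa <- stage("rsa", {
      hidden_imgs <- scene_quadrant_images(dat$scenes, hidden = TRUE)
      avg_draw <- average_drawings(dat$drawings)
      model_rdms <- list()
      if ("gist" %in% config$models)
        model_rdms$gist <- model_channel_rdms(compute_features(
          avg_draw, "gist", n_blocks = 2, n_orientations = 4, n_scales = 2))
      if ("category" %in% config$models)
        model_rdms$category <- list(category_model_rdm(
          dat$scenes$category_labels))
      if ("depth" %in% config$models)
        model_rdms$depth <- list(depth_model(dat$depth_ratings,
                                             seed = config$seed + 6)$rdm)
      if ("hmax" %in% config$models) {
        # prototypes come from a held-out synthetic scene set, never the
        # evaluated scenes
        bag <- scene_quadrant_images(
          generate_scene_set(config$n_scenes, config$n_categories,
                             seed = config$seed + 7), hidden = TRUE)
        protos <- learn_prototypes(bag, config$n_prototypes,
                                   seed = config$seed + 8)
        model_rdms$hmax <- model_channel_rdms(compute_features(
          hidden_imgs, "hmax", prototypes = protos))
      }
      splits <- enumerate_splits(config$n_runs)
      tau <- sapply(names(model_rdms), function(m)
        vapply(roi_patterns, function(v)
          evaluate_model(v, model_rdms[[m]], splits)$mean_tau_a, numeric(1)))
      tau <- matrix(tau, ncol = length(model_rdms),
                    dimnames = list(NULL, names(model_rdms)))
      subj_rdms <- lapply(roi_patterns, function(v)
        half_ldc(v, list(seq(1, config$n_runs, 2), seq(2, config$n_runs, 2))))
      nc <- noise_ceiling(subj_rdms)
      utils::write.table(
        data.frame(subject = seq_len(nrow(tau)), tau),
        file.path(config$out_dir, "rsa_tau.tsv"), sep = "\t",
        row.names = FALSE, quote = FALSE)
      list(tau = tau, noise_ceiling = nc, model_rdms = model_rdms,
           subject_rdms = subj_rdms)
    })
  }

  if ("behavior" %in% config$analyses) {
    bundle$behavior <- stage("behavior", {
      cons <- drawing_consistency(dat$drawings,
                                  n_resamples = config$n_consistency_resamples,
                                  seed = config$seed + 9)
      pred <- predictability(dat$pred_ratings)
      ldc_means <- if (!is.null(bundle$rsa))
        do.call(rbind, lapply(bundle$rsa$subject_rdms, rdm_condition_means))
      else do.call(rbind, lapply(roi_patterns, function(v)
        rdm_condition_means(half_ldc(v, list(seq(1, config$n_runs, 2),
                                             seq(2, config$n_runs, 2))))))
      cvd <- consistency_vs_decodability(cons, ldc_means)
      utils::write.table(
        data.frame(scene = seq_along(cons$per_scene_mean_r),
                   consistency_r = cons$per_scene_mean_r,
                   consistency_z = cons$per_scene_mean_fisher_z,
                   predictability_z = pred$per_scene_z),
        file.path(config$out_dir, "behavior.tsv"), sep = "\t",
        row.names = FALSE, quote = FALSE)
      list(consistency = cons, predictability = pred,
           consistency_vs_decodability = cvd, ldc_means = ldc_means)
    })
  }

  cfg_path <- file.path(config$out_dir, "config.json")
  write_config(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("scenefeedback")),
    r_version = as.character(getRversion()),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    stages = config$analyses,
    outputs = list.files(config$out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  bundle$manifest <- manifest
  invisible(bundle)
}

#' Summary figures and CSV tables for a report bundle
#'
#' Writes, for each executed analysis: per-ROI decoding accuracy
#' distributions, model-comparison bars with the noise ceiling, and the
#' consistency/predictability profile, as PNG figures with CSV companions.
#'
#' @param bundle result of [run_experiment()].
#' @param dir output directory (defaults to the bundle's `out_dir`).
#' @return character vector of files written.
#' @export
make_figures <- function(bundle, dir = bundle$config$out_dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  add <- function(p) written <<- c(written, p)

  if (!is.null(bundle$decode)) {
    tab <- bundle$decode$table
    chance <- data.frame(label_type = c("scene", "category", "depth"),
                         chance = c(1 / bundle$config$n_scenes,
                                    1 / bundle$config$n_categories, 0.5))
    p <- ggplot2::ggplot(tab, ggplot2::aes(x = label_type, y = accuracy)) +
      ggplot2::geom_jitter(width = 0.1, height = 0) +
      ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
      ggplot2::geom_errorbar(data = chance,
                             ggplot2::aes(y = NULL, ymin = chance,
                                          ymax = chance),
                             linetype = 2) +
      ggplot2::labs(y = "decoding accuracy", x = NULL)
    f <- file.path(dir, "decoding.png")
    ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 120); add(f)
    cf <- file.path(dir, "decoding_summary.csv")
    utils::write.csv(stats::aggregate(accuracy ~ label_type, tab, mean), cf,
                     row.names = FALSE); add(cf)
  }

  if (!is.null(bundle$rsa)) {
    tau <- bundle$rsa$tau
    df <- data.frame(model = rep(colnames(tau), each = nrow(tau)),
                     tau_a = as.vector(tau))
    nc <- bundle$rsa$noise_ceiling
    p <- ggplot2::ggplot(df, ggplot2::aes(x = model, y = tau_a)) +
      ggplot2::stat_summary(fun = mean, geom = "col") +
      ggplot2::geom_jitter(width = 0.1, height = 0) +
      ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = nc["lower"],
                        ymax = nc["upper"], alpha = 0.3) +
      ggplot2::labs(y = "Kendall tau-a", x = NULL)
    f <- file.path(dir, "model_comparison.png")
    ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 120); add(f)
    cf <- file.path(dir, "model_comparison.csv")
    utils::write.csv(stats::aggregate(tau_a ~ model, df, mean), cf,
                     row.names = FALSE); add(cf)
  }

  if (!is.null(bundle$behavior)) {
    cons <- bundle$behavior$consistency
    df <- data.frame(scene = seq_along(cons$per_scene_mean_r),
                     consistency = cons$per_scene_mean_r,
                     predictability = bundle$behavior$predictability$per_scene_z)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = predictability,
                                          y = consistency)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "predictability (z)",
                    y = "drawing consistency (split-half r)")
    f <- file.path(dir, "consistency.png")
    ggplot2::ggsave(f, p, width = 5, height = 4, dpi = 120); add(f)
    cf <- file.path(dir, "consistency.csv")
    utils::write.csv(df, cf, row.names = FALSE); add(cf)
  }
  written
}
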
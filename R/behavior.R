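#' Average line drawings across observers
#'
#' Pixelwise mean over observers per scene, followed by a single min-max
#' scaling applied jointly across the whole scene set (not per scene), so
#' that relative darkness between scenes is preserved: lines drawn by many
#' observers are darker than idiosyncratic ones.
#'
#' @param drawing_set a `drawing_set` with at least 1 observer.
#' @return list of grayscale matrices in `[0, 1]`, one per scene.
#' @export
average_drawings <- function(drawing_set) {
  d <- dim(drawing_set$strokes)
  if (is.null(d) || d[4] < 1) stop("drawing set has no observers")
  avgs <- lapply(seq_len(d[3]), function(s)
    apply(drawing_set$strokes[, , s, , drop = FALSE], c(1, 2), mean))
  lo <- min(vapply(avgs, min, numeric(1)))
  hi <- max(vapply(avgs, max, numeric(1)))
  if (hi == lo) stop("all drawings identical and constant: cannot scale")
  lapply(avgs, function(m) (m - lo) / (hi - lo))
}

#' Area-average (box filter) downsampling of a raster
#'
#' @param m numeric matrix whose dimensions are integer multiples of `size`.
#' @param size target `c(rows, cols)`.
#' @return downsampled matrix; block averaging preserves the mean pixel
#'   value exactly.
#' @export
downsample_raster <- function(m, size) {
  if (nrow(m) %% size[1] != 0 || ncol(m) %% size[2] != 0)
    stop("raster dimensions must be integer multiples of the target size")
  fr <- nrow(m) / size[1]; fc <- ncol(m) / size[2]
  ri <- rep(seq_len(size[1]), each = fr)
  ci <- rep(seq_len(size[2]), each = fc)
  out <- rowsum(t(rowsum(m, ri)), ci) / (fr * fc)
  t(out)
}

#' Split-half consistency of line drawings
#'
#' Per resample, observers are split at random into two subgroups of sizes
#' `floor(n/2)` and `ceiling(n/2)` (23/24 for 47 observers); drawings are
#' downsampled (area averaging, default 24 x 32), averaged within subgroup,
#' and the two subgroup-average drawings of each scene are correlated
#' (Pearson). Correlations are Fisher z-transformed (with `|r|` capped at
#' 0.999999 so identical drawings do not produce infinities) and averaged
#' over resamples.
#'
#' @param drawing_set a `drawing_set` with at least 4 observers.
#' @param n_resamples number of random splits.
#' @param downsample target raster size `c(rows, cols)`.
#' @param seed integer RNG seed.
#' @param r_cap cap on `|r|` before the Fisher transform.
#' @return object of class `consistency_result`: `per_scene_mean_fisher_z`,
#'   `per_scene_mean_r` (inverse transform of the mean z), `n_resamples`.
#' @export
drawing_consistency <- function(drawing_set, n_resamples = 1000,
                                downsample = c(24, 32), seed = 1,
                                r_cap = 0.999999) {
  d <- dim(drawing_set$strokes)
  n_obs <- d[4]; ns <- d[3]
  if (n_obs < 4) stop("need at least 4 observers for split-half consistency")
  small <- lapply(seq_len(ns), function(s)
    lapply(seq_len(n_obs), function(o)
      downsample_raster(drawing_set$strokes[, , s, o], downsample)))
  set.seed(seed)
  z <- matrix(NA_real_, n_resamples, ns)
  for (rs in seq_len(n_resamples)) {
    half1 <- sample(n_obs, floor(n_obs / 2))
    for (s in seq_len(ns)) {
      m1 <- Reduce(`+`, small[[s]][half1]) / length(half1)
      m2 <- Reduce(`+`, small[[s]][-half1]) / (n_obs - length(half1))
      if (stats::sd(as.vector(m1)) == 0 || stats::sd(as.vector(m2)) == 0)
        stop("constant raster in a subgroup average for scene ", s)
      r <- stats::cor(as.vector(m1), as.vector(m2))
      z[rs, s] <- atanh(pmin(pmax(r, -r_cap), r_cap))
    }
  }
  mz <- colMeans(z)
  structure(list(per_scene_mean_fisher_z = mz,
                 per_scene_mean_r = tanh(mz),
                 n_resamples = n_resamples),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("consistency_result: %d scenes, mean r %.3f (%d resamples)\n",
              length(x$per_scene_mean_r), mean(x$per_scene_mean_r),
              x$n_resamples))
  invisible(x)
}

#' Predictability scores from 1..7 match ratings
#'
#' Ratings are z-scored within each rater (removing rater-specific mean and
#' spread) and averaged across raters; scenes are ranked from most to least
#' predictable.
#'
#' @param ratings rater x scene numeric matrix (at least 2 raters).
#' @return object of class `predictability_scores`: `per_scene_z`,
#'   `rank_order` (scene indices, most predictable first).
#' @export
predictability <- function(ratings) {
  if (nrow(ratings) < 2) stop("need at least 2 raters")
  sds <- apply(ratings, 1, stats::sd)
  if (any(sds == 0)) stop("zero-variance rater cannot be z-scored")
  z <- t(scale(t(ratings)))
  per_scene <- colMeans(z)
  structure(list(per_scene_z = per_scene,
                 rank_order = order(per_scene, decreasing = TRUE)),
            class = "predictability_scores")
}

#' Correlate drawing consistency with per-scene decodability
#'
#' Per-scene decodability for one subject is the mean LDC of that scene to
#' all other scenes (row mean of the square-form LDC RDM). For each subject
#' the Pearson correlation across scenes between drawing consistency and
#' decodability is computed, and a one-sided Wilcoxon signed-rank test asks
#' whether the per-subject correlations are above zero at the group level.
#'
#' @param consistency a `consistency_result`.
#' @param per_scene_ldc_by_subject subject x scene matrix of mean LDC values
#'   (e.g. rows of [rdm_condition_means()] per subject).
#' @return list with `per_subject_r` and `group_p` (NA with a warning when
#'   fewer than 5 subjects).
#' @export
consistency_vs_decodability <- function(consistency,
                                        per_scene_ldc_by_subject) {
  cons <- consistency$per_scene_mean_fisher_z
  m <- as.matrix(per_scene_ldc_by_subject)
  if (ncol(m) != length(cons))
    stop("scene sets of consistency and LDC summaries do not match")
  rs <- apply(m, 1, function(row) stats::cor(row, cons))
  if (nrow(m) < 5) {
    warning("fewer than 5 subjects: group-level signed-rank test not run")
    return(list(per_subject_r = rs, group_p = NA_real_))
  }
  p <- stats::wilcox.test(rs, mu = 0, alternative = "greater",
                          exact = TRUE)$p.value
  list(per_subject_r = rs, group_p = p)
}

#' Mixed-effects slope of model advantage on drawing consistency
#'
#' Fits `performance_difference ~ consistency + (consistency | subject)`:
#' a fixed slope of the per-bin model performance difference on per-bin
#' drawing consistency with a random intercept and slope per subject.
#' Returns the fixed-slope t statistic and p-value (Satterthwaite df). With
#' a single subject the model degenerates to an ordinary regression (with a
#' warning).
#'
#' @param per_bin_perf_difference numeric vector (bins x subjects,
#'   flattened or as given).
#' @param per_bin_consistency numeric vector aligned with the above.
#' @param subject_ids subject identifier per observation.
#' @return list with `slope`, `t`, `p`, `singular` (logical).
#' @export
consistency_slope_model <- function(per_bin_perf_difference,
                                    per_bin_consistency, subject_ids) {
  df <- data.frame(y = as.numeric(per_bin_perf_difference),
                   x = as.numeric(per_bin_consistency),
                   subject = factor(subject_ids))
  if (length(unique(df$x)) < 2 || nrow(df) < 4)
    stop("need at least 2 distinct consistency values and 4 observations")
  if (nlevels(df$subject) < 2) {
    warning("single subject: falling back to ordinary least squares")
    fit <- stats::lm(y ~ x, data = df)
    sm <- summary(fit)$coefficients
    return(list(slope = sm["x", "Estimate"], t = sm["x", "t value"],
                p = sm["x", "Pr(>|t|)"], singular = FALSE))
  }
  fit <- lmerTest::lmer(y ~ x + (x | subject), data = df,
                        control = lme4::lmerControl(
                          check.conv.singular = lme4::.makeCC(
                            action = "ignore", tol = 1e-4)))
  sm <- stats::coef(summary(fit))
  list(slope = sm["x", "Estimate"], t = sm["x", "t value"],
       p = sm["x", "Pr(>|t|)"],
       singular = lme4::isSingular(fit))
}
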
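#' Generate synthetic observer line drawings of the occluded quadrant
#'
#' Each scene has a latent stroke template (a set of line segments in the
#' occluded quadrant). An observer's drawing keeps each template stroke
#' independently with probability `consistency` and adds a Poisson number of
#' idiosyncratic strokes with mean `extra_rate * (1 - consistency)`. At
#' `consistency = 1` every observer reproduces the template exactly, so all
#' drawings of a scene are identical; lower consistency lowers the split-half
#' correlation of subgroup-average drawings.
#'
#' @param scene_set a `scene_set`; drawings cover its occluded quadrant.
#' @param n_observers number of observers.
#' @param consistency scalar or per-scene vector in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param n_template_strokes strokes in each scene's template.
#' @param extra_rate mean idiosyncratic strokes per drawing at consistency 0.
#' @param stroke_width_px half-width of the rasterized pen stroke.
#' @return object of class `drawing_set`: `strokes` is a 4-d binary array
#'   `[row, col, scene, observer]`; plus `observer_ids`, `scene_ids`,
#'   `consistency` (per scene, as used).
#' @export
generate_drawings <- function(scene_set, n_observers, consistency, seed,
                              n_template_strokes = 12, extra_rate = 4,
                              stroke_width_px = 1) {
  if (any(consistency < 0 | consistency > 1))
    stop("consistency must lie in [0, 1]")
  ns <- n_scenes(scene_set)
  consistency <- rep_len(consistency, ns)
  set.seed(seed)

  qp <- quadrant_pixels(scene_set$height_px, scene_set$width_px,
                        scene_set$occluder_quadrant)
  h <- length(qp$rows); w <- length(qp$cols)

  templates <- lapply(seq_len(ns), function(s)
    replicate(n_template_strokes, random_segment(h, w), simplify = FALSE))

  strokes <- array(0L, dim = c(h, w, ns, n_observers))
  for (s in seq_len(ns)) {
    for (o in seq_len(n_observers)) {
      keep <- stats::runif(n_template_strokes) < consistency[s]
      segs <- templates[[s]][keep]
      n_extra <- stats::rpois(1, extra_rate * (1 - consistency[s]))
      if (n_extra > 0)
        segs <- c(segs, replicate(n_extra, random_segment(h, w),
                                  simplify = FALSE))
      strokes[, , s, o] <- rasterize_segments(segs, h, w, stroke_width_px)
    }
  }

  structure(list(
    strokes = strokes,
    observer_ids = paste0("obs", seq_len(n_observers)),
    scene_ids = paste0("scene", seq_len(ns)),
    consistency = consistency,
    height_px = h, width_px = w
  ), class = "drawing_set")
}

#' @export
print.drawing_set <- function(x, ...) {
  d <- dim(x$strokes)
  cat(sprintf("drawing_set: %d observers x %d scenes, %d x %d px rasters\n",
              d[4], d[3], d[1], d[2]))
  invisible(x)
}

random_segment <- function(h, w) {
  c(r0 = stats::runif(1, 1, h), c0 = stats::runif(1, 1, w),
    r1 = stats::runif(1, 1, h), c1 = stats::runif(1, 1, w))
}

# binary raster union of line segments with a square pen of given half-width
rasterize_segments <- function(segments, h, w, width_px = 1) {
  img <- matrix(0L, h, w)
  for (seg in segments) {
    len <- max(abs(seg["r1"] - seg["r0"]), abs(seg["c1"] - seg["c0"]), 1)
    t <- seq(0, 1, length.out = ceiling(len) * 2 + 1)
    rr <- round(seg["r0"] + t * (seg["r1"] - seg["r0"]))
    cc <- round(seg["c0"] + t * (seg["c1"] - seg["c0"]))
    for (dr in -width_px:width_px) for (dc in -width_px:width_px) {
      r2 <- pmin(pmax(rr + dr, 1), h)
      c2 <- pmin(pmax(cc + dc, 1), w)
      img[cbind(r2, c2)] <- 1L
    }
  }
  img
}

#' Generate rater depth estimates for each scene
#'
#' Ratings are lognormal around each scene's latent true depth: Near scenes
#' center near 10 m and Far scenes near 1000 m on a log10 scale, with
#' per-scene spread and independent rater noise.
#'
#' @param scene_set a `scene_set` (supplies Near/Far labels).
#' @param n_raters number of raters (at least 2).
#' @param seed integer RNG seed.
#' @param scene_sd SD of true per-scene log10 depth around its class center.
#' @param rater_sd SD of rater noise in log10 units.
#' @return numeric matrix raters x scenes, strictly positive (meters).
#' @export
generate_depth_ratings <- function(scene_set, n_raters, seed,
                                   scene_sd = 0.25, rater_sd = 0.2) {
  if (n_raters < 2) stop("need at least 2 raters")
  set.seed(seed)
  ns <- n_scenes(scene_set)
  center <- ifelse(scene_set$depth_labels == "Near", 1, 3)  # log10 meters
  true_log <- stats::rnorm(ns, center, scene_sd)
  log_r <- matrix(stats::rnorm(n_raters * ns, sd = rater_sd),
                  n_raters, ns, byrow = FALSE)
  log_r <- sweep(log_r, 2, true_log, "+")
  m <- 10 ^ log_r
  dimnames(m) <- list(paste0("rater", seq_len(n_raters)),
                      paste0("scene", seq_len(ns)))
  m
}

#' Generate predictability ratings of average line drawings
#'
#' Raters score how well a scene's average drawing matches the hidden scene
#' on a 1..7 scale. Scores are positively coupled to the generator's per-scene
#' drawing consistency: the expected score is `1 + 6 * consistency`, with
#' independent rater noise, rounded and clamped to 1..7.
#'
#' @param drawing_set a `drawing_set` (supplies per-scene consistency).
#' @param scene_set the matching `scene_set`.
#' @param n_raters number of raters (at least 2).
#' @param seed integer RNG seed.
#' @param rater_sd SD of rater noise on the 1..7 scale; 0 makes all raters
#'   identical.
#' @return integer matrix raters x scenes with values in 1..7.
#' @export
generate_predictability_ratings <- function(drawing_set, scene_set, n_raters,
                                            seed, rater_sd = 0.8) {
  if (n_raters < 2) stop("need at least 2 raters")
  ns <- n_scenes(scene_set)
  stopifnot(length(drawing_set$consistency) == ns)
  set.seed(seed)
  mu <- 1 + 6 * drawing_set$consistency
  sc <- matrix(stats::rnorm(n_raters * ns, sd = rater_sd), n_raters, ns)
  sc <- sweep(sc, 2, mu, "+")
  m <- matrix(as.integer(pmin(pmax(round(sc), 1), 7)), n_raters, ns)
  dimnames(m) <- list(paste0("rater", seq_len(n_raters)),
                      paste0("scene", seq_len(ns)))
  m
}
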
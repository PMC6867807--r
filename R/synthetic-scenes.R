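#' Generate a synthetic occluded scene set
#'
#' Produces procedurally generated grayscale scene images with the statistical
#' structure the downstream analyses assume: each category has a dominant
#' orientation and spatial frequency (so image-computable feature models can
#' discriminate categories), each individual scene adds its own phase,
#' frequency jitter and smoothed pixel noise (so scenes within a category are
#' distinguishable), and the occluded quadrant is replaced by uniform white.
#'
#' Categories are balanced (`n_scenes` must be divisible by `n_categories`)
#' and the binary Near/Far depth labels are balanced within category when the
#' category size is even, and globally otherwise.
#'
#' @param n_scenes number of scenes.
#' @param n_categories number of scene categories; must divide `n_scenes`.
#' @param seed integer RNG seed.
#' @param width_px,height_px raster size in pixels. The default 256 x 192
#'   preserves the 4:3 aspect of a 1024 x 768 display at quarter resolution.
#' @param field_of_view display extent in degrees of visual angle
#'   (width, height).
#' @param occluder_quadrant which quadrant is replaced by uniform white.
#' @return object of class `scene_set` with elements `images` (list of
#'   matrices in `[0, 1]`, occluder applied), `full_images` (pre-occlusion
#'   versions, the "actual hidden scene" input for feature models),
#'   `category_labels` (factor), `depth_labels` (factor Near/Far),
#'   `occluder_quadrant`, `field_of_view`, `deg_per_px`.
#' @export
generate_scene_set <- function(n_scenes, n_categories, seed,
                               width_px = 256, height_px = 192,
                               field_of_view = c(19.5, 14.7),
                               occluder_quadrant = "lower_right") {
  if (n_scenes > 0 && n_scenes %% n_categories != 0)
    stop("n_scenes (", n_scenes, ") must be divisible by n_categories (",
         n_categories, ") so that categories are balanced")
  occluder_quadrant <- match.arg(occluder_quadrant, QUADRANTS)
  set.seed(seed)

  cat_names <- scene_category_names(n_categories)
  per_cat <- if (n_scenes > 0) n_scenes / n_categories else 0
  category_labels <- factor(rep(cat_names, each = per_cat), levels = cat_names)

  # Near/Far balanced within category when possible, globally otherwise
  if (per_cat %% 2 == 0) {
    depth <- rep(rep(c("Near", "Far"), each = per_cat / 2), n_categories)
  } else {
    depth <- rep_len(c("Near", "Far"), n_scenes)
  }
  depth_labels <- factor(depth, levels = c("Near", "Far"))

  # category orientation/frequency signatures
  thetas <- (seq_len(n_categories) - 1) * pi / max(n_categories, 1)
  freqs <- if (n_categories > 0)
    exp(seq(log(0.04), log(0.16), length.out = n_categories)) else numeric(0)

  xs <- matrix(rep(seq_len(width_px), each = height_px), height_px)
  ys <- matrix(rep(seq_len(height_px), width_px), height_px)

  images <- vector("list", n_scenes)
  full_images <- vector("list", n_scenes)
  for (s in seq_len(n_scenes)) {
    k <- as.integer(category_labels[s])
    f <- freqs[k] * exp(stats::rnorm(1, 0, 0.15))      # scene-specific jitter
    th <- thetas[k] + stats::rnorm(1, 0, 0.06)
    phase <- stats::runif(1, 0, 2 * pi)
    carrier <- sin(2 * pi * f * (cos(th) * xs + sin(th) * ys) + phase)
    # second, weaker scene-specific component at a random orientation
    th2 <- stats::runif(1, 0, pi)
    f2 <- stats::runif(1, 0.03, 0.2)
    minor <- sin(2 * pi * f2 * (cos(th2) * xs + sin(th2) * ys) +
                   stats::runif(1, 0, 2 * pi))
    noise <- smooth_noise(height_px, width_px, sigma_px = 2)
    img <- carrier + 0.35 * minor + 0.5 * noise
    img <- (img - min(img)) / (max(img) - min(img))
    full_images[[s]] <- img
    qp <- quadrant_pixels(height_px, width_px, occluder_quadrant)
    img[qp$rows, qp$cols] <- 1                         # uniform white occluder
    images[[s]] <- img
  }

  structure(list(
    images = images,
    full_images = full_images,
    category_labels = category_labels,
    depth_labels = depth_labels,
    occluder_quadrant = occluder_quadrant,
    field_of_view = field_of_view,
    deg_per_px = field_of_view[1] / width_px,
    width_px = width_px, height_px = height_px
  ), class = "scene_set")
}

scene_category_names <- function(k) {
  base <- c("Beaches", "Buildings", "Forests", "Highways", "Industry",
            "Mountains")
  if (k <= length(base)) base[seq_len(k)] else paste0("category_", seq_len(k))
}

#' @export
print.scene_set <- function(x, ...) {
  cat(sprintf(
    "scene_set: %d scenes, %d categories, %d x %d px, occluder %s\n",
    length(x$images), nlevels(x$category_labels), x$height_px, x$width_px,
    x$occluder_quadrant))
  invisible(x)
}

#' Number of scenes in a scene set
#' @param scene_set a `scene_set`.
#' @export
n_scenes <- function(scene_set) length(scene_set$images)

#' Extract the occluded-quadrant sub-images of a scene set
#'
#' @param scene_set a `scene_set`.
#' @param occluded if TRUE return the occluded quadrant (the region observers
#'   draw), otherwise the full image.
#' @param hidden if TRUE crop from `full_images`, yielding the actual hidden
#'   scene patch instead of the uniform white occluder.
#' @param from_images optional explicit list of full-scene images to crop.
#' @return list of matrices.
#' @export
scene_quadrant_images <- function(scene_set, occluded = TRUE, hidden = FALSE,
                                  from_images = NULL) {
  imgs <- if (!is.null(from_images)) from_images
          else if (hidden) scene_set$full_images
          else scene_set$images
  if (!occluded) return(imgs)
  qp <- quadrant_pixels(scene_set$height_px, scene_set$width_px,
                        scene_set$occluder_quadrant)
  lapply(imgs, function(im) im[qp$rows, qp$cols, drop = FALSE])
}

# low-pass filtered standard normal field, unit-variance rescaled
smooth_noise <- function(n_rows, n_cols, sigma_px = 2) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows)
  k <- stats::dnorm(seq(-3 * sigma_px, 3 * sigma_px), sd = sigma_px)
  k <- k / sum(k)
  z <- t(apply(z, 1, function(r) stats::filter(r, k, circular = TRUE)))
  z <- apply(z, 2, function(cc) stats::filter(cc, k, circular = TRUE))
  z <- matrix(unlist(z), n_rows, n_cols)
  (z - mean(z)) / stats::sd(z)
}
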
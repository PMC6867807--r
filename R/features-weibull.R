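#' Weibull statistics of local contrast
#'
#' The distribution of local contrast magnitudes in natural images is well
#' summarized by a two-parameter Weibull distribution; its scale (beta) and
#' shape (gamma) parameters index contrast strength and the spatial
#' fragmentation of a scene. Local contrast is measured as the gradient
#' magnitude of first-order Gaussian-derivative filter responses, and the
#' Weibull parameters are fit by maximum likelihood within each region mask.
#'
#' @param image grayscale matrix in `[0, 1]`.
#' @param regions named list of logical masks (same dimensions as `image`),
#'   one per analyzed region; each mask must be non-empty.
#' @param sigma_px Gaussian-derivative scale in pixels, recycled per region.
#' @return matrix regions x 2 with columns `beta` (scale) and `gamma`
#'   (shape).
#' @export
weibull_stats <- function(image, regions, sigma_px = 1.5) {
  if (!is.matrix(image)) stop("image must be a 2-D grayscale matrix")
  stopifnot(length(regions) >= 1, all(vapply(regions, any, logical(1))))
  sigma_px <- rep_len(sigma_px, length(regions))
  out <- matrix(NA_real_, length(regions), 2,
                dimnames = list(names(regions), c("beta", "gamma")))
  for (r in seq_along(regions)) {
    mag <- gradient_magnitude(image, sigma_px[r])
    x <- mag[regions[[r]]]
    x <- x[x > 0]
    if (length(x) < 10 || stats::sd(x) == 0)
      stop("degenerate contrast distribution in region ",
           names(regions)[r] %||% r, ": cannot fit a Weibull")
    out[r, ] <- fit_weibull_ml(x)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# |gradient| of Gaussian-smoothed image via separable derivative kernels
gradient_magnitude <- function(image, sigma_px = 1.5) {
  t <- seq(-ceiling(3 * sigma_px), ceiling(3 * sigma_px))
  g <- stats::dnorm(t, sd = sigma_px); g <- g / sum(g)
  dg <- -t / sigma_px^2 * stats::dnorm(t, sd = sigma_px)
  conv_sep <- function(m, kr, kc) {
    m <- apply(m, 2, function(col) stats::filter(col, kr, circular = TRUE))
    t(apply(m, 1, function(row) stats::filter(row, kc, circular = TRUE)))
  }
  gx <- conv_sep(image, g, dg)
  gy <- conv_sep(image, dg, g)
  sqrt(gx^2 + gy^2)
}

# maximum-likelihood Weibull (scale beta, shape gamma) fit; the data are
# normalized by their mean first (Weibull MLE is scale-equivariant), which
# keeps the optimizer well-conditioned at any contrast magnitude
fit_weibull_ml <- function(x) {
  m <- mean(x)
  fit <- suppressWarnings(
    MASS::fitdistr(x / m, "weibull",
                   start = list(shape = 1.2, scale = 1),
                   lower = c(1e-3, 1e-8)))
  c(beta = m * unname(fit$estimate["scale"]),
    gamma = unname(fit$estimate["shape"]))
}

#' Central region masks for the Weibull model
#'
#' Two nested regions per analyzed quadrant, extending from fixation to
#' `radii_deg[1]` and `radii_deg[2]` degrees of visual angle (defaults 1.5
#' and 5), intersected with the quadrant.
#'
#' For a full-scene raster, fixation sits at the raster center. For a
#' quadrant crop (e.g. an occluded-quadrant drawing), pass the corner of the
#' raster adjacent to fixation via `fixation`.
#'
#' @param n_rows,n_cols raster size in pixels.
#' @param quadrant quadrant name to intersect with, or `NULL`.
#' @param field_of_view display extent in degrees (width, height) of the
#'   raster.
#' @param radii_deg the two region radii in degrees.
#' @param deg_per_px degrees per pixel.
#' @param fixation `"center"` of the raster, or the corner where fixation
#'   lies: `"top_left"`, `"top_right"`, `"bottom_left"`, `"bottom_right"`.
#' @return named list of logical masks.
#' @export
weibull_region_masks <- function(n_rows, n_cols, quadrant = NULL,
                                 field_of_view = c(19.5, 14.7),
                                 radii_deg = c(1.5, 5),
                                 deg_per_px = field_of_view[1] / n_cols,
                                 fixation = "center") {
  fixation <- match.arg(fixation, c("center", "top_left", "top_right",
                                    "bottom_left", "bottom_right"))
  if (fixation == "center") {
    g <- pixel_grid_deg(n_rows, n_cols, field_of_view)
    rr <- outer(g$y_deg^2, g$x_deg^2, "+")
  } else {
    row_off <- if (grepl("top", fixation)) (seq_len(n_rows) - 0.5)
               else (n_rows - seq_len(n_rows) + 0.5)
    col_off <- if (grepl("left", fixation)) (seq_len(n_cols) - 0.5)
               else (n_cols - seq_len(n_cols) + 0.5)
    rr <- outer((row_off * deg_per_px)^2, (col_off * deg_per_px)^2, "+")
  }
  qm <- if (is.null(quadrant)) TRUE
        else quadrant_mask(n_rows, n_cols, quadrant, field_of_view)
  masks <- lapply(radii_deg, function(rad) (rr <= rad^2) & qm)
  names(masks) <- paste0("r", radii_deg, "deg")
  masks
}

# fixation-adjacent corner of a quadrant crop: for a lower_right quadrant the
# fixation is at the crop's top-left corner, etc.
fixation_corner <- function(quadrant) {
  quadrant <- match.arg(quadrant, QUADRANTS)
  switch(quadrant,
    lower_right = "top_left", lower_left = "top_right",
    upper_right = "bottom_left", upper_left = "bottom_right")
}
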
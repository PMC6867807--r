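#' Test whether a pRF is fully contained in a visual-field quadrant
#'
#' A voxel's population receptive field is summarized as an isotropic 2D
#' Gaussian; it counts as contained when the disk of radius
#' `k_sigma * sigma_deg` around its center lies strictly inside the quadrant.
#'
#' @param x_deg,y_deg,sigma_deg pRF center coordinates and spread (degrees);
#'   vectorized.
#' @param quadrant quadrant name (see [quadrant_bounds()]).
#' @param field_of_view display extent in degrees (width, height).
#' @param k_sigma containment radius in units of sigma.
#' @return logical vector.
#' @export
prf_contained <- function(x_deg, y_deg, sigma_deg, quadrant,
                          field_of_view = c(19.5, 14.7), k_sigma = 2) {
  stopifnot(all(sigma_deg > 0))
  b <- quadrant_bounds(quadrant, field_of_view)
  r <- k_sigma * sigma_deg
  (x_deg - r) > b["xmin"] & (x_deg + r) < b["xmax"] &
    (y_deg - r) > b["ymin"] & (y_deg + r) < b["ymax"]
}

#' Shrink an occluded ROI away from the occluder border
#'
#' Keeps the voxels whose `2 sigma` pRF disk lies inside the occluder
#' quadrant after the quadrant's two interior borders (the edges shared with
#' stimulated cortex, i.e. the fixation axes) are moved inward by
#' `margin_deg`.
#'
#' @param voxel_info data.frame with columns `voxel_id`, `x_deg`, `y_deg`,
#'   `sigma_deg` (e.g. a `voxel_pattern_set$voxel_info` subset).
#' @param occluder_quadrant quadrant name.
#' @param margin_deg non-negative border shift in degrees.
#' @param field_of_view display extent in degrees.
#' @param k_sigma containment radius in units of sigma.
#' @return object of class `roi_selection`: list with `voxel_ids`,
#'   `roi_label`, `margin_deg`.
#' @export
shrink_roi <- function(voxel_info, occluder_quadrant, margin_deg = 0,
                       field_of_view = c(19.5, 14.7), k_sigma = 2) {
  if (margin_deg < 0) stop("margin_deg must be non-negative")
  b <- quadrant_bounds(occluder_quadrant, field_of_view)
  # interior borders are the x = 0 and y = 0 edges; shift both inward
  if (b["xmin"] == 0) b["xmin"] <- margin_deg else b["xmax"] <- -margin_deg
  if (b["ymin"] == 0) b["ymin"] <- margin_deg else b["ymax"] <- -margin_deg
  r <- k_sigma * voxel_info$sigma_deg
  keep <- (voxel_info$x_deg - r) > b["xmin"] &
    (voxel_info$x_deg + r) < b["xmax"] &
    (voxel_info$y_deg - r) > b["ymin"] &
    (voxel_info$y_deg + r) < b["ymax"]
  structure(list(voxel_ids = voxel_info$voxel_id[keep],
                 roi_label = occluder_quadrant, margin_deg = margin_deg),
            class = "roi_selection")
}

#' Border-shift ROI series
#'
#' The ROI restriction analysis repeats [shrink_roi()] over a series of
#' margins (default 0 to 2.75 degrees in 0.25-degree steps, 12 selections).
#'
#' @inheritParams shrink_roi
#' @param margins_deg vector of margins.
#' @return list of `roi_selection`.
#' @export
border_shift_series <- function(voxel_info, occluder_quadrant,
                                margins_deg = seq(0, 2.75, by = 0.25),
                                field_of_view = c(19.5, 14.7), k_sigma = 2) {
  lapply(margins_deg, function(m)
    shrink_roi(voxel_info, occluder_quadrant, m, field_of_view, k_sigma))
}

#' Dimensionality-matched random control ROIs
#'
#' For comparison with a border-shrunk ROI, removes the same number of
#' voxels at random from the full ROI, repeated `n_repeats` times.
#'
#' @param voxel_ids character vector of the full ROI's voxel ids.
#' @param n_remove number of voxels to remove (must be < length(voxel_ids)).
#' @param n_repeats number of random subsets.
#' @param seed integer RNG seed.
#' @return list of `roi_selection`, each of size
#'   `length(voxel_ids) - n_remove`.
#' @export
matched_random_control <- function(voxel_ids, n_remove, n_repeats = 50,
                                   seed = 1) {
  if (n_remove >= length(voxel_ids))
    stop("n_remove must be smaller than the ROI size")
  set.seed(seed)
  lapply(seq_len(n_repeats), function(r) {
    keep <- if (n_remove == 0) voxel_ids
            else sample(voxel_ids, length(voxel_ids) - n_remove)
    structure(list(voxel_ids = sort(keep), roi_label = "matched_control",
                   margin_deg = NA_real_),
              class = "roi_selection")
  })
}
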
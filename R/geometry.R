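#' Visual-field geometry helpers
#'
#' The package works in degrees of visual angle with the origin at fixation,
#' x positive rightward and y positive upward. Images are row-major rasters
#' with row 1 at the top of the visual field, so pixel row r has a *negative*
#' y offset from the top edge.
#'
#' @name geometry
#' @keywords internal
NULL

QUADRANTS <- c("lower_right", "upper_right", "lower_left", "upper_left")

#' Bounding box of a visual-field quadrant
#'
#' @param quadrant one of `"lower_right"`, `"upper_right"`, `"lower_left"`,
#'   `"upper_left"`.
#' @param field_of_view numeric length-2, full width and height of the display
#'   in degrees of visual angle.
#' @return named numeric vector `c(xmin, xmax, ymin, ymax)` in degrees.
#' @export
quadrant_bounds <- function(quadrant, field_of_view) {
  quadrant <- match.arg(quadrant, QUADRANTS)
  hw <- field_of_view[1] / 2
  hh <- field_of_view[2] / 2
  switch(quadrant,
    lower_right = c(xmin = 0, xmax = hw, ymin = -hh, ymax = 0),
    upper_right = c(xmin = 0, xmax = hw, ymin = 0, ymax = hh),
    lower_left  = c(xmin = -hw, xmax = 0, ymin = -hh, ymax = 0),
    upper_left  = c(xmin = -hw, xmax = 0, ymin = 0, ymax = hh)
  )
}

#' Degree coordinates of pixel centers
#'
#' @param n_rows,n_cols raster dimensions in pixels.
#' @param field_of_view full display extent in degrees (width, height).
#' @return list with vectors `x_deg` (per column) and `y_deg` (per row).
#' @export
pixel_grid_deg <- function(n_rows, n_cols, field_of_view) {
  dpp <- field_of_view[1] / n_cols
  list(
    x_deg = (seq_len(n_cols) - 0.5) * dpp - field_of_view[1] / 2,
    y_deg = field_of_view[2] / 2 - (seq_len(n_rows) - 0.5) * dpp,
    deg_per_px = dpp
  )
}

#' Logical pixel mask of a quadrant
#'
#' @inheritParams pixel_grid_deg
#' @inheritParams quadrant_bounds
#' @return logical matrix, TRUE inside the quadrant.
#' @export
quadrant_mask <- function(n_rows, n_cols, quadrant, field_of_view) {
  g <- pixel_grid_deg(n_rows, n_cols, field_of_view)
  b <- quadrant_bounds(quadrant, field_of_view)
  outer(g$y_deg > b["ymin"] & g$y_deg <= b["ymax"],
        g$x_deg > b["xmin"] & g$x_deg <= b["xmax"], "&")
}

#' Row/column index ranges of a quadrant in a raster
#' @keywords internal
quadrant_pixels <- function(n_rows, n_cols, quadrant) {
  quadrant <- match.arg(quadrant, QUADRANTS)
  top <- grepl("upper", quadrant)
  right <- grepl("right", quadrant)
  rows <- if (top) seq_len(n_rows %/% 2) else (n_rows %/% 2 + 1):n_rows
  cols <- if (right) (n_cols %/% 2 + 1):n_cols else seq_len(n_cols %/% 2)
  list(rows = rows, cols = cols)
}
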
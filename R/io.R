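#' Write scene images and labels to disk
#'
#' Images go to `<dir>/scene_<i>.png` (8-bit grayscale PNG) and labels to
#' `<dir>/scenes.tsv` (columns `scene`, `file`, `category`, `depth`).
#'
#' @param scene_set a `scene_set`.
#' @param dir output directory (created if needed).
#' @return invisibly, the label table.
#' @export
write_scene_set <- function(scene_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("scene_%02d.png", seq_len(n_scenes(scene_set)))
  for (s in seq_len(n_scenes(scene_set)))
    png::writePNG(scene_set$images[[s]], file.path(dir, files[s]))
  tab <- data.frame(scene = seq_len(n_scenes(scene_set)), file = files,
                    category = as.character(scene_set$category_labels),
                    depth = as.character(scene_set$depth_labels))
  utils::write.table(tab, file.path(dir, "scenes.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' Read scene images (PNG/TIFF) and a label table from disk
#'
#' Expects the layout written by [write_scene_set()]: a `scenes.tsv` with
#' columns `scene`, `file`, `category`, `depth`. TIFF files need the
#' `tiff` package.
#'
#' @param dir directory containing `scenes.tsv` and image files.
#' @param field_of_view display extent in degrees.
#' @param occluder_quadrant occluder position of the stimuli.
#' @return a `scene_set`.
#' @export
read_scene_set <- function(dir, field_of_view = c(19.5, 14.7),
                           occluder_quadrant = "lower_right") {
  tab <- utils::read.delim(file.path(dir, "scenes.tsv"))
  images <- lapply(file.path(dir, tab$file), read_gray_image)
  structure(list(
    images = images,
    full_images = images,   # pre-occlusion originals are not on disk
    category_labels = factor(tab$category),
    depth_labels = factor(tab$depth, levels = c("Near", "Far")),
    occluder_quadrant = occluder_quadrant,
    field_of_view = field_of_view,
    deg_per_px = field_of_view[1] / ncol(images[[1]]),
    width_px = ncol(images[[1]]), height_px = nrow(images[[1]])
  ), class = "scene_set")
}

read_gray_image <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF images requires the 'tiff' package")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                              drop = FALSE], c(1, 2), mean)
  img
}

#' Write observer drawings as PNG files
#'
#' One file per observer x scene: `<dir>/obs<o>_scene<s>.png`.
#'
#' @param drawing_set a `drawing_set`.
#' @param dir output directory.
#' @export
write_drawings <- function(drawing_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(drawing_set$strokes)
  for (o in seq_len(d[4])) for (s in seq_len(d[3]))
    png::writePNG(drawing_set$strokes[, , s, o] + 0,
                  file.path(dir, sprintf("obs%02d_scene%02d.png", o, s)))
  invisible(NULL)
}

#' Read observer drawings from PNG files
#'
#' Reads the layout written by [write_drawings()] and binarizes at 0.5.
#'
#' @param dir directory of `obs*_scene*.png` files.
#' @param consistency optional per-scene consistency to attach.
#' @return a `drawing_set`.
#' @export
read_drawings <- function(dir, consistency = NA_real_) {
  files <- list.files(dir, pattern = "^obs[0-9]+_scene[0-9]+\\.png$")
  if (length(files) == 0) stop("no drawing PNGs found in ", dir)
  obs <- as.integer(sub("^obs([0-9]+)_.*", "\\1", files))
  sc <- as.integer(sub(".*_scene([0-9]+)\\.png$", "\\1", files))
  n_obs <- max(obs); ns <- max(sc)
  first <- read_gray_image(file.path(dir, files[1]))
  strokes <- array(0L, dim = c(nrow(first), ncol(first), ns, n_obs))
  for (k in seq_along(files))
    strokes[, , sc[k], obs[k]] <-
      (read_gray_image(file.path(dir, files[k])) > 0.5) * 1L
  structure(list(strokes = strokes,
                 observer_ids = paste0("obs", seq_len(n_obs)),
                 scene_ids = paste0("scene", seq_len(ns)),
                 consistency = rep_len(consistency, ns),
                 height_px = nrow(first), width_px = ncol(first)),
            class = "drawing_set")
}

#' Write voxel patterns to a long-format TSV
#'
#' Columns: `subject`, `run`, `trial`, `scene`, `category`, `depth`,
#' `voxel_id`, `roi`, `beta`.
#'
#' @param vps a `voxel_pattern_set`.
#' @param path output file.
#' @export
write_patterns_tsv <- function(vps, path) {
  ntr <- nrow(vps$betas); nv <- ncol(vps$betas)
  tab <- data.frame(
    subject = vps$subject_id,
    run = rep(vps$run_of_trial, nv),
    trial = rep(seq_len(ntr), nv),
    scene = rep(vps$scene_of_trial, nv),
    category = rep(as.character(vps$category_of_trial %||% NA), nv),
    depth = rep(as.character(vps$depth_of_trial %||% NA), nv),
    voxel_id = rep(vps$voxel_info$voxel_id, each = ntr),
    roi = rep(vps$voxel_info$roi, each = ntr),
    beta = as.vector(vps$betas))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read voxel patterns from a long-format TSV or CSV
#'
#' Accepts the layout written by [write_patterns_tsv()]; a separate pRF
#' table (see [write_prf_tsv()]) can supply voxel geometry.
#'
#' @param path beta table (TSV or CSV by extension).
#' @param prf_path optional pRF table path.
#' @return a `voxel_pattern_set`.
#' @export
read_patterns_tsv <- function(path, prf_path = NULL) {
  tab <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    utils::read.csv(path) else utils::read.delim(path)
  voxels <- unique(tab[, c("voxel_id", "roi")])
  trials <- unique(tab[, c("trial", "run", "scene", "category", "depth")])
  trials <- trials[order(trials$trial), ]
  betas <- matrix(NA_real_, nrow(trials), nrow(voxels),
                  dimnames = list(NULL, voxels$voxel_id))
  betas[cbind(match(tab$trial, trials$trial),
              match(tab$voxel_id, voxels$voxel_id))] <- tab$beta
  if (anyNA(betas)) stop("missing betas in ", path)
  info <- data.frame(voxel_id = voxels$voxel_id, roi = voxels$roi,
                     position = sub("_(V1|V2)$", "", voxels$roi),
                     area = sub("^.*_(V1|V2)$", "\\1", voxels$roi),
                     x_deg = NA_real_, y_deg = NA_real_,
                     sigma_deg = NA_real_)
  if (!is.null(prf_path)) {
    prf <- utils::read.delim(prf_path)
    m <- match(info$voxel_id, prf$voxel_id)
    info$x_deg <- prf$x_deg[m]; info$y_deg <- prf$y_deg[m]
    info$sigma_deg <- prf$sigma_deg[m]
  }
  new_voxel_pattern_set(
    betas = betas, scene_of_trial = trials$scene,
    run_of_trial = trials$run, voxel_info = info,
    category_of_trial = factor(trials$category),
    depth_of_trial = factor(trials$depth),
    subject_id = as.character(tab$subject[1]))
}

#' Write per-voxel pRF parameters as TSV
#' @param vps a `voxel_pattern_set`.
#' @param path output file.
#' @export
write_prf_tsv <- function(vps, path) {
  utils::write.table(
    vps$voxel_info[, c("voxel_id", "roi", "x_deg", "y_deg", "sigma_deg")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an RDM as TSV with canonical pair ordering
#'
#' Columns `i`, `j`, `dissimilarity`; a JSON sidecar `<path>.json` records
#' the metric and the number of conditions.
#'
#' @param rdm an `rdm`.
#' @param path output TSV path.
#' @export
write_rdm_tsv <- function(rdm, path) {
  n <- attr(rdm, "n_conditions")
  pi <- pair_index(n)
  utils::write.table(
    data.frame(i = pi$i, j = pi$j, dissimilarity = as.numeric(rdm)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(metric = attr(rdm, "metric"), n_conditions = n),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an RDM written by [write_rdm_tsv()]
#' @param path TSV path.
#' @return an `rdm`.
#' @export
read_rdm_tsv <- function(path) {
  tab <- utils::read.delim(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  new_rdm(tab$dissimilarity, meta$n_conditions, meta$metric)
}
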
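#' Feature matrix container
#'
#' @param values scene x channel numeric matrix (finite).
#' @param model_name model identifier.
#' @return object of class `feature_matrix`.
#' @export
new_feature_matrix <- function(values, model_name = "model") {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("feature matrix contains non-finite values")
  structure(values, class = c("feature_matrix", class(values)),
            model_name = model_name)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d scenes x %d channels\n",
              attr(x, "model_name"), nrow(x), ncol(x)))
  invisible(x)
}

#' Compute a feature matrix for a list of images
#'
#' Convenience dispatcher over the image-computable models.
#'
#' @param images list of grayscale matrices (one per scene).
#' @param model `"gist"`, `"weibull"` or `"hmax"`.
#' @param ... model arguments: [gist_descriptor()] settings; `regions` and
#'   `sigma_px` for [weibull_stats()]; `prototypes` for [hmax_c2()].
#' @return a `feature_matrix`.
#' @export
compute_features <- function(images, model = c("gist", "weibull", "hmax"),
                             ...) {
  model <- match.arg(model)
  rows <- switch(model,
    gist = lapply(images, gist_descriptor, ...),
    weibull = lapply(images, function(im) {
      st <- weibull_stats(im, ...)
      stats::setNames(as.vector(t(st)),
                      paste(rep(rownames(st), each = 2),
                            colnames(st), sep = "_"))
    }),
    hmax = lapply(images, hmax_c2, ...))
  new_feature_matrix(do.call(rbind, rows), model)
}

#' Binary category model RDM
#'
#' Scene pairs from the same category take dissimilarity 0 and pairs from
#' different categories take 1.
#'
#' @param category_labels vector/factor of per-scene category labels.
#' @return an `rdm` (metric `"category"`).
#' @export
category_model_rdm <- function(category_labels) {
  n <- length(category_labels)
  pi <- pair_index(n)
  v <- as.numeric(category_labels[pi$i] != category_labels[pi$j])
  new_rdm(v, n, metric = "category")
}

#' One-hot category feature matrix (K channels)
#' @param category_labels vector/factor of per-scene labels.
#' @return a `feature_matrix` with one indicator channel per category.
#' @export
category_feature_matrix <- function(category_labels) {
  f <- factor(category_labels)
  m <- stats::model.matrix(~ f - 1)
  colnames(m) <- levels(f)
  new_feature_matrix(m, "category")
}

#' Continuous depth model from rater estimates
#'
#' Depth ratings (meters) are transformed to log10; for each scene the mean
#' is bootstrapped (`n_boot` resamples of the raters) and a normal
#' distribution is fit to the resampled means. The single model channel is
#' the distribution mean, and the model RDM entry for a scene pair is the
#' squared difference of the two means.
#'
#' @param ratings rater x scene matrix of positive depths in meters.
#' @param n_boot number of bootstrap resamples of the mean.
#' @param seed integer RNG seed.
#' @return list with `distribution` (data.frame `scene`, `mean_log10_m`,
#'   `sd_log10_m`), `feature_matrix` (1 channel) and `rdm`.
#' @export
depth_model <- function(ratings, n_boot = 1000, seed = 1) {
  if (any(ratings <= 0)) stop("depth ratings must be positive (meters)")
  set.seed(seed)
  lr <- log10(ratings)
  nr <- nrow(lr)
  boots <- apply(lr, 2, function(col)
    vapply(seq_len(n_boot), function(b) mean(col[sample.int(nr, replace = TRUE)]),
           numeric(1)))
  mu <- colMeans(boots)
  sd_ <- apply(boots, 2, stats::sd)
  ns <- ncol(lr)
  pi <- pair_index(ns)
  list(
    distribution = data.frame(scene = colnames(lr) %||% seq_len(ns),
                              mean_log10_m = mu, sd_log10_m = sd_,
                              row.names = NULL),
    feature_matrix = new_feature_matrix(matrix(mu, ncol = 1,
                                               dimnames = list(NULL, "log10_depth")),
                                        "depth"),
    rdm = new_rdm((mu[pi$i] - mu[pi$j])^2, ns, metric = "sq_euclidean")
  )
}

#' Per-channel squared-Euclidean model RDMs
#'
#' For each channel c the RDM entry for pair (i, j) is
#' `(x[i, c] - x[j, c])^2`.
#'
#' @param feature_matrix a `feature_matrix` (or plain scene x channel
#'   matrix).
#' @return list of `rdm`s, one per channel (named when channels are named).
#' @export
model_channel_rdms <- function(feature_matrix) {
  x <- as.matrix(feature_matrix)
  n <- nrow(x)
  pi <- pair_index(n)
  d <- (x[pi$i, , drop = FALSE] - x[pi$j, , drop = FALSE])^2
  out <- lapply(seq_len(ncol(x)), function(ch)
    new_rdm(d[, ch], n, metric = "sq_euclidean"))
  names(out) <- colnames(x)
  out
}
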
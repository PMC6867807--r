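#' HMAX parameters
#'
#' Configuration of the hierarchical S1 -> C1 -> S2 -> C2 model. S1 applies
#' spatial-domain Gabor simple-cell filters at several sizes and
#' orientations; C1 max-pools S1 magnitudes locally over position and over
#' adjacent filter sizes (scale bands); S2 compares C1 patches against
#' stored prototypes with a Gaussian radial-basis function; C2 takes the
#' global maximum response per prototype over all positions and bands.
#'
#' @param n_orientations number of S1 orientations.
#' @param filter_sizes_px odd Gabor filter sizes in pixels; consecutive
#'   pairs form one C1 scale band.
#' @param c1_pool_px spatial max-pool window per band (pixels).
#' @param c1_stride_px pooling stride per band (pixels).
#' @return list of class `hmax_params`.
#' @export
hmax_params <- function(n_orientations = 4,
                        filter_sizes_px = c(7, 9, 11, 13),
                        c1_pool_px = c(8, 10), c1_stride_px = c(4, 5)) {
  stopifnot(length(filter_sizes_px) %% 2 == 0)
  n_bands <- length(filter_sizes_px) / 2
  structure(list(n_orientations = n_orientations,
                 filter_sizes_px = filter_sizes_px,
                 n_bands = n_bands,
                 c1_pool_px = rep_len(c1_pool_px, n_bands),
                 c1_stride_px = rep_len(c1_stride_px, n_bands)),
            class = "hmax_params")
}

# spatial Gabor kernel (real part), zero-mean, unit-norm
gabor_kernel <- function(size, theta, lambda = size / 2.2, gamma = 0.3,
                         sigma = size / 4.5) {
  half <- (size - 1) / 2
  x <- matrix(rep(-half:half, each = size), size)
  y <- matrix(rep(-half:half, size), size)
  xr <- x * cos(theta) + y * sin(theta)
  yr <- -x * sin(theta) + y * cos(theta)
  k <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2)) *
    cos(2 * pi * xr / lambda)
  k <- k - mean(k)
  k / sqrt(sum(k^2))
}

# 'same'-size FFT convolution (correlation) of image with kernel
conv2_same <- function(image, kernel) {
  h <- nrow(image); w <- ncol(image)
  kh <- nrow(kernel); kw <- ncol(kernel)
  ph <- h + kh - 1; pw <- w + kw - 1
  A <- matrix(0, ph, pw); A[1:h, 1:w] <- image
  B <- matrix(0, ph, pw); B[1:kh, 1:kw] <- kernel[kh:1, kw:1]
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) /
    (ph * pw)
  r0 <- (kh - 1) %/% 2; c0 <- (kw - 1) %/% 2
  full[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)]
}

# C1 maps: list over bands, each an array [rows, cols, orientations]
hmax_c1 <- function(image, params) {
  thetas <- (seq_len(params$n_orientations) - 1) * pi / params$n_orientations
  lapply(seq_len(params$n_bands), function(b) {
    sizes <- params$filter_sizes_px[(2 * b - 1):(2 * b)]
    pool <- params$c1_pool_px[b]; stride <- params$c1_stride_px[b]
    maps <- lapply(thetas, function(th) {
      s1 <- pmax(abs(conv2_same(image, gabor_kernel(sizes[1], th))),
                 abs(conv2_same(image, gabor_kernel(sizes[2], th))))
      max_pool(s1, pool, stride)
    })
    array(unlist(maps), dim = c(dim(maps[[1]]), length(maps)))
  })
}

max_pool <- function(m, pool, stride) {
  rs <- seq(1, nrow(m) - pool + 1, by = stride)
  cs <- seq(1, ncol(m) - pool + 1, by = stride)
  out <- matrix(0, length(rs), length(cs))
  for (i in seq_along(rs)) for (j in seq_along(cs))
    out[i, j] <- max(m[rs[i]:(rs[i] + pool - 1), cs[j]:(cs[j] + pool - 1)])
  out
}

#' Sample C1 prototype patches from a bag of images
#'
#' Prototypes are multi-orientation C1 patches sampled at random images,
#' bands, positions and patch sizes. They should be learned from images
#' outside the evaluation set (e.g. held-out synthetic scenes).
#'
#' @param image_bag non-empty list of grayscale matrices.
#' @param n_prototypes number of prototypes to sample.
#' @param patch_sizes candidate square patch sizes in C1 units.
#' @param seed integer RNG seed.
#' @param params an `hmax_params`.
#' @return object of class `hmax_prototypes`: list of patches (arrays
#'   `[size, size, n_orientations]`) with the sampling provenance
#'   (`source_image`, `band`, `size`) stored alongside.
#' @export
learn_prototypes <- function(image_bag, n_prototypes, patch_sizes = c(4, 8),
                             seed = 1, params = hmax_params()) {
  if (length(image_bag) == 0) stop("image_bag must be non-empty")
  set.seed(seed)
  c1_bag <- lapply(image_bag, hmax_c1, params = params)
  patches <- vector("list", n_prototypes)
  meta <- data.frame(source_image = integer(n_prototypes),
                     band = integer(n_prototypes),
                     size = integer(n_prototypes))
  for (p in seq_len(n_prototypes)) {
    repeat {
      im <- sample.int(length(image_bag), 1)
      b <- sample.int(params$n_bands, 1)
      sz <- sample(patch_sizes, 1)
      c1 <- c1_bag[[im]][[b]]
      if (dim(c1)[1] >= sz && dim(c1)[2] >= sz) break
    }
    r <- sample.int(dim(c1)[1] - sz + 1, 1)
    cc <- sample.int(dim(c1)[2] - sz + 1, 1)
    patches[[p]] <- c1[r:(r + sz - 1), cc:(cc + sz - 1), , drop = FALSE]
    meta[p, ] <- c(im, b, sz)
  }
  structure(list(patches = patches, meta = meta, params = params),
            class = "hmax_prototypes")
}

#' @export
print.hmax_prototypes <- function(x, ...) {
  cat(sprintf("hmax_prototypes: %d patches, sizes {%s}, %d orientations\n",
              length(x$patches),
              paste(sort(unique(x$meta$size)), collapse = ", "),
              x$params$n_orientations))
  invisible(x)
}

#' HMAX C2 features of an image
#'
#' Computes the C1 maps of `image` and, for every prototype, the maximum
#' Gaussian radial-basis match `exp(-d^2 / (2 * sigma2))` over all positions
#' and scale bands, where `d` is the Euclidean distance between the C1 patch
#' and the prototype. An image that contains a prototype's source patch
#' yields the maximum attainable response 1 for that prototype, and the
#' global max makes responses invariant to where the patch occurs.
#'
#' @param image grayscale matrix.
#' @param prototypes an `hmax_prototypes` (non-empty).
#' @param rbf_sigma2_scale RBF variance per patch element.
#' @return numeric vector of length `n_prototypes` in `(0, 1]`.
#' @export
hmax_c2 <- function(image, prototypes, rbf_sigma2_scale = 0.05) {
  if (!inherits(prototypes, "hmax_prototypes") ||
      length(prototypes$patches) == 0)
    stop("prototypes must be a non-empty hmax_prototypes object")
  params <- prototypes$params
  c1 <- hmax_c1(image, params)
  sizes <- sort(unique(prototypes$meta$size))
  # im2col per (band, patch size): positions x patch elements
  unrolled <- lapply(seq_len(params$n_bands), function(b) {
    lapply(stats::setNames(sizes, sizes), function(sz) {
      d <- dim(c1[[b]])
      if (d[1] < sz || d[2] < sz) return(NULL)
      n_pos_r <- d[1] - sz + 1; n_pos_c <- d[2] - sz + 1
      idx <- as.vector(outer(seq_len(sz), (seq_len(sz) - 1) * d[1], "+"))
      idx <- as.vector(outer(idx, (seq_len(d[3]) - 1) * d[1] * d[2], "+"))
      base <- as.vector(outer(seq_len(n_pos_r), (seq_len(n_pos_c) - 1) * d[1],
                              "+")) - 1
      m <- matrix(c1[[b]][rep(idx, each = length(base)) + base],
                  length(base), length(idx))
      list(m = m, sq = rowSums(m^2))
    })
  })
  vapply(seq_along(prototypes$patches), function(p) {
    pv <- as.vector(prototypes$patches[[p]])
    sz <- prototypes$meta$size[p]
    sigma2 <- rbf_sigma2_scale * length(pv)
    best <- -Inf
    for (b in seq_len(params$n_bands)) {
      u <- unrolled[[b]][[as.character(sz)]]
      if (is.null(u)) next
      d2 <- u$sq - 2 * drop(u$m %*% pv) + sum(pv^2)
      best <- max(best, -max(min(d2), 0))   # clamp float negatives to 0
    }
    exp(best / (2 * sigma2))
  }, numeric(1))
}
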
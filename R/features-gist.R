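#' Gist descriptor: localized oriented bandpass energy
#'
#' A bank of log-Gabor filters (`n_scales` spatial frequencies x
#' `n_orientations` orientations) is applied in the frequency domain; the
#' quadrature (squared complex magnitude) energy of each filter response is
#' averaged within an `n_blocks x n_blocks` spatial grid. With the defaults
#' (4 x 4 grid, 8 orientations, 4 scales) the descriptor has
#' `16 * 8 * 4 = 512` dimensions.
#'
#' Orientation is the angle of the spatial wave vector: channel orientation 0
#' responds to gratings varying along x (vertical bars), and channels step by
#' `pi / n_orientations`.
#'
#' @param image grayscale matrix with values in `[0, 1]`.
#' @param n_blocks grid size per side.
#' @param n_orientations number of orientation channels.
#' @param n_scales number of spatial-frequency channels.
#' @param f_range center spatial frequencies span (cycles/pixel), log-spaced.
#' @return named numeric vector of length
#'   `n_blocks^2 * n_orientations * n_scales`; names are
#'   `s<scale>_o<orientation>_b<row><col>`.
#' @export
gist_descriptor <- function(image, n_blocks = 4, n_orientations = 8,
                            n_scales = 4, f_range = c(0.02, 0.3)) {
  if (!is.matrix(image)) stop("image must be a 2-D grayscale matrix")
  h <- nrow(image); w <- ncol(image)
  Fimg <- stats::fft(image - mean(image))
  bank <- gabor_bank(h, w, n_orientations, n_scales, f_range)
  out <- numeric(0)
  nm <- character(0)
  for (s in seq_len(n_scales)) for (o in seq_len(n_orientations)) {
    resp <- stats::fft(Fimg * bank[[s]][[o]], inverse = TRUE) / (h * w)
    energy <- Mod(resp)^2
    blocks <- block_means(energy, n_blocks)
    out <- c(out, as.vector(t(blocks)))
    nm <- c(nm, sprintf("s%d_o%d_b%d%d", s, o,
                        rep(seq_len(n_blocks), each = n_blocks),
                        rep(seq_len(n_blocks), n_blocks)))
  }
  stats::setNames(out, nm)
}

# complex log-Gabor transfer functions on the FFT grid; list [[scale]][[orient]]
gabor_bank <- function(h, w, n_orientations, n_scales,
                       f_range = c(0.02, 0.3)) {
  fy <- fft_freqs(h)
  fx <- fft_freqs(w)
  FX <- matrix(rep(fx, each = h), h)
  FY <- matrix(rep(fy, w), h)
  rho <- sqrt(FX^2 + FY^2)
  ang <- atan2(FY, FX)
  f_c <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_scales))
  sigma_f <- log(2) / 2                       # ~1 octave radial bandwidth
  sigma_th <- 0.6 * pi / n_orientations
  lapply(seq_len(n_scales), function(s) {
    radial <- exp(-(log(pmax(rho, 1e-12) / f_c[s]))^2 / (2 * sigma_f^2))
    radial[rho == 0] <- 0                     # no DC response
    # drop the unpaired Nyquist frequencies of even-sized grids: they exist
    # only with negative sign, which would break rotational symmetry
    radial[abs(FX) >= 0.5 | abs(FY) >= 0.5] <- 0
    lapply(seq_len(n_orientations), function(o) {
      th <- (o - 1) * pi / n_orientations
      # one-sided in orientation: a real image's Hermitian spectrum puts a
      # conjugate lobe at th + pi, so selecting one half-plane yields a
      # complex (quadrature) response whose squared magnitude is the energy
      # envelope
      d <- ang - th
      d <- atan2(sin(d), cos(d))              # wrap to (-pi, pi]
      radial * exp(-d^2 / (2 * sigma_th^2))
    })
  })
}

fft_freqs <- function(n) {
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k <- c(0:(n / 2 - 1), -(n / 2):-1)
  k / n
}

# mean within an nb x nb grid of (approximately equal) rectangular blocks
block_means <- function(m, nb) {
  ri <- cut(seq_len(nrow(m)), nb, labels = FALSE)
  ci <- cut(seq_len(ncol(m)), nb, labels = FALSE)
  out <- matrix(0, nb, nb)
  for (i in seq_len(nb)) for (j in seq_len(nb))
    out[i, j] <- mean(m[ri == i, ci == j])
  out
}

#' Split-half reliability of Gist features of average drawings
#'
#' Observers are randomly split in half (sizes `floor(n/2)` and
#' `ceiling(n/2)`, e.g. 23/24 for 47 observers), drawings are averaged
#' within each half, Gist descriptors are computed for both half-average
#' drawings of each scene, and the per-scene Pearson correlation between the
#' two halves' descriptors is averaged over `n_splits` random splits.
#'
#' @param drawing_set a `drawing_set` with at least 2 observers.
#' @param n_splits number of random splits.
#' @param seed integer RNG seed.
#' @param ... passed to [gist_descriptor()].
#' @return numeric vector: mean split-half correlation per scene.
#' @export
gist_split_half_reliability <- function(drawing_set, n_splits = 50, seed = 1,
                                        ...) {
  n_obs <- dim(drawing_set$strokes)[4]
  ns <- dim(drawing_set$strokes)[3]
  if (n_obs < 2) stop("need at least 2 observers")
  set.seed(seed)
  acc <- matrix(0, n_splits, ns)
  for (sp in seq_len(n_splits)) {
    half1 <- sample(n_obs, floor(n_obs / 2))
    for (s in seq_len(ns)) {
      m1 <- apply(drawing_set$strokes[, , s, half1, drop = FALSE], c(1, 2),
                  mean)
      m2 <- apply(drawing_set$strokes[, , s, -half1, drop = FALSE], c(1, 2),
                  mean)
      g1 <- gist_descriptor(m1, ...)
      g2 <- gist_descriptor(m2, ...)
      acc[sp, s] <- if (stats::sd(g1) == 0 || stats::sd(g2) == 0) NA_real_
                    else stats::cor(g1, g2)
    }
  }
  colMeans(acc)
}
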
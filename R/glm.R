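#' Canonical two-gamma hemodynamic response function
#'
#' Difference of two gamma densities with unit rate: a positive lobe peaking
#' at `peak_s` seconds and an undershoot peaking at `undershoot_s`, scaled by
#' `1/ratio`. The response is normalized so its maximum is 1.
#'
#' @param t_s non-negative time(s) in seconds.
#' @param peak_s time-to-peak of the positive lobe (seconds).
#' @param undershoot_s time-to-peak of the undershoot (seconds).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @return HRF amplitude at `t_s` (vectorized).
#' @export
two_gamma_hrf <- function(t_s, peak_s = 6, undershoot_s = 16, ratio = 6) {
  stopifnot(all(t_s >= 0))
  h <- function(t) stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    stats::dgamma(t, shape = undershoot_s + 1, rate = 1) / ratio
  # peak height for normalization: gamma mode is at shape - 1 = peak_s
  h(t_s) / h(peak_s)
}

#' Event design for one run
#'
#' @param onsets_s event onsets in seconds.
#' @param durations_s event durations in seconds (recycled).
#' @param condition_of_event condition label per event.
#' @param TR_s repetition time in seconds.
#' @param run_length_s total run duration in seconds.
#' @return object of class `event_design`.
#' @export
event_design <- function(onsets_s, durations_s, condition_of_event, TR_s,
                         run_length_s) {
  durations_s <- rep_len(durations_s, length(onsets_s))
  if (any(onsets_s < 0) || any(onsets_s + durations_s > run_length_s))
    stop("event onsets must be non-negative and events must end within the run")
  structure(list(onsets_s = onsets_s, durations_s = durations_s,
                 condition_of_event = as.character(condition_of_event),
                 TR_s = TR_s, run_length_s = run_length_s),
            class = "event_design")
}

#' Build an HRF-convolved design matrix
#'
#' One column per condition: the condition's boxcar (overlapping events of
#' the same condition merge into one indicator) convolved with the two-gamma
#' HRF on a fine time grid, then sampled at the TR.
#'
#' @param design an `event_design`.
#' @param dt_s convolution grid resolution (seconds).
#' @param ... passed to [two_gamma_hrf()].
#' @return numeric matrix (volumes x conditions) with condition column names.
#' @export
build_design <- function(design, dt_s = 0.1, ...) {
  stopifnot(inherits(design, "event_design"))
  conds <- unique(design$condition_of_event)
  n_fine <- ceiling(design$run_length_s / dt_s)
  t_fine <- (seq_len(n_fine) - 1) * dt_s
  hrf <- two_gamma_hrf(seq(0, 32, by = dt_s), ...)
  t_vol <- seq(0, design$run_length_s - design$TR_s, by = design$TR_s)
  X <- sapply(conds, function(cond) {
    box <- rep(0, n_fine)
    for (e in which(design$condition_of_event == cond)) {
      idx <- t_fine >= design$onsets_s[e] &
        t_fine < design$onsets_s[e] + design$durations_s[e]
      box[idx] <- 1                          # merge same-condition overlaps
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_fine)] * dt_s
    stats::approx(t_fine, conv, xout = t_vol, rule = 2)$y
  })
  X <- matrix(X, ncol = length(conds), dimnames = list(NULL, conds))
  X
}

#' Ordinary least-squares GLM betas
#'
#' Fits `timecourse ~ intercept + design` by least squares and returns the
#' per-condition amplitude estimates.
#'
#' @param timecourse numeric vector (or matrix time x voxels).
#' @param design regressor matrix (time x conditions) from [build_design()].
#' @return named vector (or conditions x voxels matrix) of beta estimates.
#' @export
fit_glm <- function(timecourse, design) {
  timecourse <- as.matrix(timecourse)
  if (nrow(timecourse) != nrow(design))
    stop("timecourse and design have different numbers of time points")
  X <- cbind(intercept = 1, design)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  b <- qr.coef(qr(X), timecourse)
  out <- b[-1, , drop = FALSE]
  rownames(out) <- colnames(design)
  if (ncol(out) == 1) out[, 1] else out
}
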
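#' Cross-validated linear discriminant contrast (crossnobis) RDM
#'
#' For each condition pair (i, j) the LDC is the cross-validated Mahalanobis
#' contrast `t(delta_A) %*% solve(Sigma) %*% delta_B / n_voxels`, where
#' `delta_X` is the difference of condition mean patterns in data half X and
#' `Sigma` is a noise covariance estimated from the residuals of half A.
#' Because the two pattern differences come from independent data halves the
#' estimator is unbiased: its expectation is 0 when conditions do not differ,
#' and entries can be negative. The estimate is symmetrized by averaging the
#' A->B and B->A directions.
#'
#' The noise covariance is diagonal with shrinkage: per-voxel residual
#' variances are shrunk toward their mean,
#' `(1 - shrinkage) * s_v^2 + shrinkage * mean(s^2)`, or replaced by the
#' identity when `identity_cov = TRUE`.
#'
#' @param betas_A,betas_B trial x voxel matrices for the two halves (same
#'   voxels).
#' @param cond_A,cond_B condition index per trial in each half; both halves
#'   must contain every condition.
#' @param shrinkage shrinkage weight in `[0, 1]` toward the mean variance.
#' @param identity_cov if TRUE use the identity noise covariance.
#' @return an `rdm` (metric `"ldc"`), entries may be negative.
#' @export
ldc_rdm <- function(betas_A, cond_A, betas_B, cond_B, shrinkage = 0.2,
                    identity_cov = FALSE) {
  conds <- sort(unique(c(cond_A, cond_B)))
  if (!all(conds %in% cond_A) || !all(conds %in% cond_B))
    stop("every condition must be present in both halves")
  nv <- ncol(betas_A)
  stopifnot(ncol(betas_B) == nv)
  mean_and_prec <- function(betas, cond) {
    mu <- t(vapply(conds, function(cd)
      colMeans(betas[cond == cd, , drop = FALSE]), numeric(nv)))
    if (identity_cov) return(list(mu = mu, w = rep(1, nv)))
    resid <- betas - mu[match(cond, conds), , drop = FALSE]
    df <- nrow(betas) - length(conds)
    v <- if (df > 0) colSums(resid^2) / df else rep(1, nv)
    v <- (1 - shrinkage) * v + shrinkage * mean(v)
    list(mu = mu, w = 1 / v)          # inverse of the diagonal covariance
  }
  A <- mean_and_prec(betas_A, cond_A)
  B <- mean_and_prec(betas_B, cond_B)
  pi <- pair_index(length(conds))
  dA <- A$mu[pi$i, , drop = FALSE] - A$mu[pi$j, , drop = FALSE]
  dB <- B$mu[pi$i, , drop = FALSE] - B$mu[pi$j, , drop = FALSE]
  ab <- rowSums(sweep(dA, 2, A$w, "*") * dB) / nv
  ba <- rowSums(sweep(dB, 2, B$w, "*") * dA) / nv
  new_rdm((ab + ba) / 2, length(conds), metric = "ldc")
}

#' Enumerate split-quarter cross-validation plans
#'
#' Runs are divided into a fit half and a test half of `n_runs / 2` runs
#' each; all `choose(n_runs, n_runs / 2)` ordered (fit, test) assignments are
#' enumerated (70 plans for 8 runs). Within each half, the two quarters are
#' assigned by a fixed canonical rule: the sorted runs of the half alternate
#' between quarters.
#'
#' @param n_runs number of runs; must be divisible by 4.
#' @return list of `split_plan` objects with elements `fit_half`,
#'   `test_half`, `fit_quarters`, `test_quarters`.
#' @export
enumerate_splits <- function(n_runs = 8) {
  if (n_runs %% 4 != 0) stop("n_runs must be divisible by 4")
  half <- n_runs / 2
  combos <- utils::combn(n_runs, half)
  quarters <- function(runs) {
    runs <- sort(runs)
    list(runs[seq(1, length(runs), by = 2)],
         runs[seq(2, length(runs), by = 2)])
  }
  lapply(seq_len(ncol(combos)), function(k) {
    fit <- combos[, k]
    test <- setdiff(seq_len(n_runs), fit)
    structure(list(fit_half = fit, test_half = test,
                   fit_quarters = quarters(fit),
                   test_quarters = quarters(test)),
              class = "split_plan")
  })
}

#' Kendall's tau-a rank correlation
#'
#' `(concordant - discordant) / (n * (n - 1) / 2)`: the denominator counts
#' all pairs, so ties reduce the attainable correlation (unlike tau-b). This
#' is the appropriate variant when a model predicting tied values should not
#' be rewarded for them.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return tau-a in `[-1, 1]`.
#' @export
kendall_tau_a <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  if (n < 2) stop("need at least 2 observations")
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  ut <- upper.tri(sx)
  sum(sx[ut] * sy[ut]) / (n * (n - 1) / 2)
}

#' Leave-one-pair-out non-negative least-squares RDM prediction
#'
#' Model-channel RDMs are combined with non-negative weights to predict a
#' data RDM. For each condition pair (i, j), weights are fit by NNLS on all
#' pairs that involve neither i nor j, and the held-out entry is predicted
#' from those weights; assembling all entries yields the predicted RDM. The
#' design includes an unconstrained intercept (implemented as a +1/-1 column
#' pair) because LDC data RDMs carry an arbitrary offset relative to model
#' units.
#'
#' @param channel_rdms list of `rdm` objects (the model channels).
#' @param fit_rdm the data `rdm` to fit.
#' @param intercept include the unconstrained intercept column.
#' @return predicted `rdm` with attribute `"weights"` (pairs x channels
#'   matrix of the NNLS weights fit for each held-out pair).
#' @export
nnls_fit_predict <- function(channel_rdms, fit_rdm, intercept = TRUE) {
  n <- attr(fit_rdm, "n_conditions")
  pi <- pair_index(n)
  X <- do.call(cbind, lapply(channel_rdms, as.numeric))
  stopifnot(nrow(X) == length(fit_rdm))
  y <- as.numeric(fit_rdm)
  if (intercept) X <- cbind(X, 1, -1)
  pred <- numeric(nrow(X))
  W <- matrix(NA_real_, nrow(X), length(channel_rdms))
  for (p in seq_len(nrow(X))) {
    keep <- pi$i != pi$i[p] & pi$i != pi$j[p] &
      pi$j != pi$i[p] & pi$j != pi$j[p]
    if (sum(keep) < 1)
      stop("fewer than 2 conditions remain after excluding the held-out pair")
    w <- pracma::lsqnonneg(X[keep, , drop = FALSE], y[keep])$x
    pred[p] <- sum(X[p, ] * w)
    W[p, ] <- w[seq_along(channel_rdms)]
  }
  out <- new_rdm(pred, n, metric = "nnls_prediction")
  attr(out, "weights") <- W
  out
}

# run-by-scene mean patterns for RSA: one pattern per (run, scene)
run_scene_patterns <- function(vps, runs) {
  keep <- vps$run_of_trial %in% runs
  betas <- vps$betas[keep, , drop = FALSE]
  scene <- vps$scene_of_trial[keep]
  run <- vps$run_of_trial[keep]
  key <- interaction(run, scene, drop = TRUE)
  mu <- rowsum(betas, key) / as.vector(table(key))
  parts <- do.call(rbind, strsplit(rownames(mu), ".", fixed = TRUE))
  list(betas = mu, scene = as.integer(parts[, 2]), run = as.integer(parts[, 1]))
}

# LDC between the two quarters of one half
half_ldc <- function(vps, quarters, shrinkage = 0.2, identity_cov = FALSE) {
  qa <- run_scene_patterns(vps, quarters[[1]])
  qb <- run_scene_patterns(vps, quarters[[2]])
  ldc_rdm(qa$betas, qa$scene, qb$betas, qb$scene, shrinkage, identity_cov)
}

#' Cross-validated model evaluation over all split-quarter plans
#'
#' For each split plan: an LDC RDM is computed between the two quarters of
#' the fit half, model channels are fit to it with leave-one-pair-out NNLS
#' producing a predicted RDM, an independent LDC RDM is computed from the
#' test half's quarters, and the predicted and test RDMs are compared with
#' Kendall's tau-a. The per-plan correlations are averaged.
#'
#' @param vps a `voxel_pattern_set` (all runs).
#' @param channel_rdms list of model-channel `rdm`s.
#' @param splits optional list of `split_plan`s (defaults to all plans for
#'   the set's number of runs).
#' @param shrinkage,identity_cov passed to the LDC noise covariance.
#' @return list with `mean_tau_a` and `tau_a_per_split`.
#' @export
evaluate_model <- function(vps, channel_rdms, splits = NULL, shrinkage = 0.2,
                           identity_cov = FALSE) {
  if (is.null(splits)) splits <- enumerate_splits(max(vps$run_of_trial))
  taus <- vapply(splits, function(sp) {
    stopifnot(length(intersect(sp$fit_half, sp$test_half)) == 0)
    fit_rdm <- half_ldc(vps, sp$fit_quarters, shrinkage, identity_cov)
    pred <- nnls_fit_predict(channel_rdms, fit_rdm)
    test_rdm <- half_ldc(vps, sp$test_quarters, shrinkage, identity_cov)
    kendall_tau_a(as.numeric(pred), as.numeric(test_rdm))
  }, numeric(1))
  list(mean_tau_a = mean(taus), tau_a_per_split = taus)
}

#' Noise ceiling for model correlations
#'
#' The upper bound is the mean over subjects of tau-a between each subject's
#' RDM and the all-subject mean RDM; the lower bound replaces the mean RDM by
#' the leave-one-subject-out mean.
#'
#' @param subject_rdms list of `rdm`s (or numeric vectors) of equal length,
#'   one per subject; at least 2 subjects.
#' @return named numeric `c(lower, upper)`.
#' @export
noise_ceiling <- function(subject_rdms) {
  if (length(subject_rdms) < 2) stop("noise ceiling needs at least 2 subjects")
  M <- do.call(rbind, lapply(subject_rdms, as.numeric))
  mu <- colMeans(M)
  upper <- mean(vapply(seq_len(nrow(M)), function(s)
    kendall_tau_a(M[s, ], mu), numeric(1)))
  lower <- mean(vapply(seq_len(nrow(M)), function(s)
    kendall_tau_a(M[s, ], colMeans(M[-s, , drop = FALSE])), numeric(1)))
  c(lower = lower, upper = upper)
}

#' Sliding-bin model comparison along a scene ordering
#'
#' Scenes are ordered (typically by predictability) and RSA model evaluation
#' is repeated in sliding windows of `bin_size` scenes (stride 1), yielding
#' `n - bin_size + 1` bins. When exactly two models are supplied, a paired
#' two-sided Wilcoxon signed-rank test across subjects compares them within
#' each bin and p-values are corrected across bins with the
#' Benjamini-Yekutieli FDR procedure, which remains valid under the
#' dependence induced by overlapping bins.
#'
#' @param scene_order integer vector: scene indices from most to least
#'   predictable.
#' @param models named list; each element is a list of channel `rdm`s over
#'   the full scene set.
#' @param patterns list of `voxel_pattern_set`, one per subject.
#' @param bin_size scenes per bin (>= 2).
#' @param splits,shrinkage,identity_cov passed to [evaluate_model()].
#' @return list with `tau` (bin x model x subject array), `bins` (list of
#'   scene index vectors), and for two models `p_raw`, `p_adj`.
#' @export
binned_model_comparison <- function(scene_order, models, patterns,
                                    bin_size = 8, splits = NULL,
                                    shrinkage = 0.2, identity_cov = FALSE) {
  if (length(scene_order) < bin_size)
    stop("bin_size larger than the number of scenes")
  n_bins <- length(scene_order) - bin_size + 1
  bins <- lapply(seq_len(n_bins), function(b)
    scene_order[b:(b + bin_size - 1)])
  tau <- array(NA_real_, dim = c(n_bins, length(models), length(patterns)),
               dimnames = list(NULL, names(models), NULL))
  for (b in seq_len(n_bins)) {
    scenes <- bins[[b]]
    for (m in seq_along(models)) {
      sub_rdms <- lapply(models[[m]], subset_rdm, conditions = scenes)
      for (s in seq_along(patterns)) {
        vps <- subset_patterns(patterns[[s]], scenes = scenes)
        vps$scene_of_trial <- match(vps$scene_of_trial, scenes)
        tau[b, m, s] <- evaluate_model(vps, sub_rdms, splits, shrinkage,
                                       identity_cov)$mean_tau_a
      }
    }
  }
  out <- list(tau = tau, bins = bins)
  if (length(models) == 2) {
    p_raw <- vapply(seq_len(n_bins), function(b)
      stats::wilcox.test(tau[b, 1, ], tau[b, 2, ], paired = TRUE,
                         alternative = "two.sided",
                         exact = FALSE)$p.value, numeric(1))
    out$p_raw <- p_raw
    out$p_adj <- stats::p.adjust(p_raw, method = "BY")
  }
  out
}
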
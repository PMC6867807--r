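#' Z-score trial patterns across voxels
#'
#' Each trial's beta vector is standardized to mean 0 and SD 1 across voxels.
#' This removes trial-wise global amplitude differences before decoding and
#' is computed per trial vector, independently of any cross-validation fold,
#' so it cannot leak information between folds.
#'
#' @param patterns trial x voxel numeric matrix.
#' @return matrix of the same shape.
#' @export
znorm <- function(patterns) {
  patterns <- as.matrix(patterns)
  if (ncol(patterns) < 2) stop("need at least 2 voxels to z-score")
  sds <- apply(patterns, 1, stats::sd)
  if (any(sds == 0)) stop("constant trial vector cannot be z-scored")
  (patterns - rowMeans(patterns)) / sds
}

# pairwise (one-vs-one) linear SVM with majority voting; vote ties are broken
# by the summed signed decision values accumulated per class
svm_ovo_predict <- function(train_x, train_y, test_x, cost = 1) {
  train_y <- droplevels(factor(train_y))
  classes <- levels(train_y)
  fit <- e1071::svm(train_x, train_y, kernel = "linear", cost = cost,
                    scale = FALSE)
  dv <- attr(stats::predict(fit, test_x, decision.values = TRUE),
             "decision.values")
  votes <- matrix(0, nrow(test_x), length(classes),
                  dimnames = list(NULL, classes))
  score <- votes
  for (cn in colnames(dv)) {
    pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
    d <- dv[, cn]
    votes[, pair[1]] <- votes[, pair[1]] + (d > 0)
    votes[, pair[2]] <- votes[, pair[2]] + (d <= 0)
    score[, pair[1]] <- score[, pair[1]] + d
    score[, pair[2]] <- score[, pair[2]] - d
  }
  pred <- vapply(seq_len(nrow(test_x)), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) top <- top[which.max(score[i, top])]
    classes[top]
  }, character(1))
  factor(pred, levels = classes)
}

#' Leave-one-run-out cross-validated decoding
#'
#' Single-trial linear SVM decoding with a pairwise (one-vs-one) multiclass
#' scheme. Trial patterns are z-scored across voxels, a model is trained on
#' all runs but one and tested on the held-out run, and this is repeated so
#' every run serves once as the test set. For `"category"` and `"depth"`
#' targets, scene labels are collapsed to the group label before training
#' and testing.
#'
#' @param vps a `voxel_pattern_set`.
#' @param label_type `"scene"`, `"category"` or `"depth"`.
#' @param cost SVM regularization parameter.
#' @return object of class `decoding_result`: `accuracy_per_fold`,
#'   `mean_accuracy`, `chance_level`, `n_classes`, `label_type`.
#' @export
loro_decode <- function(vps, label_type = c("scene", "category", "depth"),
                        cost = 1) {
  label_type <- match.arg(label_type)
  labels <- trial_labels(vps, label_type)
  runs <- sort(unique(vps$run_of_trial))
  if (length(runs) < 2) stop("need at least 2 runs for leave-one-run-out CV")
  x <- znorm(vps$betas)
  acc <- vapply(runs, function(r) {
    tr <- vps$run_of_trial != r
    if (nlevels(droplevels(labels[tr])) < nlevels(droplevels(labels)))
      stop("a class is absent from the training folds for run ", r)
    pred <- svm_ovo_predict(x[tr, , drop = FALSE], labels[tr],
                            x[!tr, , drop = FALSE], cost)
    mean(as.character(pred) == as.character(labels[!tr]))
  }, numeric(1))
  k <- nlevels(droplevels(labels))
  structure(list(accuracy_per_fold = stats::setNames(acc, paste0("run", runs)),
                 mean_accuracy = mean(acc), chance_level = 1 / k,
                 n_classes = k, label_type = label_type),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result [%s]: mean accuracy %.3f (chance %.3f, %d folds)\n",
              x$label_type, x$mean_accuracy, x$chance_level,
              length(x$accuracy_per_fold)))
  invisible(x)
}

#' Permutation test of decoding accuracy
#'
#' Builds a null distribution by shuffling training-set labels within each
#' training fold while leaving test labels intact, refitting the classifier
#' for every shuffle. The p-value uses the standard add-one rule
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @inheritParams loro_decode
#' @param n_perm number of label shuffles (>= 1).
#' @param seed integer RNG seed.
#' @return object of class `permutation_null`: `null_accuracies`, `observed`,
#'   `p_value`, `chance_level`.
#' @export
permutation_test <- function(vps, label_type = c("scene", "category", "depth"),
                             n_perm = 1000, seed = 1, cost = 1) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  label_type <- match.arg(label_type)
  observed <- loro_decode(vps, label_type, cost)$mean_accuracy
  labels <- trial_labels(vps, label_type)
  runs <- sort(unique(vps$run_of_trial))
  x <- znorm(vps$betas)
  set.seed(seed)
  null_acc <- vapply(seq_len(n_perm), function(p) {
    fold_acc <- vapply(runs, function(r) {
      tr <- vps$run_of_trial != r
      ytr <- sample(labels[tr])       # shuffle within the training fold only
      pred <- svm_ovo_predict(x[tr, , drop = FALSE], ytr,
                              x[!tr, , drop = FALSE], cost)
      mean(as.character(pred) == as.character(labels[!tr]))
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  p <- (1 + sum(null_acc >= observed)) / (1 + n_perm)
  structure(list(null_accuracies = null_acc, observed = observed,
                 p_value = p, chance_level = 1 / nlevels(droplevels(labels))),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null: observed %.3f, null mean %.3f (%d perms), p = %.4g\n",
              x$observed, mean(x$null_accuracies),
              length(x$null_accuracies), x$p_value))
  invisible(x)
}

#' Cross-classification over held-out scenes
#'
#' Tests whether category (or depth) information generalizes to scenes never
#' seen during training. Per iteration, one scene per category (or per depth
#' class) is held out, so training uses 18 of 24 scenes for category and 22
#' of 24 for depth; the classifier is trained on group labels of the
#' remaining scenes' trials and tested on the held-out scenes' trials, with
#' leave-one-run-out independence between train and test data. Accuracies are
#' averaged over `n_iter` random hold-out draws.
#'
#' @inheritParams loro_decode
#' @param grouping `"category"` or `"depth"`.
#' @param n_iter number of random hold-out iterations.
#' @param seed integer RNG seed.
#' @return a `decoding_result` whose `accuracy_per_fold` holds per-iteration
#'   accuracies and with attribute `n_train_scenes`.
#' @export
cross_classify <- function(vps, grouping = c("category", "depth"),
                           n_iter = 100, seed = 1, cost = 1) {
  grouping <- match.arg(grouping)
  labels <- trial_labels(vps, grouping)
  scene <- vps$scene_of_trial
  scene_group <- tapply(as.character(labels), scene, function(v) v[1])
  groups <- split(as.integer(names(scene_group)), scene_group)
  if (length(unique(lengths(groups))) > 1)
    stop("cannot balance hold-out: groups have unequal numbers of scenes")
  runs <- sort(unique(vps$run_of_trial))
  x <- znorm(vps$betas)
  set.seed(seed)
  acc <- vapply(seq_len(n_iter), function(it) {
    held <- vapply(groups, function(g) if (length(g) == 1) g else sample(g, 1),
                   numeric(1))
    te_scene <- scene %in% held
    fold_acc <- vapply(runs, function(r) {
      tr <- !te_scene & vps$run_of_trial != r
      te <- te_scene & vps$run_of_trial == r
      pred <- svm_ovo_predict(x[tr, , drop = FALSE], labels[tr],
                              x[te, , drop = FALSE], cost)
      mean(as.character(pred) == as.character(labels[te]))
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  k <- nlevels(droplevels(labels))
  res <- structure(list(accuracy_per_fold = acc, mean_accuracy = mean(acc),
                        chance_level = 1 / k, n_classes = k,
                        label_type = grouping),
                   class = "decoding_result")
  attr(res, "n_train_scenes") <- length(unique(scene)) - length(groups)
  res
}

#' Group-level one-sided Wilcoxon signed-rank test against chance
#'
#' @param per_subject_accuracy numeric vector, one mean accuracy per subject
#'   (at least 5 subjects).
#' @param chance chance level to test against.
#' @return p-value for the one-sided alternative (median above chance).
#' @export
group_test <- function(per_subject_accuracy, chance) {
  if (length(per_subject_accuracy) < 5)
    stop("group test needs at least 5 subjects")
  d <- per_subject_accuracy - chance
  if (all(d == 0)) stop("all subjects exactly at chance: no signed ranks")
  stats::wilcox.test(per_subject_accuracy, mu = chance,
                     alternative = "greater", exact = TRUE)$p.value
}
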
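#' Cross-validated decision vectors
#'
#' Runs the full pipeline under stratified n-fold cross-validation: for
#' each fold, trains a classifier bank on the training split and
#' predicts per-direction decision vectors for every held-out subject.
#' The decision vectors are independent of the run-length threshold `k`,
#' so any k-sweep can reuse them as a pure post-processing pass.
#'
#' @param cohort An [mri_cohort] with both classes.
#' @param bank_config A [bank_config()].
#' @param n_folds Number of folds.
#' @param seed Seed controlling fold assignment (bank seeding comes from
#'   `bank_config$seed`).
#' @param verbose Print per-fold progress.
#' @return List with `decision_vectors` (named per subject), `fold`
#'   (named integer), `folds` (the [split_folds()] output) and `labels`.
#' @export
cv_decision_vectors <- function(cohort, bank_config, n_folds = 10L,
                                seed = 1L, verbose = FALSE) {
  folds <- split_folds(cohort, n_folds, seed)
  labels <- cohort_labels(cohort)
  dvs <- list()
  fold_of <- integer(0)
  for (f in seq_along(folds)) {
    if (verbose) message("fold ", f, "/", length(folds))
    bank <- train_bank(cohort_subset(cohort, folds[[f]]$train), bank_config)
    pred <- predict_decision_vectors(bank,
                                     cohort_subset(cohort, folds[[f]]$test))
    dvs[names(pred)] <- pred
    fold_of[names(pred)] <- f
  }
  ids <- cohort_ids(cohort)
  list(decision_vectors = dvs[ids], fold = fold_of[ids],
       folds = folds, labels = labels[ids])
}

eval_from_dvs <- function(cv, k) {
  ids <- names(cv$decision_vectors)
  pred <- vapply(cv$decision_vectors, diagnose, integer(1), k = k)
  labels <- cv$labels
  per_fold <- vapply(seq_along(cv$folds), function(f) {
    sel <- cv$fold[ids] == f
    mean(pred[sel] == labels[sel])
  }, numeric(1))
  confusion <- table(truth = factor(labels, levels = c(0L, 1L)),
                     prediction = factor(pred, levels = c(0L, 1L)))
  structure(
    list(per_fold_accuracy = per_fold,
         overall_accuracy = mean(pred == labels),
         confusion = confusion,
         k = as.integer(k),
         predictions = data.frame(subject_id = ids, label = labels,
                                  fold = cv$fold[ids], prediction = pred,
                                  row.names = NULL),
         decision_vectors = cv$decision_vectors),
    class = "sf_eval"
  )
}

#' @export
print.sf_eval <- function(x, ...) {
  cat("<sf_eval> pooled accuracy ", sprintf("%.4f", x$overall_accuracy),
      " over ", length(x$per_fold_accuracy), " folds (k = ", x$k, ")\n",
      sep = "")
  print(x$confusion)
  invisible(x)
}

#' Cross-validated diagnosis accuracy
#'
#' Pooled (micro-averaged) accuracy of the subject-level diagnosis under
#' stratified n-fold cross-validation at run-length threshold `k`.
#'
#' @inheritParams cv_decision_vectors
#' @param k Run-length threshold.
#' @return An `sf_eval` object: per-fold and pooled accuracy, 2 x 2
#'   confusion table, per-subject predictions, and the cached decision
#'   vectors (reusable for localization or other `k`).
#' @export
cross_validate <- function(cohort, bank_config, k = 3L, n_folds = 10L,
                           seed = 1L, verbose = FALSE) {
  cv <- cv_decision_vectors(cohort, bank_config, n_folds, seed, verbose)
  eval_from_dvs(cv, k)
}

#' Select the run-length threshold k by cross-validated accuracy
#'
#' Trains the banks once (predictions do not depend on `k`) and sweeps
#' the decision stage over `k_grid`, reporting pooled accuracy per `k`
#' and the accuracy-maximizing value (smallest on ties). The customary
#' grid is `{2, 3, 4, 5}`.
#'
#' @inheritParams cv_decision_vectors
#' @param k_grid Integer vector of candidate thresholds (all >= 1).
#' @return List with `table` (data.frame `k`, `accuracy`), `best_k`, and
#'   `evals` (named list of `sf_eval`, one per k).
#' @export
select_k <- function(cohort, bank_config, k_grid = 2:5, n_folds = 10L,
                     seed = 1L, verbose = FALSE) {
  k_grid <- as.integer(k_grid)
  if (!length(k_grid) || any(k_grid < 1L)) stop("`k_grid` must be >= 1")
  cv <- cv_decision_vectors(cohort, bank_config, n_folds, seed, verbose)
  evals <- lapply(k_grid, function(k) eval_from_dvs(cv, k))
  names(evals) <- paste0("k", k_grid)
  acc <- vapply(evals, `[[`, numeric(1), "overall_accuracy")
  list(table = data.frame(k = k_grid, accuracy = unname(acc)),
       best_k = k_grid[which.max(acc)],
       evals = evals)
}

#' Mean localization overlap of an evaluation result
#'
#' Mean intersection-over-union between each true-positive subject's
#' predicted lesion mask (k-filtered separable intersection of its
#' decision vectors) and a reference mask. Returns 0 when there are no
#' true positives (documented convention).
#'
#' @param eval_result An `sf_eval` from [cross_validate()].
#' @param truth A [lesion_mask].
#' @param k Run-length threshold; defaults to the one stored in
#'   `eval_result`.
#' @return List with `mean_iou`, `n_true_positives`, `per_subject`
#'   (named numeric vector of IoU values).
#' @export
mean_localization_iou <- function(eval_result, truth, k = eval_result$k) {
  stopifnot(inherits(eval_result, "sf_eval"), inherits(truth, "lesion_mask"))
  p <- eval_result$predictions
  tp <- p$subject_id[p$label == 1L & p$prediction == 1L]
  if (!length(tp))
    return(list(mean_iou = 0, n_true_positives = 0L,
                per_subject = numeric(0)))
  ious <- vapply(tp, function(id)
    localization_overlap(subject_mask(eval_result$decision_vectors[[id]], k),
                         truth), numeric(1))
  list(mean_iou = mean(ious), n_true_positives = length(tp),
       per_subject = ious)
}

#' Phantom recovery experiment
#'
#' End-to-end check of the pipeline on a synthetic cohort with a known
#' planted lesion: generates the phantom, runs stratified
#' cross-validation, and reports pooled diagnosis accuracy together with
#' the mean localization IoU of true positives against the planted
#' truth. With `n_folds = 2` this reduces to a symmetric train/holdout
#' split.
#'
#' @param config A [phantom_config()].
#' @param bank_config A [bank_config()].
#' @param k Run-length threshold.
#' @param n_folds Number of CV folds.
#' @param seed Seed for the fold split (the phantom uses `config$seed`).
#' @return List with `accuracy`, `mean_iou`, `n_true_positives`, `eval`
#'   (the `sf_eval`), and `truth`.
#' @export
recovery_experiment <- function(config, bank_config, k = 3L, n_folds = 5L,
                                seed = config$seed, verbose = FALSE) {
  ph <- generate_cohort(config)
  ev <- cross_validate(ph$cohort, bank_config, k = k, n_folds = n_folds,
                       seed = seed, verbose = verbose)
  loc <- mean_localization_iou(ev, ph$truth_mask, k)
  list(accuracy = ev$overall_accuracy, mean_iou = loc$mean_iou,
       n_true_positives = loc$n_true_positives, eval = ev,
       truth = ph$truth_mask)
}
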
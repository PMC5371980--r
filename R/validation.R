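# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into k folds, so class proportions are preserved and
# every held-out fold contains both classes whenever each class has >= k.
stratified_folds <- function(classes, k) {
  fold <- integer(length(classes))
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validated AUC of a marker combination
#'
#' Estimates out-of-sample discrimination: samples are split into `k`
#' class-stratified folds; for each fold the score model is fitted on the
#' remaining folds only (for the GLM score) and the held-out samples are
#' scored and summarized by AUC. Performance is the mean of the per-fold
#' AUCs. Fully reproducible given `seed`.
#'
#' @param dataset A [marker_dataset()].
#' @param members Character vector of marker names forming the combination.
#' @param method Score construction, see [combo_score()].
#' @param thr Signal cutoff for the count score.
#' @param k Number of folds (default 10).
#' @param seed Integer RNG seed for the fold assignment.
#' @return An object of class `cv_result`: `k`, `fold_aucs`, `mean_auc`,
#'   `fold_assignment` (integer vector aligned with samples), `seed`.
#' @export
cross_validate <- function(dataset, members, method = c("glm", "count"),
                           thr = NULL, k = 10, seed = 1) {
  method <- match.arg(method)
  dataset <- drop_incomplete(dataset)
  if (k < 2) stop("`k` must be >= 2")
  class_n <- table(dataset$classes)
  if (any(class_n < k))
    stop("smallest class has ", min(class_n), " samples; choose k <= ",
         min(class_n))
  fold <- with_seed(seed, stratified_folds(dataset$classes, k))
  fold_aucs <- vapply(seq_len(k), function(f) {
    test <- fold == f
    scorer <- if (method == "glm") {
      train <- marker_dataset(dataset$values[!test, , drop = FALSE],
                              dataset$classes[!test],
                              positive_label = dataset$positive_label,
                              sample_ids = dataset$sample_ids[!test],
                              marker_names = dataset$marker_names)
      fit_glm_score(train, members)
    } else {
      if (is.null(thr)) stop("`thr` is required for the count score")
      function(values) rowSums(values[, members, drop = FALSE] > thr)
    }
    sc <- scorer(dataset$values[test, , drop = FALSE])
    roc_curve(sc, dataset$classes[test], dataset$positive_label)$auc
  }, numeric(1))
  structure(list(k = k, fold_aucs = fold_aucs, mean_auc = mean(fold_aucs),
                 fold_assignment = fold, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV: mean AUC = %.4f (range %.3f-%.3f)\n",
              x$k, x$mean_auc, min(x$fold_aucs), max(x$fold_aucs)))
  invisible(x)
}

#' Permutation test for AUC significance
#'
#' Builds a null AUC distribution by repeatedly shuffling the class labels
#' (the marker matrix is left intact), refitting the score model on the
#' permuted labels and recomputing the AUC. The empirical p-value uses the
#' add-one estimator `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, which
#' can never report zero.
#'
#' @inheritParams cross_validate
#' @param n_perm Number of label permutations (default 1000).
#' @return An object of class `permutation_result`: `observed_auc`,
#'   `null_aucs`, `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(dataset, members, method = c("glm", "count"),
                             thr = NULL, n_perm = 1000, seed = 1) {
  method <- match.arg(method)
  dataset <- drop_incomplete(dataset)
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  auc_for <- function(classes) {
    ds <- marker_dataset(dataset$values, classes,
                         positive_label = dataset$positive_label,
                         sample_ids = dataset$sample_ids,
                         marker_names = dataset$marker_names)
    sc <- combo_score(ds, members, method = method, thr = thr)
    roc_curve(sc, classes, dataset$positive_label)$auc
  }
  observed <- auc_for(dataset$classes)
  null_aucs <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    auc_for(sample(dataset$classes)), numeric(1)))
  p <- (1 + sum(null_aucs >= observed)) / (1 + n_perm)
  structure(list(observed_auc = observed, null_aucs = null_aucs,
                 p_value = p, n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed AUC = %.4f, null mean = %.4f, p = %.4g (%d permutations)\n",
    x$observed_auc, mean(x$null_aucs), x$p_value, x$n_perm))
  invisible(x)
}
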
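# Evaluation protocols: top-k weighted accuracy, confusion matrices,
# stratified k-fold cross-validation, cross-platform transfer, the
# feature-band sweep, and the cross-platform correlation diagnostic.

truth_vector <- function(preds, truth) {
  if (inherits(truth, "expression_matrix") || inherits(truth, "enrichment_matrix")) {
    truth <- truth$origin_class
  }
  missing <- setdiff(preds$samples, names(truth))
  if (length(missing)) stop("missing truth label: ", paste(missing, collapse = ", "))
  tv <- truth[preds$samples]
  if (anyNA(tv)) stop("missing truth label: ",
                      paste(preds$samples[is.na(tv)], collapse = ", "))
  tv
}

#' Top-k weighted accuracy
#'
#' Fraction of samples whose true class appears among the k highest-ranked
#' predictions. Pooled over samples, this equals the class-support-weighted
#' mean of the per-class top-k accuracies (hence "weighted accuracy").
#'
#' @param preds An `origin_predictions` object.
#' @param truth Named character vector mapping sample ID to true class (or
#'   an annotated matrix whose `origin_class` is used).
#' @param k Rank cutoff.
#' @return Accuracy in `[0, 1]`.
#' @export
topk_weighted_accuracy <- function(preds, truth, k) {
  tv <- truth_vector(preds, truth)
  tk <- top_k(preds, k)
  mean(vapply(seq_along(tv), function(i) tv[[i]] %in% tk[i, ], logical(1)))
}

#' Per-class top-k accuracy
#'
#' @inheritParams topk_weighted_accuracy
#' @return Named numeric vector: for each true class, the fraction of its
#'   samples whose truth is within the top k predictions.
#' @export
per_class_topk <- function(preds, truth, k) {
  tv <- truth_vector(preds, truth)
  tk <- top_k(preds, k)
  hit <- vapply(seq_along(tv), function(i) tv[[i]] %in% tk[i, ], logical(1))
  vapply(split(hit, tv), mean, numeric(1))
}

#' Confusion matrix of top-1 predictions
#'
#' Entry `(t, p)` counts samples with true class `t` and top-1 prediction
#' `p`; row sums equal the true class supports and `trace/n` equals top-1
#' accuracy.
#'
#' @inheritParams topk_weighted_accuracy
#' @param vocab An [origin_vocabulary()] fixing the axis order (defaults to
#'   the prediction vocabulary).
#' @return Integer matrix `[true class x predicted class]`.
#' @export
confusion_matrix <- function(preds, truth, vocab = NULL) {
  vocab <- vocab %||% preds$vocabulary
  tv <- truth_vector(preds, truth)
  p1 <- top_k(preds, 1)[, 1]
  bad <- setdiff(unique(c(tv, p1)), vocab)
  if (length(bad)) stop("class outside vocabulary: ", paste(bad, collapse = ", "))
  cm <- table(factor(tv, levels = vocab), factor(p1, levels = vocab))
  matrix(as.integer(cm), nrow(cm), ncol(cm),
         dimnames = list(truth = as.character(vocab),
                         predicted = as.character(vocab)))
}

#' Cross-platform transfer validation
#'
#' Trains the ensemble on all samples of one platform and scores it on all
#' samples of the other, returning the macro-averaged F1 over the classes
#' present in the test split. Test classes absent from training cannot be
#' predicted; they are excluded from the macro mean with a warning.
#'
#' @param em An `enrichment_matrix` spanning exactly two platforms, fully
#'   labeled.
#' @param sel A `feature_selection` (or character vector of features).
#' @param train_platform Platform label to train on.
#' @param grid,seed Passed to [train_origin_model()].
#' @param cv_folds Tuning folds.
#' @return Macro-F1 on the held-out platform; the trained model, the
#'   predictions and the per-class F1 are attached as attributes.
#' @export
cross_platform_validation <- function(em, sel, train_platform,
                                      grid = default_grid(), seed = 1,
                                      cv_folds = 3) {
  plats <- unique(em$platform)
  if (length(plats) != 2L) stop("need exactly two platforms")
  if (!train_platform %in% plats) stop("unknown platform: ", train_platform)
  tr_ids <- names(em$platform)[em$platform == train_platform]
  te_ids <- names(em$platform)[em$platform != train_platform]
  model <- train_origin_model(subset_samples(em, tr_ids), sel, grid = grid,
                              cv_folds = cv_folds, seed = seed)
  em_te <- subset_samples(em, te_ids)
  preds <- predict(model, em_te)
  tv <- truth_vector(preds, em_te)
  test_classes <- sort(unique(unname(tv)))
  scored <- intersect(test_classes, model$vocabulary)
  dropped <- setdiff(test_classes, scored)
  if (length(dropped)) {
    warning("class absent from training excluded from macro-F1: ",
            paste(dropped, collapse = ", "))
  }
  p1 <- top_k(preds, 1)[, 1]
  f1 <- vapply(scored, function(cls) macro_f1(tv, p1, classes = cls), numeric(1))
  out <- mean(f1)
  attr(out, "per_class_f1") <- f1
  attr(out, "model") <- model
  attr(out, "predictions") <- preds
  out
}

#' Stratified k-fold cross-validation
#'
#' Shuffles samples into k class-stratified folds, trains on k-1 folds and
#' scores top-1 accuracy on the held-out fold.
#'
#' @param em Fully labeled `enrichment_matrix`.
#' @param sel Features to use.
#' @param k Number of folds; every class needs at least k samples.
#' @param grid,seed Passed to [train_origin_model()].
#' @param cv_folds Inner tuning folds for each training run.
#' @return Numeric vector of k per-fold top-1 accuracies.
#' @export
kfold_cv <- function(em, sel, k = 5, grid = default_grid(), seed = 1,
                     cv_folds = 3) {
  y <- em$origin_class
  if (anyNA(y)) stop("every sample needs an origin_class label")
  folds <- stratified_folds(y, k, derive_seed(seed, 11L))
  vapply(seq_len(k), function(fold) {
    tr_ids <- colnames(em$values)[folds != fold]
    te_ids <- colnames(em$values)[folds == fold]
    model <- train_origin_model(subset_samples(em, tr_ids), sel, grid = grid,
                                cv_folds = cv_folds, seed = seed)
    em_te <- subset_samples(em, te_ids)
    topk_weighted_accuracy(predict(model, em_te), em_te, k = 1)
  }, numeric(1))
}

#' Sweep feature-selection bands and training-cohort compositions
#'
#' For each band half-width delta, selects features on the full (two
#' platform) training matrix, then trains on each cohort composition —
#' platform A only, platform B only, and A+B combined — and reports top-1
#' weighted accuracy on the test matrix. A delta whose band is empty is
#' reported as failed and the sweep continues.
#'
#' @param em_train Fully labeled two-platform `enrichment_matrix`.
#' @param em_test Labeled `enrichment_matrix` to evaluate on.
#' @param deltas Numeric vector of band half-widths.
#' @param grid,seed,cv_folds Passed to [train_origin_model()].
#' @return Data frame with columns `delta`, `training_platforms`,
#'   `n_features`, `accuracy`, `status`.
#' @export
band_sweep <- function(em_train, em_test, deltas, grid = default_grid(),
                       seed = 1, cv_folds = 3) {
  if (!length(deltas)) stop("deltas must be nonempty")
  plats <- sort(unique(em_train$platform))
  if (length(plats) != 2L) stop("need exactly two platforms in em_train")
  aucs <- feature_auc(em_train, positive_platform = plats[1])
  comps <- list(plats[1], plats[2], plats)
  names(comps) <- c(plats, paste(plats, collapse = "+"))

  rows <- list()
  for (delta in deltas) {
    sel <- tryCatch(select_band(aucs, delta, positive_platform = plats[1]),
                    error = function(e) e)
    for (ci in seq_along(comps)) {
      comp_name <- names(comps)[ci]
      if (inherits(sel, "error")) {
        rows[[length(rows) + 1L]] <-
          data.frame(delta = delta, training_platforms = comp_name,
                     n_features = 0L, accuracy = NA_real_, status = "failed")
        next
      }
      ids <- names(em_train$platform)[em_train$platform %in% comps[[ci]]]
      acc <- tryCatch({
        model <- train_origin_model(subset_samples(em_train, ids), sel,
                                    grid = grid, cv_folds = cv_folds,
                                    seed = seed)
        topk_weighted_accuracy(predict(model, em_test), em_test, k = 1)
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(delta = delta, training_platforms = comp_name,
                   n_features = length(sel$selected), accuracy = acc,
                   status = if (is.na(acc)) "failed" else "ok")
    }
  }
  do.call(rbind, rows)
}

#' Cross-platform correlation diagnostic
#'
#' Quantifies how comparable the two platforms are before and after
#' featurization: for one origin class, computes the per-feature mean
#' vector on each platform and returns the Pearson correlation between the
#' two platforms' mean vectors, at the gene-expression level and at the
#' gene-set-score level. Rank-based featurization should raise the
#' correlation when the platforms apply different monotone distortions to
#' expression.
#'
#' @param expr An [expression_matrix()].
#' @param em The matching `enrichment_matrix`.
#' @param class_label Origin class to profile; both platforms need at least
#'   2 samples of it.
#' @return Named numeric vector `c(gene_level_r, set_level_r)`.
#' @export
platform_correlation_diagnostic <- function(expr, em, class_label) {
  level_r <- function(x) {
    plats <- sort(unique(x$platform))
    if (length(plats) != 2L) stop("need exactly two platforms")
    mv <- lapply(plats, function(p) {
      ids <- names(x$platform)[x$platform == p &
                                 !is.na(x$origin_class) &
                                 x$origin_class == class_label]
      if (length(ids) < 2L) stop("class ", class_label,
                                 " needs >= 2 samples on platform ", p)
      rowMeans(x$values[, ids, drop = FALSE])
    })
    if (stats::sd(mv[[1]]) == 0 || stats::sd(mv[[2]]) == 0) {
      stop("zero variance in per-class mean vector")
    }
    stats::cor(mv[[1]], mv[[2]])
  }
  c(gene_level_r = level_r(expr), set_level_r = level_r(em))
}

#' Full evaluation report
#'
#' @inheritParams topk_weighted_accuracy
#' @param ks Rank cutoffs to report.
#' @param fold_scores Optional per-fold accuracies from [kfold_cv()].
#' @return An `evaluation_report`: confusion matrix, top-k weighted
#'   accuracies, per-class top-k accuracies, macro-F1, and fold scores.
#' @export
evaluation_report <- function(preds, truth, ks = c(1, 2), fold_scores = NULL) {
  tv <- truth_vector(preds, truth)
  p1 <- top_k(preds, 1)[, 1]
  structure(list(
    confusion = confusion_matrix(preds, truth),
    top_k_accuracy = stats::setNames(
      vapply(ks, function(k) topk_weighted_accuracy(preds, truth, k), numeric(1)),
      paste0("top", ks)),
    per_class_topk = lapply(stats::setNames(ks, paste0("top", ks)),
                            function(k) per_class_topk(preds, truth, k)),
    macro_f1 = macro_f1(tv, p1, classes = sort(unique(unname(tv)))),
    fold_scores = fold_scores
  ), class = "evaluation_report")
}

#' @method print evaluation_report
#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  for (nm in names(x$top_k_accuracy)) {
    cat(sprintf("  %s weighted accuracy: %.3f\n", nm, x$top_k_accuracy[[nm]]))
  }
  cat(sprintf("  macro-F1: %.3f\n", x$macro_f1))
  invisible(x)
}

#' Write an evaluation report (JSON) and its confusion matrix (TSV)
#'
#' @param report An `evaluation_report`.
#' @param json_path Output JSON path.
#' @param confusion_path Optional TSV path for the confusion matrix.
#' @export
write_report <- function(report, json_path, confusion_path = NULL) {
  out <- list(top_k_accuracy = as.list(report$top_k_accuracy),
              per_class_topk = lapply(report$per_class_topk, as.list),
              macro_f1 = report$macro_f1,
              fold_scores = report$fold_scores)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(confusion_path)) {
    df <- data.frame(truth = rownames(report$confusion), report$confusion,
                     check.names = FALSE)
    utils::write.table(df, confusion_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}
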
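# Origin classification: a soft-voting ensemble of three base learners over
# selected gene-set features — multinomial ridge regression (glmnet),
# gradient-boosted trees (xgboost), and an RBF-kernel SVM with probability
# outputs (e1071). Hyperparameters are tuned by grid search with stratified
# cross-validation maximizing macro-F1; the ensemble averages the members'
# class-probability vectors.

#' Default hyperparameter grid
#'
#' @return A list with one element per ensemble member: `logistic` (inverse
#'   regularization strength `cost`), `gbt` (`num_leaves`, `n_estimators`,
#'   fixed `learning_rate`), `svm` (`cost`; the RBF kernel width is set by
#'   the median heuristic on the training data).
#' @export
default_grid <- function() {
  list(logistic = list(cost = c(0.1, 1, 10)),
       gbt = list(num_leaves = c(15, 31), n_estimators = c(100, 300),
                  learning_rate = 0.1),
       svm = list(cost = c(1, 10)))
}

#' Small hyperparameter grid for quick runs
#'
#' One configuration per member; useful for smoke tests and sweeps where
#' the full grid of [default_grid()] is unnecessarily expensive.
#' @return A grid list in the same shape as [default_grid()].
#' @export
small_grid <- function() {
  list(logistic = list(cost = 1),
       gbt = list(num_leaves = 31, n_estimators = 100, learning_rate = 0.1),
       svm = list(cost = 1))
}

# lambda for glmnet's ridge penalty from an sklearn-style inverse
# regularization strength C
lambda_of_cost <- function(cost, n) 1 / (cost * n)

# RBF kernel width 1/sigma^2 by the median heuristic: median squared
# euclidean distance between (up to 256) training rows.
median_heuristic_gamma <- function(X, seed) {
  idx <- seq_len(nrow(X))
  if (length(idx) > 256L) {
    idx <- withr::with_seed(derive_seed(seed, 1L), sample(idx, 256L))
  }
  d2 <- as.numeric(stats::dist(X[idx, , drop = FALSE]))^2
  med <- stats::median(d2)
  if (!is.finite(med) || med <= 0) 1 / ncol(X) else 1 / med
}

fit_member_logistic <- function(X, y, costs, weights) {
  n <- nrow(X)
  lams <- sort(unique(lambda_of_cost(costs, n)), decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                        lambda = lams, weights = weights,
                        standardize = FALSE)
  list(kind = "logistic", fit = fit, n_train = n)
}

predict_member_logistic <- function(member, X, vocab, cost) {
  s <- lambda_of_cost(cost, member$n_train)
  p <- stats::predict(member$fit, X, s = s, type = "response")[, , 1, drop = TRUE]
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
  p[, vocab, drop = FALSE]
}

fit_member_gbt <- function(X, y, vocab, num_leaves, n_rounds, learning_rate,
                           weights, seed) {
  d <- xgboost::xgb.DMatrix(X, label = as.integer(factor(y, levels = vocab)) - 1L,
                            weight = weights, nthread = 1)
  params <- list(objective = "multi:softprob", num_class = length(vocab),
                 eta = learning_rate, max_leaves = num_leaves,
                 grow_policy = "lossguide", max_depth = 0,
                 tree_method = "hist", nthread = 1, seed = seed)
  fit <- xgboost::xgb.train(params = params, data = d, nrounds = n_rounds,
                            verbose = 0)
  list(kind = "gbt", fit = fit)
}

predict_member_gbt <- function(member, X, vocab, n_estimators = NULL) {
  d <- xgboost::xgb.DMatrix(X, nthread = 1)
  p <- if (is.null(n_estimators)) {
    stats::predict(member$fit, d)
  } else {
    stats::predict(member$fit, d, iterationrange = c(1, n_estimators))
  }
  colnames(p) <- vocab
  p
}

fit_member_svm <- function(X, y, vocab, cost, gamma, class_weights, seed) {
  yf <- factor(y, levels = vocab)
  withr::with_seed(derive_seed(seed, 2L), {
    fit <- e1071::svm(x = X, y = yf, kernel = "radial", cost = cost,
                      gamma = gamma, probability = TRUE, scale = FALSE,
                      class.weights = class_weights)
  })
  list(kind = "svm", fit = fit)
}

predict_member_svm <- function(member, X, vocab) {
  pr <- stats::predict(member$fit, X, probability = TRUE)
  p <- attr(pr, "probabilities")
  p[, vocab, drop = FALSE]
}

#' Train the soft-voting origin classifier
#'
#' Restricts the enrichment matrix to the selected features, standardizes
#' each feature to zero mean / unit variance using training statistics
#' (stored in the model and reapplied at prediction time), and fits the
#' three ensemble members, each tuned independently by grid search with
#' stratified `cv_folds`-fold cross-validation maximizing macro-F1 on the
#' pooled out-of-fold predictions. Deterministic given `seed`.
#'
#' @param em An `enrichment_matrix` with an origin-class label for every
#'   sample; at least 2 classes, each with at least `cv_folds` samples.
#' @param sel A `feature_selection` (or a character vector of feature
#'   names); every selected feature must be present in `em`.
#' @param grid Hyperparameter grid, see [default_grid()].
#' @param cv_folds Folds for the tuning cross-validation.
#' @param seed Integer seed controlling fold assignment and the stochastic
#'   members.
#' @param balanced If `TRUE`, weight training samples inversely to class
#'   frequency (`n / (K * n_class)`).
#' @return An `origin_model`.
#' @export
train_origin_model <- function(em, sel, grid = default_grid(), cv_folds = 3,
                               seed = 1, balanced = FALSE) {
  features <- if (inherits(sel, "feature_selection")) sel$selected else sel
  missing <- setdiff(features, rownames(em$values))
  if (length(missing)) stop("unknown feature: ", paste(missing, collapse = ", "))
  y <- em$origin_class
  if (anyNA(y)) stop("every training sample needs an origin_class label")
  vocab <- origin_vocabulary(sort(unique(unname(y))))
  if (length(vocab) < 2L) stop("need at least 2 origin classes")
  counts <- table(y)
  if (any(counts < cv_folds)) {
    stop("class with fewer samples than folds: ",
         paste(names(counts)[counts < cv_folds], collapse = ", "))
  }

  X <- t(em$values[features, , drop = FALSE])
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")

  weights <- rep(1, length(y))
  if (balanced) {
    w_class <- length(y) / (length(vocab) * counts)
    weights <- as.numeric(w_class[y])
  }
  class_weights <- if (balanced) {
    stats::setNames(as.numeric(length(y) / (length(vocab) * counts[vocab])), vocab)
  } else NULL

  gamma <- median_heuristic_gamma(Xs, seed)
  folds <- stratified_folds(y, cv_folds, derive_seed(seed, 3L))
  best <- tune_members(Xs, y, vocab, grid, folds, weights, class_weights,
                       gamma, seed)

  members <- list(
    logistic = c(fit_member_logistic(Xs, y, grid$logistic$cost, weights),
                 list(cost = best$logistic$cost)),
    gbt = c(fit_member_gbt(Xs, y, vocab, best$gbt$num_leaves,
                           best$gbt$n_estimators,
                           grid$gbt$learning_rate %||% 0.1,
                           weights, seed),
            list(num_leaves = best$gbt$num_leaves,
                 n_estimators = best$gbt$n_estimators)),
    svm = c(fit_member_svm(Xs, y, vocab, best$svm$cost, gamma,
                           class_weights, seed),
            list(cost = best$svm$cost))
  )

  structure(list(vocabulary = vocab, features = features,
                 center = center, scale = scale, gamma = gamma,
                 members = members, weights = rep(1 / 3, 3),
                 training_meta = list(grid = grid, best = best,
                                      cv_folds = cv_folds, seed = seed,
                                      balanced = balanced,
                                      n_train = length(y))),
            class = "origin_model")
}

# Grid search: pooled out-of-fold macro-F1 per candidate, first maximum wins.
tune_members <- function(Xs, y, vocab, grid, folds, weights, class_weights,
                         gamma, seed) {
  k <- max(folds)
  n <- length(y)
  score_of <- function(pred) macro_f1(y, pred, classes = vocab)

  costs_log <- grid$logistic$cost
  leaves <- grid$gbt$num_leaves
  n_est <- sort(grid$gbt$n_estimators)
  lr <- grid$gbt$learning_rate %||% 0.1
  costs_svm <- grid$svm$cost

  oof_log <- matrix(NA_character_, n, length(costs_log))
  oof_gbt <- array(NA_character_, c(n, length(leaves), length(n_est)))
  oof_svm <- matrix(NA_character_, n, length(costs_svm))

  for (fold in seq_len(k)) {
    tr <- folds != fold; va <- !tr
    Xtr <- Xs[tr, , drop = FALSE]; Xva <- Xs[va, , drop = FALSE]
    ytr <- y[tr]; wtr <- weights[tr]

    ml <- fit_member_logistic(Xtr, ytr, costs_log, wtr)
    for (ci in seq_along(costs_log)) {
      p <- predict_member_logistic(ml, Xva, vocab, costs_log[ci])
      oof_log[va, ci] <- vocab[max.col(p, ties.method = "first")]
    }
    for (li in seq_along(leaves)) {
      mg <- fit_member_gbt(Xtr, ytr, vocab, leaves[li], max(n_est), lr,
                           wtr, seed)
      for (ni in seq_along(n_est)) {
        p <- predict_member_gbt(mg, Xva, vocab, n_estimators = n_est[ni])
        oof_gbt[va, li, ni] <- vocab[max.col(p, ties.method = "first")]
      }
    }
    for (ci in seq_along(costs_svm)) {
      ms <- fit_member_svm(Xtr, ytr, vocab, costs_svm[ci], gamma,
                           class_weights, seed)
      p <- predict_member_svm(ms, Xva, vocab)
      oof_svm[va, ci] <- vocab[max.col(p, ties.method = "first")]
    }
  }

  f1_log <- apply(oof_log, 2L, score_of)
  gbt_combo <- expand.grid(li = seq_along(leaves), ni = seq_along(n_est))
  f1_gbt <- mapply(function(li, ni) score_of(oof_gbt[, li, ni]),
                   gbt_combo$li, gbt_combo$ni)
  f1_svm <- apply(oof_svm, 2L, score_of)

  gb <- gbt_combo[which.max(f1_gbt), ]
  list(logistic = list(cost = costs_log[which.max(f1_log)],
                       cv_macro_f1 = max(f1_log)),
       gbt = list(num_leaves = leaves[gb$li], n_estimators = n_est[gb$ni],
                  cv_macro_f1 = max(f1_gbt)),
       svm = list(cost = costs_svm[which.max(f1_svm)],
                  cv_macro_f1 = max(f1_svm)))
}

#' Predict origin-class probabilities for new samples
#'
#' Soft vote: the weighted mean of the three members' class-probability
#' vectors, renormalized to sum to 1. The per-sample ranking orders classes
#' by decreasing probability, ties broken by vocabulary order.
#'
#' @param object An `origin_model`.
#' @param em An `enrichment_matrix` containing all model features.
#' @param ... Unused.
#' @return An `origin_predictions` object: `samples`, `vocabulary`, and a
#'   `probs` matrix `[samples x classes]`.
#' @export
predict.origin_model <- function(object, em, ...) {
  missing <- setdiff(object$features, rownames(em$values))
  if (length(missing)) stop("missing feature: ", paste(missing, collapse = ", "))
  X <- t(em$values[object$features, , drop = FALSE])
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  vocab <- object$vocabulary

  p_log <- predict_member_logistic(object$members$logistic, Xs, vocab,
                                   object$members$logistic$cost)
  p_gbt <- predict_member_gbt(object$members$gbt, Xs, vocab)
  p_svm <- predict_member_svm(object$members$svm, Xs, vocab)

  w <- object$weights / sum(object$weights)
  probs <- w[1] * p_log + w[2] * p_gbt + w[3] * p_svm
  probs <- probs / rowSums(probs)
  rownames(probs) <- colnames(em$values)

  structure(list(samples = colnames(em$values),
                 vocabulary = vocab, probs = probs),
            class = "origin_predictions")
}

#' @method print origin_predictions
#' @export
print.origin_predictions <- function(x, ...) {
  cat(sprintf("<origin_predictions> %d samples x %d classes\n",
              length(x$samples), length(x$vocabulary)))
  invisible(x)
}

#' @method print origin_model
#' @export
print.origin_model <- function(x, ...) {
  cat(sprintf("<origin_model> %d classes, %d features, members: %s\n",
              length(x$vocabulary), length(x$features),
              paste(names(x$members), collapse = " + ")))
  invisible(x)
}

# Per-sample class ranking by decreasing probability; ties broken by
# vocabulary order.
prediction_ranking <- function(pred) {
  t(apply(pred$probs, 1L, function(p) {
    pred$vocabulary[order(-p, seq_along(p))]
  }))
}

#' Top-k ranked classes per sample
#'
#' @param pred An `origin_predictions` object.
#' @param k Number of top-ranked classes, `1 <= k <= |vocabulary|`.
#' @return Character matrix `[samples x k]`, row names the sample IDs.
#' @export
top_k <- function(pred, k) {
  K <- length(pred$vocabulary)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > K) {
    stop("k must lie in 1..", K)
  }
  r <- prediction_ranking(pred)[, seq_len(k), drop = FALSE]
  rownames(r) <- pred$samples
  r
}

#' Turn predictions into a table
#'
#' @param x An `origin_predictions` object.
#' @param ... Unused.
#' @return Data frame: `sample_id`, one probability column per class, then
#'   `top1` and `top2` (the latter only when the vocabulary has >= 2
#'   classes).
#' @export
as.data.frame.origin_predictions <- function(x, ...) {
  r <- prediction_ranking(x)
  df <- data.frame(sample_id = x$samples, x$probs, check.names = FALSE,
                   row.names = NULL)
  df$top1 <- r[, 1]
  if (length(x$vocabulary) >= 2L) df$top2 <- r[, 2]
  df
}

#' Save / load a fitted origin model
#'
#' Serialized as a single versioned archive; a load/save round trip
#' reproduces predictions bit-identically within a package version.
#'
#' @param model An `origin_model`.
#' @param path Archive path.
#' @export
save_origin_model <- function(model, path) {
  model$members$gbt$fit_raw <- xgboost::xgb.save.raw(model$members$gbt$fit)
  model$members$gbt$fit <- NULL
  saveRDS(list(format_version = 1L,
               package_version = as.character(utils::packageVersion("cuporigin")),
               model = model), path)
  invisible(path)
}

#' @rdname save_origin_model
#' @return `load_origin_model`: the restored `origin_model`.
#' @export
load_origin_model <- function(path) {
  archive <- readRDS(path)
  if (!identical(archive$format_version, 1L)) {
    stop("unsupported model archive version")
  }
  model <- archive$model
  model$members$gbt$fit <- xgboost::xgb.load.raw(model$members$gbt$fit_raw)
  model$members$gbt$fit_raw <- NULL
  model
}

#' Write predictions as TSV
#'
#' @param pred An `origin_predictions` object.
#' @param path Output path.
#' @export
write_predictions <- function(pred, path) {
  df <- as.data.frame(pred)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
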
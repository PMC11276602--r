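hand_preds <- function() {
  # 10 samples over three classes with known top-1 hits:
  # class a: 3 samples all correct; class b: 2 samples, 1 correct;
  # class c: 5 samples, none correct.
  vocab <- c("a", "b", "c")
  probs <- rbind(
    a1 = c(0.8, 0.1, 0.1), a2 = c(0.7, 0.2, 0.1), a3 = c(0.6, 0.3, 0.1),
    b1 = c(0.1, 0.8, 0.1), b2 = c(0.6, 0.3, 0.1),
    c1 = c(0.5, 0.3, 0.2), c2 = c(0.5, 0.3, 0.2), c3 = c(0.2, 0.5, 0.3),
    c4 = c(0.4, 0.35, 0.25), c5 = c(0.45, 0.3, 0.25))
  colnames(probs) <- vocab
  truth <- c(a1 = "a", a2 = "a", a3 = "a", b1 = "b", b2 = "b",
             c1 = "c", c2 = "c", c3 = "c", c4 = "c", c5 = "c")
  list(preds = make_preds(probs, vocab), truth = truth)
}

test_that("pooled top-k accuracy equals the support-weighted per-class mean", {
  h <- hand_preds()
  acc1 <- topk_weighted_accuracy(h$preds, h$truth, 1)
  per <- per_class_topk(h$preds, h$truth, 1)
  expect_equal(unname(per), c(1.0, 0.5, 0.0))
  support <- table(h$truth)[names(per)]
  expect_equal(acc1, sum(per * support) / sum(support))
  expect_equal(acc1, 0.4)
  expect_equal(topk_weighted_accuracy(h$preds, h$truth, 3), 1.0)
  # monotone in k
  acc2 <- topk_weighted_accuracy(h$preds, h$truth, 2)
  expect_gte(acc2, acc1)
  expect_gte(1.0, acc2)
  expect_error(topk_weighted_accuracy(h$preds, h$truth[-1], 1),
               "missing truth")
})

test_that("confusion matrix conserves supports and its trace gives top-1 accuracy", {
  h <- hand_preds()
  cm <- confusion_matrix(h$preds, h$truth)
  expect_identical(as.integer(rowSums(cm)),
                   unname(as.integer(table(h$truth))))
  expect_equal(sum(diag(cm)) / sum(cm),
               topk_weighted_accuracy(h$preds, h$truth, 1))
  # all-correct predictions give a diagonal matrix
  vocab <- c("a", "b")
  probs <- rbind(x1 = c(0.9, 0.1), x2 = c(0.2, 0.8))
  colnames(probs) <- vocab
  cm2 <- confusion_matrix(make_preds(probs, vocab),
                          c(x1 = "a", x2 = "b"))
  expect_identical(cm2, matrix(c(1L, 0L, 0L, 1L), 2, 2,
                               dimnames = list(truth = vocab,
                                               predicted = vocab)))
  expect_error(confusion_matrix(h$preds, c(h$truth[-10], c5 = "zebra")),
               "outside vocabulary")
})

test_that("stratified k-fold CV returns k deterministic per-fold accuracies", {
  co <- small_cohort()
  em <- co$em
  scores <- kfold_cv(em, rownames(em$values), k = 3, grid = small_grid(),
                     seed = 2)
  expect_length(scores, 3L)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_identical(kfold_cv(em, rownames(em$values), k = 3,
                            grid = small_grid(), seed = 2), scores)
  expect_error(kfold_cv(em, rownames(em$values), k = 50), "infeasible")
})

test_that("cross-platform transfer is bounded by same-split optimism", {
  co <- small_cohort()
  em <- co$em
  transfer <- cross_platform_validation(em, rownames(em$values),
                                        train_platform = "microarray",
                                        grid = small_grid(), seed = 3)
  expect_true(transfer >= 0 && transfer <= 1)
  # degenerate check: scoring the training platform itself is at least as good
  model <- attr(transfer, "model")
  ids_a <- names(em$platform)[em$platform == "microarray"]
  em_a <- subset_samples(em, ids_a)
  p1 <- top_k(predict(model, em_a), 1)[, 1]
  self_f1 <- cuporigin:::macro_f1(em_a$origin_class, p1,
                                  sort(unique(unname(em_a$origin_class))))
  expect_gte(self_f1, as.numeric(transfer))
})

test_that("test-only classes are excluded from transfer macro-F1 with a warning", {
  co <- small_cohort()
  em <- co$em
  # drop one class from the training platform only
  drop <- names(em$platform)[em$platform == "microarray" &
                               em$origin_class == "adrenal_gland"]
  em2 <- subset_samples(em, setdiff(colnames(em$values), drop))
  expect_warning(
    f1 <- cross_platform_validation(em2, rownames(em2$values),
                                    train_platform = "microarray",
                                    grid = small_grid(), seed = 3),
    "absent from training")
  expect_false("adrenal_gland" %in% names(attr(f1, "per_class_f1")))
})

test_that("band sweep reports every delta x composition and survives empty bands", {
  co <- small_cohort()
  em <- co$em
  strat <- paste(em$origin_class, em$platform)
  folds <- cuporigin:::stratified_folds(strat, 4, 17)
  em_tr <- subset_samples(em, colnames(em$values)[folds != 4])
  em_te <- subset_samples(em, colnames(em$values)[folds == 4])
  sw <- band_sweep(em_tr, em_te, deltas = c(0.25, 0.5),
                   grid = small_grid(), seed = 3, cv_folds = 2)
  expect_identical(nrow(sw), 6L)
  expect_setequal(unique(sw$training_platforms),
                  c("microarray", "rnaseq", "microarray+rnaseq"))
  expect_true(all(sw$accuracy[sw$status == "ok"] >= 0))

  # a matrix whose single feature is perfectly platform-separated: every
  # small band is empty, rows are marked failed, and the sweep continues
  vals <- matrix(c(1, 2, 3, 11, 12, 13), 1,
                 dimnames = list("F", paste0("s", 1:6)))
  em_sep <- cuporigin:::new_annotated_matrix(
    vals, platform = rep(c("a", "b"), each = 3),
    origin_class = rep(c("x", "y"), 3),
    class = "enrichment_matrix", what = "gene_set")
  sw2 <- band_sweep(em_sep, em_sep, deltas = 0.1, grid = small_grid(),
                    seed = 1)
  expect_identical(nrow(sw2), 3L)
  expect_true(all(sw2$status == "failed"))
})

test_that("correlation diagnostic is exact on identical platforms and flags degenerate input", {
  withr::with_seed(41, {
    half <- matrix(rlnorm(30 * 4), 30, 4)
  })
  vals <- cbind(half, half)
  dimnames(vals) <- list(sprintf("g%02d", 1:30), paste0("s", 1:8))
  expr <- make_expr(vals, platform = rep(c("a", "b"), each = 4),
                    origin_class = rep("lung", 8))
  gs <- gene_set_collection(list(S1 = sprintf("g%02d", 1:8),
                                 S2 = sprintf("g%02d", 9:16),
                                 S3 = sprintf("g%02d", c(3, 17:22)),
                                 S4 = sprintf("g%02d", 23:30),
                                 S5 = sprintf("g%02d", c(5, 12, 24:28))))
  em <- featurize(expr, gs, n_null = 20, seed = 13)
  r <- platform_correlation_diagnostic(expr, em, "lung")
  expect_equal(unname(r), c(1, 1))
  expect_error(platform_correlation_diagnostic(expr, em, "breast"),
               ">= 2 samples")
  expr_const <- expr
  expr_const$values[, 1:4] <- 1
  expect_error(platform_correlation_diagnostic(expr_const, em, "lung"),
               "zero variance")
})

test_that("evaluation reports serialize their accuracy block", {
  h <- hand_preds()
  rep <- evaluation_report(h$preds, h$truth, ks = c(1, 2))
  expect_equal(unname(rep$top_k_accuracy["top1"]), 0.4)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, jp, cp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$top_k_accuracy$top1, 0.4)
  expect_identical(length(readLines(cp)), 4L)
})
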
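# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

# Stratified fold assignment: every class is spread as evenly as possible
# across folds. Returns an integer vector of fold ids (1..k) aligned with y.
stratified_folds <- function(y, k, seed) {
  y <- as.character(y)
  if (any(table(y) < k)) {
    stop("stratification infeasible: class with fewer than ", k, " samples")
  }
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Macro-averaged F1 over the classes present in `truth`.
# Classes never predicted and never true contribute nothing; a class with
# zero precision+recall gets F1 = 0.
macro_f1 <- function(truth, pred, classes = sort(unique(as.character(truth)))) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  f1 <- vapply(classes, function(cls) {
    tp <- sum(truth == cls & pred == cls)
    fp <- sum(truth != cls & pred == cls)
    fn <- sum(truth == cls & pred != cls)
    denom <- 2 * tp + fp + fn
    if (denom == 0) 0 else 2 * tp / denom
  }, numeric(1))
  mean(f1)
}

# 32-bit polynomial rolling hash of a character scalar; used for config
# fingerprints in machine-readable run logs (no cryptographic intent).
config_hash32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Derive a sub-seed from a base seed and a small integer tag, staying inside
# the 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(tag)) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
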
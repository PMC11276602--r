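# Independent oracles and shared fixtures. The oracles deliberately use the
# naive step-by-step formulation so they share no code with the package.

# Brute-force KS running sum: walk the full ranking, +1/m at members,
# -1/(N-m) otherwise; return the deviation of largest magnitude (positive
# wins ties).
es_oracle <- function(ranking, members) {
  hits <- ranking %in% members
  m <- sum(hits)
  N <- length(ranking)
  # integer step numerators over the common denominator m*(N-m) keep the
  # walk and the tie rule exact
  rs <- cumsum(ifelse(hits, N - m, -m))
  d_plus <- max(rs)   # the walk ends at 0, so max >= 0 and min <= 0
  d_minus <- min(rs)
  num <- if (d_plus >= abs(d_minus)) d_plus else d_minus
  num / (m * (N - m))
}

# ES values are ratios with denominator m*(N-m); comparing the integerized
# numerator makes the check exact regardless of floating-point summation
# order.
expect_same_es <- function(es, oracle, m, N) {
  expect_identical(round(es * m * (N - m), 6),
                   round(oracle * m * (N - m), 6))
}

# Exhaustive pair-counting AUC with half credit for ties.
auc_oracle <- function(pos, neg) {
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Hand-built expression matrix from a dense value matrix.
make_expr <- function(values, platform, origin_class = NULL) {
  expression_matrix(values, platform, origin_class)
}

# Hand-built enrichment-like prediction object for evaluation tests.
make_preds <- function(probs, vocab) {
  structure(list(samples = rownames(probs),
                 vocabulary = origin_vocabulary(vocab),
                 probs = probs),
            class = "origin_predictions")
}

# Small synthetic cohort for module-level classifier/evaluation tests:
# cheap but separable enough to train on.
small_cohort <- function(seed = 7) {
  cfg <- synth_config(n_genes = 600, n_classes = 3,
                      samples_per_class_per_platform = 8,
                      n_gene_sets = 60, set_size_range = c(8, 15),
                      frac_class_informative = 0.4,
                      frac_platform_biased = 0.1,
                      class_effect = 1.2, activation_cv = 0.3,
                      platform_effect = 0.5, seed = seed)
  gen <- synth_generate(cfg)
  em <- featurize(gen$expression, gen$gene_sets, min_set_size = 5,
                  n_null = 50, seed = 13)
  list(gen = gen, em = em)
}

# Default-condition cohort shared by the acceptance properties; featurized
# once per test run on first use.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_cohort <- function() {
  if (is.null(.acceptance_cache$cohort)) {
    cfg <- synth_config()
    gen <- synth_generate(cfg)
    em <- featurize(gen$expression, gen$gene_sets)
    aucs <- feature_auc(em, positive_platform = "microarray")
    .acceptance_cache$cohort <- list(cfg = cfg, gen = gen, em = em,
                                     aucs = aucs)
  }
  .acceptance_cache$cohort
}
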
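# Single-sample gene-set featurization.
#
# Each sample's expression profile is reduced to a ranking of the gene
# universe; each gene set is scored by the unweighted GSEA running sum over
# that ranking, i.e. the signed Kolmogorov-Smirnov statistic comparing the
# rank positions of set members against non-members. Scores are then
# normalized by the mean |ES| of random same-size sets so that sets of
# different sizes are comparable.

#' Rank a sample's genes by decreasing expression
#'
#' Produces the ranked profile that the enrichment score walks over. Ties in
#' expression are broken lexicographically by gene symbol (byte order), so
#' the ranking is a deterministic bijection over the gene universe and is
#' invariant under any strictly increasing transform of the sample's values.
#'
#' @param m An [expression_matrix()].
#' @param sample A sample ID present in `m`.
#' @return An object of class `ranked_profile`: list with `ranking`
#'   (character vector, best-expressed gene first) and `tie_rule`.
#' @export
rank_genes <- function(m, sample) {
  if (!sample %in% colnames(m$values)) stop("unknown sample: ", sample)
  v <- m$values[, sample]
  ord <- order(-v, rownames(m$values), method = "radix")
  structure(list(ranking = rownames(m$values)[ord],
                 tie_rule = "lexicographic"),
            class = "ranked_profile")
}

# Signed KS enrichment score from sorted member positions within a universe
# of size N. Walking the ranking, a member adds 1/m and a non-member
# subtracts 1/(N-m); the score is the deviation of largest magnitude, with
# the positive peak winning ties. The peak can only occur at a member
# position and the trough just before one, so only member positions are
# needed.
es_from_positions <- function(pos, N) {
  m <- length(pos)
  pos <- sort.int(pos)
  i <- seq_len(m)
  # work on integer numerators over the common denominator m*(N-m) so the
  # peak/trough comparison (and the |D+| wins tie rule) is exact
  d_plus <- max(i * (N - m) - (pos - i) * m)
  d_minus <- min((i - 1) * (N - m) - (pos - i) * m)
  num <- if (d_plus >= abs(d_minus)) d_plus else d_minus
  num / (m * (N - m))
}

#' Signed enrichment score of a gene set in a ranked profile
#'
#' Unweighted GSEA running sum (equivalently, the signed two-sample KS
#' statistic on rank positions): members concentrated at the top of the
#' ranking give a score near +1, members concentrated at the bottom a score
#' near -1, and uniformly spread members a score near 0. The sign is taken
#' from the deviation of larger magnitude; at equal magnitude the positive
#' peak wins.
#'
#' @param profile A `ranked_profile` from [rank_genes()] (or a character
#'   vector giving the ranking directly).
#' @param members Character vector of member gene symbols; only members
#'   present in the profile's universe count, and at least one but not all
#'   universe genes must be members.
#' @return A single score in `[-1, 1]`.
#' @export
enrichment_score <- function(profile, members) {
  ranking <- if (inherits(profile, "ranked_profile")) profile$ranking else profile
  pos <- which(ranking %in% members)
  N <- length(ranking)
  if (!length(pos)) stop("gene set has no members in the universe")
  if (length(pos) == N) stop("gene set covers the entire universe")
  es_from_positions(pos, N)
}

# Mean |ES| of n_null uniformly drawn size-m subsets of a size-N universe.
# For a uniformly random set the member positions are a uniform sample of
# 1..N whatever the ranking, so the factor depends only on (N, m, seed).
null_es_factor <- function(N, m, n_null, seed) {
  withr::with_seed(derive_seed(seed, m), {
    mean(abs(vapply(seq_len(n_null), function(i) {
      es_from_positions(sample.int(N, m), N)
    }, numeric(1))))
  })
}

#' Normalize an enrichment score against random same-size sets
#'
#' NES = ES divided by the mean |ES| of `n_null` random gene sets of the
#' same size drawn uniformly without replacement from the profile's
#' universe. The sign of the ES is preserved and the result is deterministic
#' given `(seed, n_null, universe)`.
#'
#' @param es Signed enrichment score.
#' @param set_size Number of set members in the universe.
#' @param profile A `ranked_profile` (or character ranking) defining the
#'   universe size.
#' @param n_null Number of null draws (>= 1).
#' @param seed Integer seed for the null draws.
#' @return The normalized enrichment score.
#' @export
normalize_score <- function(es, set_size, profile, n_null = 100, seed = 13) {
  ranking <- if (inherits(profile, "ranked_profile")) profile$ranking else profile
  N <- length(ranking)
  if (n_null < 1) stop("n_null must be >= 1")
  if (set_size < 1 || set_size >= N) stop("set_size must satisfy 1 <= m < N")
  denom <- null_es_factor(N, set_size, n_null, seed)
  if (denom <= 0) stop("degenerate null: mean |ES| is zero")  # cannot occur for 1 <= m < N
  es / denom
}

#' Featurize an expression cohort into gene-set enrichment scores
#'
#' Converts a gene-by-sample expression matrix into a gene-set-by-sample
#' matrix of signed normalized enrichment scores. Each sample is scored
#' independently (column independence), scoring is rank-based (invariant to
#' any per-sample strictly increasing transform of expression), and the
#' null scaling factor is computed once per distinct surviving set size and
#' reused across samples.
#'
#' Gene sets with fewer than `min_set_size` members present in the matrix's
#' gene universe (or covering the whole universe) are dropped and recorded
#' in the result's `params$dropped_sets`.
#'
#' @param m An [expression_matrix()].
#' @param gs A `gene_set_collection`.
#' @param min_set_size Minimum number of member genes that must be present
#'   in the universe for a set to be scored.
#' @param n_null Null draws per set size for NES scaling.
#' @param seed Integer seed driving the null draws.
#' @return An `enrichment_matrix`: scores matrix `[gene_sets x samples]`,
#'   per-sample `platform`/`origin_class` carried over from `m`, and a
#'   `params` record (`min_set_size`, `n_null`, `seed`, `dropped_sets`).
#' @export
featurize <- function(m, gs, min_set_size = 5, n_null = 100, seed = 13) {
  genes <- rownames(m$values)
  N <- length(genes)
  member_idx <- lapply(gs$sets, function(mem) which(genes %in% mem))
  sizes <- lengths(member_idx)
  keep <- sizes >= min_set_size & sizes < N
  dropped <- names(gs$sets)[!keep]
  if (!any(keep)) stop("no gene set survives the min_set_size filter")
  member_idx <- member_idx[keep]
  sizes <- sizes[keep]

  # position of every gene in every sample's ranking
  S <- ncol(m$values)
  pos <- matrix(0L, N, S)
  for (j in seq_len(S)) {
    ord <- order(-m$values[, j], genes, method = "radix")
    pos[ord, j] <- seq_len(N)
  }

  factors <- vapply(sort(unique(sizes)), function(sz) {
    null_es_factor(N, sz, n_null, seed)
  }, numeric(1))
  names(factors) <- as.character(sort(unique(sizes)))

  scores <- matrix(NA_real_, length(member_idx), S,
                   dimnames = list(names(member_idx), colnames(m$values)))
  for (k in seq_along(member_idx)) {
    idx <- member_idx[[k]]
    fac <- factors[[as.character(sizes[[k]])]]
    for (j in seq_len(S)) {
      scores[k, j] <- es_from_positions(pos[idx, j], N) / fac
    }
  }

  out <- new_annotated_matrix(scores, platform = m$platform,
                              origin_class = m$origin_class,
                              class = "enrichment_matrix", what = "gene_set")
  out$params <- list(min_set_size = min_set_size, n_null = n_null,
                     seed = seed, dropped_sets = dropped)
  out
}

#' @method print enrichment_matrix
#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("<enrichment_matrix> %d gene sets x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$params)) {
    cat(sprintf("  min_set_size=%d, n_null=%d, seed=%d, dropped=%d\n",
                x$params$min_set_size, x$params$n_null, x$params$seed,
                length(x$params$dropped_sets)))
  }
  invisible(x)
}
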
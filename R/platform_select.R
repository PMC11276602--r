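# Platform-neutral feature selection.
#
# Each gene-set feature is scored by the ROC AUC of the single-feature
# classifier separating the two measurement platforms. Features with AUC
# near 0.5 carry no platform signal and are retained; features far from 0.5
# encode platform, not biology, and are dropped.

#' Single-feature platform-discrimination AUC
#'
#' For every gene-set feature, the area under the ROC curve of the
#' one-feature classifier that separates the positive platform from the
#' other. Computed via the tie-corrected rank-sum (Mann-Whitney) identity:
#' `AUC = P(score_pos > score_neg) + 0.5 * P(score_pos == score_neg)`,
#' which is exact and O(n log n) per feature.
#'
#' @param em An `enrichment_matrix` whose samples span exactly two platforms,
#'   with at least one sample of each.
#' @param positive_platform The platform label treated as the positive class.
#' @return Named numeric vector of AUCs in `[0, 1]`, one per feature, in the
#'   matrix's feature order.
#' @export
feature_auc <- function(em, positive_platform) {
  plats <- unique(em$platform)
  if (length(plats) != 2L) {
    stop("need exactly two platforms, found: ", paste(plats, collapse = ", "))
  }
  if (!positive_platform %in% plats) {
    stop("positive_platform not present: ", positive_platform)
  }
  is_pos <- em$platform == positive_platform
  n1 <- sum(is_pos); n2 <- sum(!is_pos)
  aucs <- apply(em$values, 1L, function(v) {
    r <- rank(v)  # midranks handle ties as 1/2
    (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  })
  stats::setNames(as.numeric(aucs), rownames(em$values))
}

#' Retain features within a band around AUC 0.5
#'
#' Keeps exactly the features with `|AUC - 0.5| <= delta` (boundary
#' inclusive, with a 1e-12 guard against floating-point representation of
#' the band edge). Smaller bands are nested inside larger ones.
#'
#' @param aucs Named numeric vector from [feature_auc()].
#' @param delta Band half-width in `(0, 0.5]`.
#' @param positive_platform Optional label recorded for provenance.
#' @return A `feature_selection`: list with `feature_auc`, `band_delta`,
#'   `positive_platform` and `selected` (feature names in input order).
#' @export
select_band <- function(aucs, delta, positive_platform = NA_character_) {
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 0.5) {
    stop("delta must lie in (0, 0.5]")
  }
  if (is.null(names(aucs))) stop("aucs must be named by feature")
  selected <- names(aucs)[abs(aucs - 0.5) <= delta + 1e-12]
  if (!length(selected)) {
    stop(sprintf("no feature within the AUC band 0.5 +/- %g", delta))
  }
  structure(list(feature_auc = aucs, band_delta = delta,
                 positive_platform = positive_platform, selected = selected),
            class = "feature_selection")
}

#' @method print feature_selection
#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d/%d features within AUC 0.5 +/- %g\n",
              length(x$selected), length(x$feature_auc), x$band_delta))
  invisible(x)
}

#' Histogram of platform-discrimination AUCs
#'
#' Bins AUC values over `[0, 1]` with half-open bins `[lo, hi)`; the final
#' bin is closed so AUC = 1 is counted.
#'
#' @param aucs Named numeric vector of AUCs.
#' @param bin_width Bin width; must divide `[0, 1]` into at least 2 bins.
#' @return Data frame with columns `bin_lo`, `bin_hi`, `count`.
#' @export
auc_histogram <- function(aucs, bin_width) {
  if (!is.numeric(bin_width) || bin_width <= 0 || bin_width > 0.5) {
    stop("bin_width must divide (0, 1] into at least 2 bins")
  }
  n_bins <- round(1 / bin_width)
  if (abs(n_bins * bin_width - 1) > 1e-9 || n_bins < 2) {
    stop("bin_width must divide (0, 1] into at least 2 bins")
  }
  bin <- pmin(floor(aucs / bin_width) + 1L, n_bins)
  data.frame(bin_lo = (seq_len(n_bins) - 1) * bin_width,
             bin_hi = seq_len(n_bins) * bin_width,
             count = as.integer(tabulate(bin, nbins = n_bins)))
}

#' Write a feature-selection report
#'
#' TSV with columns `gene_set`, `auc`, `selected` (0/1); the band half-width
#' and positive platform go to a YAML sidecar at `<path>.params.yaml`.
#'
#' @param sel A `feature_selection`.
#' @param path Output TSV path.
#' @export
write_selection <- function(sel, path) {
  df <- data.frame(gene_set = names(sel$feature_auc),
                   auc = unname(sel$feature_auc),
                   selected = as.integer(names(sel$feature_auc) %in% sel$selected))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(band_delta = sel$band_delta,
                        positive_platform = sel$positive_platform),
                   paste0(path, ".params.yaml"))
  invisible(path)
}

#' Read a feature-selection report written by [write_selection()]
#'
#' @param path TSV path (the `<path>.params.yaml` sidecar must exist).
#' @return A `feature_selection`.
#' @export
read_selection <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  params <- yaml::read_yaml(paste0(path, ".params.yaml"))
  structure(list(feature_auc = stats::setNames(df$auc, df$gene_set),
                 band_delta = params$band_delta,
                 positive_platform = params$positive_platform %||% NA_character_,
                 selected = df$gene_set[df$selected == 1L]),
            class = "feature_selection")
}
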
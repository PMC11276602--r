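# Two-platform synthetic cohort generator.
#
# Emulates the structure of a microarray cohort and an RNA-seq cohort
# measuring the same biology: a shared set of origin classes drives
# class-dependent activation of "informative" gene sets on both platforms,
# while "biased" gene sets receive a platform-dependent shift of their
# member genes (injected before ranking, so it contaminates the gene-level
# data the way a real platform effect does) and each platform additionally
# applies its own monotone distortion to the expression scale.

ORGAN_SITES <- c("adrenal_gland", "bile_duct", "bladder", "brain", "breast",
                 "colorectal", "head_and_neck", "kidney", "liver", "lung",
                 "ovary", "pancreas", "prostate", "skin", "stomach",
                 "thyroid", "uterus")

#' Synthetic cohort configuration
#'
#' Defaults define the study conditions used throughout the package's tests:
#' 10,000 genes, 6 origin classes, 20 samples per class per platform (240
#' samples total), 300 gene sets of 15-40 genes of which 20% are
#' class-informative (activated in exactly one class) and 20% are
#' platform-biased. Effects are expressed in units of the per-gene noise SD
#' on the log2 scale; the default platform effect is sized so that biased
#' features reach a platform-discrimination AUC around 0.8-1.0 while
#' informative features stay near 0.5. The microarray transform is strongly
#' compressive (power 0.3), emulating the narrow dynamic range of intensity
#' data relative to RNA-seq estimates.
#'
#' @param n_genes Number of genes.
#' @param n_classes Number of origin classes (named after organ sites, up
#'   to 17).
#' @param samples_per_class_per_platform Samples per (class, platform) cell.
#' @param n_gene_sets Number of gene sets.
#' @param set_size_range Length-2 integer vector, inclusive member-count
#'   range.
#' @param frac_class_informative Fraction of sets activated in exactly one
#'   class.
#' @param frac_platform_biased Fraction of sets whose member genes are
#'   shifted on the second platform only. The two fractions must sum to at
#'   most 1; the remaining sets are background.
#' @param class_effect Mean log2 up-shift, in noise-SD units, of an
#'   informative set's member genes in samples of its class (both
#'   platforms).
#' @param activation_cv Lognormal sdlog of the per-(sample, set) activation
#'   factor multiplying `class_effect`, modelling tumor-to-tumor variation
#'   in pathway activation strength.
#' @param platform_effect Mean log2 shift, in noise-SD units, of a biased
#'   set's member genes on the second platform.
#' @param noise_sd Per-gene Gaussian noise SD on the log2 scale.
#' @param platform_transform Named list (one entry per platform) of monotone
#'   distortions applied to the linear-scale expression values:
#'   `scale * value^exponent + offset` with `scale > 0`, `exponent > 0`.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A validated `synth_config`.
#' @export
synth_config <- function(n_genes = 10000,
                         n_classes = 6,
                         samples_per_class_per_platform = 20,
                         n_gene_sets = 300,
                         set_size_range = c(15, 40),
                         frac_class_informative = 0.2,
                         frac_platform_biased = 0.2,
                         class_effect = 0.4,
                         activation_cv = 0.9,
                         platform_effect = 0.5,
                         noise_sd = 1.0,
                         platform_transform = list(
                           microarray = list(scale = 30, offset = 50, exponent = 0.3),
                           rnaseq = list(scale = 1, offset = 0, exponent = 1)),
                         seed = 1) {
  cfg <- list(n_genes = n_genes, n_classes = n_classes,
              samples_per_class_per_platform = samples_per_class_per_platform,
              n_gene_sets = n_gene_sets, set_size_range = set_size_range,
              frac_class_informative = frac_class_informative,
              frac_platform_biased = frac_platform_biased,
              class_effect = class_effect, activation_cv = activation_cv,
              platform_effect = platform_effect,
              noise_sd = noise_sd, platform_transform = platform_transform,
              seed = seed)
  if (n_genes < 10 || n_gene_sets < 1 || n_classes < 2) {
    stop("invalid config: need n_genes >= 10, n_gene_sets >= 1, n_classes >= 2")
  }
  if (n_classes > length(ORGAN_SITES)) {
    stop("invalid config: at most ", length(ORGAN_SITES), " classes")
  }
  if (length(set_size_range) != 2L || set_size_range[1] < 1 ||
      set_size_range[2] < set_size_range[1] ||
      set_size_range[2] > n_genes) {
    stop("invalid config: bad set_size_range")
  }
  fracs <- c(frac_class_informative, frac_platform_biased)
  if (any(fracs < 0) || any(fracs > 1) || sum(fracs) > 1) {
    stop("invalid config: fractions must lie in [0,1] and sum to <= 1")
  }
  if (class_effect < 0 || platform_effect < 0 || noise_sd <= 0 ||
      activation_cv < 0) {
    stop("invalid config: effects must be >= 0 and noise_sd > 0")
  }
  if (length(platform_transform) != 2L || is.null(names(platform_transform))) {
    stop("invalid config: platform_transform needs two named entries")
  }
  for (tf in platform_transform) {
    if ((tf$scale %||% 1) <= 0 || (tf$exponent %||% 1) <= 0) {
      stop("invalid config: transform must be strictly increasing")
    }
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic two-platform cohort
#'
#' Baseline expression is lognormal per gene (log2 baseline ~ N(7, 2)).
#' Informative sets' member genes are shifted up by
#' `class_effect * noise_sd` (log2 scale) in samples of the assigned class
#' on both platforms; biased sets' member genes are shifted by
#' `platform_effect * noise_sd` on the second platform only; i.i.d.
#' N(0, noise_sd) noise is added per gene and sample; finally each
#' platform's monotone distortion is applied to the linear-scale values.
#'
#' @param cfg A [synth_config()].
#' @return List with `expression` (an [expression_matrix()]), `gene_sets`
#'   (a `gene_set_collection`) and `truth` (a `synth_truth`: `class_of_set`,
#'   `biased_sets`, `sample_labels`, plus the config).
#' @export
synth_generate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  platforms <- names(cfg$platform_transform)
  classes <- ORGAN_SITES[seq_len(cfg$n_classes)]
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  n_per <- cfg$samples_per_class_per_platform

  labels <- expand.grid(rep = seq_len(n_per), class = classes,
                        platform = platforms, stringsAsFactors = FALSE)
  labels$sample_id <- sprintf("%s_%s_%02d", labels$platform, labels$class,
                              labels$rep)

  withr::with_seed(cfg$seed, {
    sizes <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]),
                    cfg$n_gene_sets, replace = TRUE)
    sets <- lapply(sizes, function(sz) sample(genes, sz))
    names(sets) <- sprintf("SET_%03d", seq_len(cfg$n_gene_sets))

    n_inf <- round(cfg$frac_class_informative * cfg$n_gene_sets)
    n_bias <- round(cfg$frac_platform_biased * cfg$n_gene_sets)
    role_order <- sample(names(sets))
    informative <- role_order[seq_len(n_inf)]
    biased <- role_order[n_inf + seq_len(n_bias)]
    class_of_set <- stats::setNames(
      sample(rep_len(classes, n_inf)), informative)

    base_log2 <- stats::rnorm(cfg$n_genes, mean = 7, sd = 2)
    log2_expr <- matrix(base_log2, cfg$n_genes, nrow(labels),
                        dimnames = list(genes, labels$sample_id))
    log2_expr <- log2_expr +
      matrix(stats::rnorm(length(log2_expr), 0, cfg$noise_sd),
             nrow(log2_expr), ncol(log2_expr))

    # Pathway activation varies from tumor to tumor: each sample activates
    # an informative set with a lognormal per-(sample, set) factor around 1.
    for (set_name in informative) {
      cls <- class_of_set[[set_name]]
      cols <- which(labels$class == cls)
      rows <- match(sets[[set_name]], genes)
      act <- stats::rlnorm(length(cols), meanlog = 0,
                           sdlog = cfg$activation_cv)
      log2_expr[rows, cols] <- log2_expr[rows, cols] +
        cfg$class_effect * cfg$noise_sd *
          matrix(act, length(rows), length(cols), byrow = TRUE)
    }
    for (set_name in biased) {
      cols <- labels$platform == platforms[2]
      rows <- match(sets[[set_name]], genes)
      log2_expr[rows, cols] <- log2_expr[rows, cols] +
        cfg$platform_effect * cfg$noise_sd
    }
  })

  values <- 2^log2_expr
  for (p in platforms) {
    tf <- cfg$platform_transform[[p]]
    cols <- labels$platform == p
    values[, cols] <- (tf$scale %||% 1) *
      values[, cols]^(tf$exponent %||% 1) + (tf$offset %||% 0)
  }

  expr <- expression_matrix(values,
                            platform = stats::setNames(labels$platform,
                                                       labels$sample_id),
                            origin_class = stats::setNames(labels$class,
                                                           labels$sample_id))
  truth <- structure(list(class_of_set = class_of_set,
                          biased_sets = biased,
                          sample_labels = labels[, c("sample_id", "platform",
                                                     "class")],
                          config = cfg),
                     class = "synth_truth")
  list(expression = expr,
       gene_sets = gene_set_collection(
         sets, stats::setNames(rep("synthetic", length(sets)), names(sets))),
       truth = truth)
}

#' Check planted-signal recovery against a selection
#'
#' Reports how a feature selection treats the generator's planted signal:
#' the fraction of platform-biased sets excluded, the fraction of
#' class-informative sets retained, and the mean normalized enrichment
#' score of informative sets inside versus outside their assigned class.
#'
#' @param truth A `synth_truth` from the same generation run.
#' @param em The `enrichment_matrix` featurized from that run's expression.
#' @param sel A `feature_selection` computed on `em`.
#' @return List with `biased_excluded_frac`, `informative_retained_frac`,
#'   `informative_nes_in_class`, `informative_nes_out_class`.
#' @export
expected_properties <- function(truth, em, sel) {
  stopifnot(inherits(truth, "synth_truth"))
  known <- names(sel$feature_auc)
  planted <- c(names(truth$class_of_set), truth$biased_sets)
  if (!all(planted %in% union(known, em$params$dropped_sets %||% character()))) {
    stop("mismatched provenance: selection does not cover the planted sets")
  }
  biased <- intersect(truth$biased_sets, known)
  informative <- intersect(names(truth$class_of_set), known)

  in_class <- out_class <- numeric(0)
  for (set_name in informative) {
    cls <- truth$class_of_set[[set_name]]
    if (!set_name %in% rownames(em$values)) next
    is_in <- !is.na(em$origin_class) & em$origin_class == cls
    in_class <- c(in_class, mean(em$values[set_name, is_in]))
    out_class <- c(out_class, mean(em$values[set_name, !is_in]))
  }

  list(
    biased_excluded_frac =
      if (length(biased)) mean(!biased %in% sel$selected) else NA_real_,
    informative_retained_frac =
      if (length(informative)) mean(informative %in% sel$selected) else NA_real_,
    informative_nes_in_class = mean(in_class),
    informative_nes_out_class = mean(out_class)
  )
}

#' Write the generator's ground truth as JSON
#'
#' @param truth A `synth_truth`.
#' @param path Output path.
#' @export
write_synth_truth <- function(truth, path) {
  out <- list(class_of_set = as.list(truth$class_of_set),
              biased_sets = truth$biased_sets,
              sample_labels = truth$sample_labels,
              config = unclass(truth$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
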
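# Data model and file IO: expression matrices, sample metadata, GMT gene-set
# collections, and the TSV matrix dialect used throughout the pipeline.

#' Construct an expression matrix with per-sample annotations
#'
#' The container used by every pipeline stage: a gene-by-sample numeric
#' matrix (expression units are arbitrary — RSEM, normalized intensity, TPM —
#' because downstream featurization is rank-based) plus a platform label and
#' an optional origin-class label per sample.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique, non-empty strings; all
#'   values must be finite.
#' @param platform Character vector of platform labels (e.g. `"microarray"`,
#'   `"rnaseq"`), one per sample, in column order or named by sample ID.
#' @param origin_class Character vector of origin-class labels, one per
#'   sample, or `NULL`/`NA` for unlabeled prediction input.
#' @return An object of class `expression_matrix` with elements `values`,
#'   `platform`, `origin_class` (the latter two named by sample ID).
#' @export
expression_matrix <- function(values, platform, origin_class = NULL) {
  new_annotated_matrix(values, platform, origin_class,
                       class = "expression_matrix", what = "gene")
}

# Shared constructor/validator for expression and enrichment matrices.
new_annotated_matrix <- function(values, platform, origin_class, class, what) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("empty matrix: need at least one ", what, " and one sample")
  }
  rn <- rownames(values); cn <- colnames(values)
  if (is.null(rn) || anyNA(rn) || any(!nzchar(trimws(rn)))) {
    stop(what, " names missing or empty")
  }
  if (anyDuplicated(rn)) stop("duplicate ", what, " names")
  if (is.null(cn) || anyDuplicated(cn)) stop("sample IDs missing or duplicated")
  if (!all(is.finite(values))) stop("non-finite values in matrix")

  align <- function(x, default = NA_character_) {
    if (is.null(x)) x <- rep(default, ncol(values))
    x <- as.character(x)
    if (!is.null(names(x))) {
      if (!setequal(names(x), cn)) stop("annotation names do not match sample IDs")
      x <- x[cn]
    } else if (length(x) != ncol(values)) {
      stop("annotation length does not match sample count")
    }
    names(x) <- cn
    x
  }
  platform <- align(platform)
  if (anyNA(platform)) stop("missing platform label")
  origin_class <- align(origin_class)
  origin_class[!is.na(origin_class) & !nzchar(origin_class)] <- NA_character_

  structure(list(values = values, platform = platform,
                 origin_class = origin_class),
            class = class)
}

#' @method print expression_matrix
#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  platforms:", paste(names(table(x$platform)), table(x$platform),
                            sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' Gene, feature and sample accessors
#'
#' @param x An `expression_matrix` or `enrichment_matrix`.
#' @return Character vector of gene symbols (or gene-set names) / sample IDs.
#' @export
feature_names <- function(x) rownames(x$values)

#' @rdname feature_names
#' @export
sample_ids <- function(x) colnames(x$values)

#' Subset an annotated matrix by sample
#'
#' @param x An `expression_matrix` or `enrichment_matrix`.
#' @param samples Character vector of sample IDs (order preserved).
#' @return The same class of object restricted to `samples`.
#' @export
subset_samples <- function(x, samples) {
  missing <- setdiff(samples, colnames(x$values))
  if (length(missing)) stop("unknown sample: ", paste(missing, collapse = ", "))
  out <- x
  out$values <- x$values[, samples, drop = FALSE]
  out$platform <- x$platform[samples]
  out$origin_class <- x$origin_class[samples]
  out
}

#' Read an expression matrix and its sample metadata
#'
#' The matrix file is TSV with header `gene_id` followed by sample IDs, one
#' gene per row. The metadata file is TSV with columns `sample_id`,
#' `platform`, `origin_class` (`origin_class` may be empty for prediction
#' input). Metadata is joined by sample ID, never by position. Duplicate gene
#' rows (e.g. multiple probes mapped to one symbol) are collapsed by keeping
#' the row with the highest mean expression; gene symbols are trimmed of
#' surrounding whitespace and matched case-sensitively.
#'
#' @param matrix_path Path to the matrix TSV.
#' @param metadata_path Path to the metadata TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  vals <- read_matrix_tsv(matrix_path, what = "gene")
  meta <- read_metadata(metadata_path)
  missing <- setdiff(colnames(vals), meta$sample_id)
  if (length(missing)) {
    stop("unannotated sample: ", paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(vals), meta$sample_id), ]
  expression_matrix(vals,
                    platform = stats::setNames(meta$platform, meta$sample_id),
                    origin_class = stats::setNames(meta$origin_class, meta$sample_id))
}

read_metadata <- function(path) {
  meta <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "platform", "origin_class")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  meta$origin_class[!nzchar(meta$origin_class)] <- NA_character_
  meta
}

# Parse a TSV matrix with a gene_id/gene_set header column, collapsing
# duplicate row labels by highest row mean.
read_matrix_tsv <- function(path, what = c("gene", "gene_set")) {
  what <- match.arg(what)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = NA)
  if (ncol(df) < 2L) stop("malformed header: expected gene column plus samples")
  ids <- trimws(as.character(df[[1]]))
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(vals) == 0L) stop("empty matrix ", path)
  if (!is.numeric(vals)) stop("non-numeric cell in matrix ", path)
  rownames(vals) <- ids
  if (anyDuplicated(ids)) {
    means <- rowMeans(vals)
    # keep, for every duplicated symbol, the row with the highest mean
    ord <- order(ids, -means)
    keep <- ord[!duplicated(ids[ord])]
    vals <- vals[sort(keep), , drop = FALSE]
  }
  vals
}

#' Write an expression or enrichment matrix as TSV
#'
#' Row 1 is `gene_id` (expression) or `gene_set` (enrichment) followed by
#' sample IDs; values are written at full double precision so that a
#' write/read round trip reproduces the matrix to within 1e-12.
#'
#' @param m An `expression_matrix` or `enrichment_matrix`.
#' @param path Output path.
#' @export
write_matrix <- function(m, path) {
  if (ncol(m$values) == 0L) stop("empty sample list")
  label <- if (inherits(m, "enrichment_matrix")) "gene_set" else "gene_id"
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(label, colnames(m$values)), collapse = "\t"), con)
  body <- apply(m$values, 1L, function(row) {
    paste(format(row, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t")
  })
  writeLines(paste(rownames(m$values), body, sep = "\t"), con)
  invisible(path)
}

#' Write sample metadata as TSV
#'
#' @param m An `expression_matrix` or `enrichment_matrix`.
#' @param path Output path.
#' @export
write_metadata <- function(m, path) {
  df <- data.frame(sample_id = colnames(m$values),
                   platform = unname(m$platform),
                   origin_class = ifelse(is.na(m$origin_class), "",
                                         unname(m$origin_class)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...` (the
#' MSigDB dialect). Member symbols duplicated within a line are deduplicated
#' keeping first occurrence; file order is preserved.
#'
#' @param path Path to a GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `description` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list(); desc <- character()
  for (f in fields) {
    if (length(f) < 3L) {
      stop("GMT line with no members: ", f[[1]] %||% "<empty>")
    }
    name <- trimws(f[[1]])
    if (name %in% names(sets)) stop("duplicate gene-set name: ", name)
    members <- unique(trimws(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line with no members: ", name)
    sets[[name]] <- members
    desc[[name]] <- f[[2]]
  }
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (unique set names; members
#'   deduplicated, at least one per set).
#' @param description Optional named character vector of free-text
#'   descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("set names must be unique")
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) < 1L)) stop("every gene set needs at least one member")
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = sets, description = description[names(sets)]),
            class = "gene_set_collection")
}

#' @method print gene_set_collection
#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, member counts %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Write a gene-set collection in GMT format
#'
#' @param gs A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(gs, path) {
  lines <- vapply(names(gs$sets), function(nm) {
    paste(c(nm, gs$description[[nm]], gs$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an enrichment matrix and its sample metadata
#'
#' Counterpart of [write_matrix()] for gene-set-by-sample score matrices
#' (header column `gene_set`).
#'
#' @inheritParams read_expression
#' @return An `enrichment_matrix`.
#' @export
read_enrichment <- function(matrix_path, metadata_path) {
  vals <- read_matrix_tsv(matrix_path, what = "gene_set")
  meta <- read_metadata(metadata_path)
  missing <- setdiff(colnames(vals), meta$sample_id)
  if (length(missing)) {
    stop("unannotated sample: ", paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(vals), meta$sample_id), ]
  new_annotated_matrix(vals,
                       platform = stats::setNames(meta$platform, meta$sample_id),
                       origin_class = stats::setNames(meta$origin_class, meta$sample_id),
                       class = "enrichment_matrix", what = "gene_set")
}

#' Construct an origin-class vocabulary
#'
#' A fixed, ordered list of origin-class names; the order is used for every
#' probability vector and confusion-matrix axis derived from it.
#'
#' @param classes Character vector of unique, non-empty class names.
#' @return Character vector of class `origin_vocabulary`.
#' @export
origin_vocabulary <- function(classes) {
  classes <- as.character(classes)
  if (!length(classes) || anyNA(classes) || any(!nzchar(classes))) {
    stop("class names must be non-empty")
  }
  if (anyDuplicated(classes)) stop("duplicate class names")
  structure(classes, class = "origin_vocabulary")
}
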
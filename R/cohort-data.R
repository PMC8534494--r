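#' Cohort expression dataset
#'
#' The unit of analysis for the multicohort pipeline: one cohort's
#' genes-by-samples expression matrix together with per-sample class labels
#' and a platform tag. Array-like cohorts carry continuous log2-scale
#' expression; counts cohorts carry non-negative integer read counts that
#' must be run through [preprocess_counts()] before co-normalization.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids) and
#'   samples in columns (colnames = sample ids).
#' @param class_labels Character vector, one label per sample, each one of
#'   `"responder"`, `"nonresponder"` or `"control"`. Responders are coded 1
#'   and non-responders 0 wherever a binary response label is needed.
#' @param cohort_id Single string identifying the cohort.
#' @param platform `"array"` for continuous log2-scale expression or
#'   `"counts"` for raw RNA-seq counts.
#'
#' @return An object of class `cohort_dataset`: a list with elements `expr`,
#'   `class_labels`, `cohort_id` and `platform`.
#' @seealso [generate_multicohort()], [preprocess_counts()],
#'   [coconut_normalize()]
#' @export
cohort_dataset <- function(expr, class_labels, cohort_id,
                           platform = c("array", "counts")) {
  platform <- match.arg(platform)
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("`expr` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("`expr` must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(expr)))
    stop("gene ids must be unique")
  if (anyDuplicated(colnames(expr)))
    stop("sample ids must be unique")
  class_labels <- as.character(class_labels)
  if (length(class_labels) != ncol(expr))
    stop("`class_labels` must have one entry per sample")
  bad <- setdiff(unique(class_labels), c("responder", "nonresponder", "control"))
  if (length(bad))
    stop("invalid class labels: ", paste(bad, collapse = ", "))
  if (anyNA(class_labels))
    stop("class label missing for at least one sample")
  if (platform == "counts" && (any(expr < 0) || any(expr != floor(expr))))
    stop("counts platform requires non-negative integer expression values")
  names(class_labels) <- colnames(expr)
  structure(
    list(expr = expr, class_labels = class_labels,
         cohort_id = as.character(cohort_id)[1], platform = platform),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  tab <- table(factor(x$class_labels,
                      levels = c("responder", "nonresponder", "control")))
  cat(sprintf("<cohort_dataset> %s [%s]: %d genes x %d samples (%d R / %d NR / %d HC)\n",
              x$cohort_id, x$platform, nrow(x$expr), ncol(x$expr),
              tab[["responder"]], tab[["nonresponder"]], tab[["control"]]))
  invisible(x)
}

#' @rdname cohort_dataset
#' @param x A `cohort_dataset`.
#' @export
gene_ids <- function(x) rownames(x$expr)

#' @rdname cohort_dataset
#' @export
sample_ids <- function(x) colnames(x$expr)

#' Subset a cohort dataset by samples and/or genes
#'
#' @param x A [cohort_dataset()].
#' @param samples,genes Character vectors of ids to keep (default: all).
#' @return A `cohort_dataset` restricted to the requested ids, in the
#'   requested order.
#' @export
cohort_subset <- function(x, samples = sample_ids(x), genes = gene_ids(x)) {
  missing_s <- setdiff(samples, sample_ids(x))
  missing_g <- setdiff(genes, gene_ids(x))
  if (length(missing_s))
    stop("unknown sample ids: ", paste(utils::head(missing_s, 5), collapse = ", "))
  if (length(missing_g))
    stop("unknown gene ids: ", paste(utils::head(missing_g, 5), collapse = ", "))
  cohort_dataset(x$expr[genes, samples, drop = FALSE],
                 x$class_labels[samples], x$cohort_id, x$platform)
}

#' Split a cohort into diseased (responder/non-responder) and control parts
#'
#' @param x A [cohort_dataset()].
#' @return `diseased_samples()` and `control_samples()` return the
#'   corresponding sample subset as a `cohort_dataset` (possibly with zero
#'   samples).
#' @export
diseased_samples <- function(x) {
  keep <- sample_ids(x)[x$class_labels != "control"]
  cohort_subset(x, samples = keep)
}

#' @rdname diseased_samples
#' @export
control_samples <- function(x) {
  keep <- sample_ids(x)[x$class_labels == "control"]
  cohort_subset(x, samples = keep)
}

#' Binary response labels for the diseased samples of a cohort
#'
#' @param x A [cohort_dataset()].
#' @return Named integer vector over diseased samples: responder = 1,
#'   non-responder = 0.
#' @export
response_labels <- function(x) {
  lab <- x$class_labels[x$class_labels != "control"]
  stats::setNames(as.integer(lab == "responder"), names(lab))
}

#' Intersect the gene universes of several cohorts
#'
#' Genes not measured in every cohort are excluded from all downstream
#' analyses, mirroring the shared-gene universe of a multicohort study.
#'
#' @param datasets List of [cohort_dataset()] objects.
#' @return Character vector of gene ids present in every cohort, in the order
#'   of the first cohort.
#' @export
shared_genes <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  Reduce(intersect, lapply(datasets, gene_ids))
}

# ---- Plain-text interchange -------------------------------------------------

#' Read and write cohort expression matrices and sample metadata as TSV
#'
#' Expression files are tab-separated with gene ids in the first column
#' (header `gene_id`) and one column per sample. The metadata file has
#' columns `sample_id`, `cohort_id`, `class`, `platform`.
#'
#' @param x A [cohort_dataset()] (for writers) .
#' @param path File path.
#' @return `write_cohort_tsv()` invisibly returns `path`;
#'   `read_cohort_tsv()` returns a `cohort_dataset` assembled from the
#'   expression file and the rows of `metadata` matching its samples.
#' @export
write_cohort_tsv <- function(x, path) {
  df <- data.frame(gene_id = gene_ids(x), x$expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @param metadata Data frame with columns `sample_id`, `cohort_id`, `class`,
#'   `platform`, as written by [write_metadata_tsv()].
#' @export
read_cohort_tsv <- function(path, metadata) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- as.character(df[[1]])
  meta <- metadata[match(colnames(expr), metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata missing for samples: ",
         paste(utils::head(colnames(expr)[is.na(meta$sample_id)], 5), collapse = ", "))
  cohort <- unique(meta$cohort_id)
  platform <- unique(meta$platform)
  if (length(cohort) != 1L || length(platform) != 1L)
    stop("expression file mixes cohorts or platforms")
  cohort_dataset(expr, meta$class, cohort, platform)
}

#' @rdname write_cohort_tsv
#' @param datasets List of [cohort_dataset()] objects.
#' @export
write_metadata_tsv <- function(datasets, path) {
  meta <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(sample_id = sample_ids(d), cohort_id = d$cohort_id,
               class = unname(d$class_labels), platform = d$platform,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_metadata_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
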
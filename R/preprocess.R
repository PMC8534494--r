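#' Filter genes with low counts per million
#'
#' Removes genes whose maximum CPM across all samples falls below a
#' threshold. CPM uses raw library sizes (column sums), since filtering
#' precedes normalization-factor estimation.
#'
#' @param counts A [cohort_dataset()] with platform `"counts"`.
#' @param cpm_threshold Keep genes with max CPM >= this value (default 5).
#' @return The filtered `cohort_dataset`; sample set unchanged.
#' @export
filter_low_expressed <- function(counts, cpm_threshold = 5) {
  stopifnot(inherits(counts, "cohort_dataset"))
  if (counts$platform != "counts")
    stop("`filter_low_expressed()` expects a counts cohort")
  lib <- colSums(counts$expr)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts$expr)[lib == 0], collapse = ", "))
  cpm <- sweep(counts$expr, 2, lib, "/") * 1e6
  keep <- apply(cpm, 1, max) >= cpm_threshold
  cohort_subset(counts, genes = gene_ids(counts)[keep])
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors (Robinson & Oshlack) for a filtered
#' counts cohort, computed with edgeR. The reference sample is the one whose
#' upper-quartile CPM is closest to the mean upper-quartile; per-sample
#' log-ratios (M) and log-abundances (A) over genes nonzero in both sample
#' and reference are doubly trimmed and combined by a precision-weighted
#' mean; factors are re-centred to geometric mean 1.
#'
#' @param counts A [cohort_dataset()] with platform `"counts"`, >= 2 samples.
#' @param trim_M,trim_A Two-sided trim fractions for the M and A values
#'   (canonical defaults 0.3 and 0.05).
#' @return An object of class `norm_factors`: data frame with columns
#'   `sample_id`, `lib_size`, `tmm_factor`.
#' @export
tmm_factors <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  stopifnot(inherits(counts, "cohort_dataset"))
  if (counts$platform != "counts")
    stop("`tmm_factors()` expects a counts cohort")
  if (ncol(counts$expr) < 2L)
    stop("TMM needs at least 2 samples")
  lib <- colSums(counts$expr)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts$expr)[lib == 0], collapse = ", "))
  f <- suppressWarnings(
    edgeR::calcNormFactors(counts$expr, lib.size = lib, method = "TMM",
                           logratioTrim = trim_M, sumTrim = trim_A)
  )
  if (any(!is.finite(f))) {
    warning("no genes survived trimming for some sample(s); factor set to 1")
    f[!is.finite(f)] <- 1
    f <- f / exp(mean(log(f)))
  }
  structure(
    data.frame(sample_id = colnames(counts$expr), lib_size = lib,
               tmm_factor = f, row.names = NULL),
    class = c("norm_factors", "data.frame")
  )
}

#' voom-style log2-CPM transform
#'
#' Converts counts to normalized log2 counts-per-million using the voom
#' expression formula:
#' `log2((counts + prior) / (lib_size * tmm_factor + 1) * 1e6)`.
#' Precision weights are not computed: downstream effect-size and scoring
#' stages consume only the expression matrix.
#'
#' @param counts A [cohort_dataset()] with platform `"counts"`.
#' @param factors A `norm_factors` object from [tmm_factors()] computed on
#'   the same samples.
#' @param prior Prior count added to every observation (default 0.5).
#' @return A [cohort_dataset()] with platform `"array"` (continuous
#'   log2-scale expression).
#' @export
log2_cpm <- function(counts, factors, prior = 0.5) {
  stopifnot(inherits(counts, "cohort_dataset"), inherits(factors, "norm_factors"))
  if (!identical(as.character(factors$sample_id), colnames(counts$expr)))
    stop("`factors` do not match the samples of `counts`")
  eff <- factors$lib_size * factors$tmm_factor + 1
  expr <- log2(sweep(counts$expr + prior, 2, eff, "/") * 1e6)
  cohort_dataset(expr, counts$class_labels, counts$cohort_id, "array")
}

#' Full counts-cohort preprocessing
#'
#' Convenience wrapper chaining [filter_low_expressed()], [tmm_factors()]
#' and [log2_cpm()], turning a raw counts cohort into an array-compatible
#' normalized log2-CPM cohort.
#'
#' @inheritParams filter_low_expressed
#' @inheritParams log2_cpm
#' @param trim_M,trim_A Passed to [tmm_factors()].
#' @return A [cohort_dataset()] of normalized log2-CPM expression.
#' @export
preprocess_counts <- function(counts, cpm_threshold = 5, trim_M = 0.3,
                              trim_A = 0.05, prior = 0.5) {
  filtered <- filter_low_expressed(counts, cpm_threshold)
  log2_cpm(filtered, tmm_factors(filtered, trim_M, trim_A), prior)
}
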
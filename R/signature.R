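#' Gene signature with directional gene lists
#'
#' @param pos Character vector of genes overexpressed in responders.
#' @param neg Character vector of genes underexpressed in responders.
#'   The two lists must be disjoint and jointly non-empty.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(pos = character(), neg = character()) {
  pos <- as.character(pos)
  neg <- as.character(neg)
  if (anyDuplicated(c(pos, neg)))
    stop("signature gene lists must be disjoint and free of duplicates")
  if (length(pos) + length(neg) == 0L)
    stop("signature must contain at least one gene")
  structure(list(pos = pos, neg = neg), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %d pos / %d neg\n", length(x$pos), length(x$neg)))
  if (length(x$pos)) cat("  pos:", paste(x$pos, collapse = ", "), "\n")
  if (length(x$neg)) cat("  neg:", paste(x$neg, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname gene_signature
#' @param sig A `gene_signature`.
#' @param path File path for the JSON serialization `{"pos": [...], "neg": [...]}`.
#' @export
write_signature_json <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  jsonlite::write_json(list(pos = sig$pos, neg = sig$neg), path)
  invisible(path)
}

#' @rdname gene_signature
#' @export
read_signature_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gene_signature(pos = unlist(x$pos), neg = unlist(x$neg))
}

#' Anti-TNFa response (ATR) score
#'
#' Per-sample signature score: the difference of geometric means of
#' positive- and negative-signature gene expression,
#' `GeoMean(pos) - GeoMean(neg) * (Npos / Nneg)`, z-scored within the
#' cohort. If the signature has no positive genes the score collapses to
#' `-GeoMean(neg)`; with no negative genes it is `GeoMean(pos)`. Because a
#' geometric mean requires positive values, the signature genes' expression
#' submatrix is first translated so its minimum equals 1; this anchoring
#' makes the z-scored output invariant to adding a constant to every
#' signature gene and to the values of non-signature genes.
#'
#' @param expr A [cohort_dataset()] with continuous (log2-scale) expression.
#' @param sig A [gene_signature()] whose genes are all present in `expr`.
#' @return Named numeric vector of z-scored ATR scores (sample ids as
#'   names), with the cohort id in attribute `"cohort_id"`. Within a cohort
#'   of >= 2 samples with non-degenerate raw scores the vector has mean 0
#'   and SD 1.
#' @export
atr_score <- function(expr, sig) {
  stopifnot(inherits(expr, "cohort_dataset"), inherits(sig, "gene_signature"))
  sig_genes <- c(sig$pos, sig$neg)
  missing_g <- setdiff(sig_genes, gene_ids(expr))
  if (length(missing_g))
    stop("signature gene(s) absent from cohort ", expr$cohort_id, ": ",
         paste(missing_g, collapse = ", "))
  if (ncol(expr$expr) < 1L) stop("no samples to score")
  sub <- expr$expr[sig_genes, , drop = FALSE]
  sub <- sub + (1 - min(sub))
  geo <- function(genes) {
    if (length(genes) == 1L) sub[genes, ]
    else exp(colMeans(log(sub[genes, , drop = FALSE])))
  }
  raw <- if (length(sig$pos) == 0L) {
    -geo(sig$neg)
  } else if (length(sig$neg) == 0L) {
    geo(sig$pos)
  } else {
    geo(sig$pos) - geo(sig$neg) * (length(sig$pos) / length(sig$neg))
  }
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) {
    if (length(raw) > 1L) warning("degenerate raw scores in cohort ",
                                  expr$cohort_id, "; all z-scores set to 0")
    z <- rep(0, length(raw))
  } else {
    z <- (raw - mean(raw)) / s
  }
  names(z) <- colnames(expr$expr)
  attr(z, "cohort_id") <- expr$cohort_id
  z
}

#' Sample-size-weighted AUROC across datasets
#'
#' The forward-search objective: the sum over datasets of the trapezoidal
#' AUROC times the dataset's number of scored samples. The normalized
#' variant divides by the total sample count.
#'
#' @param scores_by_dataset List of numeric score vectors, one per dataset.
#' @param labels_by_dataset List of matching binary label vectors
#'   (responder = 1, non-responder = 0); every dataset must contain both
#'   classes.
#' @return List with `sum` (the weighted AUROC), `normalized`, `aurocs`
#'   (per-dataset AUROCs) and `n` (per-dataset sample counts).
#' @examples
#' weighted_auroc(list(c(1, 2, 3, 4)), list(c(0, 0, 1, 1)))$sum  # 4
#' @export
weighted_auroc <- function(scores_by_dataset, labels_by_dataset) {
  stopifnot(length(scores_by_dataset) == length(labels_by_dataset))
  nms <- names(scores_by_dataset)
  aurocs <- numeric(length(scores_by_dataset))
  n <- integer(length(scores_by_dataset))
  for (i in seq_along(scores_by_dataset)) {
    s <- scores_by_dataset[[i]]
    l <- as.integer(labels_by_dataset[[i]])
    if (length(s) != length(l)) stop("scores/labels length mismatch")
    if (!any(l == 1L) || !any(l == 0L))
      stop("dataset ", if (is.null(nms)) i else nms[i],
           " has a single class among scored samples")
    aurocs[i] <- auroc(s, l)
    n[i] <- length(s)
  }
  list(sum = sum(n * aurocs), normalized = sum(n * aurocs) / sum(n),
       aurocs = stats::setNames(aurocs, nms), n = stats::setNames(n, nms))
}

# Objective for a candidate signature on a list of prepared
# (expression, labels) diseased cohorts.
signature_objective <- function(sig, datasets) {
  scores <- lapply(datasets, function(d) as.numeric(atr_score(d, sig)))
  labels <- lapply(datasets, response_labels)
  weighted_auroc(scores, labels)
}

#' Greedy forward search for a parsimonious signature
#'
#' Starting from a directional candidate pool (typically the LOSO
#' meta-analysis survivors), iteration 0 selects the single gene whose
#' one-gene signature maximizes the sample-size-weighted AUROC across all
#' datasets; each later iteration tentatively adds every remaining
#' candidate to its directional list and retains the best addition if its
#' increase in weighted AUROC is at least `threshold`, otherwise the search
#' terminates. Ties are broken toward the larger absolute candidate effect
#' size, then lexicographic gene id, making the search deterministic.
#'
#' @param candidates Data frame with columns `gene`, `direction`
#'   (`"pos"`/`"neg"`) and optionally `effect_size` (see
#'   [signature_candidates()]).
#' @param datasets List of [cohort_dataset()] objects; only their diseased
#'   samples are scored.
#' @param threshold Stopping threshold on the increase in weighted AUROC
#'   (default 0.1).
#' @param threshold_scale `"sum"` (default) interprets `threshold` on the
#'   unnormalized weighted-AUROC scale (sum of per-dataset AUROC times
#'   sample count); `"mean"` on the normalized (mean AUROC) scale.
#' @return List with `signature` (the final [gene_signature()]) and `trace`
#'   (data frame: step, gene, direction, objective after addition on both
#'   scales, and the increase).
#' @export
greedy_forward_search <- function(candidates, datasets, threshold = 0.1,
                                  threshold_scale = c("sum", "mean")) {
  threshold_scale <- match.arg(threshold_scale)
  candidates <- as.data.frame(candidates)
  if (!all(c("gene", "direction") %in% names(candidates)))
    stop("`candidates` needs columns `gene` and `direction`")
  if (nrow(candidates) == 0L) stop("empty candidate list")
  if (!all(candidates$direction %in% c("pos", "neg")))
    stop("candidate directions must be 'pos' or 'neg'")
  if (is.null(candidates$effect_size)) candidates$effect_size <- 0
  if (anyDuplicated(candidates$gene)) stop("duplicate candidate genes")
  diseased <- lapply(datasets, diseased_samples)
  # deterministic evaluation order = tie-break order
  ord <- order(-abs(candidates$effect_size), candidates$gene)
  candidates <- candidates[ord, , drop = FALSE]

  pos <- character()
  neg <- character()
  remaining <- seq_len(nrow(candidates))
  current <- -Inf
  trace <- list()
  step <- 0L
  repeat {
    best_val <- NULL
    best_i <- NA_integer_
    for (i in remaining) {
      cand_pos <- if (candidates$direction[i] == "pos") c(pos, candidates$gene[i]) else pos
      cand_neg <- if (candidates$direction[i] == "neg") c(neg, candidates$gene[i]) else neg
      val <- signature_objective(gene_signature(cand_pos, cand_neg), diseased)
      obj <- if (threshold_scale == "sum") val$sum else val$normalized
      if (is.null(best_val) || obj > best_val$obj) {
        best_val <- list(obj = obj, val = val)
        best_i <- i
      }
    }
    increase <- best_val$obj - current
    accept <- step == 0L || increase >= threshold
    if (!accept) break
    i <- best_i
    if (candidates$direction[i] == "pos") pos <- c(pos, candidates$gene[i])
    else neg <- c(neg, candidates$gene[i])
    step <- step + 1L
    trace[[step]] <- data.frame(
      step = step, gene = candidates$gene[i],
      direction = candidates$direction[i],
      wauroc_sum = best_val$val$sum,
      wauroc_normalized = best_val$val$normalized,
      increase = if (step == 1L) NA_real_ else increase,
      stringsAsFactors = FALSE)
    current <- best_val$obj
    remaining <- setdiff(remaining, i)
    if (!length(remaining)) break
  }
  list(signature = gene_signature(pos, neg),
       trace = do.call(rbind, trace),
       threshold = threshold, threshold_scale = threshold_scale)
}
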
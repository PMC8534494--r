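check_binary_labels <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("missing values in scores or labels")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present")
  labels
}

#' Empirical ROC curve with tie-aware trapezoidal AUROC
#'
#' Threshold sweep over the observed scores with equal scores grouped into a
#' single step (producing diagonal segments for ties), so the trapezoidal
#' area equals the rank statistic (concordant pairs + half the tied pairs)
#' divided by `n_pos * n_neg`.
#'
#' @param scores Numeric scores (higher = more responder-like).
#' @param labels Binary labels (responder = 1, non-responder = 0); both
#'   classes must be present.
#' @return An object of class `roc_curve`: list with `points` (data frame of
#'   operating points `fpr`, `tpr` from (0,0) to (1,1)), `auroc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  thr <- sort(unique(scores), decreasing = TRUE)
  idx <- match(scores, thr)
  pos_at <- tabulate(idx[labels == 1L], nbins = length(thr))
  neg_at <- tabulate(idx[labels == 0L], nbins = length(thr))
  tpr <- c(0, cumsum(pos_at) / n_pos)
  fpr <- c(0, cumsum(neg_at) / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr),
                 auroc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUROC %.4f (%d pos / %d neg, %d points)\n",
              x$auroc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' @rdname roc_curve
#' @return `auroc()` returns the area as a bare number.
#' @export
auroc <- function(scores, labels) roc_curve(scores, labels)$auroc

#' Youden-optimal classification cutpoint
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over cutoffs at
#' midpoints between adjacent distinct scores (plus the two degenerate
#' all-positive / all-negative cutoffs), under the rule
#' score >= cutoff => predicted responder. Ties in J are broken toward
#' higher sensitivity.
#'
#' @inheritParams roc_curve
#' @return An object of class `cutpoint_report`: list with `cutoff`,
#'   `sensitivity`, `specificity`, `accuracy`, `J`.
#' @export
youden_cutpoint <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  s <- sort(unique(scores))
  cutoffs <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
               s[length(s)] + 1)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  best <- NULL
  for (cut in cutoffs) {
    pred <- scores >= cut
    sens <- sum(pred & labels == 1L) / n_pos
    spec <- sum(!pred & labels == 0L) / n_neg
    J <- sens + spec - 1
    if (is.null(best) || J > best$J + 1e-12 ||
        (abs(J - best$J) <= 1e-12 && sens > best$sensitivity)) {
      best <- list(cutoff = cut, sensitivity = sens, specificity = spec,
                   accuracy = mean((pred & labels == 1L) | (!pred & labels == 0L)),
                   J = J)
    }
  }
  structure(best, class = "cutpoint_report")
}

#' @export
print.cutpoint_report <- function(x, ...) {
  cat(sprintf(
    "<cutpoint_report> cutoff %.4g: sens %.3f, spec %.3f, acc %.3f (J = %.3f)\n",
    x$cutoff, x$sensitivity, x$specificity, x$accuracy, x$J))
  invisible(x)
}

# Binormal summary of one empirical curve: probit(TPR) regressed on
# probit(FPR) over interior operating points, weighted by the delta-method
# precision of the probit-transformed empirical rates
# (Var[qnorm(p-hat)] ~ p(1-p) / (n * dnorm(qnorm(p))^2), summed over both
# coordinates) so near-degenerate corner points do not dominate the fit.
# Curves too coarse to regress are summarized from their AUROC by the
# equal-variance inversion (b = 1).
binormal_params <- function(curve) {
  pts <- curve$points
  interior <- pts$fpr > 0 & pts$fpr < 1 & pts$tpr > 0 & pts$tpr < 1
  fallback <- function() {
    # continuity-corrected so separable curves stay finite
    cc <- 1 / (2 * (curve$n_pos * curve$n_neg + 1))
    auc <- min(max(curve$auroc, cc), 1 - cc)
    c(a = sqrt(2) * stats::qnorm(auc), b = 1)
  }
  if (sum(interior) < 3L) {
    warning("ROC curve with < 3 interior points; using equal-variance binormal fit from its AUROC")
    return(fallback())
  }
  x <- stats::qnorm(pts$fpr[interior])
  y <- stats::qnorm(pts$tpr[interior])
  vy <- pts$tpr[interior] * (1 - pts$tpr[interior]) /
    (curve$n_pos * stats::dnorm(y)^2)
  vx <- pts$fpr[interior] * (1 - pts$fpr[interior]) /
    (curve$n_neg * stats::dnorm(x)^2)
  fit <- stats::lm(y ~ x, weights = 1 / (vy + vx))
  ab <- c(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]))
  if (!all(is.finite(ab)) || ab["b"] <= 0) {
    warning("degenerate probit regression; using equal-variance binormal fit from its AUROC")
    return(fallback())
  }
  ab
}

weighted_sd <- function(x, w) {
  m <- sum(w * x) / sum(w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

#' Smoothed pooled ROC curve across datasets
#'
#' Kester-Buntinx-style pooling: each dataset's empirical curve is
#' summarized by binormal parameters (intercept `a` and slope `b` of a
#' precision-weighted probit(TPR)-on-probit(FPR) regression over its
#' interior operating points); parameters are pooled as sample-size
#' weighted means; the pooled smooth curve is
#' `TPR(FPR) = pnorm(a + b * qnorm(FPR))` with a pointwise confidence band
#' equal to the weighted SD of the per-dataset smooth curves; pooled AUROC
#' by trapezoidal integration of the pooled curve.
#'
#' @param curves List of >= 2 [roc_curve()] objects.
#' @param weights Numeric sample sizes, one per curve.
#' @param grid_size Number of FPR grid points (default 1001).
#' @return An object of class `pooled_roc`: list with `params` (per-curve
#'   a, b and weight), `a`, `b` (pooled), `curve` (data frame `fpr`, `tpr`,
#'   `band` = pointwise half-width), `auroc`.
#' @export
pooled_roc <- function(curves, weights, grid_size = 1001) {
  if (length(curves) < 2L) stop("pooling needs >= 2 curves")
  if (length(weights) != length(curves) || any(weights <= 0))
    stop("`weights` must be positive, one per curve")
  ab <- t(vapply(curves, binormal_params, numeric(2)))
  a <- sum(weights * ab[, "a"]) / sum(weights)
  b <- sum(weights * ab[, "b"]) / sum(weights)
  fpr <- seq(0, 1, length.out = grid_size)
  qf <- stats::qnorm(fpr)
  per <- vapply(seq_len(nrow(ab)),
                function(i) stats::pnorm(ab[i, "a"] + ab[i, "b"] * qf),
                numeric(grid_size))
  # endpoints are exact for every binormal curve
  per[1, ] <- 0
  per[grid_size, ] <- 1
  tpr <- stats::pnorm(a + b * qf)
  tpr[1] <- 0
  tpr[grid_size] <- 1
  band <- apply(per, 1, weighted_sd, w = weights)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(params = data.frame(a = ab[, "a"], b = ab[, "b"], weight = weights),
         a = a, b = b,
         curve = data.frame(fpr = fpr, tpr = tpr, band = band),
         auroc = auc),
    class = "pooled_roc"
  )
}

#' @export
print.pooled_roc <- function(x, ...) {
  cat(sprintf("<pooled_roc> %d curves: a = %.3f, b = %.3f, pooled AUROC %.4f\n",
              nrow(x$params), x$a, x$b, x$auroc))
  invisible(x)
}

#' Operating point on the pooled smooth ROC curve
#'
#' Reads the complementary coordinate off the pooled binormal curve: with
#' sensitivity fixed at `value`, returns the specificity (1 - FPR at that
#' TPR); with specificity fixed, returns the sensitivity.
#'
#' @param pooled A [pooled_roc()].
#' @param fix `"sensitivity"` or `"specificity"`.
#' @param value The fixed coordinate, in (0, 1).
#' @return The complementary coordinate as a bare number.
#' @export
operating_point <- function(pooled, fix = c("sensitivity", "specificity"),
                            value) {
  stopifnot(inherits(pooled, "pooled_roc"))
  fix <- match.arg(fix)
  if (!is.finite(value) || value <= 0 || value >= 1)
    stop("`value` must lie in (0, 1)")
  if (fix == "sensitivity") {
    fpr <- stats::pnorm((stats::qnorm(value) - pooled$a) / pooled$b)
    1 - fpr
  } else {
    stats::pnorm(pooled$a + pooled$b * stats::qnorm(1 - value))
  }
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a selected gene
#' set and each pathway against a background universe:
#' `p = P(X >= overlap)` with population `N = |background|`, successes
#' `K = |pathway (intersect) background|` and draws `n = |selected|`, with
#' Benjamini-Hochberg adjustment across pathways.
#'
#' @param selected Character vector of selected genes (must be a subset of
#'   `background`).
#' @param pathways Named list of gene sets (e.g. from [read_gmt()]); each is
#'   intersected with the background before testing.
#' @param background Character vector: the gene universe.
#' @return Data frame (one row per pathway, ordered by p): `pathway`,
#'   `pathway_size`, `overlap`, `gene_ratio`, `p`, `q`.
#' @export
hypergeometric_ora <- function(selected, pathways, background) {
  selected <- unique(as.character(selected))
  background <- unique(as.character(background))
  if (length(setdiff(selected, background)))
    stop("`selected` must be a subset of `background`")
  if (!length(pathways) || is.null(names(pathways)))
    stop("`pathways` must be a named list of gene sets")
  N <- length(background)
  n <- length(selected)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(unique(as.character(pathways[[nm]])), background)
    K <- length(pw)
    ov <- length(intersect(pw, selected))
    p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, pathway_size = K, overlap = ov,
               gene_ratio = ov / n, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$p, out$pathway), , drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' Tab-delimited gene-set format: one set per line as
#' `name <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1))
}

#' Per-dataset Youden performance summary
#'
#' Convenience helper: per-dataset AUROC and Youden-point
#' sensitivity/specificity/accuracy plus their means (unweighted by
#' default, matching the reporting convention of multicohort signature
#' studies; sample-size weighting optional).
#'
#' @param scores_by_dataset,labels_by_dataset Lists as in
#'   [weighted_auroc()].
#' @param weighted If `TRUE`, means are sample-size weighted.
#' @return List with `per_dataset` (data frame) and `mean` (named vector of
#'   mean auroc, sensitivity, specificity, accuracy).
#' @export
evaluate_performance <- function(scores_by_dataset, labels_by_dataset,
                                 weighted = FALSE) {
  stopifnot(length(scores_by_dataset) == length(labels_by_dataset))
  rows <- lapply(seq_along(scores_by_dataset), function(i) {
    s <- scores_by_dataset[[i]]
    l <- labels_by_dataset[[i]]
    cp <- youden_cutpoint(s, l)
    data.frame(dataset = if (is.null(names(scores_by_dataset))) as.character(i)
               else names(scores_by_dataset)[i],
               n = length(s), auroc = auroc(s, l), cutoff = cp$cutoff,
               sensitivity = cp$sensitivity, specificity = cp$specificity,
               accuracy = cp$accuracy, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  w <- if (weighted) per$n else rep(1, nrow(per))
  m <- vapply(c("auroc", "sensitivity", "specificity", "accuracy"),
              function(col) sum(w * per[[col]]) / sum(w), numeric(1))
  list(per_dataset = per, mean = m)
}
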
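#' Fit ComBat batch adjustments on healthy controls
#'
#' Co-normalization across cohorts under the assumption that healthy
#' controls from different cohorts represent the same distribution: a
#' parametric empirical-Bayes ComBat fit (batch = cohort, no covariates)
#' using only the control samples. The returned per-cohort location/scale
#' adjustments are later applied unchanged to the diseased samples of each
#' cohort via [coconut_apply()].
#'
#' Algorithm: (1) per-gene grand mean `alpha_g` (sample-size-weighted over
#' cohort means, i.e. the mean over all control samples) and pooled residual
#' variance `sigma_g^2` (mean squared residual about cohort means);
#' (2) standardize; (3) per-cohort per-gene additive (`gamma_hat`) and
#' multiplicative (`delta2_hat`, population-variance convention so that
#' batch-free data is an exact fixed point) batch effects; (4) shrinkage
#' with a normal prior on gamma and an inverse-gamma prior on delta^2,
#' hyperparameters by method of moments across genes within a cohort,
#' iterated to convergence of the coupled posterior means.
#'
#' @param controls List of [cohort_dataset()] objects holding only
#'   control samples (>= 2 cohorts, >= 2 controls each). Use
#'   [control_samples()] to extract them.
#' @param conv Relative-change convergence tolerance of the fixed-point
#'   iteration (default 1e-4).
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `coconut_adjustment` with elements `genes`,
#'   `cohorts`, `alpha` (per-gene mean), `sigma` (per-gene pooled SD),
#'   `gamma_star` and `delta2_star` (genes x cohorts matrices of shrunk
#'   batch effects; `delta2_star` strictly positive).
#' @export
combat_fit_controls <- function(controls, conv = 1e-4, max_iter = 100) {
  if (length(controls) < 2L)
    stop("co-normalization needs >= 2 cohorts")
  for (d in controls) {
    stopifnot(inherits(d, "cohort_dataset"))
    n_ctrl <- sum(d$class_labels == "control")
    if (n_ctrl < 2L || n_ctrl != ncol(d$expr))
      stop("cohort ", d$cohort_id,
           " must contribute >= 2 samples, all labelled control")
  }
  cohorts <- vapply(controls, function(d) d$cohort_id, character(1))
  if (anyDuplicated(cohorts)) stop("duplicate cohort ids")
  genes <- shared_genes(controls)
  if (!length(genes)) stop("no genes shared by all cohorts")
  mats <- lapply(controls, function(d) d$expr[genes, , drop = FALSE])
  n_b <- vapply(mats, ncol, integer(1))
  N <- sum(n_b)
  k <- length(mats)

  batch_means <- vapply(mats, rowMeans, numeric(length(genes)))
  alpha <- as.numeric(batch_means %*% (n_b / N))
  resid2 <- Reduce(`+`, lapply(seq_len(k), function(i)
    rowSums((mats[[i]] - batch_means[, i])^2)))
  var_pooled <- resid2 / N
  if (any(var_pooled == 0)) {
    warning(sum(var_pooled == 0),
            " gene(s) with zero pooled control variance dropped")
    keep <- var_pooled > 0
    genes <- genes[keep]
    mats <- lapply(mats, function(m) m[keep, , drop = FALSE])
    batch_means <- batch_means[keep, , drop = FALSE]
    alpha <- alpha[keep]
    var_pooled <- var_pooled[keep]
  }
  sigma <- sqrt(var_pooled)

  gamma_star <- delta2_star <- matrix(NA_real_, length(genes), k,
                                      dimnames = list(genes, cohorts))
  for (i in seq_len(k)) {
    sdat <- (mats[[i]] - alpha) / sigma
    n <- n_b[i]
    g_hat <- rowMeans(sdat)
    d_hat <- rowSums((sdat - g_hat)^2) / n  # population variance
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    m <- mean(d_hat)
    s2 <- stats::var(d_hat)
    if (s2 <= .Machine$double.eps * m^2) {
      # degenerate inverse-gamma prior: all scale effects identical
      g_star <- (t2 * n * g_hat + d_hat * g_bar) / (t2 * n + d_hat)
      d_star <- rep(m, length(d_hat))
    } else {
      a_prior <- (2 * s2 + m^2) / s2
      b_prior <- (m * s2 + m^3) / s2
      g_old <- g_hat
      d_old <- d_hat
      for (it in seq_len(max_iter)) {
        g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
        sum2 <- rowSums((sdat - g_new)^2)
        d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
        change <- max(abs(g_new - g_old) / pmax(abs(g_old), .Machine$double.eps),
                      abs(d_new - d_old) / d_old)
        g_old <- g_new
        d_old <- d_new
        if (change < conv) break
      }
      g_star <- g_old
      d_star <- d_old
    }
    stopifnot(all(d_star > 0))
    gamma_star[, i] <- g_star
    delta2_star[, i] <- d_star
  }
  structure(
    list(genes = genes, cohorts = cohorts, alpha = stats::setNames(alpha, genes),
         sigma = stats::setNames(sigma, genes),
         gamma_star = gamma_star, delta2_star = delta2_star),
    class = "coconut_adjustment"
  )
}

#' @export
print.coconut_adjustment <- function(x, ...) {
  cat(sprintf("<coconut_adjustment> %d genes x %d cohorts\n",
              length(x$genes), length(x$cohorts)))
  rep_df <- coconut_report(x)
  print(rep_df, row.names = FALSE)
  invisible(x)
}

#' Per-cohort summary of fitted batch adjustments
#'
#' @param adj A `coconut_adjustment` from [combat_fit_controls()].
#' @return Data frame with per-cohort mean absolute additive effect and mean
#'   multiplicative effect.
#' @export
coconut_report <- function(adj) {
  stopifnot(inherits(adj, "coconut_adjustment"))
  data.frame(cohort_id = adj$cohorts,
             mean_abs_gamma = colMeans(abs(adj$gamma_star)),
             mean_delta2 = colMeans(adj$delta2_star),
             row.names = NULL)
}

#' Apply fitted COCONUT adjustments to full cohorts
#'
#' Applies the control-derived per-cohort location/scale correction to every
#' sample (diseased and control) of each cohort:
#' `x' = ((x - alpha)/sigma - gamma*) / sqrt(delta2*) * sigma + alpha`.
#' The map is affine per (cohort, gene), so within-cohort rank order and
#' class contrasts are preserved up to the per-gene scale factor. The gene
#' universe is restricted to the genes the adjustment was fitted on.
#'
#' @param datasets List of [cohort_dataset()] objects whose cohort ids all
#'   appear in `adj`.
#' @param adj A `coconut_adjustment` from [combat_fit_controls()].
#' @return List of adjusted `cohort_dataset` objects on the pooled control
#'   scale (log2-expression units), class labels preserved.
#' @export
coconut_apply <- function(datasets, adj) {
  stopifnot(inherits(adj, "coconut_adjustment"))
  lapply(datasets, function(d) {
    stopifnot(inherits(d, "cohort_dataset"))
    i <- match(d$cohort_id, adj$cohorts)
    if (is.na(i))
      stop("cohort id not in adjustment: ", d$cohort_id)
    missing_g <- setdiff(adj$genes, gene_ids(d))
    if (length(missing_g))
      stop("cohort ", d$cohort_id, " lacks adjusted gene(s): ",
           paste(utils::head(missing_g, 5), collapse = ", "))
    x <- d$expr[adj$genes, , drop = FALSE]
    z <- (x - adj$alpha) / adj$sigma
    z <- (z - adj$gamma_star[, i]) / sqrt(adj$delta2_star[, i])
    out <- z * adj$sigma + adj$alpha
    cohort_dataset(out, d$class_labels, d$cohort_id, d$platform)
  })
}

#' One-step COCONUT co-normalization
#'
#' Fits ComBat on the control samples of every cohort and applies the
#' adjustments to all samples. Every cohort must contain >= 2 controls.
#'
#' @param datasets List of [cohort_dataset()] objects (continuous
#'   expression; preprocess counts cohorts first).
#' @inheritParams combat_fit_controls
#' @return List with elements `datasets` (adjusted cohorts) and `adjustment`
#'   (the fitted `coconut_adjustment`).
#' @export
coconut_normalize <- function(datasets, conv = 1e-4, max_iter = 100) {
  adj <- combat_fit_controls(lapply(datasets, control_samples),
                             conv = conv, max_iter = max_iter)
  list(datasets = coconut_apply(datasets, adj), adjustment = adj)
}
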
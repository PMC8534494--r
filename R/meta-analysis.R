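#' Hedges' g standardized mean difference
#'
#' Small-sample-corrected standardized mean difference between two groups:
#' `d = (mean(x_pos) - mean(x_neg)) / s_pooled` with the unbiased pooled SD,
#' bias correction `J = 1 - 3 / (4(n1 + n2 - 2) - 1)`, `g = J * d`, and
#' `var_g = J^2 * ((n1 + n2)/(n1 n2) + d^2 / (2(n1 + n2)))`. Positive g
#' means overexpressed in responders.
#'
#' @param x_pos,x_neg Numeric vectors (responders / non-responders), each
#'   with >= 2 values.
#' @return List with elements `g` and `var_g`.
#' @examples
#' hedges_g(c(2, 3, 4), c(0, 1, 2))  # g = 1.6
#' @export
hedges_g <- function(x_pos, x_neg) {
  n1 <- length(x_pos)
  n2 <- length(x_neg)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 values")
  sp2 <- ((n1 - 1) * stats::var(x_pos) + (n2 - 1) * stats::var(x_neg)) /
    (n1 + n2 - 2)
  if (sp2 <= 0) stop("undefined effect: pooled SD is zero")
  d <- (mean(x_pos) - mean(x_neg)) / sqrt(sp2)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  list(g = J * d,
       var_g = J^2 * ((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))))
}

# Vectorized per-gene Hedges' g for one cohort's diseased samples.
# Returns a data.frame over genes; genes with zero pooled SD get NA (the
# caller excludes them from the analysis universe).
dataset_effects <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  lab <- response_labels(dataset)
  if (length(lab) == 0L) stop("cohort ", dataset$cohort_id, " has no diseased samples")
  x <- diseased_samples(dataset)$expr
  pos <- names(lab)[lab == 1L]
  neg <- names(lab)[lab == 0L]
  n1 <- length(pos)
  n2 <- length(neg)
  if (n1 < 2L || n2 < 2L)
    stop("cohort ", dataset$cohort_id,
         " needs >= 2 responders and >= 2 non-responders")
  xp <- x[, pos, drop = FALSE]
  xn <- x[, neg, drop = FALSE]
  m1 <- rowMeans(xp)
  m2 <- rowMeans(xn)
  v1 <- rowSums((xp - m1)^2) / (n1 - 1)
  v2 <- rowSums((xn - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  d <- ifelse(sp2 > 0, (m1 - m2) / sqrt(sp2), NA_real_)
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  data.frame(gene = rownames(x), g = J * d,
             var_g = J^2 * ((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))),
             n_pos = n1, n_neg = n2, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment-based random-effects summary of per-cohort effect sizes:
#' fixed-effect weights `w_i = 1/v_i`, Cochran's
#' `Q = sum w_i (g_i - g_FE)^2`, between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, random-effects
#' weights `1/(v_i + tau2)`, pooled mean, its standard error, and a
#' two-sided z-test p-value from the standard normal. For k = 1 the pooled
#' effect is the single study's effect with `tau2 = 0`.
#'
#' @param g Numeric vector of per-cohort effect sizes.
#' @param v Numeric vector of their variances (positive), same length.
#' @return List with `mu`, `se`, `tau2`, `z`, `p`, `k`.
#' @examples
#' dl_pool(c(0.5, 1.0), c(0.1, 0.1))  # mu 0.75, se 0.25, tau2 0.025, z 3
#' @export
dl_pool <- function(g, v) {
  ok <- is.finite(g) & is.finite(v)
  g <- g[ok]
  v <- v[ok]
  k <- length(g)
  if (k == 0L) stop("no valid cohort effects to pool")
  if (any(v <= 0)) stop("effect variances must be positive")
  if (k == 1L) {
    mu <- g
    se <- sqrt(v)
    tau2 <- 0
  } else {
    w <- 1 / v
    mu_fe <- sum(w * g) / sum(w)
    Q <- sum(w * (g - mu_fe)^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (v + tau2)
    mu <- sum(ws * g) / sum(ws)
    se <- 1 / sqrt(sum(ws))
  }
  z <- mu / se
  list(mu = mu, se = se, tau2 = tau2, z = z,
       p = 2 * stats::pnorm(-abs(z)), k = k)
}

# Vectorized DL pooling over a genes x cohorts effect matrix.
dl_pool_matrix <- function(G, V) {
  k <- ncol(G)
  W <- 1 / V
  sw <- rowSums(W)
  mu_fe <- rowSums(W * G) / sw
  Q <- rowSums(W * (G - mu_fe)^2)
  tau2 <- pmax(0, (Q - (k - 1)) / (sw - rowSums(W^2) / sw))
  Ws <- 1 / (V + tau2)
  mu <- rowSums(Ws * G) / rowSums(Ws)
  se <- 1 / sqrt(rowSums(Ws))
  z <- mu / se
  data.frame(mu = mu, se = se, tau2 = tau2, z = z,
             p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, clipped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, order-preserving in `p`.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Significance thresholds for differential expression
#'
#' @param fdr_max Maximum BH q-value (default 0.10).
#' @param es_min Minimum absolute pooled effect size (default 0.8).
#' @return An object of class `significance_thresholds`.
#' @export
significance_thresholds <- function(fdr_max = 0.10, es_min = 0.8) {
  if (fdr_max <= 0 || fdr_max >= 1) stop("`fdr_max` must be in (0, 1)")
  if (es_min < 0) stop("`es_min` must be >= 0")
  structure(list(fdr_max = fdr_max, es_min = es_min),
            class = "significance_thresholds")
}

#' Multicohort random-effects meta-analysis of differential expression
#'
#' For every gene measured in all cohorts: per-cohort Hedges' g between
#' responders and non-responders, DerSimonian-Laird pooling across cohorts,
#' standard-normal two-sided p-value on the pooled effect, and BH q-values
#' across genes. Genes with an undefined effect (zero pooled SD) in any
#' cohort are excluded from the analysis universe with a warning.
#'
#' @param datasets List of >= 2 [cohort_dataset()] objects, each with >= 2
#'   responders and >= 2 non-responders.
#' @return An object of class `meta_result`: list with `table` (data frame:
#'   gene, mu, se, tau2, z, p, q, direction), `g` and `v` (genes x cohorts
#'   matrices of per-cohort effects and variances), `n_pos`, `n_neg`
#'   (per-cohort group sizes) and `cohorts`.
#' @export
run_meta <- function(datasets) {
  if (length(datasets) < 2L) stop("meta-analysis needs >= 2 datasets")
  genes <- shared_genes(datasets)
  if (!length(genes)) stop("no genes shared by all cohorts")
  effs <- lapply(datasets, dataset_effects)
  cohorts <- vapply(datasets, function(d) d$cohort_id, character(1))
  G <- vapply(effs, function(e) e$g[match(genes, e$gene)], numeric(length(genes)))
  V <- vapply(effs, function(e) e$var_g[match(genes, e$gene)], numeric(length(genes)))
  dimnames(G) <- dimnames(V) <- list(genes, cohorts)
  defined <- rowSums(!is.finite(G) | !is.finite(V)) == 0L
  if (!all(defined)) {
    warning(sum(!defined), " gene(s) with undefined effects dropped")
    G <- G[defined, , drop = FALSE]
    V <- V[defined, , drop = FALSE]
    genes <- genes[defined]
  }
  pooled <- dl_pool_matrix(G, V)
  tab <- data.frame(gene = genes, pooled,
                    q = bh_fdr(pooled$p),
                    direction = ifelse(pooled$mu >= 0, 1L, -1L),
                    stringsAsFactors = FALSE)
  structure(
    list(table = tab, g = G, v = V,
         n_pos = vapply(effs, function(e) e$n_pos[1], integer(1)),
         n_neg = vapply(effs, function(e) e$n_neg[1], integer(1)),
         cohorts = cohorts),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %d genes x %d cohorts (%s)\n",
              nrow(x$table), length(x$cohorts),
              paste(x$cohorts, collapse = ", ")))
  print(utils::head(x$table[order(x$table$p), ], 6), row.names = FALSE)
  invisible(x)
}

#' Leave-one-study-out significant gene selection
#'
#' Runs the multicohort meta-analysis k times, each round omitting one
#' cohort (round-robin). In the default `per_round` mode a gene is selected
#' iff in every round it satisfies `q <= fdr_max`, `|mu| >= es_min`, and its
#' pooled-effect sign is consistent across rounds; `full` mode instead
#' applies the thresholds to the all-cohort pooled estimate (sign
#' consistency across rounds still required).
#'
#' @param datasets List of >= 3 [cohort_dataset()] objects.
#' @param thresholds A [significance_thresholds()].
#' @param mode `"per_round"` (stricter, default) or `"full"`.
#' @return List with `genes` (selected gene ids), `direction` (named +1/-1
#'   vector over selected genes), `full` (all-cohort `meta_result` for
#'   ranking), `rounds` (list of per-round `meta_result`s, named by the
#'   held-out cohort) and `table` (per-gene summary with
#'   `n_rounds_significant`).
#' @export
loso_significant_genes <- function(datasets,
                                   thresholds = significance_thresholds(),
                                   mode = c("per_round", "full")) {
  mode <- match.arg(mode)
  stopifnot(inherits(thresholds, "significance_thresholds"))
  k <- length(datasets)
  if (k < 3L) stop("LOSO needs >= 3 datasets")
  full <- run_meta(datasets)
  rounds <- lapply(seq_len(k), function(i) run_meta(datasets[-i]))
  names(rounds) <- vapply(datasets, function(d) d$cohort_id, character(1))

  genes <- full$table$gene
  for (r in rounds) genes <- intersect(genes, r$table$gene)
  sig_mat <- vapply(rounds, function(r) {
    t <- r$table[match(genes, r$table$gene), ]
    t$q <= thresholds$fdr_max & abs(t$mu) >= thresholds$es_min
  }, logical(length(genes)))
  dir_mat <- vapply(rounds, function(r)
    r$table$direction[match(genes, r$table$gene)], integer(length(genes)))
  consistent <- apply(dir_mat, 1, function(d) length(unique(d)) == 1L)
  n_rounds_sig <- rowSums(sig_mat)

  full_t <- full$table[match(genes, full$table$gene), ]
  selected <- if (mode == "per_round") {
    n_rounds_sig == k & consistent
  } else {
    full_t$q <= thresholds$fdr_max & abs(full_t$mu) >= thresholds$es_min &
      consistent
  }
  tab <- data.frame(full_t, n_rounds_significant = n_rounds_sig,
                    direction_consistent = consistent, selected = selected,
                    stringsAsFactors = FALSE)
  sel_genes <- genes[selected]
  structure(
    list(genes = sel_genes,
         direction = stats::setNames(full_t$direction[selected], sel_genes),
         full = full, rounds = rounds, table = tab,
         thresholds = thresholds, mode = mode),
    class = "loso_result"
  )
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf(
    "<loso_result> %d significant gene(s) of %d tested (%s mode, FDR <= %g, |ES| >= %g)\n",
    length(x$genes), nrow(x$table), x$mode,
    x$thresholds$fdr_max, x$thresholds$es_min))
  invisible(x)
}

#' Pairwise dataset similarity from per-gene effect sizes
#'
#' Pearson correlation of per-gene Hedges' g between every pair of cohorts
#' over the shared gene universe; a diagnostic for whether a generalizable
#' response signal can exist across cohorts.
#'
#' @param datasets List of >= 2 [cohort_dataset()] objects.
#' @return Symmetric k x k correlation matrix with unit diagonal.
#' @export
effect_size_correlation <- function(datasets) {
  if (length(datasets) < 2L) stop("need >= 2 datasets")
  genes <- shared_genes(datasets)
  effs <- lapply(datasets, dataset_effects)
  Gm <- vapply(effs, function(e) e$g[match(genes, e$gene)], numeric(length(genes)))
  colnames(Gm) <- vapply(datasets, function(d) d$cohort_id, character(1))
  Gm <- Gm[stats::complete.cases(Gm), , drop = FALSE]
  if (nrow(Gm) < 3L) stop("fewer than 3 shared genes with defined effects")
  stats::cor(Gm)
}

#' Candidate table for the forward search from meta-analysis output
#'
#' @param x A `loso_result` or `meta_result`.
#' @param genes Optional subset of gene ids (default: selected genes of a
#'   `loso_result`, all genes of a `meta_result`).
#' @return Data frame with columns `gene`, `direction` (`"pos"`/`"neg"` by
#'   pooled-effect sign) and `effect_size` (pooled mu, used for
#'   tie-breaking).
#' @export
signature_candidates <- function(x, genes = NULL) {
  tab <- if (inherits(x, "loso_result")) {
    if (is.null(genes)) genes <- x$genes
    x$full$table
  } else if (inherits(x, "meta_result")) {
    if (is.null(genes)) genes <- x$table$gene
    x$table
  } else stop("`x` must be a loso_result or meta_result")
  t <- tab[match(genes, tab$gene), ]
  if (anyNA(t$gene)) stop("unknown gene ids in `genes`")
  data.frame(gene = t$gene,
             direction = ifelse(t$mu >= 0, "pos", "neg"),
             effect_size = t$mu, stringsAsFactors = FALSE)
}
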
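# Independent brute-force oracles. Each is written directly from the method
# definitions with explicit loops -- no shortcuts shared with the package
# implementation -- so implementation and oracle can only agree by both
# being right.

# AUROC as explicit pair counting: concordant pairs + half credit for ties,
# over all (positive, negative) pairs.
oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) total <- total + 1
      else if (p == q) total <- total + 0.5
    }
  }
  total / (length(pos) * length(neg))
}

# BH step-up by direct definition: q_(i) = min_{j >= i} m * p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, m * p[ord[j]] / j)
    q[ord[i]] <- min(1, min(vals))
  }
  q
}

# Upper-tail hypergeometric by exact enumeration of the tail with choose().
oracle_hyper_tail <- function(overlap, K, N, n) {
  total <- 0
  for (x in overlap:min(K, n)) {
    total <- total + choose(K, x) * choose(N - K, n - x)
  }
  total / choose(N, n)
}

# Brute-force TMM (Robinson & Oshlack): reference sample by the
# upper-quartile rule, per-gene M and A over genes nonzero in both sample
# and reference, double trimming by rank, precision-weighted mean of the
# surviving M values, factors re-centred to geometric mean 1. Explicit
# loops throughout.
oracle_tmm <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  lib <- colSums(counts)
  uq <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    uq[s] <- quantile(counts[, s] / lib[s], 0.75)
  }
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    obs <- counts[, s]
    rfc <- counts[, ref]
    keep <- obs > 0 & rfc > 0
    o <- obs[keep] / lib[s]
    r <- rfc[keep] / lib[ref]
    M <- log2(o / r)
    A <- (log2(o) + log2(r)) / 2
    v <- (lib[s] - obs[keep]) / (lib[s] * obs[keep]) +
      (lib[ref] - rfc[keep]) / (lib[ref] * rfc[keep])
    n <- length(M)
    loM <- floor(n * trim_M) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1
    hiA <- n + 1 - loA
    rM <- rank(M)
    rA <- rank(A)
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    f[s] <- if (any(sel)) 2^(sum(M[sel] / v[sel]) / sum(1 / v[sel])) else 1
  }
  f / exp(mean(log(f)))
}

# ---- fixture builders -------------------------------------------------------

fixture_cohort <- function(genes = 20, samples = 12, cohort_id = "c1",
                           classes = NULL, seed = 1, platform = "array") {
  set.seed(seed)
  if (is.null(classes))
    classes <- rep(c("responder", "nonresponder", "control"),
                   length.out = samples)
  if (platform == "counts") {
    expr <- matrix(rnbinom(genes * samples, mu = 200, size = 5),
                   genes, samples)
  } else {
    expr <- matrix(rnorm(genes * samples, 8, 2), genes, samples)
  }
  dimnames(expr) <- list(paste0("g", seq_len(genes)),
                         paste0(cohort_id, "_s", seq_len(samples)))
  cohort_dataset(expr, classes, cohort_id, platform)
}

planted_gene_ids <- function(cfg, idx) {
  paste0("g", formatC(idx, width = nchar(cfg$genes), flag = "0"))
}
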
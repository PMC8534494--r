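test_that("Hedges' g matches hand arithmetic and is antisymmetric", {
  h <- hedges_g(c(2, 3, 4), c(0, 1, 2))
  expect_equal(h$g, 1.6)
  expect_equal(h$var_g, 0.64)

  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3))$g, 0)

  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(sample(2:10, 1))
    b <- rnorm(sample(2:10, 1))
    f <- hedges_g(a, b)
    r <- hedges_g(b, a)
    expect_equal(f$g, -r$g)
    expect_equal(f$var_g, r$var_g)
  }
  expect_error(hedges_g(1, c(1, 2)), ">= 2")
  expect_error(hedges_g(c(1, 1), c(1, 1)), "pooled SD")
})

test_that("DL pooling matches hand arithmetic and degenerate cases", {
  r <- dl_pool(c(0.5, 1.0), c(0.1, 0.1))
  expect_equal(r$tau2, 0.025)
  expect_equal(r$mu, 0.75)
  expect_equal(r$se, 0.25)
  expect_equal(r$z, 3.0)

  # homogeneity: identical studies pool to themselves with tau2 = 0
  r2 <- dl_pool(rep(0.7, 4), rep(0.05, 4))
  expect_equal(r2$tau2, 0)
  expect_equal(r2$mu, 0.7)

  # k = 1 collapses to the single study
  r1 <- dl_pool(0.3, 0.2)
  expect_equal(r1$mu, 0.3)
  expect_equal(r1$se, sqrt(0.2))
  expect_equal(r1$tau2, 0)

  # invariant to cohort ordering
  set.seed(2)
  g <- rnorm(5); v <- runif(5, 0.05, 0.3)
  p <- sample(5)
  expect_equal(dl_pool(g, v), dl_pool(g[p], v[p]))
})

test_that("DL pooling agrees with metafor's DL estimator", {
  skip_if_not_installed("metafor")
  set.seed(3)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    g <- rnorm(k, 0.5, 0.5)
    v <- runif(k, 0.02, 0.3)
    mine <- dl_pool(g, v)
    ref <- metafor::rma(yi = g, vi = v, method = "DL")
    expect_equal(mine$mu, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(mine$se, ref$se, tolerance = 1e-10)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-10)
  }
})

test_that("BH q-values match the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.005, 0.05, 0.5)), c(0.015, 0.075, 0.5))
  expect_equal(bh_fdr(rep(0.03, 4)), rep(0.03, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(4)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(diff(q[order(p)]) >= 0))  # order-preserving in p
  }
})

test_that("run_meta pools per-gene effects over the shared gene universe", {
  cfg <- simulation_config(n_cohorts = 3, genes = 80, n_responders = 10,
                           n_nonresponders = 10, n_controls = 2,
                           platform_types = "array", seed = 5)
  ds <- generate_multicohort(cfg)
  m <- run_meta(ds)
  expect_equal(nrow(m$table), 80)
  expect_true(all(m$table$tau2 >= 0))
  expect_true(all(m$table$p >= 0 & m$table$p <= 1))
  expect_true(all(m$table$q >= 0 & m$table$q <= 1))

  # row-level agreement with the scalar primitives
  g1 <- m$table$gene[7]
  lab <- lapply(ds, response_labels)
  per <- lapply(seq_along(ds), function(i) {
    x <- diseased_samples(ds[[i]])$expr[g1, ]
    hedges_g(x[lab[[i]] == 1], x[lab[[i]] == 0])
  })
  pooled <- dl_pool(vapply(per, `[[`, numeric(1), "g"),
                    vapply(per, `[[`, numeric(1), "var_g"))
  row <- m$table[m$table$gene == g1, ]
  expect_equal(row$mu, pooled$mu)
  expect_equal(row$se, pooled$se)
  expect_equal(row$tau2, pooled$tau2)
  expect_equal(row$p, pooled$p)

  # duplicating the datasets leaves mu intact and shrinks the SE
  dup <- c(ds, lapply(ds, function(d) {
    cohort_dataset(`colnames<-`(d$expr, paste0("dup_", colnames(d$expr))),
                   d$class_labels, paste0(d$cohort_id, "_dup"), d$platform)
  }))
  m2 <- run_meta(dup)
  # with near-equal per-cohort variances the pooled mean is essentially
  # unchanged while the SE shrinks
  expect_lt(max(abs(m2$table$mu - m$table$mu)), 0.01)
  expect_true(all(m2$table$se < m$table$se))

  expect_error(run_meta(ds[1]), ">= 2 datasets")
})

test_that("null meta-analysis matches the idealized DL oracle's type-I error", {
  # the DL z-test at k=4 is conservative under the null: an oracle
  # simulation with KNOWN variances gives type-I ~ 0.037 at alpha = 0.05
  frac <- vapply(1:3, function(s) {
    cfg <- simulation_config(n_cohorts = 4, genes = 2000, n_responders = 30,
                             n_nonresponders = 30, n_controls = 2,
                             batch_shift_sd = 0, batch_scale_sd = 0,
                             platform_types = "array", seed = s)
    m <- run_meta(generate_multicohort(cfg))
    mean(m$table$p < 0.05)
  }, numeric(1))
  expect_gt(mean(frac), 0.025)
  expect_lt(mean(frac), 0.05)
  expect_equal(mean(frac), 0.037, tolerance = 0.2)
})

test_that("pooled estimates are consistent for the planted effect", {
  stats_at <- function(n) {
    cfg <- simulation_config(n_cohorts = 4, genes = 300, n_responders = n,
                             n_nonresponders = n, n_controls = 2,
                             planted_genes = data.frame(gene = 1:50, delta = 1),
                             platform_types = "array", seed = 101)
    m <- run_meta(generate_multicohort(cfg))
    mu <- m$table$mu[match(planted_gene_ids(cfg, 1:50), m$table$gene)]
    c(bias = mean(mu) - 1, rmse = sqrt(mean((mu - 1)^2)))
  }
  res <- vapply(c(20, 50, 100), stats_at, numeric(2))
  expect_true(all(abs(res["bias", ]) < 0.1))
  # estimation error shrinks monotonically with per-cohort sample size
  expect_true(all(diff(res["rmse", ]) < 0))
})

test_that("LOSO intersection selects planted genes with consistent direction", {
  planted <- data.frame(gene = 1:20, delta = rep(c(1.2, -1.2), 10))
  cfg <- simulation_config(n_cohorts = 4, genes = 500, n_responders = 30,
                           n_nonresponders = 30, n_controls = 2,
                           planted_genes = planted,
                           platform_types = "array", seed = 23)
  ds <- generate_multicohort(cfg)
  l <- loso_significant_genes(ds)
  pg <- planted_gene_ids(cfg, 1:20)
  expect_gte(mean(pg %in% l$genes), 0.8)
  expect_lte(sum(!l$genes %in% pg), 0.1 * length(l$genes))
  # signs match the planted directions
  expect_true(all(l$direction[intersect(l$genes, pg[1:20 %% 2 == 1])] == 1))
  expect_true(all(l$direction[intersect(l$genes, pg[1:20 %% 2 == 0])] == -1))

  # the intersection is contained in every single-round significant set
  for (r in l$rounds) {
    sig_r <- r$table$gene[r$table$q <= 0.10 & abs(r$table$mu) >= 0.8]
    expect_true(all(l$genes %in% sig_r))
  }

  # an unattainable effect-size threshold empties the selection
  l_inf <- loso_significant_genes(ds, significance_thresholds(es_min = Inf))
  expect_length(l_inf$genes, 0)

  expect_error(loso_significant_genes(ds[1:2]), ">= 3")
})

test_that("full-k mode applies thresholds to the pooled estimate only", {
  planted <- data.frame(gene = 1:10, delta = 1.0)
  cfg <- simulation_config(n_cohorts = 4, genes = 300, n_responders = 15,
                           n_nonresponders = 15, n_controls = 2,
                           planted_genes = planted,
                           platform_types = "array", seed = 29)
  ds <- generate_multicohort(cfg)
  per_round <- loso_significant_genes(ds, mode = "per_round")
  full <- loso_significant_genes(ds, mode = "full")
  # per-round selection is the stricter of the two
  expect_true(all(per_round$genes %in% full$genes))
})

test_that("effect-size correlations separate signal-sharing from null cohorts", {
  planted <- data.frame(gene = 1:100, delta = rep(c(1.5, -1.5), 50))
  cfg_sig <- simulation_config(n_cohorts = 2, genes = 500, n_responders = 30,
                               n_nonresponders = 30, n_controls = 2,
                               planted_genes = planted, noise_sd = 1,
                               platform_types = "array", seed = 31)
  r_sig <- effect_size_correlation(generate_multicohort(cfg_sig))
  expect_equal(unname(diag(r_sig)), c(1, 1))
  expect_true(isSymmetric(r_sig))
  expect_gt(r_sig[1, 2], 0.5)

  cfg_null <- simulation_config(n_cohorts = 2, genes = 2000, n_responders = 30,
                                n_nonresponders = 30, n_controls = 2,
                                platform_types = "array", seed = 37)
  r_null <- effect_size_correlation(generate_multicohort(cfg_null))
  expect_lt(abs(r_null[1, 2]), 0.1)
})
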
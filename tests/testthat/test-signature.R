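sig_cohort <- function(expr, id = "c1",
                       classes = rep(c("responder", "nonresponder"),
                                     length.out = ncol(expr))) {
  cohort_dataset(expr, classes, id, "array")
}

test_that("gene signature lists must be disjoint and non-empty", {
  expect_error(gene_signature(), "at least one gene")
  expect_error(gene_signature(pos = "a", neg = "a"), "disjoint")
  s <- gene_signature(pos = c("a", "b"), neg = "c")
  expect_identical(s$pos, c("a", "b"))
  path <- tempfile(fileext = ".json")
  write_signature_json(s, path)
  s2 <- read_signature_json(path)
  expect_identical(s2$pos, s$pos)
  expect_identical(s2$neg, s$neg)
})

test_that("ATR score matches direct arithmetic for a single positive gene", {
  expr <- matrix(c(1, 2, 4), nrow = 1,
                 dimnames = list("gA", paste0("s", 1:3)))
  d <- sig_cohort(expr, classes = rep("responder", 3))
  z <- as.numeric(atr_score(d, gene_signature(pos = "gA")))
  # raw scores [1,2,4]; z-scored with the sample-SD convention
  expect_equal(z, (c(1, 2, 4) - 7 / 3) / sd(c(1, 2, 4)))
  expect_equal(round(z, 3), c(-0.873, -0.218, 1.091))
})

test_that("ATR score collapses correctly when one gene list is empty", {
  set.seed(1)
  expr <- matrix(rnorm(4 * 6, 8, 2), 4, 6,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  d <- sig_cohort(expr)
  # Npos = 0: z-score of -GeoMean(neg)
  z_neg <- as.numeric(atr_score(d, gene_signature(neg = c("g1", "g2"))))
  sub <- expr[c("g1", "g2"), ]
  shifted <- sub + (1 - min(sub))
  raw <- -exp(colMeans(log(shifted)))
  expect_equal(z_neg, as.numeric(scale(raw)), tolerance = 1e-12)

  # Nneg = 0: z-score of GeoMean(pos)
  z_pos <- as.numeric(atr_score(d, gene_signature(pos = c("g1", "g2"))))
  expect_equal(z_pos, as.numeric(scale(-raw)), tolerance = 1e-12)
  expect_equal(z_pos, -z_neg)

  # full formula with both lists
  z_both <- as.numeric(atr_score(d, gene_signature(pos = "g1",
                                                   neg = c("g2", "g3"))))
  sub2 <- expr[c("g1", "g2", "g3"), ]
  sh2 <- sub2 + (1 - min(sub2))
  raw2 <- sh2["g1", ] - exp(colMeans(log(sh2[c("g2", "g3"), ]))) * (1 / 2)
  expect_equal(z_both, as.numeric(scale(raw2)), tolerance = 1e-12)
})

test_that("ATR score is invariant to re-anchoring and non-signature genes", {
  set.seed(2)
  expr <- matrix(rnorm(6 * 10, 8, 2), 6, 10,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  d <- sig_cohort(expr)
  sig <- gene_signature(pos = c("g1", "g2"), neg = "g3")
  z <- atr_score(d, sig)

  # adding a constant to every signature gene re-anchors to the same values
  shifted <- expr
  shifted[c("g1", "g2", "g3"), ] <- shifted[c("g1", "g2", "g3"), ] + 5
  expect_equal(atr_score(sig_cohort(shifted), sig), z, tolerance = 1e-12)

  # non-signature gene values are irrelevant
  perturbed <- expr
  perturbed[c("g4", "g5", "g6"), ] <- rnorm(30, 0, 10)
  expect_equal(atr_score(sig_cohort(perturbed), sig), z)

  # missing signature genes are reported by name
  expect_error(atr_score(d, gene_signature(pos = "g1", neg = "gX")), "gX")

  # degenerate raw scores yield all-zero output with a warning
  const <- matrix(5, 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  expect_warning(z0 <- atr_score(sig_cohort(const), gene_signature(pos = "g1")),
                 "degenerate")
  expect_equal(as.numeric(z0), rep(0, 4))
})

test_that("weighted AUROC is the sample-size weighted sum of dataset AUROCs", {
  # perfect separation, n = 10
  w <- weighted_auroc(list(c(1:5, 11:15)), list(rep(c(0, 1), each = 5)))
  expect_equal(w$sum, 10)
  expect_equal(w$normalized, 1)

  # hand arithmetic: AUROC 0.8 with n = 20 and 0.9 with n = 10
  s1 <- c(1:10, 2.5, 4.5, 6.5, 8.5, 10.5, 11, 12, 13, 14, 15)
  l1 <- rep(c(0, 1), each = 10)
  s2 <- c(1, 2, 3, 4, 5, 3, 6, 7, 8, 9)
  l2 <- rep(c(0, 1), each = 5)
  stopifnot(auroc(s1, l1) == 0.8, auroc(s2, l2) == 0.9)
  w2 <- weighted_auroc(list(s1, s2), list(l1, l2))
  expect_equal(w2$sum, 16 + 9)
  expect_equal(w2$normalized, 25 / 30)

  # flipping labels complements each AUROC
  w3 <- weighted_auroc(list(s1, s2), list(1 - l1, 1 - l2))
  expect_equal(unname(w3$aurocs), 1 - unname(w2$aurocs))

  expect_error(weighted_auroc(list(1:4), list(rep(1, 4))), "single class")
})

test_that("greedy search handles trivial candidate sets deterministically", {
  set.seed(3)
  cfg <- simulation_config(n_cohorts = 2, genes = 30, n_responders = 10,
                           n_nonresponders = 10, n_controls = 2,
                           planted_genes = data.frame(gene = 1, delta = 2),
                           platform_types = "array", seed = 3)
  ds <- generate_multicohort(cfg)
  pg <- planted_gene_ids(cfg, 1)

  one <- greedy_forward_search(
    data.frame(gene = pg, direction = "pos"), ds, threshold = 0.1)
  expect_identical(one$signature$pos, pg)
  expect_identical(nrow(one$trace), 1L)

  # an infinite threshold stops after the mandatory first gene
  cands <- signature_candidates(run_meta(ds))
  inf <- greedy_forward_search(cands, ds, threshold = Inf)
  expect_length(c(inf$signature$pos, inf$signature$neg), 1)
  # ... and that first gene is the strongest single discriminator
  expect_identical(c(inf$signature$pos, inf$signature$neg), pg)

  expect_error(greedy_forward_search(cands[0, ], ds), "empty candidate")
})

test_that("search trace is nondecreasing and respects candidate directions", {
  planted <- data.frame(gene = 1:5, delta = c(1.5, 1.5, 1.5, -1.5, -1.5))
  cfg <- simulation_config(n_cohorts = 4, genes = 200, n_responders = 25,
                           n_nonresponders = 25, n_controls = 2,
                           planted_genes = planted,
                           platform_types = "array", seed = 41)
  ds <- generate_multicohort(cfg)
  m <- run_meta(ds)
  cands <- signature_candidates(m)
  sr <- greedy_forward_search(cands, ds, threshold = 0.1)
  expect_true(all(diff(sr$trace$wauroc_sum) >= 0.1 - 1e-9))
  expect_true(all(sr$trace$increase[-1] >= 0.1 - 1e-9))
  for (i in seq_len(nrow(sr$trace))) {
    dir <- cands$direction[match(sr$trace$gene[i], cands$gene)]
    lst <- if (dir == "pos") sr$signature$pos else sr$signature$neg
    expect_true(sr$trace$gene[i] %in% lst)
  }
  expect_length(intersect(sr$signature$pos, sr$signature$neg), 0)
})

test_that("planted signatures are recovered and generalize to held-out data", {
  pass <- vapply(1:3, function(s) {
    planted <- data.frame(gene = 1:5, delta = c(1.5, 1.5, 1.5, -1.5, -1.5))
    cfg <- simulation_config(n_cohorts = 5, genes = 400, n_responders = 25,
                             n_nonresponders = 25, n_controls = 2,
                             planted_genes = planted,
                             platform_types = "array", seed = s)
    ds <- generate_multicohort(cfg)
    m <- run_meta(ds[1:4])
    pg <- planted_gene_ids(cfg, 1:5)
    cands <- signature_candidates(m, genes = c(pg, setdiff(m$table$gene, pg)[1:95]))
    sr <- greedy_forward_search(cands, ds[1:4], threshold = 0.1)
    genes <- c(sr$signature$pos, sr$signature$neg)
    held <- as.numeric(atr_score(diseased_samples(ds[[5]]), sr$signature))
    c(frac_planted = mean(genes %in% pg),
      heldout = auroc(held, response_labels(ds[[5]])))
  }, numeric(2))
  # selected genes are predominantly planted and the score generalizes
  expect_true(all(pass["frac_planted", ] >= 0.5))
  expect_true(all(pass["heldout", ] >= 0.85))
})

test_that("ATR score of a null signature has chance-level AUROC", {
  cfg <- simulation_config(n_cohorts = 1, genes = 50, n_responders = 100,
                           n_nonresponders = 100, n_controls = 2,
                           platform_types = "array", seed = 53)
  d <- generate_multicohort(cfg)[[1]]
  sc <- as.numeric(atr_score(diseased_samples(d),
                             gene_signature(pos = c("g01", "g02"),
                                            neg = c("g03", "g04"))))
  a <- auroc(sc, response_labels(d))
  se <- sqrt((100 + 100 + 1) / (12 * 100 * 100))
  expect_lt(abs(a - 0.5), 3 * se)
})
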
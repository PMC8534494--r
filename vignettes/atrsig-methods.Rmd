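---
title: "Multicohort discovery of anti-TNFa response signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicohort discovery of anti-TNFa response signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Anti-TNFa biologics (infliximab, adalimumab and relatives) fail in a large
fraction of IBD patients, and no clinical factor predicts who will respond.
A transcriptomic predictor must survive the heterogeneity of real patient
cohorts: different platforms (microarray vs RNA-seq), tissues, disease
subtypes and centres. `atrsig` implements a discovery workflow built for
exactly that setting: several independent cohorts of pretreatment mucosal
biopsies, each with responder/non-responder labels, are co-normalized,
meta-analysed gene by gene, and distilled into a small geometric-mean score
signature whose discriminatory performance is evaluated per cohort and
pooled.

Because the real accessions cannot be redistributed, the package ships a
synthetic multi-cohort generator with planted effect sizes. Every stage of
the pipeline is exercised and tested against data whose ground truth is
known.

## The generative model

`simulation_config()` / `generate_multicohort()` draw, for cohort $c$,
gene $g$, sample $s$:

$$x_{gs} = \beta_g + \gamma_{cg} + \lambda_{cg}\,\big( \mu_{g}(s) + \varepsilon_{gs}\big),
\qquad \varepsilon_{gs} \sim N(0, \sigma^2)$$

with per-gene baselines $\beta_g \sim N(8, 2^2)$ (log2 array-intensity
range), additive batch offsets $\gamma_{cg} \sim N(0,
\texttt{batch\_shift\_sd}^2)$, multiplicative batch factors $\lambda_{cg} =
e^{N(0,\texttt{batch\_scale\_sd}^2)}$, and a class effect $\mu_g(s) =
\delta_g \sigma$ for responders at planted genes, 0 otherwise. Three
properties matter downstream:

* healthy controls of all cohorts share one distribution *before* batch
  effects — the co-normalization assumption, made true by construction;
* batch effects are location/scale per (cohort, gene) — exactly the model
  ComBat estimates, so co-normalization success is a testable invariant
  rather than luck;
* the true standardized effect size of a planted gene is $\delta_g$
  regardless of batch parameters, because shift and scale act on signal and
  noise alike.

Counts cohorts exponentiate the same latent log2 surface into per-sample
proportions and draw negative-binomial counts around
`seq_depth_mean`-centred library sizes (`dispersion` 0 gives Poisson), so
class effects on the log scale are identical across platforms.

One RNG stream per cohort is derived from the master seed; adding a cohort
never perturbs earlier cohorts' data, and the generator restores the
caller's RNG state.

Defaults mirror a four-cohort IBD study: responders/non-responders 19/25,
8/16, 20/17, 24/7 (136 diseased samples), one counts cohort plus three
array cohorts, `batch_shift_sd = 1`, `batch_scale_sd = 0.3`, `noise_sd =
1`. The number of healthy controls per cohort (10) and the gene count are
package choices at realistic desk scale; tests use 400–2000 genes, the
acceptance run 2000.

## Counts preprocessing

`preprocess_counts()` chains three steps. The low-expression filter keeps
genes whose *maximum* CPM over samples reaches 5, computed with raw library
sizes (filtering precedes factor estimation). TMM normalization factors are
delegated to edgeR's `calcNormFactors()` with the canonical trims (0.3 on
M, 0.05 on A); the test suite pins them to an independently coded
brute-force trimmed mean at 1e-8. The log2-CPM transform is the voom
expression formula,
$\log_2\!\big((c_{gs} + 0.5)/(L_s f_s + 1) \times 10^6\big)$, with prior
count 0.5 and the +1 on the effective library size; precision weights are
not computed because downstream stages (effect sizes, scores) consume only
the expression matrix.

## COCONUT co-normalization

`combat_fit_controls()` is a parametric empirical-Bayes ComBat (batch =
cohort, no covariates) fitted **only on healthy controls**; the fitted
per-cohort location/scale corrections are then applied unchanged to the
diseased samples by `coconut_apply()` — response labels never influence the
transform. The fit standardizes by the pooled control mean and variance,
estimates per-cohort per-gene additive ($\hat\gamma$) and multiplicative
($\hat\delta^2$) effects, and shrinks them with a normal prior on $\gamma$
and an inverse-gamma prior on $\delta^2$ (method-of-moments
hyperparameters, fixed-point iteration to a relative change below 1e-4,
capped at 100 iterations).

Two deliberate choices:

* $\hat\delta^2$ uses the population ($\div n$) variance so that batch-free
  data is an *exact* fixed point ($\gamma^* = 0$, $\delta^{2*} = 1$); with
  the $\div(n-1)$ convention the no-batch case converges to $n/(n-1)$
  instead. At realistic control counts the two conventions agree on
  adjusted values to a fraction of a percent, and the suite cross-checks
  the whole fit against `sva::ComBat` at a 0.05 absolute tolerance.
* Every cohort must contribute at least two controls. This is stricter than
  pooling "whichever controls are available", but it is the contract under
  which applying control-derived corrections to cases is well defined.

EB shrinkage has a visible consequence worth knowing: when the true
standardized batch offsets are nearly constant across genes, the
between-gene variance of $\hat\gamma$ is small, the prior dominates, and
per-gene corrections shrink toward the cohort mean offset. A constant
injected shift is therefore removed on average (>90% in the tests) but
leaves per-gene residuals of a few tenths — identical to sva's behaviour,
and inherent to ComBat rather than to this implementation.

Adjusted values are mapped back to the pooled control scale (multiply by
$\sigma_g$, add $\alpha_g$) so they remain interpretable log2 expression.
Genes absent from any cohort, or with zero pooled control variance, are
dropped before fitting.

## LOSO meta-analysis

Per cohort and gene, `hedges_g()` computes the small-sample-corrected
standardized mean difference between responders and non-responders
($J = 1 - 3/(4m - 1)$ at $m = n_1 + n_2 - 2$ degrees of freedom, variance
$J^2[(n_1+n_2)/(n_1 n_2) + d^2/(2(n_1+n_2))]$). `dl_pool()` combines
cohorts with the DerSimonian–Laird moment estimator of between-study
variance and reports a two-sided z-test p-value; `bh_fdr()` applies
Benjamini–Hochberg across genes (via `stats::p.adjust`, pinned to a
brute-force step-up oracle in the tests). The analysis universe is the
intersection of genes measured in every cohort.

`loso_significant_genes()` runs the meta-analysis k times, omitting each
cohort once. The default (`per_round`) selection requires every round to
satisfy q <= 10% *and* |pooled effect| >= 0.8 *and* a consistent effect
sign; sign consistency is required because the downstream score needs an
unambiguous positive/negative split. A `full` mode applies the thresholds
to the all-cohort pooled estimate instead (the weaker reading of
"significant in a LOSO analysis"); `per_round` is the stricter default.

Calibration note: under a global null the DL z-test at k = 4 cohorts is
conservative — truncating $\hat\tau^2$ at zero inflates the standard error
whenever Q exceeds its null mean. An oracle simulation with *known*
variances puts the type-I error at alpha = 0.05 near 0.037, and the
pipeline reproduces exactly that, so the conservatism is a property of the
estimator, not of the implementation. Power analyses in the tests use
planted effects of |delta| = 1.0–1.2 at 30+30 per cohort, where LOSO
recovery exceeds 80% with essentially no false genes.

## The ATR score and the forward search

For a signature with positive (up in responders) and negative gene lists,
the per-sample raw score is

$$\mathrm{GeoMean}(\text{pos}) - \mathrm{GeoMean}(\text{neg}) \times
\frac{N_{pos}}{N_{neg}},$$

z-scored within each cohort; with an empty positive list it collapses to
$-\mathrm{GeoMean}(\text{neg})$, with an empty negative list to
$\mathrm{GeoMean}(\text{pos})$. Two conventions are fixed explicitly:

* z-scoring uses the sample ($\div(N-1)$) SD, matching `scale()`;
* geometric means require positive values, so the signature genes'
  submatrix is translated so its minimum equals 1. Anchoring on the
  signature rows (rather than the whole matrix) makes the z-scored output
  exactly invariant both to adding a constant to every signature gene and
  to the values of all non-signature genes.

`greedy_forward_search()` maximizes the sample-size-weighted AUROC
$\sum_d n_d \cdot \mathrm{AUROC}_d$. Iteration 0 keeps the best single-gene
signature; each later iteration tentatively adds every remaining candidate
in its meta-analysis direction and keeps the best addition if the objective
gains at least the stopping threshold. The threshold (default 0.1) is
interpreted on the unnormalized sum scale — on ~136 samples that is a mean
AUROC gain of ~0.0007, i.e. roughly "stop when no gene wins even a couple
of score-pair inversions anywhere". A `threshold_scale = "mean"` switch
interprets it on the normalized scale instead. Ties are broken toward the
larger absolute candidate effect size, then lexicographic gene id, making
the search fully deterministic.

Two behaviours of this objective are worth understanding before trusting a
selected gene list. First, the geometric mean dilutes: adding a weaker
(even truly differential) gene to a strong list can *decrease* the
in-sample objective, so the search legitimately terminates at small local
optima — parsimony is partly an artifact of the score's geometry. Second,
near the in-sample ceiling, null genes can occasionally clear the threshold
by fixing a handful of score pairs, so short overfitting tails occur. The
held-out validation in the tests shows the resulting signatures generalize
well (held-out AUROC >= 0.85 across all tested seeds) even when the exact
planted set is not recovered; identity of the selected genes is the fragile
quantity, performance is not.

## Evaluation

`roc_curve()` sweeps thresholds with tied scores grouped into single steps,
so the trapezoidal area equals the tie-aware rank statistic (concordant +
half-tied pairs) — pinned to a pair-counting oracle in the tests.
`youden_cutpoint()` maximizes sensitivity + specificity − 1 over midpoints
between adjacent distinct scores (plus the two degenerate cutoffs) under
the rule "score >= cutoff predicts responder", breaking ties toward higher
sensitivity. Reported mean sensitivity/specificity/accuracy are unweighted
means of per-cohort Youden-point metrics by default (a sample-size-weighted
option exists).

`pooled_roc()` smooths and pools per-cohort curves in the binormal family:
each curve is summarized by the intercept and slope of a probit(TPR) on
probit(FPR) regression over its interior operating points, weighted by the
delta-method precision of the probit-transformed empirical rates so that
near-corner points do not dominate; parameters are pooled as sample-size
weighted means; the pooled curve is $\Phi(a + b\,\Phi^{-1}(\mathrm{FPR}))$
with a pointwise band equal to the weighted SD of the per-cohort smooth
curves, and the pooled AUROC is its trapezoidal integral. Curves with fewer
than three interior points (tiny or separable cohorts) fall back to the
equal-variance inversion $b = 1$, $a = \sqrt2\,\Phi^{-1}(\mathrm{AUROC})$
with a continuity correction, with a warning. `operating_point()` reads
rule-in/rule-out coordinates (e.g. specificity at 95% sensitivity) off the
pooled curve in closed form.

`hypergeometric_ora()` tests gene-set over-representation with the
upper-tail hypergeometric probability against a background universe and BH
adjustment across sets. This is deliberately an over-representation test,
not a ranked walk-statistic GSEA: the described computation — overlap
counts against a background with a hypergeometric tail — is ORA, and that
is what is implemented and tested (exact tail enumeration for all
backgrounds up to 50 genes).

## The pipeline

`run_pipeline()` chains the stages — simulate/ingest, preprocess counts
cohorts, co-normalize, LOSO meta-analysis, forward search, evaluation,
optional ORA — writing every intermediate table as TSV, the signature as
JSON, and a manifest with md5 digests of each stage's outputs plus a
gene-count ledger (inputs, post-filter, shared, tested, significant,
signature). Runs are pure functions of config + master seed; the
integration tests assert digest-identical reruns. A stage failure aborts
with the stage named and earlier outputs retained. The package's interface
is its functions; `scripts/acceptance.R` in the source repository is a
worked end-to-end driver.

## Problem sizes used in the tests

Unit and property tests run at 50–2000 genes and 2–5 cohorts of 5–50
samples per class; calibration and recovery checks use the conditions they
describe (null calibration at G = 2000 with four 30+30 cohorts; LOSO
recovery with 20 planted genes of |delta| = 1.2; search recovery with 5
planted genes of |delta| = 1.5 among 200 candidates in four 25+25
cohorts; binormal pooling recovery at 2000 scores per class). These sizes
were chosen as the smallest at which the statistical assertions have
comfortable margins.

## What the synthetic data does and does not show

The generator reproduces the *structural* assumptions of the analysis:
shared control distribution, location/scale batch effects, platform split,
planted standardized effects. It does not emulate gene–gene correlation,
platform-specific mean–variance relationships beyond the NB counts model,
probe-level artifacts, sample mislabeling, or cohort-specific biology
(tissue, subtype). Passing tests therefore demonstrate that the pipeline
recovers what it assumes — correctness of the machinery, calibration of
its statistics — not that the method will find a real signature in any
particular clinical dataset. The known limitations that carry over to real
data are the ones documented above: DL conservatism at small k, EB
shrinkage residuals under near-constant batch offsets, and the greedy
search's local optima.
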
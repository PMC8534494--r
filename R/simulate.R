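#' Configuration for the multi-cohort expression simulator
#'
#' Defines the statistical structure the downstream analysis assumes and
#' must be able to exploit: a shared healthy-control distribution across
#' cohorts, per-cohort per-gene batch effects (additive shift plus
#' multiplicative scale, exactly the location/scale model ComBat estimates),
#' and a planted set of signature genes with known standardized mean
#' differences between responders and non-responders.
#'
#' The defaults mirror the cohort structure of a four-cohort IBD anti-TNFa
#' discovery study: three array cohorts and one RNA-seq counts cohort with
#' responder/non-responder group sizes 19/25, 8/16, 20/17 and 24/7
#' (136 diseased samples in total), plus healthy controls in every cohort.
#'
#' @param n_cohorts Number of cohorts (k).
#' @param genes Total number of genes G.
#' @param n_responders,n_nonresponders,n_controls Per-cohort group sizes;
#'   scalars are recycled to length `n_cohorts`. Every group needs at least
#'   2 samples (Hedges' g requires >= 2 per group).
#' @param planted_genes `NULL` or a data frame with columns `gene` (integer
#'   index in `1:genes`, no duplicates) and `delta` (signed true standardized
#'   effect size; positive = overexpressed in responders).
#' @param batch_shift_sd SD of per-cohort per-gene additive offsets
#'   (log2 units).
#' @param batch_scale_sd SD of per-cohort per-gene log multiplicative
#'   factors.
#' @param noise_sd Within-group SD (log2 units); must be positive.
#' @param platform_types Per-cohort tag, `"array"` or `"counts"`; scalars
#'   recycled.
#' @param seq_depth_mean Mean library size for counts cohorts.
#' @param dispersion Negative-binomial dispersion for counts cohorts
#'   (0 = Poisson).
#' @param seed Master integer seed; one RNG stream per cohort is derived
#'   from it, so adding a cohort never perturbs earlier cohorts' data.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cohorts = 4,
                              genes = 5000,
                              n_responders = c(19, 8, 20, 24),
                              n_nonresponders = c(25, 16, 17, 7),
                              n_controls = 10,
                              planted_genes = NULL,
                              batch_shift_sd = 1,
                              batch_scale_sd = 0.3,
                              noise_sd = 1,
                              platform_types = c("counts", "array", "array", "array"),
                              seq_depth_mean = 2e6,
                              dispersion = 0.1,
                              seed = 1) {
  n_cohorts <- as.integer(n_cohorts)
  genes <- as.integer(genes)
  if (n_cohorts < 1L || genes < 1L)
    stop("invalid config: `n_cohorts` and `genes` must be positive")
  rec <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, n_cohorts)
    if (length(x) != n_cohorts)
      stop("invalid config: `", what, "` must have length 1 or n_cohorts")
    x
  }
  n_responders <- as.integer(rec(n_responders, "n_responders"))
  n_nonresponders <- as.integer(rec(n_nonresponders, "n_nonresponders"))
  n_controls <- as.integer(rec(n_controls, "n_controls"))
  if (any(c(n_responders, n_nonresponders, n_controls) < 2L))
    stop("invalid config: all group sizes must be >= 2")
  platform_types <- rec(as.character(platform_types), "platform_types")
  if (!all(platform_types %in% c("array", "counts")))
    stop("invalid config: platform types must be 'array' or 'counts'")
  if (batch_shift_sd < 0 || batch_scale_sd < 0)
    stop("invalid config: batch-effect SDs must be >= 0")
  if (noise_sd <= 0)
    stop("invalid config: `noise_sd` must be > 0")
  if (seq_depth_mean <= 0)
    stop("invalid config: `seq_depth_mean` must be > 0")
  if (dispersion < 0)
    stop("invalid config: `dispersion` must be >= 0")
  if (!is.null(planted_genes)) {
    planted_genes <- as.data.frame(planted_genes)
    if (!all(c("gene", "delta") %in% names(planted_genes)))
      stop("invalid config: `planted_genes` needs columns `gene` and `delta`")
    planted_genes$gene <- as.integer(planted_genes$gene)
    if (anyDuplicated(planted_genes$gene) ||
        any(planted_genes$gene < 1L) || any(planted_genes$gene > genes))
      stop("invalid config: planted gene ids must be a unique subset of 1..G")
  }
  structure(
    list(n_cohorts = n_cohorts, genes = genes,
         n_responders = n_responders, n_nonresponders = n_nonresponders,
         n_controls = n_controls, planted_genes = planted_genes,
         batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
         noise_sd = noise_sd, platform_types = platform_types,
         seq_depth_mean = seq_depth_mean, dispersion = dispersion,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %d cohorts, %d genes, %d planted, seed %d\n",
              x$n_cohorts, x$genes,
              if (is.null(x$planted_genes)) 0L else nrow(x$planted_genes),
              x$seed))
  invisible(x)
}

# Run expr with a private RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derived per-cohort stream seed (kept within 32-bit integer range).
cohort_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% 2147483647)
}

gene_id_vector <- function(genes) {
  paste0("g", formatC(seq_len(genes), width = nchar(genes), flag = "0"))
}

# Per-gene baseline means shared by all cohorts (drawn from the master seed):
# normal on the log2 scale to resemble array intensity dynamic range.
baseline_means <- function(config) {
  with_seed(config$seed, stats::rnorm(config$genes, mean = 8, sd = 2))
}

cohort_class_vector <- function(config, index) {
  rep(c("responder", "nonresponder", "control"),
      c(config$n_responders[index], config$n_nonresponders[index],
        config$n_controls[index]))
}

# Latent log2-scale signal for one cohort:
#   signal_gs = baseline_g + shift_cg + scale_cg * (class_effect_gs + noise_gs)
# Responders of planted genes get a mean offset of delta_g * noise_sd so the
# true standardized effect size equals delta_g; controls carry no class
# effect, hence the shared control distribution across cohorts before batch
# effects. Batch shift/scale act identically on all classes within a cohort.
cohort_signal_draw <- function(config, index, baseline) {
  G <- config$genes
  classes <- cohort_class_vector(config, index)
  S <- length(classes)
  shift <- stats::rnorm(G, 0, config$batch_shift_sd)
  scale <- exp(stats::rnorm(G, 0, config$batch_scale_sd))
  noise <- matrix(stats::rnorm(G * S, 0, config$noise_sd), nrow = G)
  effect <- matrix(0, nrow = G, ncol = S)
  if (!is.null(config$planted_genes)) {
    resp <- classes == "responder"
    effect[config$planted_genes$gene, resp] <-
      config$planted_genes$delta * config$noise_sd
  }
  signal <- baseline + shift + scale * (effect + noise)
  rownames(signal) <- gene_id_vector(G)
  colnames(signal) <- sprintf("cohort%d_s%03d", index, seq_len(S))
  list(signal = signal, classes = classes)
}

#' Latent log2 signal of one simulated cohort
#'
#' Diagnostic accessor: returns the noise-free-of-sequencing log2-scale
#' expression surface that the counts model exponentiates, exactly as drawn
#' for [generate_multicohort()] under the same config. Useful for checking
#' the counts model's convergence to its latent proportions.
#'
#' @param config A [simulation_config()].
#' @param cohort_index Cohort number in `1:n_cohorts`.
#' @return Numeric matrix (genes x samples) of log2 signal.
#' @export
cohort_log2_signal <- function(config, cohort_index) {
  stopifnot(inherits(config, "simulation_config"))
  baseline <- baseline_means(config)
  with_seed(cohort_seed(config$seed, cohort_index),
            cohort_signal_draw(config, cohort_index, baseline))$signal
}

generate_one_cohort <- function(config, index, baseline) {
  with_seed(cohort_seed(config$seed, index), {
    drawn <- cohort_signal_draw(config, index, baseline)
    id <- paste0("cohort", index)
    if (config$platform_types[index] == "array") {
      cohort_dataset(drawn$signal, drawn$classes, id, "array")
    } else {
      S <- ncol(drawn$signal)
      # per-sample library sizes: lognormal around seq_depth_mean (mean-preserving)
      depth <- config$seq_depth_mean *
        exp(stats::rnorm(S, -0.25^2 / 2, 0.25))
      lin <- 2^drawn$signal
      prop <- sweep(lin, 2, colSums(lin), "/")
      mu <- sweep(prop, 2, depth, "*")
      counts <- if (config$dispersion == 0) {
        matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu))
      } else {
        matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
               nrow = nrow(mu))
      }
      dimnames(counts) <- dimnames(drawn$signal)
      cohort_dataset(counts, drawn$classes, id, "counts")
    }
  })
}

#' Generate synthetic multi-cohort expression data
#'
#' Draws `n_cohorts` cohorts under the generative model described in
#' [simulation_config()]. Healthy controls of all cohorts share one
#' distribution before batch effects are applied (the co-normalization
#' assumption); per-cohort batch parameters are drawn once per cohort; the
#' output is bit-identical for identical configs.
#'
#' @param config A [simulation_config()].
#' @return List of [cohort_dataset()] objects, one per cohort.
#' @examples
#' cfg <- simulation_config(n_cohorts = 2, genes = 50,
#'                          n_responders = 5, n_nonresponders = 5,
#'                          n_controls = 4, platform_types = "array",
#'                          seed = 7)
#' generate_multicohort(cfg)
#' @export
generate_multicohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  baseline <- baseline_means(config)
  lapply(seq_len(config$n_cohorts),
         function(i) generate_one_cohort(config, i, baseline))
}

#' Generate a single RNA-seq counts cohort
#'
#' Counts are negative-binomial with per-gene means proportional to the
#' exponentiated array-model log2 signal times a per-sample library-size
#' factor centred on `seq_depth_mean`; class effects on the log scale are
#' identical to the array model.
#'
#' @param config A [simulation_config()].
#' @param cohort_index Index of a cohort whose platform tag is `"counts"`.
#' @return A [cohort_dataset()] with platform `"counts"`.
#' @export
generate_counts_cohort <- function(config, cohort_index) {
  stopifnot(inherits(config, "simulation_config"))
  cohort_index <- as.integer(cohort_index)
  if (cohort_index < 1L || cohort_index > config$n_cohorts)
    stop("`cohort_index` out of range")
  if (config$platform_types[cohort_index] != "counts")
    stop("cohort ", cohort_index, " is not a counts cohort")
  generate_one_cohort(config, cohort_index, baseline_means(config))
}
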
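#' Configuration for a full discovery run
#'
#' Bundles the inputs and tuning parameters of the end-to-end workflow:
#' simulate (or ingest) multi-cohort data, preprocess counts cohorts,
#' co-normalize on healthy controls, run the LOSO meta-analysis, search for
#' a parsimonious signature, and evaluate it.
#'
#' @param simulation A [simulation_config()], or `NULL` to ingest existing
#'   TSV inputs.
#' @param dataset_paths Character vector of expression TSV paths (required
#'   when `simulation` is `NULL`).
#' @param metadata_path Path to the sample-metadata TSV (required with
#'   `dataset_paths`).
#' @param out_dir Output directory (created if missing).
#' @param cpm_threshold CPM filter for counts cohorts (default 5).
#' @param fdr_max,es_min Significance thresholds (defaults 0.10 and 0.8).
#' @param loso_mode `"per_round"` or `"full"` (see
#'   [loso_significant_genes()]).
#' @param forward_threshold,threshold_scale Forward-search stopping rule
#'   (defaults 0.1 on the `"sum"` scale).
#' @param operating_sensitivity,operating_specificity Fixed coordinates for
#'   the rule-in / rule-out operating points on the pooled ROC.
#' @param gmt_path Optional GMT file for over-representation analysis of
#'   the significant genes.
#' @param seed Master seed; when simulating, it overrides the simulation
#'   config's seed so one integer controls the whole run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulation = NULL, dataset_paths = NULL,
                       metadata_path = NULL, out_dir,
                       cpm_threshold = 5, fdr_max = 0.10, es_min = 0.8,
                       loso_mode = c("per_round", "full"),
                       forward_threshold = 0.1,
                       threshold_scale = c("sum", "mean"),
                       operating_sensitivity = 0.95,
                       operating_specificity = 0.90,
                       gmt_path = NULL, seed = 1) {
  loso_mode <- match.arg(loso_mode)
  threshold_scale <- match.arg(threshold_scale)
  if (is.null(simulation)) {
    if (is.null(dataset_paths) || is.null(metadata_path))
      stop("either `simulation` or (`dataset_paths` + `metadata_path`) is required")
    missing_p <- c(dataset_paths, metadata_path)
    missing_p <- missing_p[!file.exists(missing_p)]
    if (length(missing_p))
      stop("input path(s) do not exist: ", paste(missing_p, collapse = ", "))
  } else {
    stopifnot(inherits(simulation, "simulation_config"))
    simulation$seed <- as.integer(seed)
  }
  if (!is.null(gmt_path) && !file.exists(gmt_path))
    stop("input path(s) do not exist: ", gmt_path)
  thr <- significance_thresholds(fdr_max, es_min)  # validates ranges
  if (forward_threshold < 0) stop("`forward_threshold` must be >= 0")
  structure(
    list(simulation = simulation, dataset_paths = dataset_paths,
         metadata_path = metadata_path, out_dir = out_dir,
         cpm_threshold = cpm_threshold, thresholds = thr,
         loso_mode = loso_mode, forward_threshold = forward_threshold,
         threshold_scale = threshold_scale,
         operating_sensitivity = operating_sensitivity,
         operating_specificity = operating_specificity,
         gmt_path = gmt_path, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' YAML keys mirror the arguments of [run_config()]; the `simulation` block
#' mirrors [simulation_config()] (with `planted_genes` as a list of
#' `{gene, delta}` records).
#'
#' @param path Path to a YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    if (!is.null(s$planted_genes))
      s$planted_genes <- do.call(rbind, lapply(s$planted_genes, as.data.frame))
    sim <- do.call(simulation_config, s)
  }
  args <- y[setdiff(names(y), "simulation")]
  args$simulation <- sim
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(run_config, args)
}

stage_digest <- function(paths) {
  d <- tools::md5sum(paths)
  stats::setNames(as.character(d), basename(paths))
}

#' Run the full discovery pipeline
#'
#' Executes the stages in order -- simulate/ingest, preprocess counts
#' cohorts, COCONUT co-normalization, LOSO meta-analysis, greedy forward
#' search, evaluation (and optional over-representation analysis) --
#' writing intermediate TSVs, the signature JSON, score and performance
#' tables and a JSON run manifest under `config$out_dir`. Fully
#' deterministic given the master seed. A stage failure aborts with the
#' failing stage named; outputs of completed stages are retained.
#'
#' @param config A [run_config()].
#' @return An object of class `run_manifest`: list with the config digest,
#'   package version, per-stage output digests and notes, and the
#'   gene/sample count ledger. Also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  counts_ledger <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  record <- function(name, paths, note = "") {
    stages[[name]] <<- list(name = name, outputs = stage_digest(paths),
                            note = note)
  }
  out <- function(...) file.path(config$out_dir, ...)

  # --- ingest ---------------------------------------------------------------
  datasets <- run_stage("ingest", function() {
    if (!is.null(config$simulation)) generate_multicohort(config$simulation)
    else {
      meta <- read_metadata_tsv(config$metadata_path)
      lapply(config$dataset_paths, read_cohort_tsv, metadata = meta)
    }
  })
  input_paths <- vapply(datasets, function(d) {
    write_cohort_tsv(d, out(paste0("input_", d$cohort_id, ".tsv")))
  }, character(1))
  meta_path <- write_metadata_tsv(datasets, out("metadata.tsv"))
  record("ingest", c(input_paths, meta_path),
         sprintf("%d cohorts", length(datasets)))
  counts_ledger$input_genes <- vapply(datasets, function(d) nrow(d$expr), integer(1))

  # --- preprocess counts cohorts -------------------------------------------
  datasets <- run_stage("preprocess", function() {
    lapply(datasets, function(d) {
      if (d$platform == "counts") preprocess_counts(d, config$cpm_threshold)
      else d
    })
  })
  prep_paths <- vapply(datasets, function(d) {
    write_cohort_tsv(d, out(paste0("preprocessed_", d$cohort_id, ".tsv")))
  }, character(1))
  record("preprocess", prep_paths,
         sprintf("CPM filter >= %g", config$cpm_threshold))
  counts_ledger$preprocessed_genes <-
    vapply(datasets, function(d) nrow(d$expr), integer(1))

  # --- COCONUT --------------------------------------------------------------
  conorm <- run_stage("coconut", function() coconut_normalize(datasets))
  datasets <- conorm$datasets
  conorm_paths <- vapply(datasets, function(d) {
    write_cohort_tsv(d, out(paste0("conormalized_", d$cohort_id, ".tsv")))
  }, character(1))
  rep_path <- out("coconut_report.tsv")
  utils::write.table(coconut_report(conorm$adjustment), rep_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  record("coconut", c(conorm_paths, rep_path),
         sprintf("%d shared genes", length(conorm$adjustment$genes)))
  counts_ledger$shared_genes <- length(conorm$adjustment$genes)

  # --- LOSO meta-analysis ---------------------------------------------------
  loso <- run_stage("meta_analysis", function()
    loso_significant_genes(datasets, config$thresholds, config$loso_mode))
  meta_path_out <- out("meta_loso.tsv")
  utils::write.table(loso$table, meta_path_out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  record("meta_analysis", meta_path_out,
         sprintf("%d significant of %d tested genes",
                 length(loso$genes), nrow(loso$table)))
  counts_ledger$tested_genes <- nrow(loso$table)
  counts_ledger$significant_genes <- length(loso$genes)

  # --- forward search -------------------------------------------------------
  search <- run_stage("forward_search", function() {
    if (!length(loso$genes))
      stop("no significant genes to search over")
    greedy_forward_search(signature_candidates(loso), datasets,
                          threshold = config$forward_threshold,
                          threshold_scale = config$threshold_scale)
  })
  sig_path <- write_signature_json(search$signature, out("signature.json"))
  trace_path <- out("search_trace.tsv")
  utils::write.table(search$trace, trace_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  record("forward_search", c(sig_path, trace_path),
         sprintf("%d-gene signature",
                 length(search$signature$pos) + length(search$signature$neg)))
  counts_ledger$signature_genes <-
    length(search$signature$pos) + length(search$signature$neg)

  # --- evaluation -----------------------------------------------------------
  eval_out <- run_stage("evaluation", function() {
    diseased <- lapply(datasets, diseased_samples)
    names(diseased) <- vapply(diseased, function(d) d$cohort_id, character(1))
    scores <- lapply(diseased, function(d) as.numeric(atr_score(d, search$signature)))
    labels <- lapply(diseased, response_labels)
    curves <- Map(roc_curve, scores, labels)
    perf <- evaluate_performance(scores, labels)
    pooled <- pooled_roc(curves, vapply(scores, length, integer(1)))
    list(
      scores = do.call(rbind, lapply(names(diseased), function(id)
        data.frame(cohort_id = id, sample_id = sample_ids(diseased[[id]]),
                   label = unname(labels[[id]]), atr_score = scores[[id]],
                   stringsAsFactors = FALSE))),
      perf = perf, pooled = pooled,
      operating = data.frame(
        fixed = c("sensitivity", "specificity"),
        at = c(config$operating_sensitivity, config$operating_specificity),
        complement = c(
          operating_point(pooled, "sensitivity", config$operating_sensitivity),
          operating_point(pooled, "specificity", config$operating_specificity))))
  })
  score_path <- out("atr_scores.tsv")
  utils::write.table(eval_out$scores, score_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  perf_path <- out("performance.tsv")
  utils::write.table(eval_out$perf$per_dataset, perf_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pooled_path <- out("pooled_roc.tsv")
  utils::write.table(eval_out$pooled$curve, pooled_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  op_path <- out("operating_points.tsv")
  utils::write.table(eval_out$operating, op_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  record("evaluation", c(score_path, perf_path, pooled_path, op_path),
         sprintf("pooled AUROC %.3f", eval_out$pooled$auroc))

  # --- optional ORA ---------------------------------------------------------
  if (!is.null(config$gmt_path)) {
    ora <- run_stage("ora", function()
      hypergeometric_ora(loso$genes, read_gmt(config$gmt_path),
                         loso$table$gene))
    ora_path <- out("ora.tsv")
    utils::write.table(ora, ora_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    record("ora", ora_path, sprintf("%d pathways tested", nrow(ora)))
  }

  manifest <- structure(
    list(package_version = as.character(utils::packageVersion("atrsig")),
         seed = config$seed,
         config_digest = unname(stage_digest(meta_path)["metadata.tsv"]),
         stages = stages, counts = counts_ledger,
         pooled_auroc = eval_out$pooled$auroc,
         mean_performance = as.list(eval_out$perf$mean)),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest), out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> atrsig %s, seed %d\n",
              x$package_version, x$seed))
  for (s in x$stages)
    cat(sprintf("  %-15s %s\n", s$name, s$note))
  invisible(x)
}
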
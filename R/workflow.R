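#' Generate a synthetic benchmark dataset on disk
#'
#' Wraps [simulate_multiomics()]: writes one TSV per omics block, the
#' clinical table, a `truth.tsv` with the generating cluster of every
#' sample, and the resolved configuration as YAML.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory.
#' @return Invisibly, the simulation result list.
#' @export
sadln_simulate <- function(config = simulation_config(), out_dir) {
  sim <- simulate_multiomics(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_omics(sim$data, out_dir)
  write_clinical(sim$clinical, file.path(out_dir, "clinical.tsv"))
  utils::write.table(
    data.frame(sample_id = sim$data$sample_ids, cluster = sim$labels),
    file.path(out_dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "sim_config.yaml"))
  invisible(sim)
}

#' End-to-end subtype discovery
#'
#' The full pipeline: z-score the blocks (on by default), train the
#' adversarial integration network, encode all samples in inference mode,
#' fit a Gaussian mixture with `K` components to the latent matrix, and
#' assign each sample to its maximum-posterior component. When `out_dir` is
#' given, writes `latent.tsv`, `assignments.tsv`, `trace.tsv` and the model
#' checkpoint `model.rds`.
#'
#' @param data an [omics_dataset()].
#' @param K number of subtypes to call.
#' @param config optional [architecture_config()]; defaults to the standard
#'   architecture for the dataset's block widths.
#' @param zscore standardize features first (recommended for raw inputs).
#' @param n_init,gmm_seed GMM restart count and seed (defaults: 10 restarts,
#'   seed derived from the network seed).
#' @param out_dir optional output directory.
#' @param ... passed to [architecture_config()] when `config` is NULL
#'   (e.g. `epochs`, `seed`, `lambda1`, `lambda2`, `use_attention`).
#' @return List with `model`, `trace`, `latent`, `fit`, `assignment`.
#' @export
sadln_subtype <- function(data, K, config = NULL, zscore = TRUE,
                          n_init = 10, gmm_seed = NULL, out_dir = NULL, ...) {
  stopifnot(inherits(data, "omics_dataset"))
  if (zscore) data <- zscore_blocks(data)
  config <- config %||% architecture_config(block_widths(data), ...)
  tr <- sadln_train(data, config)
  latent <- encode(tr$model, data, mode = "inference")
  fit <- gmm_fit(latent$Z, K, n_init = n_init,
                 seed = gmm_seed %||% (config$seed + 1))
  assignment <- gmm_assign(fit, data$sample_ids)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(sample_id = data$sample_ids, latent$Z, check.names = FALSE),
      file.path(out_dir, "latent.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(assignment, file.path(out_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tr$trace, file.path(out_dir, "trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sadln_save(tr$model, file.path(out_dir, "model.rds"))
  }
  list(model = tr$model, trace = tr$trace, latent = latent, fit = fit,
       assignment = assignment)
}

#' Evaluate a subtype assignment against survival and clinical labels
#'
#' Computes the permutation-calibrated log-rank p-value for differential
#' survival between subtypes and the clinical-enrichment count, and
#' assembles a report (optionally written as JSON). `-log10(p)` is reported
#' to one decimal.
#'
#' @param assignment a `cluster_assignment` data.frame (or any data.frame
#'   with `sample_id` and `cluster` columns).
#' @param clinical a [clinical_table()].
#' @param seed optional integer seed for the permutation tests.
#' @param alpha enrichment significance threshold.
#' @param out_path optional path for the JSON report.
#' @return An object of class `sadln_evaluation`.
#' @export
sadln_evaluate <- function(assignment, clinical, seed = NULL, alpha = 0.05,
                           out_path = NULL) {
  cl <- align_clinical(clinical, assignment$sample_id)
  labels <- assignment$cluster
  lr <- permutation_pvalue_logrank(cl$time, cl$event, labels, seed = seed)
  label_cols <- setdiff(colnames(cl), c("sample_id", "time", "event"))
  enr <- if (length(label_cols) > 0) {
    enrichment_count(cl, labels, alpha = alpha,
                     seed = if (is.null(seed)) NULL else seed + 1)
  } else {
    warning("no clinical label columns; enrichment analysis skipped")
    NULL
  }
  report <- list(
    logrank = list(chi2 = lr$statistic, df = lr$df,
                   p_asymptotic = lr$p_asymptotic,
                   p_perm = lr$p_hat,
                   minus_log10_p = round(-log10(lr$p_hat), 1),
                   ci = c(lr$ci_low, lr$ci_high),
                   n_perm = lr$n_perm, stopped_by = lr$stopped_by),
    enrichment = if (!is.null(enr)) {
      list(n_significant = enr$n_significant, n_tested = enr$n_tested,
           alpha = enr$alpha,
           labels = lapply(enr$results, function(r) {
             list(label = r$label, test = r$test, statistic = r$statistic,
                  p = r$p)
           }))
    })
  if (!is.null(out_path)) {
    jsonlite::write_json(report, out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  structure(list(report = report, logrank = lr, enrichment = enr),
            class = "sadln_evaluation")
}

#' @export
print.sadln_evaluation <- function(x, ...) {
  cat(sprintf("survival: -log10(p) = %.1f (permutation p = %.3g, %d permutations)\n",
              x$report$logrank$minus_log10_p, x$report$logrank$p_perm,
              x$report$logrank$n_perm))
  if (!is.null(x$enrichment)) print(x$enrichment)
  invisible(x)
}
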
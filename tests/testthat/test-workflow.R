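small_sim_config <- function(seed = 2) {
  simulation_config(n_samples = 60, n_clusters = 2,
                    block_widths = c(20, 20, 10, 20),
                    cluster_separation = 4, informative_fraction = 0.4,
                    survival_scales = c(10, 80), censor_rate = 0.2, seed = seed)
}

test_that("simulate command writes the full file set reproducibly", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sadln_simulate(small_sim_config(), d1)
  sadln_simulate(small_sim_config(), d2)
  files <- c("cnv.tsv", "mrna.tsv", "mirna.tsv", "meth.tsv",
             "clinical.tsv", "truth.tsv", "sim_config.yaml")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("the end-to-end subtyping workflow produces aligned outputs", {
  sim <- simulate_multiomics(small_sim_config())
  d <- withr::local_tempdir()
  res <- sadln_subtype(sim$data, K = 2, epochs = 10, seed = 2, out_dir = d)
  expect_equal(nrow(res$assignment), 60)
  expect_identical(res$assignment$sample_id, sim$data$sample_ids)
  expect_true(all(res$assignment$cluster %in% 1:2))
  expect_true(all(file.exists(file.path(d, c("latent.tsv", "assignments.tsv",
                                             "trace.tsv", "model.rds")))))
  asg <- read.table(file.path(d, "assignments.tsv"), header = TRUE, sep = "\t")
  expect_equal(asg$cluster, res$assignment$cluster)
  # ablation flags are honored in the stored model configuration
  res2 <- sadln_subtype(sim$data, K = 2, epochs = 1, seed = 2,
                        lambda2 = 0, use_attention = FALSE)
  expect_equal(res2$model$config$lambda2, 0)
  expect_false(res2$model$config$use_attention)
})

test_that("evaluation reports survival and enrichment in the documented schema", {
  sim <- simulate_multiomics(small_sim_config())
  asg <- data.frame(sample_id = sim$data$sample_ids, cluster = sim$labels)
  d <- withr::local_tempdir()
  out <- file.path(d, "report.json")
  ev <- sadln_evaluate(asg, sim$clinical, seed = 7, out_path = out)
  expect_lt(ev$report$logrank$p_perm, 0.05)
  expect_gt(ev$report$logrank$minus_log10_p, 1.3)
  js <- jsonlite::read_json(out)
  expect_named(js, c("logrank", "enrichment"))
  expect_named(js$logrank, c("chi2", "df", "p_asymptotic", "p_perm",
                             "minus_log10_p", "ci", "n_perm", "stopped_by"))
  expect_true(js$enrichment$n_tested >= 1)
  # shuffled labels carry no survival signal
  set.seed(22)
  asg_null <- transform(asg, cluster = sample(cluster))
  ev0 <- sadln_evaluate(asg_null, sim$clinical, seed = 8)
  expect_gt(ev0$report$logrank$p_perm, 0.05)
})

test_that("the command-line interface runs the simulate workflow", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "sadln.R", package = "sadln")
  expect_true(nzchar(cli))
  d <- withr::local_tempdir()
  out <- system2("Rscript", c(cli, "simulate", "--out", shQuote(d),
                              "--n-samples", "30", "--k", "2", "--seed", "5"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(d, "truth.tsv")))
  truth <- read.table(file.path(d, "truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(truth), 30)
  # config errors exit with status 2
  status <- suppressWarnings(
    system2("Rscript", c(cli, "simulate", "--out", shQuote(d),
                         "--n-samples", "10", "--k", "11"),
            stdout = FALSE, stderr = FALSE))
  expect_equal(status, 2)
})
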
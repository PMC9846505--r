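# Shared synthetic benchmark: n = 400 samples, four omics blocks of widths
# 200/200/50/200, K = 4 clusters, separation 3 x noise sd, cluster-linked
# exponential survival. Training runs are cached so several tests can reuse
# the same fitted pipeline.
.benchmark_cache <- new.env(parent = emptyenv())

benchmark_sim <- function() {
  if (is.null(.benchmark_cache$sim)) {
    .benchmark_cache$sim <- simulate_multiomics(simulation_config(seed = 2))
  }
  .benchmark_cache$sim
}

benchmark_pipeline <- function(seed, lambda1 = 1, epochs = 200) {
  key <- sprintf("run_s%d_l%g_e%d", seed, lambda1, epochs)
  if (is.null(.benchmark_cache[[key]])) {
    sim <- benchmark_sim()
    dz <- zscore_blocks(sim$data)
    cfg <- architecture_config(c(200, 200, 50, 200), epochs = epochs,
                               seed = seed, lambda1 = lambda1)
    tr <- sadln_train(dz, cfg)
    Z <- encode(tr$model, dz, mode = "inference")
    fit <- gmm_fit(Z$Z, 4, n_init = 10, seed = seed + 1)
    asg <- gmm_assign(fit, sim$data$sample_ids)
    .benchmark_cache[[key]] <- list(
      model = tr$model, trace = tr$trace, Z = Z$Z, fit = fit,
      assignment = asg, ari = ari(asg$cluster, sim$labels))
  }
  .benchmark_cache[[key]]
}
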
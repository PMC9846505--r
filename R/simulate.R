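#' Simulate a multi-omics dataset with known cluster structure
#'
#' Generates the data-generating process that Gaussian-mixture clustering
#' assumes: samples fall into `K` latent clusters; within each omics block an
#' `informative_fraction` of features receives cluster-specific mean shifts
#' (each cluster sits at `+/- cluster_separation/2` on each informative
#' feature, signs drawn independently per cluster and feature) while the rest
#' are pure noise. Survival times are exponential with per-cluster mean
#' `survival_scales[k]`; a `censor_rate` fraction of samples is censored at a
#' uniform point before the true event time. Two clinical label columns are
#' attached: `age`, numeric and cluster-linked, and `gender`, categorical and
#' independent of cluster (a null covariate).
#'
#' All randomness comes from `config$seed`; identical configurations yield
#' bit-identical outputs.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `data` ([omics_dataset()]), `labels`
#'   (integer cluster per sample) and `clinical` ([clinical_table()]).
#' @export
simulate_multiomics <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    K <- config$n_clusters
    labels <- sample.int(K, n, replace = TRUE, prob = config$cluster_proportions)
    sample_ids <- sprintf("s%04d", seq_len(n))
    blocks <- vector("list", length(config$block_widths))
    for (m in seq_along(config$block_widths)) {
      D <- config$block_widths[m]
      sd_m <- config$noise_sd[m]
      n_inf <- round(config$informative_fraction[m] * D)
      values <- matrix(stats::rnorm(n * D, sd = sd_m), n, D)
      if (n_inf > 0) {
        shift <- matrix(sample(c(-1, 1), K * n_inf, replace = TRUE), K, n_inf) *
          (config$cluster_separation * sd_m / 2)
        values[, seq_len(n_inf)] <- values[, seq_len(n_inf)] +
          shift[labels, , drop = FALSE]
      }
      colnames(values) <- paste0(config$block_names[m], "_f", seq_len(D))
      blocks[[m]] <- omics_block(config$block_names[m], values)
    }
    data <- omics_dataset(blocks, sample_ids)

    t_true <- stats::rexp(n, rate = 1 / config$survival_scales[labels])
    censored <- stats::runif(n) < config$censor_rate
    time <- ifelse(censored, stats::runif(n) * t_true, t_true)
    event <- as.integer(!censored)
    age <- round(50 + 3 * labels + stats::rnorm(n, sd = 8), 1)
    gender <- sample(c("female", "male"), n, replace = TRUE)
    clinical <- clinical_table(sample_ids, time, event,
                               labels = data.frame(age = age, gender = gender,
                                                   stringsAsFactors = FALSE))
    list(data = data, labels = labels, clinical = clinical)
  })
}

#' Z-score every feature column of every block
#'
#' Columns are centred and scaled to unit variance using the population
#' (1/N) variance; constant columns map to all zeros rather than NaN so that
#' degenerate features cannot poison the network input. The operation is
#' idempotent.
#'
#' @param data an [omics_dataset()].
#' @return The dataset with standardized blocks.
#' @export
zscore_blocks <- function(data) {
  stopifnot(inherits(data, "omics_dataset"))
  blocks <- lapply(data$blocks, function(b) {
    x <- b$values
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    sd_pop <- sqrt(colMeans(xc^2))
    scale_by <- ifelse(sd_pop > 0, sd_pop, 1)
    z <- sweep(xc, 2, scale_by, "/")
    z[, sd_pop == 0] <- 0
    omics_block(b$name, z, b$feature_ids)
  })
  omics_dataset(blocks, data$sample_ids)
}
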
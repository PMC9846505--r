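#' Architecture and training configuration
#'
#' Collects the hyperparameters of the integration network. Defaults follow
#' the published setting: per-omics sub-network width `d = 25`, integrated
#' dimension `latent_dim = M * d` (100 for four omics blocks), Adam at
#' learning rate 1e-4, 600 epochs, batch size 64, seed 2, loss weights
#' `lambda1 = 1` (reconstruction) and `lambda2 = 1e-4` (adversarial
#' regularization).
#'
#' @param block_input_dims integer vector, input feature count per omics block.
#' @param d width of each per-omics sub-network output.
#' @param latent_dim dimension of the integrated representation; must equal
#'   `length(block_input_dims) * d`.
#' @param learning_rate Adam learning rate. `sadln_lr_grid` holds the
#'   published candidate grid.
#' @param epochs number of training epochs.
#' @param batch_size minibatch size; the final incomplete batch is kept.
#' @param seed integer seed controlling weight initialization, batch
#'   shuffling, reparameterization noise and prior draws.
#' @param lambda1,lambda2 loss weights in `[0, 1]` for the reconstruction and
#'   adversarial terms.
#' @param use_attention logical; `FALSE` replaces the sample-wise
#'   self-attention layer by the identity (ablation).
#' @return An object of class `architecture_config`.
#' @export
architecture_config <- function(block_input_dims,
                                d = 25,
                                latent_dim = length(block_input_dims) * d,
                                learning_rate = 1e-4,
                                epochs = 600,
                                batch_size = 64,
                                seed = 2,
                                lambda1 = 1,
                                lambda2 = 1e-4,
                                use_attention = TRUE) {
  block_input_dims <- as.integer(block_input_dims)
  if (length(block_input_dims) < 1 || any(block_input_dims < 1)) {
    stop_config("block_input_dims must be positive integers, one per omics block")
  }
  if (latent_dim != length(block_input_dims) * d) {
    stop_config("latent_dim must equal number of blocks times d (",
                length(block_input_dims), " x ", d, ")")
  }
  if (lambda1 < 0 || lambda1 > 1 || lambda2 < 0 || lambda2 > 1) {
    stop_config("lambda1 and lambda2 must lie in [0, 1]")
  }
  if (epochs < 0 || batch_size < 1) stop_config("epochs must be >= 0 and batch_size >= 1")
  structure(list(
    block_input_dims = block_input_dims,
    n_blocks = length(block_input_dims),
    d = as.integer(d),
    latent_dim = as.integer(latent_dim),
    learning_rate = learning_rate,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    seed = as.integer(seed),
    lambda1 = lambda1,
    lambda2 = lambda2,
    use_attention = isTRUE(use_attention)
  ), class = "architecture_config")
}

#' Published learning-rate candidate grid
#' @export
sadln_lr_grid <- c(1e-4, 2e-4, 3e-4, 4e-4, 5e-4, 1e-5, 2e-5, 3e-5, 4e-5, 5e-5)

#' Synthetic multi-omics simulation configuration
#'
#' Describes a dataset of `n_samples` drawn from `n_clusters` latent groups
#' observed through several omics blocks. Within each block an
#' `informative_fraction` of features carries cluster-specific mean shifts of
#' magnitude `cluster_separation` (clusters sit at +/- separation/2 on each
#' informative feature); remaining features are pure Gaussian noise with
#' standard deviation `noise_sd`. Survival times are exponential with a
#' per-cluster mean (`survival_scales`) and are uniformly censored at rate
#' `censor_rate`.
#'
#' @param n_samples number of samples.
#' @param n_clusters number of latent clusters K.
#' @param block_widths integer vector of feature counts, one per omics block.
#' @param cluster_separation gap, in units of `noise_sd`, between cluster
#'   means on an informative feature.
#' @param informative_fraction fraction of features per block carrying
#'   cluster signal (recycled across blocks).
#' @param noise_sd residual standard deviation per block (recycled).
#' @param survival_scales mean survival time per cluster; length K.
#' @param censor_rate probability a sample is censored, in `[0, 1)`.
#' @param cluster_proportions mixing proportions; default uniform.
#' @param block_names labels for the blocks.
#' @param seed integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 400,
                              n_clusters = 4,
                              block_widths = c(200, 200, 50, 200),
                              cluster_separation = 3,
                              informative_fraction = 0.2,
                              noise_sd = 1,
                              survival_scales = NULL,
                              censor_rate = 0.3,
                              cluster_proportions = NULL,
                              block_names = NULL,
                              seed = 2) {
  if (n_clusters < 1) stop_config("n_clusters must be >= 1")
  if (n_clusters > n_samples) {
    stop_config("n_clusters (", n_clusters, ") exceeds n_samples (", n_samples, ")")
  }
  if (any(block_widths < 1)) stop_config("all block widths must be >= 1")
  if (censor_rate < 0 || censor_rate >= 1) stop_config("censor_rate must be in [0, 1)")
  M <- length(block_widths)
  cluster_proportions <- cluster_proportions %||% rep(1 / n_clusters, n_clusters)
  if (length(cluster_proportions) != n_clusters ||
      abs(sum(cluster_proportions) - 1) > 1e-8 || any(cluster_proportions < 0)) {
    stop_config("cluster_proportions must be ", n_clusters, " nonnegative values summing to 1")
  }
  survival_scales <- survival_scales %||% (20 * 2^(seq_len(n_clusters) - 1))
  if (length(survival_scales) != n_clusters || any(survival_scales <= 0)) {
    stop_config("survival_scales must be ", n_clusters, " positive values")
  }
  block_names <- block_names %||% (
    if (M == 4) c("cnv", "mrna", "mirna", "meth") else paste0("omics", seq_len(M)))
  structure(list(
    n_samples = as.integer(n_samples),
    n_clusters = as.integer(n_clusters),
    block_widths = as.integer(block_widths),
    cluster_separation = cluster_separation,
    informative_fraction = rep_len(informative_fraction, M),
    noise_sd = rep_len(noise_sd, M),
    survival_scales = survival_scales,
    censor_rate = censor_rate,
    cluster_proportions = cluster_proportions,
    block_names = block_names,
    seed = as.integer(seed)
  ), class = "simulation_config")
}
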
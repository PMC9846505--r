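#' Initialize an integration model
#'
#' Builds the full parameter set — per-omics sub-network affine maps, two
#' batch-norm layers, the attention projections, the shared fully-connected
#' layer, the mean/log-variance latent heads, the decoder trunk and
#' per-block output heads, and the discriminator — with Glorot-uniform
#' weights drawn from `config$seed`.
#'
#' @param config an [architecture_config()].
#' @return An object of class `sadln_model`.
#' @export
sadln_init <- function(config) {
  stopifnot(inherits(config, "architecture_config"))
  dk <- config$latent_dim
  d <- config$d
  with_seed(config$seed, {
    params <- list()
    for (m in seq_len(config$n_blocks)) {
      Dm <- config$block_input_dims[m]
      params[[paste0("sub", m, ".W")]] <- glorot(Dm, d)
      params[[paste0("sub", m, ".b")]] <- rep(0, d)
    }
    params[["bn1.gamma"]] <- rep(1, dk)
    params[["bn1.beta"]] <- rep(0, dk)
    if (config$use_attention) {
      params[["att.WK"]] <- glorot(dk, dk)
      params[["att.WQ"]] <- glorot(dk, dk)
      params[["att.WV"]] <- glorot(dk, dk)
    }
    params[["bn2.gamma"]] <- rep(1, dk)
    params[["bn2.beta"]] <- rep(0, dk)
    params[["fc.W"]] <- glorot(dk, dk)
    params[["fc.b"]] <- rep(0, dk)
    params[["mu.W"]] <- glorot(dk, dk)
    params[["mu.b"]] <- rep(0, dk)
    params[["lv.W"]] <- glorot(dk, dk)
    params[["lv.b"]] <- rep(0, dk)
    params[["dec.W"]] <- glorot(dk, dk)
    params[["dec.b"]] <- rep(0, dk)
    params[["bn3.gamma"]] <- rep(1, dk)
    params[["bn3.beta"]] <- rep(0, dk)
    for (m in seq_len(config$n_blocks)) {
      Dm <- config$block_input_dims[m]
      params[[paste0("head", m, ".W")]] <- glorot(dk, Dm)
      params[[paste0("head", m, ".b")]] <- rep(0, Dm)
    }
    params[["disc.W"]] <- glorot(dk, 1)
    params[["disc.b"]] <- 0
    structure(list(
      params = params,
      bn_stats = list(bn1 = bn_stats_init(dk), bn2 = bn_stats_init(dk),
                      bn3 = bn_stats_init(dk)),
      config = config,
      epochs_trained = 0L
    ), class = "sadln_model")
  })
}

encoder_param_names <- function(config) {
  nm <- c(paste0("sub", seq_len(config$n_blocks), ".W"),
          paste0("sub", seq_len(config$n_blocks), ".b"),
          "bn1.gamma", "bn1.beta")
  if (config$use_attention) nm <- c(nm, "att.WK", "att.WQ", "att.WV")
  c(nm, "bn2.gamma", "bn2.beta", "fc.W", "fc.b",
    "mu.W", "mu.b", "lv.W", "lv.b")
}

decoder_param_names <- function(config) {
  c("dec.W", "dec.b", "bn3.gamma", "bn3.beta",
    paste0("head", seq_len(config$n_blocks), ".W"),
    paste0("head", seq_len(config$n_blocks), ".b"))
}

#' Per-omics sub-network forward map
#'
#' The affine feature extractor applied to one omics block:
#' `y = x %*% w + b`, mapping `N x D_m` inputs to `N x d` outputs.
#' @param x_m numeric matrix, `N x D_m`.
#' @param w_m weight matrix, `D_m x d`.
#' @param b_m bias vector, length `d`.
#' @return `N x d` matrix.
#' @export
sub_network_forward <- function(x_m, w_m, b_m) {
  if (ncol(x_m) != nrow(w_m)) {
    stop_data("sub-network shape mismatch: input has ", ncol(x_m),
              " features, weights expect ", nrow(w_m))
  }
  sweep(x_m %*% w_m, 2, b_m, "+")
}

#' Concatenate per-omics feature matrices column-wise
#'
#' @param y_list list of `N x d` matrices, one per omics block, in block order.
#' @return `N x sum(d)` fused matrix.
#' @export
concat_features <- function(y_list) {
  ns <- vapply(y_list, nrow, integer(1))
  if (length(unique(ns)) != 1) stop_data("blocks disagree on sample count")
  do.call(cbind, y_list)
}

resolve_blocks <- function(model, data) {
  Xs <- if (inherits(data, "omics_dataset")) {
    unname(block_matrices(data))
  } else if (is.list(data)) {
    lapply(data, as.matrix)
  } else {
    list(as.matrix(data))
  }
  cfg <- model$config
  if (length(Xs) != cfg$n_blocks) {
    stop_data("model expects ", cfg$n_blocks, " blocks, got ", length(Xs))
  }
  for (m in seq_along(Xs)) {
    if (ncol(Xs[[m]]) != cfg$block_input_dims[m]) {
      stop_data("block ", m, " has ", ncol(Xs[[m]]), " features; config says ",
                cfg$block_input_dims[m])
    }
  }
  Xs
}

# Full encoder forward pass. In training mode the latent draw uses the
# reparameterization Z = mu + exp(log_var/2) * eps; `eps` must then be
# supplied by the caller (the training loop owns the RNG). Returns the
# updated running batch-norm statistics alongside the cache.
encoder_forward <- function(model, Xs, training = FALSE, eps = NULL) {
  p <- model$params
  cfg <- model$config
  Ys <- vector("list", cfg$n_blocks)
  for (m in seq_len(cfg$n_blocks)) {
    Ys[[m]] <- sub_network_forward(Xs[[m]], p[[paste0("sub", m, ".W")]],
                                   p[[paste0("sub", m, ".b")]])
  }
  Y <- concat_features(Ys)
  bn1 <- bn_forward(Y, list(gamma = p$bn1.gamma, beta = p$bn1.beta),
                    model$bn_stats$bn1, training)
  A <- gelu(bn1$y)
  if (cfg$use_attention) {
    att <- attention_forward(A, p$att.WK, p$att.WQ, p$att.WV)
    Zatt <- att$Z
  } else {
    att <- NULL
    Zatt <- A
  }
  bn2 <- bn_forward(Zatt, list(gamma = p$bn2.gamma, beta = p$bn2.beta),
                    model$bn_stats$bn2, training)
  FC <- sweep(bn2$y %*% p$fc.W, 2, p$fc.b, "+")
  mu <- sweep(FC %*% p$mu.W, 2, p$mu.b, "+")
  log_var <- sweep(FC %*% p$lv.W, 2, p$lv.b, "+")
  if (any(!is.finite(mu)) || any(!is.finite(log_var))) {
    stop_numerical("non-finite encoder activations")
  }
  if (training) {
    if (is.null(eps)) eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
    Z <- mu + exp(log_var / 2) * eps
  } else {
    eps <- NULL
    Z <- mu
  }
  list(Z = Z, mu = mu, log_var = log_var,
       cache = list(Xs = Xs, bn1 = bn1$cache, A_in = bn1$y, A = A,
                    att = att, bn2 = bn2$cache, FC = FC, bn2_y = bn2$y,
                    eps = eps, log_var = log_var, training = training),
       bn_stats = list(bn1 = bn1$stats, bn2 = bn2$stats))
}

# Backward pass from dL/dZ through the whole encoder.
encoder_backward <- function(model, cache, dZ) {
  p <- model$params
  cfg <- model$config
  g <- list()
  if (cache$training) {
    dmu <- dZ
    dlv <- dZ * cache$eps * 0.5 * exp(cache$log_var / 2)
  } else {
    dmu <- dZ
    dlv <- matrix(0, nrow(dZ), ncol(dZ))
  }
  g[["mu.W"]] <- t(cache$FC) %*% dmu
  g[["mu.b"]] <- colSums(dmu)
  g[["lv.W"]] <- t(cache$FC) %*% dlv
  g[["lv.b"]] <- colSums(dlv)
  dFC <- dmu %*% t(p$mu.W) + dlv %*% t(p$lv.W)
  g[["fc.W"]] <- t(cache$bn2_y) %*% dFC
  g[["fc.b"]] <- colSums(dFC)
  dbn2y <- dFC %*% t(p$fc.W)
  bn2b <- bn_backward(dbn2y, cache$bn2)
  g[["bn2.gamma"]] <- bn2b$dgamma
  g[["bn2.beta"]] <- bn2b$dbeta
  dZatt <- bn2b$dx
  if (cfg$use_attention) {
    ab <- attention_backward(dZatt, cache$att, p$att.WK, p$att.WQ, p$att.WV)
    g[["att.WK"]] <- ab$dW_K
    g[["att.WQ"]] <- ab$dW_Q
    g[["att.WV"]] <- ab$dW_V
    dA <- ab$dYp
  } else {
    dA <- dZatt
  }
  dA_in <- dA * gelu_grad(cache$A_in)
  bn1b <- bn_backward(dA_in, cache$bn1)
  g[["bn1.gamma"]] <- bn1b$dgamma
  g[["bn1.beta"]] <- bn1b$dbeta
  dY <- bn1b$dx
  d <- cfg$d
  for (m in seq_len(cfg$n_blocks)) {
    cols <- ((m - 1) * d + 1):(m * d)
    dYm <- dY[, cols, drop = FALSE]
    g[[paste0("sub", m, ".W")]] <- t(cache$Xs[[m]]) %*% dYm
    g[[paste0("sub", m, ".b")]] <- colSums(dYm)
  }
  g
}

decoder_forward <- function(model, Z, training = FALSE) {
  p <- model$params
  cfg <- model$config
  T1 <- sweep(Z %*% p$dec.W, 2, p$dec.b, "+")
  bn3 <- bn_forward(T1, list(gamma = p$bn3.gamma, beta = p$bn3.beta),
                    model$bn_stats$bn3, training)
  G <- gelu(bn3$y)
  outs <- vector("list", cfg$n_blocks)
  for (m in seq_len(cfg$n_blocks)) {
    outs[[m]] <- sweep(G %*% p[[paste0("head", m, ".W")]], 2,
                       p[[paste0("head", m, ".b")]], "+")
  }
  list(outs = outs,
       cache = list(Z = Z, bn3 = bn3$cache, G_in = bn3$y, G = G,
                    training = training),
       bn_stats = list(bn3 = bn3$stats))
}

decoder_backward <- function(model, cache, dOuts) {
  p <- model$params
  cfg <- model$config
  g <- list()
  dG <- 0
  for (m in seq_len(cfg$n_blocks)) {
    g[[paste0("head", m, ".W")]] <- t(cache$G) %*% dOuts[[m]]
    g[[paste0("head", m, ".b")]] <- colSums(dOuts[[m]])
    dG <- dG + dOuts[[m]] %*% t(p[[paste0("head", m, ".W")]])
  }
  dG_in <- dG * gelu_grad(cache$G_in)
  bn3b <- bn_backward(dG_in, cache$bn3)
  g[["bn3.gamma"]] <- bn3b$dgamma
  g[["bn3.beta"]] <- bn3b$dbeta
  dT1 <- bn3b$dx
  g[["dec.W"]] <- t(cache$Z) %*% dT1
  g[["dec.b"]] <- colSums(dT1)
  list(grads = g, dZ = dT1 %*% t(p$dec.W))
}

disc_forward <- function(model, Z) {
  logits <- drop(Z %*% model$params$disc.W) + model$params$disc.b
  stats::plogis(logits)
}

#' Encode a dataset into its integrated latent representation
#'
#' Runs the full encoder pipeline: per-omics sub-networks, concatenation,
#' batch normalization, GELU, sample-wise self-attention (identity when
#' `use_attention = FALSE`), a second batch normalization, a shared
#' fully-connected layer, and the mean / log-variance heads. In inference
#' mode `Z = mu`, batch-norm uses running statistics, and attention spans
#' the full sample set in one pass, so the call is deterministic. In
#' training mode `Z` is a reparameterized draw `mu + exp(log_var/2) * eps`.
#'
#' @param model a trained or initialized `sadln_model`.
#' @param data an [omics_dataset()] or list of block matrices.
#' @param mode `"inference"` (default) or `"train"`.
#' @return An object of class `latent_representation`: list with `Z`, `mu`,
#'   `log_var` (each `N x latent_dim`) and `sample_ids` when available.
#' @export
encode <- function(model, data, mode = c("inference", "train")) {
  mode <- match.arg(mode)
  Xs <- resolve_blocks(model, data)
  fw <- encoder_forward(model, Xs, training = (mode == "train"))
  structure(list(Z = fw$Z, mu = fw$mu, log_var = fw$log_var,
                 sample_ids = if (inherits(data, "omics_dataset")) data$sample_ids),
            class = "latent_representation")
}

#' Reconstruct omics blocks from a latent representation
#'
#' Applies the decoder: a shared fully-connected trunk with batch
#' normalization and GELU, then one linear output head per omics block.
#'
#' @param model a `sadln_model`.
#' @param Z `N x latent_dim` matrix (or a `latent_representation`).
#' @return List of `N x D_m` reconstruction matrices, one per block.
#' @export
decode <- function(model, Z) {
  if (inherits(Z, "latent_representation")) Z <- Z$Z
  Z <- as.matrix(Z)
  if (ncol(Z) != model$config$latent_dim) {
    stop_data("Z has ", ncol(Z), " columns; model latent_dim is ",
              model$config$latent_dim)
  }
  decoder_forward(model, Z, training = FALSE)$outs
}

#' Structured layer and parameter accounting
#'
#' Counts layers the way the architecture table prints them: the encoder
#' contributes input, sub-network/concatenate, batch-norm, activation,
#' attention, batch-norm, fully-connected, mean head, variance head and
#' output rows (10; 9 without attention); the decoder contributes input,
#' fully-connected, batch-norm, activation and output rows (5); the
#' discriminator input, fully-connected, sigmoid and output rows (4).
#'
#' @param model a `sadln_model`.
#' @return An object of class `sadln_summary` with a `layers` data.frame,
#'   per-component counts and the trainable parameter total.
#' @export
model_summary <- function(model) {
  cfg <- model$config
  dk <- cfg$latent_dim
  enc <- data.frame(
    component = "encoder",
    layer = c("input", "sub-networks (concatenate)", "batch-normalization",
              "activation (GELU)",
              if (cfg$use_attention) "self-attention",
              "batch-normalization", "fully-connected",
              "fully-connected (mean)", "fully-connected (log-variance)",
              "output"),
    width = c(sum(cfg$block_input_dims), dk, dk, dk,
              if (cfg$use_attention) dk,
              dk, dk, dk, dk, dk),
    stringsAsFactors = FALSE)
  dec <- data.frame(
    component = "decoder",
    layer = c("input", "fully-connected", "batch-normalization",
              "activation (GELU)", "output"),
    width = c(dk, dk, dk, dk, sum(cfg$block_input_dims)),
    stringsAsFactors = FALSE)
  dis <- data.frame(
    component = "discriminator",
    layer = c("input", "fully-connected", "sigmoid", "output"),
    width = c(dk, 1, 1, 1),
    stringsAsFactors = FALSE)
  layers <- rbind(enc, dec, dis)
  counts <- c(encoder = nrow(enc), decoder = nrow(dec),
              discriminator = nrow(dis), total = nrow(layers))
  n_par <- sum(vapply(model$params, length, numeric(1)))
  structure(list(layers = layers, counts = counts, n_parameters = n_par),
            class = "sadln_summary")
}

#' @export
print.sadln_summary <- function(x, ...) {
  cat("Integration network:", x$counts["total"], "layers (",
      x$counts["encoder"], "encoder /", x$counts["decoder"], "decoder /",
      x$counts["discriminator"], "discriminator ),",
      format(x$n_parameters, big.mark = ","), "trainable parameters\n")
  print(x$layers, row.names = FALSE)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding every parameter tensor, the
#' batch-norm running statistics and the architecture configuration;
#' reloading reproduces inference-mode output bit-exactly.
#' @param model a `sadln_model`.
#' @param path file path.
#' @export
sadln_save <- function(model, path) {
  stopifnot(inherits(model, "sadln_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname sadln_save
#' @export
sadln_load <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sadln_model")) stop_data("not a model checkpoint: ", path)
  model
}
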
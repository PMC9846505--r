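# Adam optimizer state over a named subset of parameters.
adam_init <- function(params, names) {
  list(m = lapply(params[names], function(p) p * 0),
       v = lapply(params[names], function(p) p * 0),
       t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the integration network adversarially
#'
#' Runs the three-phase adversarial-autoencoder schedule on each minibatch:
#' (1) reconstruction — encoder and decoder are updated on
#' `lambda1 * decoder_loss`; (2) discrimination — the discriminator is
#' updated on its binary cross-entropy against a fresh prior sample of the
#' batch size, with encoder outputs detached; (3) regularization — the
#' encoder alone is updated on `lambda2 * g_loss`, pushing the latent
#' distribution toward the `N(0, I)` prior. Optimization is Adam at
#' `config$learning_rate`. Batches are reshuffled every epoch from the run
#' seed and the final incomplete batch is kept. The whole run is
#' deterministic given `config$seed` on a fixed platform.
#'
#' @param data an [omics_dataset()] or list of block matrices (samples in
#'   rows). Features should be on comparable scales; see [zscore_blocks()].
#' @param config an [architecture_config()].
#' @param verbose print per-epoch losses.
#' @return List with `model` (trained `sadln_model`) and `trace` (a
#'   data.frame of per-epoch mean decoder, discriminator, adversarial and
#'   total losses).
#' @export
sadln_train <- function(data, config, verbose = FALSE) {
  stopifnot(inherits(config, "architecture_config"))
  model <- sadln_init(config)
  Xs <- resolve_blocks(model, data)
  n <- nrow(Xs[[1]])
  if (config$epochs == 0) {
    return(list(model = model,
                trace = data.frame(epoch = integer(0), decoder_loss = numeric(0),
                                   discriminator_loss = numeric(0),
                                   adversarial_loss = numeric(0),
                                   total_loss = numeric(0))))
  }
  enc_names <- encoder_param_names(config)
  dec_names <- decoder_param_names(config)
  dk <- config$latent_dim
  M <- config$n_blocks
  lr <- config$learning_rate

  with_seed(config$seed, {
    opt_rec <- adam_init(model$params, c(enc_names, dec_names))
    opt_dis <- adam_init(model$params, c("disc.W", "disc.b"))
    opt_adv <- adam_init(model$params, enc_names)
    trace <- matrix(NA_real_, config$epochs, 4)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      ep_loss <- c(0, 0, 0)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        nb <- length(idx)
        Xb <- lapply(Xs, function(x) x[idx, , drop = FALSE])

        ## phase 1: reconstruction
        eps <- matrix(stats::rnorm(nb * dk), nb, dk)
        ef <- encoder_forward(model, Xb, training = TRUE, eps = eps)
        model$bn_stats[c("bn1", "bn2")] <- ef$bn_stats
        df <- decoder_forward(model, ef$Z, training = TRUE)
        model$bn_stats["bn3"] <- df$bn_stats
        l_dec <- decoder_loss(Xb, df$outs)
        if (!is.finite(l_dec)) {
          stop_numerical("training diverged (non-finite reconstruction loss) at epoch ", epoch)
        }
        dOuts <- lapply(seq_len(M), function(m) {
          config$lambda1 * 2 * (df$outs[[m]] - Xb[[m]]) / (M * nb)
        })
        db <- decoder_backward(model, df$cache, dOuts)
        ge <- encoder_backward(model, ef$cache, db$dZ)
        upd <- adam_step(model$params, c(ge, db$grads), opt_rec, lr)
        model$params <- upd$params
        opt_rec <- upd$state

        ## phase 2: discriminator (encoder outputs detached)
        z_prior <- matrix(stats::rnorm(nb * dk), nb, dk)
        z_gen <- ef$Z
        p_prior <- pmin(pmax(disc_forward(model, z_prior), DISC_EPS), 1 - DISC_EPS)
        p_gen <- pmin(pmax(disc_forward(model, z_gen), DISC_EPS), 1 - DISC_EPS)
        l_disc <- -mean(log(p_prior)) - mean(log(1 - p_gen))
        if (!is.finite(l_disc)) {
          stop_numerical("training diverged (non-finite discriminator loss) at epoch ", epoch)
        }
        dlogit_prior <- (p_prior - 1) / nb
        dlogit_gen <- p_gen / nb
        gd <- list(
          disc.W = t(z_prior) %*% dlogit_prior + t(z_gen) %*% dlogit_gen,
          disc.b = sum(dlogit_prior) + sum(dlogit_gen))
        upd <- adam_step(model$params, gd, opt_dis, lr)
        model$params <- upd$params
        opt_dis <- upd$state

        ## phase 3: adversarial regularization of the encoder
        eps2 <- matrix(stats::rnorm(nb * dk), nb, dk)
        ef2 <- encoder_forward(model, Xb, training = TRUE, eps = eps2)
        model$bn_stats[c("bn1", "bn2")] <- ef2$bn_stats
        p2 <- pmin(pmax(disc_forward(model, ef2$Z), DISC_EPS), 1 - DISC_EPS)
        l_adv <- -mean(log(p2))
        dZ <- config$lambda2 * ((p2 - 1) / nb) %*% t(model$params$disc.W)
        ga <- encoder_backward(model, ef2$cache, dZ)
        upd <- adam_step(model$params, ga, opt_adv, lr)
        model$params <- upd$params
        opt_adv <- upd$state

        ep_loss <- ep_loss + nb * c(l_dec, l_disc, l_adv)
      }
      ep_loss <- ep_loss / n
      trace[epoch, ] <- c(ep_loss, total_loss(ep_loss[1], ep_loss[3],
                                              config$lambda1, config$lambda2))
      if (verbose) {
        message(sprintf("epoch %d: decoder %.5f discr %.5f adv %.5f",
                        epoch, ep_loss[1], ep_loss[2], ep_loss[3]))
      }
    }
    model$epochs_trained <- config$epochs
    trace <- data.frame(epoch = seq_len(config$epochs),
                        decoder_loss = trace[, 1],
                        discriminator_loss = trace[, 2],
                        adversarial_loss = trace[, 3],
                        total_loss = trace[, 4])
    list(model = model, trace = trace)
  })
}
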
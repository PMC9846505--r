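DISC_EPS <- 1e-7

#' Reconstruction loss
#'
#' Mean over the M omics blocks of the squared Frobenius distance between
#' input and reconstruction, averaged over the samples in the batch:
#' `L = (1/N) * (1/M) * sum_m ||X_I^m - X_O^m||^2`.
#'
#' @param X_I input blocks: an [omics_dataset()] or list of matrices.
#' @param X_O reconstructed blocks (list of matrices of matching shapes).
#' @return Nonnegative scalar; zero iff the reconstruction is exact.
#' @export
decoder_loss <- function(X_I, X_O) {
  if (inherits(X_I, "omics_dataset")) X_I <- unname(block_matrices(X_I))
  if (length(X_I) != length(X_O)) stop_data("block count mismatch")
  M <- length(X_I)
  n <- nrow(as.matrix(X_I[[1]]))
  total <- 0
  for (m in seq_len(M)) {
    a <- as.matrix(X_I[[m]]); b <- as.matrix(X_O[[m]])
    if (!all(dim(a) == dim(b))) stop_data("shape mismatch in block ", m)
    total <- total + sum((a - b)^2)
  }
  total / (M * n)
}

#' Adversarial losses of the discriminator and the generator
#'
#' The discriminator is trained to output 1 on draws from the latent prior
#' and 0 on encoder outputs; its loss is the binary cross-entropy
#' `-E[log D(z')] - E[log(1 - D(z))]` with the encoder outputs detached.
#' The generator (encoder) minimizes the non-saturating objective
#' `-E[log D(z)]`. Discriminator outputs are clamped to
#' `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param D a `sadln_model` (its discriminator head is used) or a function
#'   mapping a latent matrix to probabilities in (0, 1).
#' @param z_prior matrix of draws from the latent prior `N(0, I)`.
#' @param z_gen matrix of encoder outputs.
#' @return List with scalars `d_loss` and `g_loss`.
#' @export
discriminator_losses <- function(D, z_prior, z_gen) {
  if (nrow(as.matrix(z_prior)) == 0 || nrow(as.matrix(z_gen)) == 0) {
    stop_data("empty batch in discriminator loss")
  }
  f <- if (inherits(D, "sadln_model")) function(z) disc_forward(D, z) else D
  p_prior <- pmin(pmax(f(z_prior), DISC_EPS), 1 - DISC_EPS)
  p_gen <- pmin(pmax(f(z_gen), DISC_EPS), 1 - DISC_EPS)
  list(d_loss = -mean(log(p_prior)) - mean(log(1 - p_gen)),
       g_loss = -mean(log(p_gen)))
}

#' Total generator-side loss
#'
#' Weighted sum `lambda1 * l_dec + lambda2 * l_adv` applied to the encoder /
#' decoder update. `lambda2 = 0` removes the adversarial regularization;
#' `lambda1 = 0` removes the reconstruction objective (the two ablations).
#'
#' @param l_dec reconstruction loss.
#' @param l_adv generator adversarial loss.
#' @param lambda1,lambda2 weights in `[0, 1]`.
#' @return Scalar.
#' @export
total_loss <- function(l_dec, l_adv, lambda1, lambda2) {
  lambda1 * l_dec + lambda2 * l_adv
}
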
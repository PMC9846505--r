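#' Gaussian Error Linear Unit
#'
#' Exact form `x * pnorm(x)` (standard normal CDF), not the tanh
#' approximation.
#' @param x numeric vector or matrix.
#' @return Elementwise GELU of `x`.
#' @export
gelu <- function(x) x * stats::pnorm(x)

# d/dx [x Phi(x)] = Phi(x) + x phi(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

#' Sample-wise scaled dot-product self-attention
#'
#' Treats each sample's fused feature vector as a token: keys, queries and
#' values are linear projections of the same matrix, pairwise similarities
#' are scaled by `1/sqrt(d_k)`, and each output row is the softmax-weighted
#' combination of value rows. The returned weight matrix is row-stochastic
#' and encodes the learned sample-sample relationships.
#'
#' @param Yp numeric matrix, `N x d_k`, the fused per-sample features.
#' @param W_K,W_Q,W_V projection matrices, each `d_k x d_k`.
#' @return A list with `Z` (`N x d_k` attended output) and `weights`
#'   (`N x N` row-stochastic attention matrix).
#' @export
self_attention <- function(Yp, W_K, W_Q, W_V) {
  fw <- attention_forward(Yp, W_K, W_Q, W_V)
  list(Z = fw$Z, weights = fw$W)
}

attention_forward <- function(Yp, W_K, W_Q, W_V) {
  dk <- ncol(Yp)
  K <- Yp %*% W_K
  Q <- Yp %*% W_Q
  V <- Yp %*% W_V
  S <- (Q %*% t(K)) / sqrt(dk)
  if (any(!is.finite(S))) stop_numerical("non-finite attention scores")
  W <- softmax_rows(S)
  list(Z = W %*% V, W = W, K = K, Q = Q, V = V, Yp = Yp, dk = dk)
}

attention_backward <- function(dZ, cache, W_K, W_Q, W_V) {
  W <- cache$W
  dV <- t(W) %*% dZ
  dW <- dZ %*% t(cache$V)
  # softmax backward, row-wise: dS_i = W_i * (dW_i - sum_j dW_ij W_ij)
  dS <- W * (dW - rowSums(dW * W))
  dQ <- (dS %*% cache$K) / sqrt(cache$dk)
  dK <- (t(dS) %*% cache$Q) / sqrt(cache$dk)
  list(
    dYp = dQ %*% t(W_Q) + dK %*% t(W_K) + dV %*% t(W_V),
    dW_K = t(cache$Yp) %*% dK,
    dW_Q = t(cache$Yp) %*% dQ,
    dW_V = t(cache$Yp) %*% dV
  )
}

# Batch normalization over samples (one mean/variance per feature column).
# Training mode normalizes with batch statistics (population 1/N variance)
# and updates the running statistics in place; inference mode uses the
# stored running statistics.
bn_init <- function(dim) {
  list(gamma = rep(1, dim), beta = rep(0, dim))
}

bn_stats_init <- function(dim) {
  list(mean = rep(0, dim), var = rep(1, dim))
}

bn_forward <- function(x, par, stats, training, momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    stats_new <- list(mean = momentum * stats$mean + (1 - momentum) * mu,
                      var = momentum * stats$var + (1 - momentum) * v)
  } else {
    mu <- stats$mean
    v <- stats$var
    xc <- sweep(x, 2, mu)
    stats_new <- stats
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_sd, "*")
  y <- sweep(sweep(xhat, 2, par$gamma, "*"), 2, par$beta, "+")
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, gamma = par$gamma,
                           n = nrow(x), training = training),
       stats = stats_new)
}

bn_backward <- function(dy, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$gamma, "*")
  if (cache$training) {
    n <- cache$n
    t1 <- sweep(dxhat, 2, colSums(dxhat) / n)
    t2 <- sweep(xhat, 2, colSums(dxhat * xhat) / n, "*")
    dx <- sweep(t1 - t2, 2, cache$inv_sd, "*")
  } else {
    dx <- sweep(dxhat, 2, cache$inv_sd, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}
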